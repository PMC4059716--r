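# Shared fixtures built in code.

toy_matrix <- function(values = 1:6, nprobe = 2, nsample = 3) {
  matrix(as.numeric(values), nprobe, nsample, byrow = TRUE,
         dimnames = list(paste0("p", seq_len(nprobe)),
                         paste0("s", seq_len(nsample))))
}

toy_labels <- function(n1 = 2, n0 = 2) {
  stats::setNames(rep(c(1L, 0L), c(n1, n0)),
                  paste0("s", seq_len(n1 + n0)))
}

# brute-force AUC oracle: all-pairs counting with half-credit for ties
auc_bruteforce <- function(neg, pos) {
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# exhaustive-threshold pAUC oracle: enumerate all thresholds, build the
# empirical ROC polygon point by point, integrate trapezoids up to t0
pauc_bruteforce <- function(neg, pos, t0) {
  thr <- sort(unique(c(neg, pos, Inf)), decreasing = TRUE)
  fpr <- numeric(0); tpr <- numeric(0)
  for (v in thr) {
    fpr <- c(fpr, sum(neg >= v) / length(neg))
    tpr <- c(tpr, sum(pos >= v) / length(pos))
  }
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= t0) break
    if (x1 > t0) {  # clip the segment at t0
      y1 <- y0 + (y1 - y0) * (t0 - x0) / (x1 - x0)
      x1 <- t0
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

# classical pooled two-sample t statistic, one probe
pooled_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  s2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  (mean(x1) - mean(x0)) / sqrt(s2 * (1 / n1 + 1 / n0))
}
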