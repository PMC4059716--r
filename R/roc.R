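#' Empirical area under the ROC curve
#'
#' Computes the full area under the empirical ROC curve of a single marker,
#' which equals the normalized Mann-Whitney statistic
#' P(pos > neg) + 0.5 P(pos = neg). Ties contribute one half, matching the
#' trapezoidal area of the tied (sloped) ROC segments.
#'
#' @param neg Marker values in the negative (control, label 0) class.
#' @param pos Marker values in the positive (case, label 1) class.
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' empirical_auc(c(1, 2, 3), c(4, 5, 6))  # 1: complete separation
#' empirical_auc(c(1, 3), c(2, 4))        # 0.75
empirical_auc <- function(neg, pos) {
  if (length(neg) == 0 || length(pos) == 0)
    stop("both classes must be non-empty", call. = FALSE)
  if (!all(is.finite(neg)) || !all(is.finite(pos)))
    stop("marker values must be finite", call. = FALSE)
  r <- rank(c(neg, pos))
  np <- length(pos)
  nn <- length(neg)
  (sum(r[nn + seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# Empirical ROC curve vertices as (fpr, tpr) pairs in increasing fpr order,
# using the >= threshold convention; tied pooled values produce the sloped
# segments of the trapezoidal convention.
roc_points <- function(neg, pos) {
  u <- sort(unique(c(neg, pos)), decreasing = TRUE)
  fpr <- vapply(u, function(v) mean(neg >= v), numeric(1))
  tpr <- vapply(u, function(v) mean(pos >= v), numeric(1))
  cbind(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Empirical partial AUC
#'
#' Trapezoidal area under the empirical ROC curve restricted to
#' false-positive rates in `[0, t0]`, with linear interpolation of the
#' curve at `t0`. At `t0 = 1` this equals [empirical_auc()].
#'
#' @inheritParams empirical_auc
#' @param t0 Upper false-positive-rate bound, in `(0, 1]`. Default 0.1.
#' @return The partial AUC in `[0, t0]`.
#' @export
empirical_pauc <- function(neg, pos, t0 = 0.1) {
  if (!is.numeric(t0) || length(t0) != 1 || t0 <= 0 || t0 > 1)
    stop("t0 must lie in (0, 1]", call. = FALSE)
  if (length(neg) == 0 || length(pos) == 0)
    stop("both classes must be non-empty", call. = FALSE)
  pts <- roc_points(neg, pos)
  x <- pts[, "fpr"]
  y <- pts[, "tpr"]
  # truncate the piecewise-linear curve at fpr = t0
  if (t0 < 1) {
    i <- findInterval(t0, x, rightmost.closed = TRUE)
    if (x[i] < t0) {
      seg <- i + 1L  # first vertex beyond t0
      yi <- y[i] + (y[seg] - y[i]) * (t0 - x[i]) / (x[seg] - x[i])
      x <- c(x[seq_len(i)], t0)
      y <- c(y[seq_len(i)], yi)
    } else {
      x <- x[seq_len(i)]
      y <- y[seq_len(i)]
    }
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Per-probe ROC scores
#'
#' Computes AUC and partial AUC for every probe, treating class-1 samples
#' as positives and class-0 samples as negatives.
#'
#' @param m Expression matrix (probes x samples).
#' @param labels Named 0/1 vector aligned to the matrix columns.
#' @param t0 Partial-AUC false-positive-rate bound.
#' @return A data frame with columns probe_id, auc, pauc, t0.
#' @export
roc_scores <- function(m, labels, t0 = 0.1) {
  validate_expression_matrix(m)
  stopifnot(identical(colnames(m), names(labels)))
  check_two_classes(labels)
  posi <- labels == 1
  auc <- apply(m, 1, function(x) empirical_auc(x[!posi], x[posi]))
  pauc <- apply(m, 1, function(x) empirical_pauc(x[!posi], x[posi], t0))
  data.frame(probe_id = rownames(m), auc = auc, pauc = pauc, t0 = t0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank probes by ROC separation
#'
#' Orders probes by how well each separates the two phenotype groups as a
#' univariate classifier. By default the criterion is two-sided, so under-
#' and over-expressed probes rank equally well: for AUC the score is
#' max(AUC, 1 - AUC); for pAUC the partial area is computed in both class
#' orientations and the larger is used. Ties keep input probe order.
#'
#' @inheritParams roc_scores
#' @param criterion `"auc"` (default) or `"pauc"`.
#' @param one_sided If `TRUE`, rank by the raw class-1-positive criterion.
#' @return A [ranked_list()] (score semantics: higher is better).
#' @export
roc_rank <- function(m, labels, t0 = 0.1, criterion = c("auc", "pauc"),
                     one_sided = FALSE) {
  criterion <- match.arg(criterion)
  sc <- roc_scores(m, labels, t0 = t0)
  if (criterion == "auc") {
    s <- if (one_sided) sc$auc else pmax(sc$auc, 1 - sc$auc)
  } else {
    if (one_sided) {
      s <- sc$pauc
    } else {
      posi <- labels == 1
      pauc_rev <- apply(m, 1, function(x) empirical_pauc(x[posi], x[!posi], t0))
      s <- pmax(sc$pauc, pauc_rev)
    }
  }
  ord <- order(-s)  # stable: ties resolve to input probe order
  out <- ranked_list("roc", sc$probe_id[ord], s[ord])
  attr(out, "roc_scores") <- sc
  out
}
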