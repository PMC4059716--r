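#' Per-probe log fold change
#'
#' Difference of group mean log-intensities, case (label 1) minus control
#' (label 0). With log2 input this is the log2 fold change.
#'
#' @param m Expression matrix (probes x samples).
#' @param labels Named 0/1 vector aligned to matrix columns.
#' @return Named numeric vector of per-probe log fold changes.
#' @export
log_fold_change <- function(m, labels) {
  validate_expression_matrix(m)
  stopifnot(identical(colnames(m), names(labels)))
  check_two_classes(labels)
  rowMeans(m[, labels == 1, drop = FALSE]) -
    rowMeans(m[, labels == 0, drop = FALSE])
}

# Newton inversion of the trigamma function (psi'(x) = y, y > 0),
# needed to solve the method-of-moments equation for the prior df.
trigamma_inverse <- function(y) {
  if (y <= 0) stop("trigamma_inverse requires y > 0", call. = FALSE)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes prior for residual variances
#'
#' Fits a shared scaled inverse chi-square prior (prior df `d0`, prior
#' variance `s0_sq`) to a set of per-probe residual variances by the
#' method of moments on the log variances: the sample variance of
#' log(s^2), in excess of the trigamma term implied by the residual df,
#' identifies `d0` via trigamma inversion, and the mean of log(s^2)
#' identifies `s0_sq` via the digamma correction. When the observed
#' log-variance spread does not exceed the chi-square prediction, `d0` is
#' infinite and all variances shrink fully to `s0_sq`.
#'
#' @param s2 Per-probe residual variances (non-negative).
#' @param df Residual degrees of freedom shared by all probes.
#' @return List with elements `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  if (df <= 0) stop("residual df must be positive", call. = FALSE)
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("degenerate variance moments: no probe has positive residual variance",
         call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-test
#'
#' Per-probe two-sample comparison with empirical-Bayes variance
#' moderation: the pooled residual variance of each probe (df = n - 2) is
#' shrunk toward a shared prior variance estimated across probes by
#' [fit_variance_prior()], giving the posterior variance
#' s2_post = (d0 s0^2 + d s^2) / (d0 + d). The moderated statistic is the
#' log fold change divided by its posterior standard error, referred to a
#' t distribution with d0 + d degrees of freedom (capped at 1e6 when the
#' prior df is infinite).
#'
#' @param m Expression matrix (probes x samples).
#' @param labels Named 0/1 vector aligned to matrix columns; each class
#'   needs at least 2 samples.
#' @param prior_df Optional prior df override. `0` reproduces the
#'   classical pooled t-test; `Inf` shrinks every variance fully to the
#'   shared prior; `NULL` (default) estimates it from the data.
#' @param adjust Multiple-testing adjustment filling the `p_adj` column:
#'   `"bonferroni"` (default) or `"bh"`.
#' @return A `moderated_t` data frame with columns probe_id, logfc, t, p,
#'   p_adj; the shared prior is attached as attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(m, labels, prior_df = NULL,
                        adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  validate_expression_matrix(m)
  stopifnot(identical(colnames(m), names(labels)))
  check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 < 2 || n0 < 2)
    stop("each class needs at least 2 samples", call. = FALSE)

  lfc <- log_fold_change(m, labels)
  v1 <- row_vars(m[, labels == 1, drop = FALSE])
  v0 <- row_vars(m[, labels == 0, drop = FALSE])
  d <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d

  prior <- fit_variance_prior(s2, d)
  d0 <- if (is.null(prior_df)) prior$d0 else prior_df
  s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)

  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  t_mod <- lfc / se
  df_total <- min(d0 + d, 1e6)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- data.frame(probe_id = rownames(m), logfc = unname(lfc),
                    t = unname(t_mod), p = unname(p),
                    p_adj = adjust_p(unname(p), adjust),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- d
  class(out) <- c("moderated_t", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjusted
#' p-values.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param method `"bonferroni"` (default) or `"bh"`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_p <- function(p_values, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

#' Fold-change and significance gate
#'
#' Keeps probes with `|logfc| > lfc_threshold` (or `logfc > lfc_threshold`
#' when `two_sided = FALSE`) and adjusted p-value `< alpha`.
#'
#' @param results A `moderated_t` data frame (columns logfc, p_adj).
#' @param lfc_threshold Log fold-change threshold. Default 2.
#' @param alpha Adjusted-p threshold. Default 0.01.
#' @param two_sided Gate on `|logfc|` (default) or on `logfc` only.
#' @return Character vector of passing probe ids, in input order.
#' @export
significance_gate <- function(results, lfc_threshold = 2, alpha = 0.01,
                              two_sided = TRUE) {
  if (nrow(results) == 0) stop("empty result set", call. = FALSE)
  fc <- if (two_sided) abs(results$logfc) else results$logfc
  results$probe_id[fc > lfc_threshold & results$p_adj < alpha]
}

#' Write a moderated-t table as TSV
#'
#' Column layout mirrors the conventional differential-expression report:
#' probe_id, logFC, t, P-value, adjusted P-value.
#'
#' @param results A `moderated_t` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_moderated_t <- function(results, path) {
  df <- data.frame(probe_id = results$probe_id, logFC = results$logfc,
                   t = results$t, `P-value` = results$p,
                   `adjusted P-value` = results$p_adj, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
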