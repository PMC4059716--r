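#' Variance-based probe filtering
#'
#' Removes the fraction of probes with the lowest overall (label-blind)
#' sample variance, the customary unsupervised pre-filter applied to
#' microarray matrices before feature selection. The threshold is the
#' empirical `remove_fraction` quantile (type 7, linear interpolation) of
#' the per-probe variances; probes with variance greater than or equal to
#' the threshold are retained, so a probe sitting exactly on the threshold
#' survives. Input probe order is preserved.
#'
#' @param m Expression matrix (probes x samples), at least 2 samples.
#' @param remove_fraction Fraction in `[0, 1)` of lowest-variance probes to
#'   remove. Default 0.5, which halves a full-size array matrix.
#' @return The filtered expression matrix.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 2, 1, 3, 1, 4), nrow = 4, byrow = TRUE,
#'             dimnames = list(paste0("p", 1:4), c("s1", "s2")))
#' nrow(variance_filter(m, 0.5))  # 2 highest-variance probes kept
variance_filter <- function(m, remove_fraction = 0.5) {
  validate_expression_matrix(m)
  if (ncol(m) < 2)
    stop("variance filter requires at least 2 samples", call. = FALSE)
  if (!is.numeric(remove_fraction) || length(remove_fraction) != 1 ||
      remove_fraction < 0 || remove_fraction >= 1)
    stop("remove_fraction must lie in [0, 1)", call. = FALSE)
  if (remove_fraction == 0) return(m)
  v <- row_vars(m)
  thr <- stats::quantile(v, probs = remove_fraction, names = FALSE, type = 7)
  m[v >= thr, , drop = FALSE]
}

# per-probe sample variance, denominator n - 1
row_vars <- function(m) {
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}
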