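#' SVM recursive feature elimination ranking
#'
#' Ranks probes by recursive feature elimination with a linear two-class
#' support vector machine: at each pass a linear SVM is trained on the
#' surviving features, the ranking criterion c_i = w_i^2 is computed from
#' the primal weight vector w, and the `step` features with the smallest
#' criterion are eliminated. The final ranking lists features in reverse
#' elimination order (last survivor first); within an eliminated chunk,
#' larger-criterion features rank better. Ties in the criterion are broken
#' by eliminating the lower column index first, so the tied feature that
#' appears later in the matrix ranks better.
#'
#' The linear kernel is required by the weight-based criterion. Features
#' are standardized to zero mean / unit variance (computed over all
#' samples) before the elimination loop; constant features standardize to
#' zero and drop out first.
#'
#' @param m Expression matrix (probes x samples).
#' @param labels Named 0/1 vector aligned to matrix columns; both classes
#'   must be present.
#' @param cost Soft-margin cost of the linear SVM. Default 1.
#' @param step Features eliminated per pass. `NULL` (default) uses an
#'   adaptive schedule: 10% of survivors per pass while more than 500
#'   remain, then one at a time, so ranks near the top are produced by
#'   strict one-at-a-time elimination.
#' @param standardize Standardize features before the loop. Default `TRUE`.
#' @return A [ranked_list()] with score semantics "rank position" (the
#'   score of a probe is its rank, 1 = best).
#' @export
svm_rfe_rank <- function(m, labels, cost = 1, step = NULL, standardize = TRUE) {
  validate_expression_matrix(m)
  stopifnot(identical(colnames(m), names(labels)))
  check_two_classes(labels)
  if (!all(is.finite(m))) stop("non-finite expression values", call. = FALSE)
  if (!is.null(step) && (step < 1 || step != round(step)))
    stop("step must be a positive integer", call. = FALSE)

  p <- nrow(m)
  probes <- rownames(m)
  if (p == 1L) return(ranked_list("svm-rfe", probes, 1, "rank position"))

  x <- t(m)
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant probes carry no signal
  }
  y <- factor(labels, levels = c(0, 1))

  surviving <- seq_len(p)
  eliminated <- integer(0)
  while (length(surviving) > 0) {
    ns <- length(surviving)
    if (ns == 1L) {
      eliminated <- c(eliminated, surviving)
      break
    }
    fit <- e1071::svm(x[, surviving, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    crit <- w^2
    st <- if (is.null(step)) {
      if (ns > 500) max(1L, floor(0.1 * ns)) else 1L
    } else {
      as.integer(step)
    }
    st <- min(st, ns)
    # ascending criterion; order() is stable, so ties fall to lower index
    drop_local <- order(crit)[seq_len(st)]
    eliminated <- c(eliminated, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  ranked_idx <- rev(eliminated)
  ranked_list("svm-rfe", probes[ranked_idx], seq_len(p), "rank position")
}
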