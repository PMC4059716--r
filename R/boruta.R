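#' All-relevant feature selection with shadow attributes
#'
#' An in-package implementation of the shadow-attribute ("Boruta")
#' all-relevant selection scheme on top of a random-forest learner. Each
#' iteration (a) builds a shadow copy of every still-undecided feature by
#' independently permuting its values across samples, (b) trains a random
#' forest on the real (not-yet-rejected) plus shadow features, (c) computes
#' each feature's permutation-importance Z-score, (d) scores a "hit" for a
#' real feature whose Z exceeds the maximum shadow Z, and (e) applies a
#' two-sided binomial test to each undecided feature's accumulated hit
#' count (Bonferroni-corrected across the undecided features), moving
#' clearly-above-chance features to `confirmed` and clearly-at-chance
#' features to `rejected`. The loop stops when every feature is decided or
#' after `max_iterations`; undecided features remain `tentative`.
#'
#' The Z-score is the forest's scaled permutation importance (mean accuracy
#' decrease over trees divided by its spread over trees); non-finite scores
#' from degenerate (e.g. constant) features count as zero and can never
#' beat a shadow.
#'
#' @param m Expression matrix (probes x samples).
#' @param labels Named 0/1 vector aligned to matrix columns.
#' @param n_trees Trees per forest. Default 500.
#' @param max_iterations Maximum shadow iterations. Default 100.
#' @param alpha Significance level of the hit test. Default 0.05.
#' @param seed Integer seed; the run is reproducible given it.
#' @return A `boruta_result` list: `decisions` (named character vector,
#'   one of confirmed/tentative/rejected per probe), `zscores` (iterations
#'   x probes matrix of per-iteration Z-scores, NA once a probe leaves the
#'   model), `n_iterations`, `hits`, `trials`.
#' @export
boruta_select <- function(m, labels, n_trees = 500, max_iterations = 100,
                          alpha = 0.05, seed = 1) {
  validate_expression_matrix(m)
  stopifnot(identical(colnames(m), names(labels)))
  check_two_classes(labels)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)

  x <- t(m)
  p <- ncol(x)
  probes <- rownames(m)
  y <- factor(labels, levels = c(0, 1))

  decisions <- stats::setNames(rep("tentative", p), probes)
  hits <- stats::setNames(integer(p), probes)
  trials <- 0L
  zhist <- list()
  # constant features can never earn importance and (all-constant) stall
  # the forest; keep them out of the model with Z fixed at 0
  varying <- apply(x, 2, function(col) length(unique(col)) > 1L)

  withr::with_seed(seed, {
    for (iter in seq_len(max_iterations)) {
      und <- which(decisions == "tentative")
      if (length(und) == 0L) break
      in_model <- which(decisions != "rejected")
      shadow <- apply(x[, und, drop = FALSE], 2, sample)
      xx <- cbind(x[, in_model, drop = FALSE], shadow)
      colnames(xx) <- c(probes[in_model], paste0(".shadow.", probes[und]))
      use <- c(varying[in_model], varying[und])
      z <- stats::setNames(rep(0, ncol(xx)), colnames(xx))
      if (any(use)) {
        rf <- randomForest::randomForest(xx[, use, drop = FALSE], y,
                                         ntree = n_trees, importance = TRUE)
        zi <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
        zi[!is.finite(zi)] <- 0
        z[use] <- zi
      }
      z_real <- z[seq_along(in_model)]
      z_shadow_max <- max(z[-seq_along(in_model)])
      zrow <- rep(NA_real_, p)
      zrow[in_model] <- z_real
      zhist[[iter]] <- zrow

      und_pos <- match(und, in_model)
      hits[und] <- hits[und] + (z_real[und_pos] > z_shadow_max)
      trials <- trials + 1L

      m_und <- length(und)
      p_conf <- stats::pbinom(hits[und] - 1L, trials, 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[und], trials, 0.5)
      decisions[und[p_conf < alpha / m_und]] <- "confirmed"
      decisions[und[p_rej < alpha / m_und]] <- "rejected"
    }
  })

  zscores <- do.call(rbind, zhist)
  colnames(zscores) <- probes
  structure(list(decisions = decisions, zscores = zscores,
                 n_iterations = length(zhist), hits = hits, trials = trials,
                 alpha = alpha, seed = seed),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decisions, c("confirmed", "tentative", "rejected")))
  cat(sprintf(
    "Shadow-attribute selection: %d iterations; %d confirmed, %d tentative, %d rejected\n",
    x$n_iterations, tab["confirmed"], tab["tentative"], tab["rejected"]))
  invisible(x)
}

#' Probes confirmed by the shadow-attribute selector
#'
#' @param result A `boruta_result`.
#' @param include_tentative Also return tentative probes. Default `FALSE`.
#' @return Character vector of probe ids.
#' @export
boruta_confirmed <- function(result, include_tentative = FALSE) {
  keep <- if (include_tentative) c("confirmed", "tentative") else "confirmed"
  names(result$decisions)[result$decisions %in% keep]
}

#' Rank probes by shadow-attribute relevance
#'
#' Orders probes by decision tier (confirmed, then tentative, then
#' rejected) and, within a tier, by descending median per-iteration
#' Z-score. Useful for top-fraction comparisons against the other rankers.
#'
#' @param result A `boruta_result`.
#' @return A [ranked_list()] whose score is the median Z-score.
#' @export
boruta_rank <- function(result) {
  med_z <- apply(result$zscores, 2, stats::median, na.rm = TRUE)
  med_z[!is.finite(med_z)] <- -Inf
  tier <- match(result$decisions, c("confirmed", "tentative", "rejected"))
  ord <- order(tier, -med_z)
  ranked_list("boruta", names(result$decisions)[ord], med_z[ord])
}

#' Write shadow-attribute decisions as TSV
#'
#' Columns: probe_id, decision, median_z.
#'
#' @param result A `boruta_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boruta_decisions <- function(result, path) {
  med_z <- apply(result$zscores, 2, stats::median, na.rm = TRUE)
  utils::write.table(
    data.frame(probe_id = names(result$decisions),
               decision = unname(result$decisions),
               median_z = unname(med_z)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
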