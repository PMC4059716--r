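#' Top-k probes of a ranked list
#'
#' @param ranked A [ranked_list()].
#' @param k Number of leading probes, `1 <= k <= nrow(ranked)`.
#' @return Character vector of the first `k` probe ids.
#' @export
top_k <- function(ranked, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > nrow(ranked) ||
      k != round(k))
    stop("k must be an integer in [1, ", nrow(ranked), "]", call. = FALSE)
  ranked$probe_id[seq_len(k)]
}

#' Intersect per-ranker candidate sets into a consensus panel
#'
#' @param sets Named list (>= 2 elements) of probe-id character vectors,
#'   one per ranker.
#' @return A `consensus_panel`: `selected` (the intersection, ordered by
#'   appearance in the first set), `membership` (for every probe in the
#'   union, which rankers proposed it), `k`, `provenance`.
#' @export
consensus_panel <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 candidate sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("candidate sets must be named by ranker", call. = FALSE)
  sets <- lapply(sets, unique)
  selected <- Reduce(intersect, sets)
  all_probes <- unique(unlist(sets, use.names = FALSE))
  membership <- lapply(stats::setNames(all_probes, all_probes), function(pr)
    names(sets)[vapply(sets, function(s) pr %in% s, logical(1))])
  structure(list(selected = selected, membership = membership,
                 set_sizes = vapply(sets, length, integer(1)),
                 k = NA_integer_, provenance = NULL),
            class = "consensus_panel")
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat(sprintf("Consensus panel: %d probe(s) in the intersection of %d sets (sizes: %s)\n",
              length(x$selected), length(x$set_sizes),
              paste(sprintf("%s=%d", names(x$set_sizes), x$set_sizes),
                    collapse = ", ")))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Combined three-ranker feature selection
#'
#' Runs the full selection procedure on an aligned two-group matrix:
#' (1) SVM-RFE ranking and (2) ROC ranking, each cut to its top `k`
#' probes; (3) the shadow-attribute selector, contributing its confirmed
#' probes; (4) a moderated-t significance gate applied to the two top-k
#' sets (fold change and adjusted p-value, with the multiplicity
#' correction computed within each gated set -- those k candidates are the
#' hypotheses under test -- while the variance prior is estimated from all
#' probes); (5) the intersection of the three resulting sets.
#'
#' @param m Expression matrix (probes x samples), already filtered.
#' @param labels Named 0/1 vector; will be aligned to the matrix.
#' @param k Top-list size for SVM-RFE and ROC. Default
#'   `ceiling(0.0366 * nrow(m))`, the study-scale ratio of a top-1,000
#'   cut on a 27,336-probe matrix.
#' @param lfc_threshold,alpha,adjust Gate parameters; defaults 2, 0.01,
#'   bonferroni. See [significance_gate()] and [adjust_p()].
#' @param gate Apply the significance gate to the SVM-RFE and ROC sets
#'   before intersecting. Default `TRUE`.
#' @param include_tentative Let tentative shadow-selector probes into its
#'   set. Default `FALSE`.
#' @param t0,roc_criterion,one_sided_roc ROC ranker parameters.
#' @param cost,rfe_step SVM-RFE parameters.
#' @param boruta_trees,boruta_max_iter,boruta_alpha Shadow-selector
#'   parameters.
#' @param seed Integer seed driving the stochastic stages.
#' @return A `consensus_panel` whose `selected` probes are ordered by
#'   matrix probe order; `provenance` holds the three ranked lists /
#'   decisions, the moderated-t table, the gated sets and the full
#'   configuration.
#' @export
select_features <- function(m, labels,
                            k = NULL,
                            lfc_threshold = 2, alpha = 0.01,
                            adjust = c("bonferroni", "bh"),
                            gate = TRUE,
                            include_tentative = FALSE,
                            t0 = 0.1, roc_criterion = "auc",
                            one_sided_roc = FALSE,
                            cost = 1, rfe_step = NULL,
                            boruta_trees = 500, boruta_max_iter = 100,
                            boruta_alpha = 0.05,
                            seed = 1) {
  adjust <- match.arg(adjust)
  al <- align_samples(m, labels)
  m <- al$matrix
  labels <- al$labels
  if (is.null(k)) k <- min(nrow(m), ceiling(0.0366 * nrow(m)))

  rfe <- svm_rfe_rank(m, labels, cost = cost, step = rfe_step)
  roc <- roc_rank(m, labels, t0 = t0, criterion = roc_criterion,
                  one_sided = one_sided_roc)
  bor <- boruta_select(m, labels, n_trees = boruta_trees,
                       max_iterations = boruta_max_iter,
                       alpha = boruta_alpha, seed = seed)
  sets <- list(
    "svm-rfe" = top_k(rfe, k),
    "roc" = top_k(roc, k),
    "boruta" = boruta_confirmed(bor, include_tentative = include_tentative))

  mt <- moderated_t(m, labels, adjust = adjust)
  gated <- sets
  if (gate) {
    gate_set <- function(ids) {
      sub <- mt[mt$probe_id %in% ids, , drop = FALSE]
      sub$p_adj <- adjust_p(sub$p, adjust)
      significance_gate(sub, lfc_threshold = lfc_threshold, alpha = alpha)
    }
    gated[["svm-rfe"]] <- gate_set(sets[["svm-rfe"]])
    gated[["roc"]] <- gate_set(sets[["roc"]])
  }

  panel <- consensus_panel(gated)
  panel$selected <- panel$selected[order(match(panel$selected, rownames(m)))]
  panel$k <- as.integer(k)
  panel$provenance <- list(
    config = list(k = k, lfc_threshold = lfc_threshold, alpha = alpha,
                  adjust = adjust, gate = gate,
                  include_tentative = include_tentative, t0 = t0,
                  roc_criterion = roc_criterion, cost = cost,
                  boruta_trees = boruta_trees,
                  boruta_max_iter = boruta_max_iter,
                  boruta_alpha = boruta_alpha, seed = seed),
    svm_rfe = rfe, roc = roc, boruta = bor, moderated_t = mt,
    raw_sets = sets, gated_sets = gated)
  message(sprintf(
    "consensus: set sizes %s -> panel of %d probe(s)%s",
    paste(sprintf("%s=%d", names(panel$set_sizes), panel$set_sizes),
          collapse = ", "),
    length(panel$selected),
    if (length(panel$selected) == 0) " [EMPTY INTERSECTION]" else ""))
  panel
}

#' Write a consensus panel as JSON
#'
#' @param panel A `consensus_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(
    list(selected = panel$selected,
         membership = panel$membership,
         set_sizes = as.list(panel$set_sizes),
         k = panel$k,
         config = panel$provenance$config),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
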