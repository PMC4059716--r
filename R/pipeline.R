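#' Run the full selection-and-evaluation pipeline
#'
#' Orchestrates variance filtering, the three rankers, the significance
#' gate, consensus intersection and six-classifier cross-validated
#' evaluation, writing every intermediate artifact into `out_dir`:
#' ranked lists (TSV), shadow-selector decisions (TSV), the moderated-t
#' table (TSV), the panel (JSON), the CV summary (TSV) and a full config
#' snapshot (JSON). Re-running with identical inputs, config and seed
#' reproduces every artifact byte-for-byte.
#'
#' @param matrix_path Path to the expression TSV, or an expression matrix.
#' @param labels_path Path to the label file, or a named 0/1 vector.
#' @param out_dir Output directory (created if needed).
#' @param remove_fraction Variance-filter fraction. Default 0.5.
#' @param k,lfc_threshold,alpha,adjust,gate,include_tentative,t0,roc_criterion,cost,rfe_step,boruta_trees,boruta_max_iter,boruta_alpha
#'   Passed to [select_features()].
#' @param cv_folds Cross-validation folds. Default 10.
#' @param seed Root seed; per-stage seeds are derived deterministically.
#' @return Invisibly, a list with the filtered matrix dimensions, the
#'   `consensus_panel`, the `cv_report_list` and the artifact paths.
#' @export
run_pipeline <- function(matrix_path, labels_path, out_dir,
                         remove_fraction = 0.5,
                         k = NULL, lfc_threshold = 2, alpha = 0.01,
                         adjust = "bonferroni", gate = TRUE,
                         include_tentative = FALSE, t0 = 0.1,
                         roc_criterion = "auc", cost = 1, rfe_step = NULL,
                         boruta_trees = 500, boruta_max_iter = 100,
                         boruta_alpha = 0.05, cv_folds = 10, seed = 1) {
  m <- if (is.character(matrix_path)) read_expression_table(matrix_path)
       else matrix_path
  labels <- if (is.character(labels_path)) read_labels(labels_path)
            else labels_path
  al <- align_samples(m, labels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n_input <- nrow(al$matrix)
  mf <- variance_filter(al$matrix, remove_fraction)
  message(sprintf("filter: %d -> %d probes (remove_fraction %.2f)",
                  n_input, nrow(mf), remove_fraction))

  panel <- select_features(mf, al$labels, k = k,
                           lfc_threshold = lfc_threshold, alpha = alpha,
                           adjust = adjust, gate = gate,
                           include_tentative = include_tentative, t0 = t0,
                           roc_criterion = roc_criterion, cost = cost,
                           rfe_step = rfe_step, boruta_trees = boruta_trees,
                           boruta_max_iter = boruta_max_iter,
                           boruta_alpha = boruta_alpha, seed = seed)

  paths <- list(
    svm_rfe = file.path(out_dir, "ranked_svm_rfe.tsv"),
    roc = file.path(out_dir, "ranked_roc.tsv"),
    boruta = file.path(out_dir, "boruta_decisions.tsv"),
    moderated_t = file.path(out_dir, "moderated_t.tsv"),
    panel = file.path(out_dir, "panel.json"),
    summary = file.path(out_dir, "cv_summary.tsv"),
    predictions = file.path(out_dir, "cv_predictions.tsv"),
    config = file.path(out_dir, "config.json"))
  write_ranked_list(panel$provenance$svm_rfe, paths$svm_rfe)
  write_ranked_list(panel$provenance$roc, paths$roc)
  write_boruta_decisions(panel$provenance$boruta, paths$boruta)
  write_moderated_t(panel$provenance$moderated_t, paths$moderated_t)
  write_panel_json(panel, paths$panel)

  reports <- NULL
  if (length(panel$selected) > 0) {
    reports <- evaluate_all(mf, al$labels, panel = panel$selected,
                            k = cv_folds, seed = seed)
    utils::write.table(cv_summary_table(reports), paths$summary, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    preds <- do.call(rbind, lapply(reports, function(r)
      do.call(rbind, lapply(r$folds, function(f)
        data.frame(model = r$model_name, sample_id = f$test_ids,
                   prediction = unname(f$predictions))))))
    utils::write.table(preds, paths$predictions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    message("empty consensus panel: classifier evaluation skipped")
  }

  snapshot <- list(
    remove_fraction = remove_fraction, cv_folds = cv_folds, seed = seed,
    probes_input = n_input, probes_filtered = nrow(mf),
    select = panel$provenance$config,
    set_sizes = as.list(panel$set_sizes),
    panel_size = length(panel$selected))
  jsonlite::write_json(snapshot, paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(filtered_dim = dim(mf), panel = panel, reports = reports,
                 paths = paths))
}
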