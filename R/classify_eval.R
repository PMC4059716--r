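#' Stratified cross-validation folds
#'
#' Partitions samples into `k` test folds whose sizes differ by at most
#' one and whose per-class counts differ by at most one across folds.
#' Samples are shuffled within class and dealt round-robin across folds,
#' with the dealing pointer carried over between classes so total fold
#' sizes stay balanced (e.g. 26 cases / 18 controls into 10 folds gives
#' fold sizes 4-5 with 2-3 cases and 1-2 controls per fold).
#'
#' @param labels Named 0/1 vector.
#' @param k Number of folds, `2 <= k <= length(labels)`.
#' @param seed Integer seed; the partition is deterministic given it.
#' @return List of `k` character vectors of test-sample ids.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  validate_labels(labels)
  n <- length(labels)
  if (!is.numeric(k) || k != round(k) || k < 2 || k > n)
    stop("k must be an integer in [2, ", n, "]", call. = FALSE)
  classes <- names(sort(table(labels), decreasing = TRUE))
  folds <- vector("list", k)
  ptr <- 0L
  withr::with_seed(seed, {
    for (cl in classes) {
      ids <- sample(names(labels)[labels == as.integer(cl)])
      for (id in ids) {
        slot <- (ptr %% k) + 1L
        folds[[slot]] <- c(folds[[slot]], id)
        ptr <- ptr + 1L
      }
    }
  })
  folds
}

#' Confusion counts for binary predictions
#'
#' Class 1 is the positive class.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return A `confusion_counts` list with fields tp, fp, tn, fn.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fp = sum(truth == 0 & pred == 1),
                 tn = sum(truth == 0 & pred == 0),
                 fn = sum(truth == 1 & pred == 0)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and F1 from confusion counts
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' accuracy = (TP+TN)/(TP+TN+FP+FN); F1 = 2TP/(2TP+FP+FN).
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never as 0.
#'
#' @param cc A `confusion_counts` (or list with tp, fp, tn, fn).
#' @return Named list with sensitivity, specificity, accuracy, f1.
#' @export
metrics_from_confusion <- function(cc) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  with(cc, list(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn)))
}

# registry of base learners: each entry fits on standardized training data
# and returns 0/1 predictions for the test rows
model_registry <- function() {
  list(
    svm = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                        kernel = "linear", cost = 1, scale = FALSE)
      as.integer(as.character(stats::predict(fit, xte)))
    },
    rf = function(xtr, ytr, xte) {
      fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                        ntree = 500)
      as.integer(as.character(stats::predict(fit, xte)))
    },
    nbayes = function(xtr, ytr, xte) {
      fit <- e1071::naiveBayes(as.data.frame(xtr),
                               factor(ytr, levels = c(0, 1)))
      as.integer(as.character(stats::predict(fit, as.data.frame(xte))))
    },
    nnet = function(xtr, ytr, xte) {
      fit <- nnet::nnet(xtr, as.numeric(ytr), size = 8, entropy = TRUE,
                        maxit = 500, trace = FALSE)
      as.integer(stats::predict(fit, xte) > 0.5)
    },
    knn = function(xtr, ytr, xte) {
      as.integer(as.character(class::knn(xtr, xte,
                                         factor(ytr, levels = c(0, 1)),
                                         k = 5)))
    },
    logistic = function(xtr, ytr, xte) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, xtr), ytr, family = stats::binomial()))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      as.integer(stats::plogis(drop(cbind(1, xte) %*% beta)) > 0.5)
    })
}

#' Names of the registered classifiers
#' @return Character vector of the six model names.
#' @export
classifier_names <- function() names(model_registry())

#' Cross-validate one classifier on a probe panel
#'
#' Fits the named classifier on the training folds and predicts each test
#' fold exactly once; standardization parameters (feature means/SDs) are
#' learned on the training folds only. Predictions are pooled over all
#' folds into a single confusion matrix from which the metric set is
#' computed (macro-averaging per-fold metrics is available via
#' `pool = FALSE`; with one or two controls per fold the pooled form is
#' the stable one).
#'
#' @param m Expression matrix restricted to the panel (probes x samples).
#' @param labels Named 0/1 vector aligned to matrix columns.
#' @param model_name One of `r paste(classifier_names(), collapse = ", ")`.
#' @param k Number of folds. Default 10.
#' @param seed Integer seed (folds and stochastic learners).
#' @param folds Optional precomputed fold list (from
#'   [stratified_folds()]), e.g. to share folds across models.
#' @param pool Pool predictions before computing metrics (default) or
#'   macro-average per-fold metrics.
#' @return A `cv_report`: model_name, folds (test ids + predictions),
#'   pooled `confusion_counts`, `metrics`, seed.
#' @export
cross_validate <- function(m, labels, model_name, k = 10, seed = 1,
                           folds = NULL, pool = TRUE) {
  validate_expression_matrix(m)
  stopifnot(identical(colnames(m), names(labels)))
  check_two_classes(labels)
  registry <- model_registry()
  if (!model_name %in% names(registry))
    stop("unknown model: ", model_name, " (choose from ",
         paste(names(registry), collapse = ", "), ")", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(labels, k = k, seed = seed)

  x <- t(m)
  fit_fun <- registry[[model_name]]
  fold_out <- vector("list", length(folds))
  withr::with_seed(seed, {
    for (i in seq_along(folds)) {
      test_ids <- folds[[i]]
      train_ids <- setdiff(names(labels), test_ids)
      xtr <- x[train_ids, , drop = FALSE]
      ctr <- colMeans(xtr)
      sds <- apply(xtr, 2, stats::sd)
      sds[sds == 0] <- 1
      xtr <- scale(xtr, center = ctr, scale = sds)
      xte <- scale(x[test_ids, , drop = FALSE], center = ctr, scale = sds)
      pred <- fit_fun(xtr, labels[train_ids], xte)
      fold_out[[i]] <- list(test_ids = test_ids,
                            predictions = stats::setNames(pred, test_ids))
    }
  })

  all_pred <- unlist(lapply(fold_out, `[[`, "predictions"))
  all_pred <- all_pred[names(labels)]
  pooled <- confusion_counts(labels, all_pred)
  metrics <- if (pool) {
    metrics_from_confusion(pooled)
  } else {
    per <- lapply(fold_out, function(f)
      metrics_from_confusion(confusion_counts(labels[f$test_ids],
                                              f$predictions)))
    lapply(stats::setNames(nm = names(per[[1]])), function(nm)
      mean(vapply(per, `[[`, numeric(1), nm), na.rm = TRUE))
  }
  structure(list(model_name = model_name, folds = fold_out, pooled = pooled,
                 metrics = metrics, seed = seed, k = length(folds)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "%s (%d-fold CV, seed %d): Sensitivity %.4f  Specificity %.4f  F1 %.4f  Accuracy %.4f\n",
    x$model_name, x$k, x$seed, m$sensitivity, m$specificity, m$f1, m$accuracy))
  invisible(x)
}

#' Cross-validate every registered classifier on one panel
#'
#' All models share the same stratified folds, so differences in the
#' summary table reflect the learners, not the resampling.
#'
#' @inheritParams cross_validate
#' @param panel Optional character vector of probe ids to restrict the
#'   matrix to (e.g. a consensus panel's `selected`).
#' @param models Model names to run; default all six.
#' @return List of `cv_report` objects (class `cv_report_list`), one per
#'   model.
#' @export
evaluate_all <- function(m, labels, panel = NULL, k = 10, seed = 1,
                         models = classifier_names(), pool = TRUE) {
  if (!is.null(panel)) {
    if (length(panel) == 0) stop("empty panel", call. = FALSE)
    missing <- setdiff(panel, rownames(m))
    if (length(missing))
      stop("panel probe(s) not in matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- m[panel, , drop = FALSE]
  }
  folds <- stratified_folds(labels, k = k, seed = seed)
  reports <- lapply(models, function(mod)
    cross_validate(m, labels, mod, seed = seed, folds = folds, pool = pool))
  names(reports) <- models
  class(reports) <- "cv_report_list"
  reports
}

#' Summary table of cross-validation metrics
#'
#' One row per model with Sensitivity, Specificity, F1score and Accuracy
#' rounded to 4 decimals.
#'
#' @param reports A `cv_report_list` from [evaluate_all()].
#' @return A data frame.
#' @export
cv_summary_table <- function(reports) {
  data.frame(
    Model = vapply(reports, `[[`, character(1), "model_name"),
    Sensitivity = round(vapply(reports, function(r) r$metrics$sensitivity,
                               numeric(1)), 4),
    Specificity = round(vapply(reports, function(r) r$metrics$specificity,
                               numeric(1)), 4),
    F1score = round(vapply(reports, function(r) r$metrics$f1, numeric(1)), 4),
    Accuracy = round(vapply(reports, function(r) r$metrics$accuracy,
                            numeric(1)), 4),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cv_report_list <- function(x, ...) {
  print(cv_summary_table(x))
  invisible(x)
}
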