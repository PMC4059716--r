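test_that("stratified folds partition 26/18 into balanced tenths", {
  y <- stats::setNames(rep(c(1L, 0L), c(26, 18)), sprintf("s%02d", 1:44))
  folds <- stratified_folds(y, k = 10, seed = 4)
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(4L, 5L)))
  n1 <- vapply(folds, function(f) sum(y[f] == 1), integer(1))
  n0 <- vapply(folds, function(f) sum(y[f] == 0), integer(1))
  expect_true(all(n1 %in% c(2L, 3L)))
  expect_true(all(n0 %in% c(1L, 2L)))
  # partition property
  expect_setequal(unlist(folds), names(y))
  expect_identical(anyDuplicated(unlist(folds)), 0L)
  # deterministic given seed
  expect_identical(folds, stratified_folds(y, k = 10, seed = 4))

  # leave-one-out
  loo <- stratified_folds(y, k = 44, seed = 1)
  expect_true(all(lengths(loo) == 1L))
  expect_error(stratified_folds(y, k = 1), "k must be")
})

test_that("confusion metrics reproduce reference confusion matrices", {
  m1 <- metrics_from_confusion(list(tp = 24, fn = 2, tn = 14, fp = 4))
  expect_equal(round(m1$sensitivity, 4), 0.9231)
  expect_equal(round(m1$specificity, 4), 0.7778)
  expect_equal(round(m1$f1, 4), 0.8889)
  expect_equal(round(m1$accuracy, 4), 0.8636)

  m2 <- metrics_from_confusion(list(tp = 20, fn = 6, tn = 14, fp = 4))
  expect_equal(round(m2$f1, 4), 0.8)
  expect_equal(round(m2$accuracy, 4), 0.7727)

  perfect <- metrics_from_confusion(list(tp = 26, fn = 0, tn = 18, fp = 0))
  expect_true(all(unlist(perfect) == 1))

  # zero denominators are undefined, not zero
  deg <- metrics_from_confusion(list(tp = 0, fn = 0, tn = 5, fp = 1))
  expect_true(is.na(deg$sensitivity))
  expect_false(is.na(deg$specificity))
})

test_that("a perfectly informative probe gives accuracy 1 for every model", {
  withr::with_seed(6, {
    y <- stats::setNames(rep(c(1L, 0L), c(12, 10)), sprintf("s%02d", 1:22))
    m <- rbind(oracle = as.numeric(y) * 4 - 2 + rnorm(22, 0, 0.01),
               noise1 = rnorm(22), noise2 = rnorm(22))
    colnames(m) <- names(y)
    for (mod in classifier_names()) {
      rep <- cross_validate(m, y, mod, k = 5, seed = 6)
      expect_equal(rep$metrics$accuracy, 1,
                   info = paste("model", mod))
    }
  })
})

test_that("evaluate_all runs the full registry deterministically", {
  d <- simulate_dataset(sim_config(n_probes = 40, n_informative = 6,
                                   n_case = 13, n_control = 9, effect = 2.5,
                                   seed = 44))
  r1 <- evaluate_all(d$matrix, d$labels, panel = d$truth, k = 10, seed = 44)
  expect_length(r1, 6)
  expect_identical(names(r1), classifier_names())
  r2 <- evaluate_all(d$matrix, d$labels, panel = d$truth, k = 10, seed = 44)
  expect_identical(cv_summary_table(r1), cv_summary_table(r2))

  # every sample predicted exactly once per model
  for (r in r1) {
    ids <- unlist(lapply(r$folds, `[[`, "test_ids"))
    expect_setequal(ids, names(d$labels))
    expect_identical(anyDuplicated(ids), 0L)
  }

  # summary columns recompute exactly from each pooled confusion
  tab <- cv_summary_table(r1)
  for (i in seq_along(r1)) {
    mm <- metrics_from_confusion(r1[[i]]$pooled)
    expect_equal(tab$Sensitivity[i], round(mm$sensitivity, 4))
    expect_equal(tab$Specificity[i], round(mm$specificity, 4))
    expect_equal(tab$F1score[i], round(mm$f1, 4))
    expect_equal(tab$Accuracy[i], round(mm$accuracy, 4))
  }

  expect_error(cross_validate(d$matrix, d$labels, "boosted"), "unknown model")
})
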