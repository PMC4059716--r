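test_that("generator honours the configured design", {
  d <- simulate_dataset(sim_config(n_case = 26, n_control = 18, seed = 3))
  expect_identical(ncol(d$matrix), 44L)
  expect_identical(sum(d$labels == 1), 26L)
  expect_identical(sum(d$labels == 0), 18L)
  expect_length(d$truth, 8)
  expect_false(anyNA(d$matrix))

  # same seed -> bit-identical data
  d2 <- simulate_dataset(sim_config(n_case = 26, n_control = 18, seed = 3))
  expect_identical(d$matrix, d2$matrix)
  expect_identical(d$truth, d2$truth)

  expect_error(sim_config(n_probes = 5, n_informative = 6), "n_informative")
  expect_error(sim_config(n_case = 1), "at least 2")
  expect_error(sim_config(effect = -1), "effect")
})

test_that("planted effects alternate in sign and scale with sigma", {
  d <- simulate_dataset(sim_config(n_probes = 100, n_informative = 6,
                                   n_case = 200, n_control = 200,
                                   effect = 2, seed = 10))
  lfc <- log_fold_change(d$matrix, d$labels)[d$truth]
  expect_identical(sum(lfc > 0), 3L)  # alternating signs
  expect_identical(sum(lfc < 0), 3L)
  # |logfc| ~ effect * sigma with sigma in [1.5, 3]
  expect_true(all(abs(lfc) > 2 & abs(lfc) < 7))
})

test_that("empirical AUC of a planted probe matches the normal-shift theory", {
  # two-sided AUC of a probe shifted by `effect` SDs is Phi(effect / sqrt 2)
  d <- simulate_dataset(sim_config(n_probes = 10, n_informative = 1,
                                   n_case = 500, n_control = 500,
                                   effect = 2, seed = 31))
  x <- d$matrix[d$truth, ]
  auc <- empirical_auc(x[d$labels == 0], x[d$labels == 1])
  auc2 <- max(auc, 1 - auc)
  expect_equal(auc2, pnorm(2 / sqrt(2)), tolerance = 0.03)

  # a strong planted effect separates almost perfectly
  d5 <- simulate_dataset(sim_config(n_probes = 10, n_informative = 1,
                                    n_case = 44, n_control = 44,
                                    effect = 5, seed = 32))
  x5 <- d5$matrix[d5$truth, ]
  a5 <- empirical_auc(x5[d5$labels == 0], x5[d5$labels == 1])
  expect_gte(max(a5, 1 - a5), 0.95)
})

test_that("null generator yields approximately uniform moderated-t p-values", {
  d <- simulate_dataset(sim_config(n_probes = 2000, n_informative = 0,
                                   seed = 41))
  mt <- moderated_t(d$matrix, d$labels)
  ks <- suppressWarnings(ks.test(mt$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("correlation blocks induce the requested correlation", {
  cfg <- sim_config(n_probes = 40, n_informative = 0, n_case = 300,
                    n_control = 300,
                    correlation_block = list(size = 20, rho = 0.6), seed = 13)
  d <- simulate_dataset(cfg)
  cors <- cor(t(d$matrix[1:20, ]))
  expect_equal(mean(cors[upper.tri(cors)]), 0.6, tolerance = 0.06)
})

test_that("fixtures write matched, loadable files", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("tiny", dir = file.path(dir, "tiny"), seed = 2)
  m <- read_expression_table(fx$matrix)
  y <- read_labels(fx$labels)
  expect_identical(dim(m), c(50L, 12L))
  expect_identical(colnames(m), names(y))
  truth <- jsonlite::read_json(fx$truth, simplifyVector = TRUE)
  expect_length(truth$informative, 4)

  fx_null <- make_fixture("null", dir = file.path(dir, "null"), seed = 2)
  truth_null <- jsonlite::read_json(fx_null$truth, simplifyVector = TRUE)
  expect_length(truth_null$informative, 0)

  fx_s <- make_fixture("study-shaped", dir = file.path(dir, "s"), seed = 2)
  truth_s <- jsonlite::read_json(fx_s$truth, simplifyVector = TRUE)
  expect_length(truth_s$informative, 8)
  expect_identical(dim(attr(fx_s, "data")$matrix), c(2000L, 44L))
})
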