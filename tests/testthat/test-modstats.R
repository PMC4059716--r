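test_that("log fold change is the case-minus-control mean difference", {
  m <- toy_matrix(c(5, 5, 3, 3, 1, 2, 1, 2), 2, 4)
  y <- toy_labels(2, 2)
  lfc <- log_fold_change(m, y)
  expect_equal(unname(lfc["p1"]), 2)
  expect_equal(unname(lfc["p2"]), 0)
  # swapping the encoding negates every logfc
  y_swapped <- stats::setNames(1L - y, names(y))
  expect_equal(log_fold_change(m, y_swapped), -lfc)
})

test_that("moderated t with prior df 0 is the classical pooled t", {
  withr::with_seed(17, {
    m <- matrix(rnorm(60 * 12, sd = rep(runif(60, 0.5, 2), 12)), 60, 12,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:12)))
    y <- stats::setNames(rep(c(1L, 0L), each = 6), colnames(m))
    mt <- moderated_t(m, y, prior_df = 0)
    t_classical <- apply(m, 1, function(x)
      pooled_t(x[y == 1], x[y == 0]))
    expect_equal(mt$t, unname(t_classical), tolerance = 1e-10)
    # p-values from the t distribution with n - 2 df
    expect_equal(mt$p, 2 * pt(-abs(mt$t), df = 10), tolerance = 1e-12)
  })
})

test_that("infinite prior df shrinks every variance to the prior", {
  withr::with_seed(18, {
    m <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
    y <- stats::setNames(rep(c(1L, 0L), each = 5), colnames(m))
    mt <- moderated_t(m, y, prior_df = Inf)
    s0 <- attr(mt, "s0_sq")
    lfc <- log_fold_change(m, y)
    expect_equal(mt$t, unname(lfc) / sqrt(s0 * (1 / 5 + 1 / 5)),
                 tolerance = 1e-12)
  })
})

test_that("prior moments match limma and an independent moment fit", {
  withr::with_seed(23, {
    # heterogeneous true variances so d0 is finite and informative
    p <- 400; n1 <- 8; n0 <- 8
    sig <- sqrt(0.5 * 4 / rchisq(p, df = 4))  # inverse-chi-square variances
    m <- matrix(rnorm(p * (n1 + n0), sd = rep(sig, n1 + n0)), p, n1 + n0,
                dimnames = list(sprintf("g%03d", 1:p),
                                sprintf("s%02d", 1:(n1 + n0))))
    y <- stats::setNames(rep(c(1L, 0L), c(n1, n0)), colnames(m))
    mt <- moderated_t(m, y)

    # limma as an independent oracle for the hyperprior and the statistic
    design <- cbind(1, as.numeric(y))
    fit <- limma::eBayes(limma::lmFit(m, design))
    expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-6)
    expect_equal(attr(mt, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
    expect_equal(mt$t, unname(fit$t[, 2]), tolerance = 1e-8)
    expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-8)

    # brute-force method-of-moments: numerically match the observed mean
    # and variance of log s^2 under the scaled-F model
    d <- n1 + n0 - 2
    v1 <- apply(m[, y == 1], 1, var); v0 <- apply(m[, y == 0], 1, var)
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d
    z <- log(s2)
    obj <- function(par) {
      d0 <- exp(par[1]); ls0 <- par[2]
      mu <- ls0 + digamma(d / 2) - log(d / 2) -
        (digamma(d0 / 2) - log(d0 / 2))
      vv <- trigamma(d / 2) + trigamma(d0 / 2)
      (mean(z) - mu)^2 + (var(z) - vv)^2
    }
    opt <- optim(c(log(4), 0), obj)
    expect_equal(attr(mt, "d0"), exp(opt$par[1]), tolerance = 0.5)
    expect_equal(log(attr(mt, "s0_sq")), opt$par[2], tolerance = 0.5)
  })
})

test_that("null moderated-t p-values are calibrated", {
  withr::with_seed(29, {
    m <- matrix(rnorm(200 * 20), 200, 20,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:20)))
    y <- stats::setNames(rep(c(1L, 0L), each = 10), colnames(m))
    mt <- moderated_t(m, y)
    rate <- mean(mt$p < 0.05)
    expect_gte(rate, 0.01)
    expect_lte(rate, 0.09)
  })
})

test_that("p-value adjustment matches hand-computed references", {
  expect_equal(adjust_p(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  # BH step-up on {0.01, 0.02, 0.03, 0.04}: p * 4 / rank, then cummin -> all 0.04
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  # m = 1 is the identity
  expect_equal(adjust_p(0.3, "bonferroni"), 0.3)
  expect_equal(adjust_p(0.3, "bh"), 0.3)
  expect_error(adjust_p(c(0.5, 1.2)), "\\[0, 1\\]")
  # order-preserving and never below raw p
  withr::with_seed(2, {
    p <- runif(50)
    adj <- adjust_p(p, "bonferroni")
    expect_true(all(adj >= p))
    # order-preserving up to the cap at 1
    expect_true(all(diff(adj[order(p)]) >= 0))
  })
})

test_that("significance gate applies both thresholds and is monotone", {
  res <- data.frame(
    probe_id = c("trps1_like", "low_fc", "high_p"),
    logfc = c(6.2601, 1.9, 5.0),
    t = c(18.92, 10, 2),
    p = c(4.95e-23, 1e-10, 0.2),
    p_adj = c(5.16e-23, 1e-10, 0.4))
  expect_identical(significance_gate(res, 2, 0.01), "trps1_like")
  expect_length(significance_gate(res, 2, 0), 0)
  # relaxing either threshold can only grow the set
  g1 <- significance_gate(res, 2, 0.01)
  expect_true(all(g1 %in% significance_gate(res, 1, 0.01)))
  expect_true(all(g1 %in% significance_gate(res, 2, 0.5)))
  # negative fold changes pass the two-sided gate only
  res2 <- data.frame(probe_id = "down", logfc = -3, t = -9, p = 1e-9,
                     p_adj = 1e-8)
  expect_identical(significance_gate(res2), "down")
  expect_length(significance_gate(res2, two_sided = FALSE), 0)
})
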