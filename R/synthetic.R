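#' Configuration for the synthetic two-group generator
#'
#' Defaults emulate the shape of a small two-group microarray study:
#' 26 cases vs 18 controls, a 2,000-probe log-intensity matrix with 8
#' planted differentially expressed probes shifted by 2 within-group
#' standard deviations. Baseline intensities sit around 7 log2 units;
#' per-probe noise SDs are drawn uniformly from `baseline_sd_range`, so a
#' 2-SD shift yields planted log fold changes of roughly 3-6 log units,
#' comfortably above a conventional logFC > 2 gate.
#'
#' @param n_probes Number of probes. Default 2000.
#' @param n_informative Number of planted differential probes. Default 8.
#' @param n_case,n_control Group sizes (each >= 2). Defaults 26 / 18.
#' @param effect Group-mean shift of planted probes, in units of that
#'   probe's noise SD (scale-free). Default 2.
#' @param baseline_mean Baseline log-intensity. Default 7.
#' @param baseline_sd_range Range for per-probe noise SDs. Default
#'   `c(1.5, 3)`.
#' @param correlation_block Optional `list(size =, rho =)` giving
#'   equicorrelated blocks among noise probes (`0 <= rho < 1`).
#' @param noise `"normal"` (default) or `"t"` for heavier tails.
#' @param t_df Degrees of freedom for `noise = "t"`. Default 5.
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_probes = 2000, n_informative = 8,
                       n_case = 26, n_control = 18,
                       effect = 2, baseline_mean = 7,
                       baseline_sd_range = c(1.5, 3),
                       correlation_block = NULL,
                       noise = c("normal", "t"), t_df = 5,
                       seed = 1) {
  noise <- match.arg(noise)
  if (n_informative > n_probes)
    stop("n_informative must not exceed n_probes", call. = FALSE)
  if (n_case < 2 || n_control < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (length(baseline_sd_range) != 2 || any(baseline_sd_range <= 0) ||
      baseline_sd_range[1] > baseline_sd_range[2])
    stop("baseline_sd_range must be positive and increasing", call. = FALSE)
  if (!is.null(correlation_block)) {
    if (is.null(correlation_block$size) || is.null(correlation_block$rho) ||
        correlation_block$rho < 0 || correlation_block$rho >= 1)
      stop("correlation_block needs size and rho in [0, 1)", call. = FALSE)
  }
  structure(list(n_probes = n_probes, n_informative = n_informative,
                 n_case = n_case, n_control = n_control, effect = effect,
                 baseline_mean = baseline_mean,
                 baseline_sd_range = baseline_sd_range,
                 correlation_block = correlation_block,
                 noise = noise, t_df = t_df, seed = seed),
            class = "sim_config")
}

#' Simulate a two-group expression matrix with planted signal
#'
#' Per probe g a noise SD sigma_g is drawn uniformly from
#' `baseline_sd_range` and values are drawn around `baseline_mean` with
#' that SD. Each informative probe has `effect * sigma_g` added to (or,
#' for alternating probes, subtracted from) its case-group mean, so both
#' over- and under-expression occur and the effect size is scale-free.
#' Optional equicorrelated blocks are induced among noise probes through a
#' shared per-sample factor. Everything is reproducible given the seed.
#'
#' For an informative probe the theoretical two-sided AUC is
#' Phi(effect / sqrt(2)).
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (probes x samples), `labels` (named 0/1
#'   vector, cases first), and `truth` (planted probe ids).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_probes
  n <- config$n_case + config$n_control
  probe_ids <- sprintf("p%05d", seq_len(p))
  sample_ids <- sprintf("s%03d", seq_len(n))
  labels <- stats::setNames(rep(c(1L, 0L), c(config$n_case, config$n_control)),
                            sample_ids)
  withr::with_seed(config$seed, {
    sigma <- stats::runif(p, config$baseline_sd_range[1],
                          config$baseline_sd_range[2])
    z <- if (config$noise == "normal") {
      matrix(stats::rnorm(p * n), p, n)
    } else {
      matrix(stats::rt(p * n, df = config$t_df) /
               sqrt(config$t_df / (config$t_df - 2)), p, n)
    }
    informative <- if (config$n_informative > 0)
      sort(sample.int(p, config$n_informative)) else integer(0)
    cb <- config$correlation_block
    if (!is.null(cb)) {
      noise_rows <- setdiff(seq_len(p), informative)
      blocks <- split(noise_rows,
                      ceiling(seq_along(noise_rows) / cb$size))
      for (b in blocks) {
        common <- stats::rnorm(n)
        z[b, ] <- sqrt(cb$rho) * matrix(common, length(b), n, byrow = TRUE) +
          sqrt(1 - cb$rho) * z[b, , drop = FALSE]
      }
    }
    m <- config$baseline_mean + z * sigma
    if (length(informative)) {
      signs <- rep_len(c(1, -1), length(informative))
      shift <- config$effect * sigma[informative] * signs
      m[informative, labels == 1] <- m[informative, labels == 1, drop = FALSE] +
        shift
    }
  })
  dimnames(m) <- list(probe_ids, sample_ids)
  list(matrix = m, labels = labels, truth = probe_ids[informative])
}

#' Write a named synthetic fixture to disk
#'
#' Produces a matched matrix TSV, labels TSV and truth JSON for one of
#' three presets: `tiny` (50 probes x 12 samples, 4 planted), `null`
#' (500 probes x 44 samples, nothing planted) and `study-shaped`
#' (2,000 probes x 44 samples, 8 planted at 2 SD -- the scaled-down
#' analogue of a 27k-probe, 26/18-sample study).
#'
#' @param name Preset name.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of file paths (matrix, labels, truth), invisibly;
#'   the simulated data as attribute `"data"`.
#' @export
make_fixture <- function(name = c("tiny", "null", "study-shaped"),
                         dir = tempfile("fixture"), seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    "tiny" = sim_config(n_probes = 50, n_informative = 4, n_case = 6,
                        n_control = 6, seed = seed),
    "null" = sim_config(n_probes = 500, n_informative = 0, seed = seed),
    "study-shaped" = sim_config(seed = seed))
  d <- simulate_dataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                labels = file.path(dir, "labels.tsv"),
                truth = file.path(dir, "truth.json"))
  write_expression_table(d$matrix, paths$matrix)
  write_labels(d$labels, paths$labels)
  jsonlite::write_json(
    list(informative = d$truth,
         config = unclass(cfg)[setdiff(names(cfg), "correlation_block")]),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- paths
  attr(out, "data") <- d
  invisible(out)
}
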