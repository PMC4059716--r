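#' Validate an expression matrix
#'
#' An expression matrix in triselect is a plain numeric matrix of log-scale
#' intensities with unique probe identifiers as row names and unique sample
#' identifiers as column names (the convention used throughout the
#' differential-expression ecosystem, e.g. limma).
#'
#' @param m A numeric matrix with complete dimnames.
#' @return The matrix, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry probe (row) and sample (column) names",
         call. = FALSE)
  dup_p <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_p))
    stop("duplicate probe identifier(s): ", paste(unique(dup_p), collapse = ", "),
         call. = FALSE)
  dup_s <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  if (anyNA(m))
    stop("expression matrix contains missing values; complete data required",
         call. = FALSE)
  invisible(m)
}

#' Read a probe-by-sample expression table
#'
#' Reads a tab-delimited text file whose header row holds sample identifiers
#' and whose first column holds probe identifiers; all remaining cells must
#' be numeric log-scale intensities. Values are never transformed on load.
#'
#' @param path Path to a TSV file.
#' @return A validated numeric matrix (probes x samples).
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_probes = 5, n_case = 3, n_control = 3))
#' f <- tempfile(fileext = ".tsv")
#' write_expression_table(d$matrix, f)
#' m <- read_expression_table(f)
#' stopifnot(identical(m, d$matrix))
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty expression table: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("malformed expression table (need >= 1 probe and >= 1 sample): ",
         path, call. = FALSE)
  probes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric or missing cell at probe row %d, sample column %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  dimnames(num) <- list(probes, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as a TSV table
#'
#' @param m A validated expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binary phenotype labels
#'
#' Expects a two-column delimited file (tab or comma) with a header row
#' `sample_id` and `label`; labels must be 0 (control) or 1 (case).
#'
#' @param path Path to the label file.
#' @return A named integer vector of 0/1 labels (names = sample ids), in
#'   file order.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label file must have columns sample_id, label",
                         call. = FALSE)
  ids <- df[[1]]
  lab <- suppressWarnings(as.integer(df[[2]]))
  bad <- is.na(lab) | !(lab %in% c(0L, 1L))
  if (any(bad))
    stop("label outside {0,1} for sample(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample identifier(s) in labels: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  stats::setNames(lab, ids)
}

#' Write phenotype labels
#'
#' @param labels Named 0/1 integer vector.
#' @param path Output path (TSV with header `sample_id\tlabel`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_labels <- function(labels) {
  if (is.null(names(labels)) || anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be a named vector of 0/1 values", call. = FALSE)
  if (anyDuplicated(names(labels)))
    stop("duplicate sample identifiers in labels", call. = FALSE)
  invisible(labels)
}

check_two_classes <- function(labels) {
  if (length(unique(as.integer(labels))) < 2L)
    stop("both classes (0 and 1) must be present", call. = FALSE)
  invisible(labels)
}

#' Align an expression matrix with a phenotype vector
#'
#' Restricts both objects to their common samples, in matrix column order.
#' Samples present in only one of the two inputs are dropped with a warning.
#'
#' @param m Expression matrix (probes x samples).
#' @param labels Named 0/1 vector.
#' @return A list with elements `matrix` and `labels`, sample-aligned.
#' @export
align_samples <- function(m, labels) {
  validate_expression_matrix(m)
  validate_labels(labels)
  common <- intersect(colnames(m), names(labels))
  if (length(common) == 0)
    stop("alignment error: no samples shared between matrix and labels",
         call. = FALSE)
  dropped <- setdiff(union(colnames(m), names(labels)), common)
  if (length(dropped))
    warning("dropping unmatched sample(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  keep <- colnames(m)[colnames(m) %in% common]
  list(matrix = m[, keep, drop = FALSE], labels = labels[keep])
}

#' Construct a ranked feature list
#'
#' @param ranker Name of the ranking algorithm.
#' @param probe_ids Probe identifiers, best first.
#' @param scores Per-probe scores aligned to `probe_ids`.
#' @param score_semantics Either `"higher is better"` or `"rank position"`.
#' @return A `ranked_list` data frame with columns rank, probe_id, score,
#'   ranker.
#' @export
ranked_list <- function(ranker, probe_ids, scores,
                        score_semantics = c("higher is better", "rank position")) {
  score_semantics <- match.arg(score_semantics)
  if (anyDuplicated(probe_ids))
    stop("ranked list probe ids must be unique", call. = FALSE)
  if (length(probe_ids) != length(scores))
    stop("probe_ids and scores must have equal length", call. = FALSE)
  out <- data.frame(rank = seq_along(probe_ids), probe_id = probe_ids,
                    score = as.numeric(scores), ranker = ranker,
                    stringsAsFactors = FALSE)
  attr(out, "score_semantics") <- score_semantics
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked list (%s; %s), %d features\n", x$ranker[1],
              attr(x, "score_semantics"), nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Write / read a ranked list as TSV
#'
#' Columns: rank, probe_id, score, ranker.
#'
#' @param rl A `ranked_list`.
#' @param path File path.
#' @return `path` (writer) or a `ranked_list` (reader).
#' @export
write_ranked_list <- function(rl, path) {
  utils::write.table(as.data.frame(rl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ranked_list(df$ranker[1], df$probe_id, df$score)
}
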