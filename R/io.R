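# Tabular IO and sample/probe alignment.
#
# Expression data travels as a plain numeric matrix (probes in rows, samples
# in columns, both dimnames set); labellings and clinical annotation travel
# as tibbles so they chain with dplyr verbs.

#' Validate a probes-by-samples expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique, non-empty probe rownames and sample colnames and no
#' non-finite values (expression is assumed on a log-like additive scale).
#'
#' @param x Numeric matrix, probes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression matrix must be a numeric matrix")
  }
  pr <- rownames(x)
  sm <- colnames(x)
  if (is.null(pr) || is.null(sm)) {
    abort("expression matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(pr)) {
    abort(paste0("duplicate probe id: ", pr[duplicated(pr)][1]))
  }
  if (anyDuplicated(sm)) {
    abort(paste0("duplicate sample id: ", sm[duplicated(sm)][1]))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-finite expression value at probe '%s', sample '%s'",
      pr[bad[1]], sm[bad[2]]
    ))
  }
  invisible(x)
}

#' Read a probes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers; the body must be numeric. Missing values are rejected by
#' default; `impute = TRUE` opts into per-probe median imputation (each
#' imputed cell is reported via a message).
#'
#' @param path Path to a tab-separated file.
#' @param impute Replace missing cells by the probe's median across samples
#'   instead of failing. Default `FALSE`.
#' @return A validated numeric matrix (probes x samples).
#' @export
read_expression_matrix <- function(path, impute = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  raw_samples <- hdr[-1]
  if (anyDuplicated(raw_samples)) {
    abort(paste0("duplicate sample id: ", raw_samples[duplicated(raw_samples)][1]))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ), na = c("NA", ""), progress = FALSE, show_col_types = FALSE)
  probe_ids <- as.character(df[[1]])
  if (anyDuplicated(probe_ids)) {
    abort(paste0("duplicate probe id: ", probe_ids[duplicated(probe_ids)][1]))
  }
  sample_ids <- colnames(df)[-1]
  x <- as.matrix(df[, -1, drop = FALSE])
  dimnames(x) <- list(probe_ids, sample_ids)
  if (anyNA(x)) {
    if (!impute) {
      bad <- which(is.na(x), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "missing/non-numeric value at probe '%s', sample '%s' (use impute = TRUE for per-probe median imputation)",
        probe_ids[bad[1]], sample_ids[bad[2]]
      ))
    }
    n_bad <- sum(is.na(x))
    med <- apply(x, 1, median, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- med[idx[, 1]]
    inform(sprintf("imputed %d missing cell(s) by per-probe median", n_bad))
  }
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix as TSV
#'
#' @param x Numeric matrix (probes x samples).
#' @param path Output path.
#' @param digits Significant digits used when formatting values (default 6).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, digits = 6) {
  validate_expression_matrix(x)
  df <- tibble::as_tibble(signif(x, digits), rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Construct a per-sample labelling
#'
#' A labelling is a tibble with columns `sample_id` and `label`, where each
#' label is one of the class list or the literal states `"INCONSISTENT"` /
#' `"UNASSIGNED"` (case-sensitive).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param label Character vector of states, same length.
#' @param classes The fixed class list (default [default_classes()]).
#' @return A tibble with columns `sample_id`, `label`.
#' @export
labelling <- function(sample_id, label, classes = default_classes()) {
  if (length(sample_id) != length(label)) {
    abort("sample_id and label must have equal length")
  }
  sample_id <- as.character(sample_id)
  label <- as.character(label)
  if (anyDuplicated(sample_id)) {
    abort(paste0("duplicate sample id: ", sample_id[duplicated(sample_id)][1]))
  }
  ok <- label %in% c(classes, STATE_INCONSISTENT, STATE_UNASSIGNED)
  if (!all(ok)) {
    abort(paste0("unknown label: ", label[!ok][1]))
  }
  tibble(sample_id = sample_id, label = label)
}

#' Read a labelling from TSV
#'
#' Two tab-separated columns `sample_id`, `label` with a header row.
#'
#' @inheritParams labelling
#' @param path Path to the file.
#' @param classes The fixed class list; `NULL` infers it as the sorted
#'   distinct non-state labels in the file.
#' @return A labelling tibble.
#' @export
read_labelling <- function(path, classes = default_classes()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                        show_col_types = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df))) {
    abort("labelling file must have columns sample_id, label")
  }
  classes <- classes %||%
    sort(setdiff(unique(df$label), c(STATE_INCONSISTENT, STATE_UNASSIGNED)))
  labelling(df$sample_id, df$label, classes = classes)
}

#' Write a labelling as TSV
#' @param lab Labelling tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelling <- function(lab, path) {
  readr::write_tsv(lab[, c("sample_id", "label")], path, progress = FALSE)
  invisible(path)
}

#' Read clinical annotation from TSV
#'
#' Columns `sample_id`, `er`, `pr`, `her2` (values `+`, `-` or `unknown`),
#' `time` (days, non-negative) and `event` (0/1). `time` and `event` must be
#' present or absent together per sample.
#'
#' @param path Path to the file.
#' @return A tibble with the columns above.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    er = readr::col_character(),
    pr = readr::col_character(),
    her2 = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer()
  ), na = c("NA", ""), progress = FALSE, show_col_types = FALSE)
  validate_clinical(df)
  df
}

#' Validate a clinical table
#' @param df Tibble as produced by [read_clinical()].
#' @return `df`, invisibly.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "er", "pr", "her2", "time", "event")
  if (!all(need %in% colnames(df))) {
    abort(paste0("clinical table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1]))
  }
  for (m in c("er", "pr", "her2")) {
    bad <- !(df[[m]] %in% c("+", "-", "unknown") | is.na(df[[m]]))
    if (any(bad)) abort(sprintf("invalid %s status '%s'", m, df[[m]][bad][1]))
  }
  if (any(df$time < 0, na.rm = TRUE)) abort("negative survival time")
  if (any(is.na(df$time) != is.na(df$event))) {
    abort("survival time and event flag must be present together")
  }
  invisible(df)
}

#' Write a clinical table as TSV
#' @param df Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Align an expression matrix and a labelling on shared samples
#'
#' Restricts both to the intersection of their sample ids, in matrix column
#' order, and reports the intersection size.
#'
#' @param x Expression matrix (probes x samples).
#' @param lab Labelling tibble.
#' @return A list with elements `matrix` and `labelling`.
#' @export
align_samples <- function(x, lab) {
  validate_expression_matrix(x)
  shared <- intersect(colnames(x), lab$sample_id)
  if (length(shared) == 0) abort("no samples shared between matrix and labelling")
  inform(sprintf("aligned on %d shared sample(s)", length(shared)))
  keep <- colnames(x)[colnames(x) %in% shared]
  list(
    matrix = x[, keep, drop = FALSE],
    labelling = lab[match(keep, lab$sample_id), , drop = FALSE]
  )
}

# Samples currently carrying a class label (not INCONSISTENT/UNASSIGNED).
assigned <- function(lab) {
  lab[!(lab$label %in% c(STATE_INCONSISTENT, STATE_UNASSIGNED)), , drop = FALSE]
}
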