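#' Write a tabular result as TSV
#'
#' Deterministic writer used for every tabular output: tab-separated, no
#' quoting, missing values written as `NA`, and numeric columns formatted
#' with 17 significant digits so that re-reading reproduces the numbers
#' bit-exact.
#'
#' @param x a data.frame (or matrix, converted with its rownames as a first
#'   `row_id` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(row_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    x, check.names = FALSE, stringsAsFactors = FALSE)
  kt_assert(is.data.frame(x), "`x` must be a data.frame or matrix")
  out <- x
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    kt_stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
            "karyotme_io_error")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path input path.
#' @return a data.frame; columns that parse fully as numbers are numeric.
#' @export
read_table <- function(path) {
  kt_assert(file.exists(path), sprintf("file not found: %s", path),
            "karyotme_io_error")
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "NA",
                          colClasses = "character")
  for (j in seq_along(df)) {
    v <- df[[j]]
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) df[[j]] <- num
  }
  df
}

#' Read a genes-by-samples expression matrix
#'
#' Tab-delimited, first column gene symbol, remaining columns samples.
#' Values must be non-negative (normalized expression such as TPM).
#'
#' @param path input TSV path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  kt_assert(file.exists(path), sprintf("file not found: %s", path),
            "karyotme_io_error")
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  kt_assert(ncol(raw) >= 2, "expression table needs gene column + samples",
            "karyotme_format_error")
  genes <- as.character(raw[[1]])
  kt_assert(!anyDuplicated(genes), "duplicated gene ids in expression table")
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression(m)
  m
}

validate_expression <- function(m) {
  kt_assert(is.matrix(m) && is.numeric(m), "expression must be a numeric matrix")
  kt_assert(!anyDuplicated(rownames(m)) && !anyDuplicated(colnames(m)),
            "duplicated gene or sample ids")
  kt_assert(all(is.finite(m)), "expression values must be finite")
  kt_assert(all(m >= 0), "expression values must be non-negative")
  invisible(m)
}

#' Write a genes-by-samples expression matrix
#' @param m numeric matrix, genes in rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a clinical table
#'
#' Tab-delimited per-sample clinical covariates. Required: `sample_id`,
#' `os_time` (non-negative), `os_event` (0/1 or TRUE/FALSE). Recognized
#' optional columns: `tumor_type`, `tmb` (mut/Mb), `pdl1_positive`,
#' `cd8_fraction`, `b_fraction`, `purity`, `ploidy`. Missing values are the
#' `NA` token and stay missing; nothing is imputed.
#'
#' @param path input TSV path.
#' @return a data.frame of class `ClinicalTable`.
#' @export
read_clinical_table <- function(path) {
  df <- read_table(path)
  clinical_table(df)
}

#' Validate a clinical table
#' @param df data.frame with at least `sample_id`, `os_time`, `os_event`.
#' @return the validated table.
#' @export
clinical_table <- function(df) {
  kt_assert(all(c("sample_id", "os_time", "os_event") %in% names(df)),
            "clinical table needs sample_id, os_time, os_event")
  df$sample_id <- as.character(df$sample_id)
  kt_assert(!anyDuplicated(df$sample_id), "duplicated sample ids in clinical table")
  kt_assert(all(df$os_time >= 0, na.rm = TRUE), "os_time must be >= 0")
  df$os_event <- as.logical(df$os_event)
  if (!is.null(df$purity))
    kt_assert(all(df$purity > 0 & df$purity <= 1, na.rm = TRUE),
              "purity must be in (0, 1]")
  if (!is.null(df$ploidy))
    kt_assert(all(df$ploidy > 0, na.rm = TRUE), "ploidy must be > 0")
  for (col in c("cd8_fraction", "b_fraction"))
    if (!is.null(df[[col]]))
      kt_assert(all(df[[col]] >= 0 & df[[col]] <= 1, na.rm = TRUE),
                sprintf("%s must be in [0, 1]", col))
  if (!is.null(df$tmb))
    kt_assert(all(df$tmb >= 0, na.rm = TRUE), "tmb must be >= 0")
  if (!is.null(df$pdl1_positive)) df$pdl1_positive <- as.logical(df$pdl1_positive)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}
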