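#' Copy-number profile container
#'
#' A `CopyNumberProfile` holds log2 copy-number values (log2 of total copy
#' number relative to ploidy; 0 = copy-neutral) for one resolution level:
#' whole chromosome arms (`"1q"`, `"9p"`), cytobands (`"1q21"`), or genes
#' (HGNC symbols). Values are stored as a samples x features numeric matrix;
#' missing measurements are `NA`.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   unique dimnames. Values must be finite or `NA`.
#' @param level one of `"arm"`, `"cytoband"`, `"gene"`. Determines the
#'   feature-naming convention, which is validated.
#' @return an object of class `CopyNumberProfile`.
#' @examples
#' m <- matrix(c(0.4, 0, -0.3, 0.1), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("1q", "9p")))
#' cn <- copy_number_profile(m, level = "arm")
#' @export
copy_number_profile <- function(values, level = c("arm", "cytoband", "gene")) {
  level <- match.arg(level)
  kt_assert(is.matrix(values) && is.numeric(values),
            "`values` must be a numeric matrix (samples x features)")
  kt_assert(!is.null(rownames(values)) && !is.null(colnames(values)),
            "`values` must carry sample (row) and feature (column) names")
  kt_assert(!anyDuplicated(rownames(values)), "duplicated sample ids")
  kt_assert(!anyDuplicated(colnames(values)), "duplicated feature ids")
  kt_assert(all(is.finite(values) | is.na(values)),
            "log2 copy-number values must be finite or NA")
  validate_feature_names(colnames(values), level)
  structure(list(level = level, values = values),
            class = "CopyNumberProfile")
}

ARM_REGEX      <- "^(1[0-9]|2[0-2]|[1-9]|X|Y)[pq]$"
CYTOBAND_REGEX <- "^(1[0-9]|2[0-2]|[1-9]|X|Y)[pq][0-9]+(\\.[0-9]+)?$"

validate_feature_names <- function(ids, level) {
  kt_assert(all(nzchar(ids)), "empty feature id")
  bad <- switch(level,
    arm      = ids[!grepl(ARM_REGEX, ids)],
    cytoband = ids[!grepl(CYTOBAND_REGEX, ids)],
    gene     = character(0)
  )
  kt_assert(length(bad) == 0,
            sprintf("feature ids not valid at level '%s': %s",
                    level, paste(head(bad, 5), collapse = ", ")))
  invisible(TRUE)
}

#' @export
print.CopyNumberProfile <- function(x, ...) {
  cat(sprintf("CopyNumberProfile [%s]: %d samples x %d features\n",
              x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.CopyNumberProfile <- function(x) dim(x$values)

sample_ids  <- function(profile) rownames(profile$values)
feature_ids <- function(profile) colnames(profile$values)

#' Read a GISTIC2-style copy-number table
#'
#' Reads a tab-delimited table whose first column is the feature id and whose
#' remaining columns are samples (the orientation GISTIC2 broad-values and
#' all-data-by-genes files use), returning a [copy_number_profile()] with
#' samples in rows. Cells equal to `"NA"` or empty are stored as missing;
#' any other non-numeric cell is a parse error reported with its row and
#' column.
#'
#' @param path path to a TSV file.
#' @param level resolution level of the feature ids; see
#'   [copy_number_profile()].
#' @return a `CopyNumberProfile`.
#' @export
read_copy_number_table <- function(path, level = c("arm", "cytoband", "gene")) {
  level <- match.arg(level)
  kt_assert(file.exists(path), sprintf("file not found: %s", path),
            "karyotme_io_error")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2)
    kt_stop(sprintf("malformed header in %s: need a feature column plus >=1 sample column", path),
            "karyotme_format_error")
  feats <- raw[[1]]
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0)
    kt_stop(sprintf("duplicated feature row(s): %s",
                    paste(head(dup, 5), collapse = ", ")),
            "karyotme_format_error")
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells) & !(cells %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    kt_stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                    cells[bad[1, 1], bad[1, 2]], feats[bad[1, 1]],
                    colnames(cells)[bad[1, 2]]),
            "karyotme_parse_error")
  dimnames(num) <- list(feats, colnames(cells))
  copy_number_profile(t(num), level = level)
}

#' Write a copy-number profile as a feature-by-sample TSV
#'
#' Inverse of [read_copy_number_table()]: features in rows, samples in
#' columns, missing written as `NA`, numbers at full (round-trip) precision.
#'
#' @param profile a `CopyNumberProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_copy_number_table <- function(profile, path) {
  m <- t(profile$values)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}
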