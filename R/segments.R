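#' Read a SEG file of segmented log2 copy number
#'
#' Parses a tab-delimited segment file (sample, chromosome, start, end,
#' segment mean as the last column; an optional probe-count column between
#' is ignored, as in GISTIC2 `.seg` files). Chromosome names are normalized
#' to `"1"..."22", "X", "Y"` (a `chr` prefix is stripped; `23`/`24` map to
#' `X`/`Y`). Coordinates are stored 0-based half-open; files using the
#' 1-based inclusive dialect must set `one_based = TRUE`, which decrements
#' the start by one on load.
#'
#' @param path path to the SEG file (with header).
#' @param one_based logical; set `TRUE` when the file uses 1-based inclusive
#'   coordinates.
#' @return a `data.frame` with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `log2_cn`, of class `SegmentTable`.
#' @export
read_segments <- function(path, one_based = FALSE) {
  kt_assert(file.exists(path), sprintf("file not found: %s", path),
            "karyotme_io_error")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 5)
    kt_stop("SEG file needs >= 5 columns: sample, chrom, start, end, [n_probes,] mean",
            "karyotme_format_error")
  seg <- data.frame(
    sample_id  = as.character(raw[[1]]),
    chromosome = normalize_chromosome(raw[[2]]),
    start      = as.numeric(raw[[3]]),
    end        = as.numeric(raw[[4]]),
    log2_cn    = as.numeric(raw[[ncol(raw)]]),
    stringsAsFactors = FALSE
  )
  if (one_based) seg$start <- seg$start - 1
  segment_table(seg)
}

#' Construct and validate a segment table
#'
#' @param seg data.frame with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `log2_cn`; coordinates 0-based half-open.
#' @return the validated `SegmentTable`.
#' @export
segment_table <- function(seg) {
  need <- c("sample_id", "chromosome", "start", "end", "log2_cn")
  kt_assert(all(need %in% names(seg)),
            paste("segment table needs columns:", paste(need, collapse = ", ")))
  seg$chromosome <- normalize_chromosome(seg$chromosome)
  bad <- which(!(seg$start < seg$end))
  if (length(bad) > 0)
    kt_stop(sprintf("segment with start >= end at row %d (%s:%s-%s)",
                    bad[1], seg$chromosome[bad[1]], seg$start[bad[1]],
                    seg$end[bad[1]]),
            "karyotme_validation_error")
  kt_assert(!anyNA(seg$log2_cn), "NaN/NA segment mean not allowed")
  class(seg) <- c("SegmentTable", "data.frame")
  seg
}

CHROMOSOMES <- c(as.character(1:22), "X", "Y")

normalize_chromosome <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  bad <- unique(x[!(x %in% CHROMOSOMES)])
  if (length(bad) > 0)
    kt_stop(sprintf("unknown chromosome token(s): %s",
                    paste(head(bad, 5), collapse = ", ")),
            "karyotme_validation_error")
  x
}

#' Read a UCSC cytoBand file
#'
#' Expects the standard headerless `cytoBand.txt` layout: chrom, start, end,
#' band (e.g. `q21.1`), Giemsa stain. Bands are returned 0-based half-open
#' with derived full band names (`"1q21.1"`) and arm labels (`"1q"`), sorted
#' and checked for overlap within each chromosome.
#'
#' @param path path to a cytoBand.txt-style file.
#' @return a `data.frame` (`CytobandMap`) with columns `chromosome`,
#'   `start`, `end`, `band_name`, `arm`.
#' @export
read_cytoband_map <- function(path) {
  kt_assert(file.exists(path), sprintf("file not found: %s", path),
            "karyotme_io_error")
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  kt_assert(ncol(raw) >= 4, "cytoBand file needs >= 4 columns",
            "karyotme_format_error")
  bands <- data.frame(
    chromosome = normalize_chromosome(raw[[1]]),
    start      = as.numeric(raw[[2]]),
    end        = as.numeric(raw[[3]]),
    band       = as.character(raw[[4]]),
    stringsAsFactors = FALSE
  )
  kt_assert(all(grepl("^[pq]", bands$band)),
            "band names must start with the arm letter p or q")
  bands$band_name <- paste0(bands$chromosome, bands$band)
  bands$arm <- paste0(bands$chromosome, substr(bands$band, 1, 1))
  bands <- bands[order(match(bands$chromosome, CHROMOSOMES), bands$start), ]
  for (ch in unique(bands$chromosome)) {
    b <- bands[bands$chromosome == ch, ]
    kt_assert(all(b$start < b$end), sprintf("degenerate band on chr%s", ch))
    kt_assert(all(b$start[-1] >= b$end[-nrow(b)]),
              sprintf("overlapping bands on chr%s", ch))
  }
  rownames(bands) <- NULL
  out <- bands[, c("chromosome", "start", "end", "band_name", "arm")]
  class(out) <- c("CytobandMap", "data.frame")
  out
}

# Collapse a cytoband map to feature intervals at the requested level.
# Cytoband features are major bands ("1q21", sub-bands merged); arm features
# span from the first to the last band of the arm.
feature_intervals <- function(bands, level = c("arm", "cytoband")) {
  level <- match.arg(level)
  key <- if (level == "arm") bands$arm else sub("\\.[0-9]+$", "", bands$band_name)
  out <- do.call(rbind, lapply(split(bands, key), function(b) {
    data.frame(feature_id = unique(if (level == "arm") b$arm
                                   else sub("\\.[0-9]+$", "", b$band_name)),
               chromosome = b$chromosome[1],
               start = min(b$start), end = max(b$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$chromosome, CHROMOSOMES), out$start), ]
}

#' Project segments onto arm or cytoband features
#'
#' Each feature value is the overlap-length-weighted mean of the segment
#' log2 copy-number means over the feature's genomic interval. Features
#' whose covered fraction is below `min_coverage` are set to missing; a
#' sample with no overlap anywhere yields an all-missing row plus a warning.
#'
#' @param segments a `SegmentTable` (see [read_segments()]).
#' @param bands a `CytobandMap` (see [read_cytoband_map()]).
#' @param level `"arm"` or `"cytoband"`.
#' @param min_coverage minimum covered fraction of the feature interval
#'   before a value is emitted (default 0.5).
#' @return a `CopyNumberProfile` at the requested level.
#' @export
map_segments_to_features <- function(segments, bands,
                                     level = c("arm", "cytoband"),
                                     min_coverage = 0.5) {
  level <- match.arg(level)
  kt_assert(min_coverage >= 0 && min_coverage <= 1,
            "`min_coverage` must be in [0, 1]", "karyotme_config_error")
  feats <- feature_intervals(bands, level)
  samples <- unique(segments$sample_id)
  vals <- matrix(NA_real_, length(samples), nrow(feats),
                 dimnames = list(samples, feats$feature_id))
  for (s in samples) {
    seg_s <- segments[segments$sample_id == s, ]
    any_overlap <- FALSE
    for (j in seq_len(nrow(feats))) {
      f <- feats[j, ]
      seg_f <- seg_s[seg_s$chromosome == f$chromosome, ]
      if (nrow(seg_f) == 0) next
      ov <- pmin(seg_f$end, f$end) - pmax(seg_f$start, f$start)
      keep <- ov > 0
      if (!any(keep)) next
      any_overlap <- TRUE
      covered <- sum(ov[keep])
      if (covered / (f$end - f$start) >= min_coverage)
        vals[s, j] <- sum(ov[keep] * seg_f$log2_cn[keep]) / covered
    }
    if (!any_overlap)
      warning(sprintf("sample %s overlaps no %s feature; all values missing",
                      s, level))
  }
  copy_number_profile(vals, level = level)
}
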