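#' Default cytotoxic signature genes
#'
#' The seven cytotoxic-lymphocyte genes whose ranked expression defines the
#' Immune Score: components of the T-cell receptor / CD3 complex (CD247,
#' CD2, CD3E) and cytolytic effector genes (GZMH, GZMK, PRF1, NKG7). Their
#' joint expression tracks CD8 T-cell and NK-cell infiltration in bulk
#' RNA-seq.
#' @export
CYTOTOXIC_SIGNATURE <- c("CD247", "CD2", "CD3E", "GZMH", "NKG7", "PRF1", "GZMK")

#' Rank-sum cytotoxic Immune Score
#'
#' Computes the per-sample Immune Score (IS) from bulk expression: each
#' signature gene is ranked across all samples of the cohort (ascending,
#' ties averaged), the per-sample ranks are summed, and the sums are
#' re-ranked (ascending, ties averaged) to give the final IS rank. Higher
#' expression of the cytotoxic genes therefore yields a higher IS
#' ("hotter" tumor). Because only ranks enter, the score is invariant to
#' any per-gene strictly increasing transform of expression (log,
#' quantile normalization, ...). Scores are cohort-relative and must not
#' be compared across cohorts.
#'
#' @param expr numeric matrix of normalized expression, genes in rows,
#'   samples in columns; >= 2 samples.
#' @param signature gene symbols of the signature (default the seven
#'   cytotoxic genes, [CYTOTOXIC_SIGNATURE]).
#' @param min_genes minimum number of signature genes that must be present
#'   in `expr` (default: all of them). Fewer present genes is an error
#'   listing the missing symbols.
#' @return a data.frame (`ImmuneScoreTable`) with columns `sample_id`,
#'   `rank_sum`, `is_rank`; the genes used are stored in the
#'   `signature_genes` attribute.
#' @examples
#' expr <- matrix(rexp(14 * 6), 14, 6,
#'                dimnames = list(c(CYTOTOXIC_SIGNATURE, paste0("G", 1:7)),
#'                                paste0("S", 1:6)))
#' is_tab <- cytotoxic_immune_score(expr)
#' @export
cytotoxic_immune_score <- function(expr, signature = CYTOTOXIC_SIGNATURE,
                                   min_genes = length(signature)) {
  kt_assert(is.matrix(expr) && ncol(expr) >= 2,
            "`expr` must be a genes x samples matrix with >= 2 samples")
  present <- intersect(signature, rownames(expr))
  if (length(present) < min_genes)
    kt_stop(sprintf("signature genes missing from expression: %s",
                    paste(setdiff(signature, present), collapse = ", ")),
            "karyotme_validation_error")
  sub <- expr[present, , drop = FALSE]
  gene_ranks <- t(apply(sub, 1, rank, ties.method = "average"))
  rank_sum <- colSums(gene_ranks)
  is_rank <- rank(rank_sum, ties.method = "average")
  structure(data.frame(sample_id = colnames(expr), rank_sum = rank_sum,
                       is_rank = is_rank, stringsAsFactors = FALSE,
                       row.names = NULL),
            signature_genes = present,
            class = c("ImmuneScoreTable", "data.frame"))
}

#' Classify samples as immune cold / intermediate / hot
#'
#' Samples in the bottom `low_pct` percent of the Immune Score are immune
#' cold; samples in the top `high_pct` percent are immune hot; the rest are
#' intermediate. Boundaries use a ceiling rule on counts: with `n` samples
#' and distinct scores, exactly `ceiling(low_pct/100 * n)` are cold and
#' `ceiling(high_pct/100 * n)` are hot. With tie-averaged ranks a boundary
#' tie can leave fewer samples in the extreme classes (all-tied cohorts are
#' entirely intermediate); the cutoff ranks used are recorded in
#' attributes.
#'
#' @param scores an `ImmuneScoreTable` from [cytotoxic_immune_score()].
#' @param low_pct,high_pct percentile widths of the cold and hot classes
#'   (defaults 30/30); must sum to < 100.
#' @return the table with an added `is_class` factor column
#'   (`cold`/`intermediate`/`hot`) and cutoff attributes.
#' @export
binarize_immune_score <- function(scores, low_pct = 30, high_pct = 30) {
  kt_assert(low_pct + high_pct < 100,
            "low_pct + high_pct must be < 100", "karyotme_config_error")
  kt_assert(low_pct > 0 && high_pct > 0,
            "percentile widths must be positive", "karyotme_config_error")
  n <- nrow(scores)
  kt_assert(n >= 4, "need >= 4 samples to binarize")
  cold_cut <- ceiling(low_pct / 100 * n)           # cold iff is_rank <= cold_cut
  hot_cut  <- n - ceiling(high_pct / 100 * n) + 1  # hot iff is_rank >= hot_cut
  cls <- rep("intermediate", n)
  cls[scores$is_rank <= cold_cut] <- "cold"
  cls[scores$is_rank >= hot_cut] <- "hot"
  scores$is_class <- factor(cls, levels = c("cold", "intermediate", "hot"))
  attr(scores, "cold_cutoff_rank") <- cold_cut
  attr(scores, "hot_cutoff_rank") <- hot_cut
  attr(scores, "low_pct") <- low_pct
  attr(scores, "high_pct") <- high_pct
  scores
}

#' Default cell-type vocabulary for deconvolution scores
#' @export
CELL_TYPES <- c("CD8_T", "CD4_T", "B", "NK", "anti_tumor_macrophage",
                "pro_tumor_macrophage", "dendritic", "neutrophil",
                "fibroblast", "endothelial")

# xCell-style names mapped onto the canonical vocabulary
DEFAULT_CELLTYPE_ALIASES <- c(
  "CD8+ T-cells"   = "CD8_T",
  "CD4+ T-cells"   = "CD4_T",
  "B-cells"        = "B",
  "NK cells"       = "NK",
  "Macrophages M1" = "anti_tumor_macrophage",
  "Macrophages M2" = "pro_tumor_macrophage",
  "DC"             = "dendritic",
  "Neutrophils"    = "neutrophil",
  "Fibroblasts"    = "fibroblast",
  "Endothelial cells" = "endothelial"
)

#' Load a cell-type enrichment score table
#'
#' Reads deconvolution output (e.g. xCell) as a TSV with sample ids in the
#' first column and one column per cell type. Cell-type names are passed
#' through an alias map onto a canonical vocabulary and, if `allowed` is
#' given, validated against it. Scores must be non-negative.
#'
#' @param path input TSV path (samples x cell types).
#' @param aliases named character vector mapping input names to canonical
#'   names; defaults to an xCell-style map. Unmapped names pass through.
#' @param allowed optional character vector of permitted canonical names
#'   (default [CELL_TYPES]); an unknown cell type is an error. `NULL`
#'   disables the check.
#' @return numeric matrix samples x cell types (`CellTypeScoreTable`).
#' @export
load_celltype_scores <- function(path, aliases = DEFAULT_CELLTYPE_ALIASES,
                                 allowed = CELL_TYPES) {
  kt_assert(file.exists(path), sprintf("file not found: %s", path),
            "karyotme_io_error")
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  kt_assert(ncol(raw) >= 2, "cell-type table needs sample column + scores",
            "karyotme_format_error")
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1]])
  celltype_scores(m, aliases = aliases, allowed = allowed)
}

#' Validate and normalize a cell-type score matrix
#' @param m numeric matrix, samples x cell types, non-negative.
#' @inheritParams load_celltype_scores
#' @return the validated matrix with canonical column names.
#' @export
celltype_scores <- function(m, aliases = DEFAULT_CELLTYPE_ALIASES,
                            allowed = CELL_TYPES) {
  kt_assert(is.matrix(m) && is.numeric(m), "scores must be a numeric matrix")
  hit <- colnames(m) %in% names(aliases)
  colnames(m)[hit] <- aliases[colnames(m)[hit]]
  if (!is.null(allowed)) {
    bad <- setdiff(colnames(m), allowed)
    kt_assert(length(bad) == 0,
              sprintf("unknown cell type(s) without alias: %s",
                      paste(bad, collapse = ", ")))
  }
  kt_assert(all(m >= 0, na.rm = TRUE), "negative cell-type score")
  kt_assert(!anyDuplicated(rownames(m)), "duplicated sample ids")
  class(m) <- c("CellTypeScoreTable", "matrix", "array")
  m
}
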