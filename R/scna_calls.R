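#' Adjust log2 copy number for tumor purity and ploidy
#'
#' Corrects observed (mixture) copy number for normal-cell contamination
#' with the standard mixture formula, then re-expresses tumor copy number
#' relative to tumor ploidy. Per sample with purity \eqn{\alpha} and ploidy
#' \eqn{\tau}:
#' \deqn{CN_{obs} = 2 \cdot 2^{x},\quad
#'       CN_t = \frac{CN_{obs} - 2(1-\alpha)}{\alpha},\quad
#'       x' = \log_2(\max(CN_t, \epsilon) / \tau)}
#' where \eqn{x} is the raw log2 ratio. With purity 1 and ploidy 2 the
#' adjustment is the identity.
#'
#' @param profile a `CopyNumberProfile` of raw log2 ratios.
#' @param clinical a `ClinicalTable` carrying `purity` and `ploidy` columns.
#' @param on_missing what to do when a profiled sample lacks purity/ploidy:
#'   `"skip"` (leave its values untouched, with a warning) or `"error"`.
#' @param eps floor applied to the corrected tumor copy number before the
#'   log (default 0.01 copies), preventing `-Inf` for homozygous losses in
#'   impure samples.
#' @return a `CopyNumberProfile` of adjusted values.
#' @export
adjust_for_purity_ploidy <- function(profile, clinical,
                                     on_missing = c("skip", "error"),
                                     eps = 0.01) {
  on_missing <- match.arg(on_missing)
  kt_assert(inherits(profile, "CopyNumberProfile"), "not a CopyNumberProfile")
  kt_assert(all(c("purity", "ploidy") %in% names(clinical)),
            "clinical table lacks purity/ploidy columns")
  kt_assert(eps > 0, "`eps` must be positive", "karyotme_config_error")
  idx <- match(sample_ids(profile), clinical$sample_id)
  purity <- clinical$purity[idx]
  ploidy <- clinical$ploidy[idx]
  kt_assert(all(purity > 0 & purity <= 1, na.rm = TRUE),
            "purity must be in (0, 1]")
  kt_assert(all(ploidy > 0, na.rm = TRUE), "ploidy must be > 0")
  missing <- is.na(purity) | is.na(ploidy)
  if (any(missing)) {
    msg <- sprintf("%d sample(s) lack purity/ploidy: %s", sum(missing),
                   paste(head(sample_ids(profile)[missing], 5), collapse = ", "))
    if (on_missing == "error") kt_stop(msg, "karyotme_validation_error")
    warning(paste(msg, "- left unadjusted"))
  }
  vals <- profile$values
  for (i in which(!missing)) {
    cn_obs <- 2 * 2^vals[i, ]
    cn_t <- (cn_obs - 2 * (1 - purity[i])) / purity[i]
    vals[i, ] <- log2(pmax(cn_t, eps) / ploidy[i])
  }
  copy_number_profile(vals, level = profile$level)
}

#' Call discrete gains and losses
#'
#' Thresholds a log2 copy-number profile into `gain` / `neutral` / `loss`
#' calls. Comparisons are strict: a value is a gain iff it exceeds
#' `gain_thr` and a loss iff it is below `loss_thr`; values exactly at a
#' threshold are neutral. Missing values stay missing.
#'
#' @param profile a `CopyNumberProfile`.
#' @param gain_thr gain threshold on log2 copy number (default 0.2).
#' @param loss_thr loss threshold (default -0.2).
#' @return a character matrix (samples x features) of class `SCNACallTable`
#'   with values `"gain"`, `"neutral"`, `"loss"` or `NA`, carrying the
#'   thresholds as attributes.
#' @export
call_scna <- function(profile, gain_thr = 0.2, loss_thr = -0.2) {
  kt_assert(loss_thr < 0 && 0 < gain_thr,
            "thresholds must satisfy loss_thr < 0 < gain_thr",
            "karyotme_config_error")
  v <- profile$values
  calls <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  calls[!is.na(v)] <- "neutral"
  calls[!is.na(v) & v > gain_thr] <- "gain"
  calls[!is.na(v) & v < loss_thr] <- "loss"
  structure(calls, gain_thr = gain_thr, loss_thr = loss_thr,
            level = profile$level, class = c("SCNACallTable", "matrix", "array"))
}

#' Per-sample aneuploidy score
#'
#' The aneuploidy score (AS) of a sample is the sum of absolute log2
#' copy-number values over all non-missing features at one resolution
#' level; it quantifies global chromosomal-instability burden and serves
#' as a covariate in every association model. A sample with no usable
#' feature gets a missing score with a warning.
#'
#' @param profile a `CopyNumberProfile`.
#' @return a data.frame (`AneuploidyScoreTable`) with columns `sample_id`
#'   and `AS`, carrying the level as an attribute.
#' @export
aneuploidy_score <- function(profile) {
  v <- profile$values
  n_ok <- rowSums(!is.na(v))
  as_val <- rowSums(abs(v), na.rm = TRUE)
  as_val[n_ok == 0] <- NA_real_
  if (any(n_ok == 0))
    warning(sprintf("sample(s) with all-missing features: %s",
                    paste(head(rownames(v)[n_ok == 0], 5), collapse = ", ")))
  structure(data.frame(sample_id = rownames(v), AS = as_val,
                       stringsAsFactors = FALSE, row.names = NULL),
            level = profile$level,
            class = c("AneuploidyScoreTable", "data.frame"))
}
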