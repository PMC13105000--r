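# Direction-stratified association engine.
#
# For every feature, a "gain" model excludes samples called loss at that
# feature and a "loss" model excludes samples called gain, so that the two
# directions of copy-number change never confound each other. The continuous
# log2 copy number is the predictor of interest; the discrete call is used
# only for exclusion. The per-sample aneuploidy score always enters as a
# covariate to absorb global chromosomal instability.

align_samples <- function(profile, calls, as_table, extra_ids = NULL) {
  ids <- Reduce(intersect, Filter(Negate(is.null), list(
    sample_ids(profile), rownames(calls), as_table$sample_id, extra_ids)))
  kt_assert(length(ids) >= 2, "fewer than 2 samples shared across inputs")
  ids
}

#' Logistic models of immune class on copy number
#'
#' Fits, per feature, a logistic regression of an immune-class indicator
#' (`phenotype` vs all other samples) on the feature's continuous log2
#' copy number plus the aneuploidy score. For a `direction = "gain"` model,
#' samples whose discrete call at that feature is a loss are excluded (and
#' vice versa). Features with fewer than `min_n` usable samples, a constant
#' predictor, or no outcome variation are skipped with a machine-readable
#' reason code.
#'
#' @param profile `CopyNumberProfile` (continuous log2 values).
#' @param calls `SCNACallTable` from [call_scna()] at the same level.
#' @param is_table binarized `ImmuneScoreTable` (needs `is_class`).
#' @param as_table `AneuploidyScoreTable` from [aneuploidy_score()].
#' @param direction `"gain"` or `"loss"`: which copy-number direction this
#'   model interrogates.
#' @param phenotype `"cold"` or `"hot"`: the immune class coded 1.
#' @param min_n minimum usable samples per feature (default 20).
#' @param drop_intermediate drop intermediate-class samples instead of
#'   coding them 0 (default `FALSE`).
#' @param tumor_type cohort label copied into the output.
#' @return a data.frame (`AssociationResult`) with one row per feature:
#'   `tumor_type`, `level`, `feature_id`, `direction`, `phenotype`,
#'   `effect` (coefficient of the log2 term), `p`, `n_used`, `reason`
#'   (`NA` when fitted; `too_few_samples`, `no_outcome_variation`,
#'   `constant_predictor`, or `all_excluded` otherwise).
#' @export
fit_is_logistic <- function(profile, calls, is_table, as_table,
                            direction = c("gain", "loss"),
                            phenotype = c("cold", "hot"),
                            min_n = 20, drop_intermediate = FALSE,
                            tumor_type = "cohort") {
  direction <- match.arg(direction)
  phenotype <- match.arg(phenotype)
  kt_assert("is_class" %in% names(is_table),
            "is_table must be binarized (see binarize_immune_score)")
  ids <- align_samples(profile, calls, as_table, is_table$sample_id)
  cls <- setNames(as.character(is_table$is_class), is_table$sample_id)[ids]
  as_vec <- setNames(as_table$AS, as_table$sample_id)[ids]
  opposite <- if (direction == "gain") "loss" else "gain"

  rows <- lapply(feature_ids(profile), function(f) {
    x <- profile$values[ids, f]
    cl <- calls[ids, f]
    keep <- !is.na(x) & !is.na(cl) & !is.na(as_vec) & cl != opposite
    if (drop_intermediate) keep <- keep & cls != "intermediate"
    out <- data.frame(tumor_type = tumor_type, level = profile$level,
                      feature_id = f, direction = direction,
                      phenotype = phenotype, effect = NA_real_, p = NA_real_,
                      n_used = sum(keep), reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (sum(keep) == 0) { out$reason <- "all_excluded"; return(out) }
    if (sum(keep) < min_n) { out$reason <- "too_few_samples"; return(out) }
    y <- as.integer(cls[keep] == phenotype)
    if (length(unique(y)) < 2) { out$reason <- "no_outcome_variation"; return(out) }
    if (stats::sd(x[keep]) == 0) { out$reason <- "constant_predictor"; return(out) }
    fit <- suppressWarnings(
      stats::glm(y ~ x[keep] + as_vec[keep], family = stats::binomial()))
    sm <- summary(fit)$coefficients
    if (!"x[keep]" %in% rownames(sm)) { out$reason <- "fit_failed"; return(out) }
    out$effect <- sm["x[keep]", "Estimate"]
    out$p <- sm["x[keep]", "Pr(>|z|)"]
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("AssociationResult", "data.frame")
  res
}

#' Linear models of cell-type abundance on copy number
#'
#' One model per (feature, cell type): the cell-type enrichment score
#' (rank-transformed to normal scores by default, to tame the skew of
#' deconvolution output) is regressed on the feature's continuous log2
#' copy number plus the aneuploidy score, with the same opposite-direction
#' exclusion rule as [fit_is_logistic()]. A negative effect means lower
#' abundance with higher copy number.
#'
#' @inheritParams fit_is_logistic
#' @param celltypes `CellTypeScoreTable` (samples x cell types).
#' @param rank_transform transform scores to normal scores
#'   `qnorm((rank - 0.5) / n)` before fitting (default `TRUE`); `FALSE`
#'   uses the raw scale.
#' @return an `AssociationResult` data.frame with `phenotype` holding the
#'   cell-type name.
#' @export
fit_celltype_linear <- function(profile, calls, celltypes, as_table,
                                direction = c("gain", "loss"),
                                min_n = 20, rank_transform = TRUE,
                                tumor_type = "cohort") {
  direction <- match.arg(direction)
  ids <- align_samples(profile, calls, as_table, rownames(celltypes))
  as_vec <- setNames(as_table$AS, as_table$sample_id)[ids]
  opposite <- if (direction == "gain") "loss" else "gain"

  combos <- expand.grid(feature_id = feature_ids(profile),
                        cell_type = colnames(celltypes),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    f <- combos$feature_id[k]; ct <- combos$cell_type[k]
    x <- profile$values[ids, f]
    cl <- calls[ids, f]
    sc <- celltypes[ids, ct]
    keep <- !is.na(x) & !is.na(cl) & !is.na(as_vec) & !is.na(sc) & cl != opposite
    out <- data.frame(tumor_type = tumor_type, level = profile$level,
                      feature_id = f, direction = direction, phenotype = ct,
                      effect = NA_real_, p = NA_real_, n_used = sum(keep),
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (sum(keep) == 0) { out$reason <- "all_excluded"; return(out) }
    if (sum(keep) < min_n) { out$reason <- "too_few_samples"; return(out) }
    y <- sc[keep]
    if (stats::sd(y) == 0) { out$reason <- "constant_outcome"; return(out) }
    if (stats::sd(x[keep]) == 0) { out$reason <- "constant_predictor"; return(out) }
    if (rank_transform) {
      n <- length(y)
      y <- stats::qnorm((rank(y, ties.method = "average") - 0.5) / n)
    }
    fit <- stats::lm(y ~ x[keep] + as_vec[keep])
    sm <- summary(fit)$coefficients
    if (!"x[keep]" %in% rownames(sm)) { out$reason <- "fit_failed"; return(out) }
    out$effect <- sm["x[keep]", "Estimate"]
    out$p <- sm["x[keep]", "Pr(>|t|)"]
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("AssociationResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment within analysis groups
#'
#' Adds a `q` column with step-up BH-adjusted p-values, computed
#' independently within each group defined by the `group_keys` columns
#' (those present), so that, e.g., different tumor types or SCNA
#' directions never share one correction. Rows with missing `p` (skipped
#' features) get missing `q` and do not count toward the group size.
#'
#' @param results an `AssociationResult` data.frame with a `p` column.
#' @param group_keys columns defining independent adjustment groups.
#' @return `results` with a `q` column.
#' @export
bh_adjust <- function(results,
                      group_keys = c("tumor_type", "level", "direction",
                                     "phenotype")) {
  kt_assert("p" %in% names(results), "results lack a p column")
  pv <- results$p
  kt_assert(all(pv >= 0 & pv <= 1, na.rm = TRUE), "p-values outside [0, 1]")
  keys <- intersect(group_keys, names(results))
  grp <- if (length(keys) > 0)
    interaction(results[keys], drop = TRUE) else factor(rep(1, nrow(results)))
  q <- rep(NA_real_, nrow(results))
  for (g in levels(grp)) {
    sel <- which(grp == g & !is.na(pv))
    if (length(sel) > 0) q[sel] <- stats::p.adjust(pv[sel], method = "BH")
  }
  results$q <- q
  results
}

#' Signed association landscape
#'
#' Reduces the cold and hot models to one signed score per
#' (feature, direction): the phenotype with the smaller adjusted p wins,
#' and the score is `-log10(q)` with hot positive and cold negative
#' (events above the axis associate with an immune-hot microenvironment,
#' events below with immune-cold). Ties, including the degenerate
#' `q = 1` vs `q = 1` case where the score is 0, break toward cold. A
#' feature present in only one table uses that table alone.
#'
#' @param results_cold,results_hot `AssociationResult` data.frames with `q`
#'   columns for the cold and hot phenotype models on the same features.
#' @return data.frame with `feature_id`, `direction`, `q_cold`, `q_hot`,
#'   `winner`, `signed_score`.
#' @export
build_signed_landscape <- function(results_cold, results_hot) {
  kt_assert(all(c("q") %in% names(results_cold)) &&
              all(c("q") %in% names(results_hot)),
            "run bh_adjust first: q column required")
  key <- c("feature_id", "direction")
  m <- merge(results_cold[, c(key, "q")], results_hot[, c(key, "q")],
             by = key, all = TRUE, suffixes = c("_cold", "_hot"))
  qc <- ifelse(is.na(m$q_cold), Inf, m$q_cold)
  qh <- ifelse(is.na(m$q_hot), Inf, m$q_hot)
  hot_wins <- qh < qc
  q_best <- pmin(qc, qh)
  m$winner <- ifelse(hot_wins, "hot", "cold")
  m$signed_score <- ifelse(hot_wins, 1, -1) * (-log10(q_best))
  m$winner[!is.finite(q_best)] <- NA_character_
  m$signed_score[!is.finite(q_best)] <- NA_real_
  m
}

#' Filter cell-type associations by p and directional consistency
#'
#' Applies the two retention rules for copy-number / cell-type
#' associations: any association with `p > p_max` is dropped, and a
#' (feature, cell type) pair whose gain and loss effects share the same
#' sign is dropped entirely — a gain lowering and a loss also lowering the
#' same cell type cannot both reflect copy-number dosage.
#'
#' @param gain_results,loss_results `AssociationResult` data.frames from
#'   [fit_celltype_linear()] for the two directions.
#' @param p_max maximum retained p-value (default 0.2).
#' @return the retained rows of both tables, row-bound.
#' @export
filter_celltype_associations <- function(gain_results, loss_results,
                                         p_max = 0.2) {
  both <- rbind(gain_results, loss_results)
  both <- both[!is.na(both$p) & both$p <= p_max, , drop = FALSE]
  key <- paste(both$feature_id, both$phenotype)
  g <- both[both$direction == "gain", ]
  l <- both[both$direction == "loss", ]
  kg <- paste(g$feature_id, g$phenotype)
  kl <- paste(l$feature_id, l$phenotype)
  shared <- intersect(kg, kl)
  inconsistent <- shared[
    sign(g$effect[match(shared, kg)]) == sign(l$effect[match(shared, kl)])]
  out <- both[!(key %in% inconsistent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count significant associations per cell type
#'
#' Tallies associations with `q < q_thr` by cell type, SCNA direction and
#' abundance direction (`high` if the effect is positive — more copies,
#' more of the cell type — `low` if negative).
#'
#' @param results `AssociationResult` data.frame with `q`.
#' @param q_thr significance threshold on adjusted p (default 0.05).
#' @return data.frame `cell_type`, `direction`, `abundance`, `n`.
#' @export
count_significant_by_celltype <- function(results, q_thr = 0.05) {
  sig <- results[!is.na(results$q) & results$q < q_thr &
                   !is.na(results$effect), , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(cell_type = character(0), direction = character(0),
                      abundance = character(0), n = integer(0)))
  sig$abundance <- ifelse(sig$effect > 0, "high", "low")
  agg <- stats::aggregate(list(n = rep(1L, nrow(sig))),
                          by = list(cell_type = sig$phenotype,
                                    direction = sig$direction,
                                    abundance = sig$abundance), FUN = sum)
  agg[order(agg$cell_type, agg$direction, agg$abundance), , drop = FALSE]
}

#' Compare cell-type proportions between SCNA status groups
#'
#' Two-sided Welch t-tests of per-patient cell-type fractions between
#' patients carrying an alteration at one feature and patients without it
#' (e.g. per-patient single-cell proportions split by inferred copy-number
#' status). Identical degenerate groups (both constant and equal) return
#' t = 0, p = 1.
#'
#' @param proportions numeric matrix patients x cell types (or a named
#'   vector for a single cell type) of fractions in `[0, 1]`.
#' @param scna_status logical vector (or 2-level factor with `TRUE`/altered
#'   first level) per patient: `TRUE` = altered.
#' @param feature_id label copied into the output.
#' @return data.frame (`ProportionComparison`) with `feature_id`,
#'   `cell_type`, `mean_altered`, `mean_unaltered`, `t`, `p`.
#' @export
compare_proportions_by_scna <- function(proportions, scna_status,
                                        feature_id = "feature") {
  if (is.vector(proportions))
    proportions <- matrix(proportions, ncol = 1,
                          dimnames = list(names(proportions), "cell_type"))
  status <- as.logical(scna_status)
  kt_assert(length(status) == nrow(proportions),
            "scna_status length must match patients")
  kt_assert(!anyNA(status), "scna_status must not be missing")
  kt_assert(sum(status) >= 2 && sum(!status) >= 2,
            "each SCNA status group needs >= 2 patients")
  rows <- lapply(colnames(proportions), function(ct) {
    a <- proportions[status, ct]; u <- proportions[!status, ct]
    if (stats::sd(a) == 0 && stats::sd(u) == 0 && mean(a) == mean(u)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, u, var.equal = FALSE)
    }
    data.frame(feature_id = feature_id, cell_type = ct,
               mean_altered = mean(a), mean_unaltered = mean(u),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ProportionComparison", "data.frame")
  out
}
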