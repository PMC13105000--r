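# Arm-level SCNA survival analysis: categorical Gain/Loss/Neutral coding,
# a genome-wide Cox landscape, Kaplan-Meier stratification, and an
# expression-based chromosome-1q inference score for cohorts without DNA.

#' Categorize copy number for survival contrasts
#'
#' Survival models use a wider categorical threshold than the association
#' models: Gain if log2(CN) > `gain_thr`, Loss if below `loss_thr`,
#' Neutral otherwise (strict inequalities; a value exactly at a threshold
#' is Neutral). Missing values stay missing.
#'
#' @param profile an arm-level `CopyNumberProfile`.
#' @param gain_thr,loss_thr thresholds (defaults +0.3 / -0.3).
#' @return character matrix samples x features with values
#'   `"Gain"`/`"Loss"`/`"Neutral"`/`NA` (`SurvivalCategorization`).
#' @export
categorize_for_survival <- function(profile, gain_thr = 0.3, loss_thr = -0.3) {
  kt_assert(loss_thr < 0 && 0 < gain_thr,
            "thresholds must satisfy loss_thr < 0 < gain_thr",
            "karyotme_config_error")
  v <- profile$values
  cat <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  cat[!is.na(v)] <- "Neutral"
  cat[!is.na(v) & v > gain_thr] <- "Gain"
  cat[!is.na(v) & v < loss_thr] <- "Loss"
  structure(cat, gain_thr = gain_thr, loss_thr = loss_thr,
            class = c("SurvivalCategorization", "matrix", "array"))
}

#' Genome-wide SCNA survival landscape
#'
#' For every arm, fits two univariate Cox proportional-hazards models
#' (Efron ties): Gain vs Neutral with Loss samples excluded, and Loss vs
#' Neutral with Gain samples excluded — the same opposite-direction
#' exclusion used by the association engine. The signed survival score is
#' `-log10(p)` with the sign of the log hazard ratio, so deleterious
#' events (HR > 1) sit above the axis. P-values are BH-adjusted across
#' arms within each direction.
#'
#' @param clinical `ClinicalTable` with `os_time` and `os_event`.
#' @param categories `SurvivalCategorization` from
#'   [categorize_for_survival()].
#' @param min_events minimum number of events among the samples entering a
#'   contrast (default 10); contrasts below it are skipped with a reason.
#' @return data.frame with one row per (feature, direction):
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p`, `q`, `n`, `n_events`,
#'   `signed_score`, `reason`.
#' @export
cox_landscape <- function(clinical, categories, min_events = 10) {
  ids <- intersect(clinical$sample_id, rownames(categories))
  kt_assert(length(ids) >= 2, "no shared samples")
  surv <- survival::Surv(
    clinical$os_time[match(ids, clinical$sample_id)],
    clinical$os_event[match(ids, clinical$sample_id)])
  rows <- list()
  for (f in colnames(categories)) {
    for (dir in c("Gain", "Loss")) {
      other <- if (dir == "Gain") "Loss" else "Gain"
      cl <- categories[ids, f]
      keep <- which(!is.na(cl) & cl != other)
      out <- data.frame(feature_id = f, direction = tolower(dir),
                        hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n = length(keep),
                        n_events = sum(clinical$os_event[
                          match(ids[keep], clinical$sample_id)], na.rm = TRUE),
                        signed_score = NA_real_, reason = NA_character_,
                        stringsAsFactors = FALSE)
      x <- as.integer(cl[keep] == dir)
      if (length(unique(x)) < 2) {
        out$reason <- "no_group_variation"
      } else if (out$n_events < min_events) {
        out$reason <- "too_few_events"
      } else {
        fit <- tryCatch(
          survival::coxph(surv[keep] ~ x, ties = "efron"),
          error = function(e) NULL, warning = function(w) {
            suppressWarnings(survival::coxph(surv[keep] ~ x, ties = "efron"))
          })
        if (is.null(fit)) {
          out$reason <- "fit_failed"
        } else {
          sm <- summary(fit)
          out$hazard_ratio <- unname(sm$conf.int[1, "exp(coef)"])
          out$ci_low <- unname(sm$conf.int[1, "lower .95"])
          out$ci_high <- unname(sm$conf.int[1, "upper .95"])
          out$p <- unname(sm$coefficients[1, "Pr(>|z|)"])
          out$signed_score <- sign(log(out$hazard_ratio)) * (-log10(out$p))
        }
      }
      rows[[length(rows) + 1]] <- out
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (dir in unique(res$direction)) {
    sel <- which(res$direction == dir & !is.na(res$p))
    res$q[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  res
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survival estimates per group and a two-sided log-rank
#' test of their equality.
#'
#' @param clinical `ClinicalTable` with `os_time`, `os_event`.
#' @param group_labels vector of group labels aligned with
#'   `clinical$sample_id` (or named by sample id); >= 2 distinct groups
#'   required.
#' @return list with `curves` (data.frame: group, time, n_risk, n_event,
#'   surv), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(clinical, group_labels) {
  if (!is.null(names(group_labels)))
    group_labels <- group_labels[clinical$sample_id]
  kt_assert(length(group_labels) == nrow(clinical),
            "group_labels must align with clinical samples")
  keep <- !is.na(group_labels) & !is.na(clinical$os_time) &
    !is.na(clinical$os_event)
  grp <- factor(group_labels[keep])
  kt_assert(nlevels(grp) >= 2, "need >= 2 groups for a log-rank test")
  surv <- survival::Surv(clinical$os_time[keep], clinical$os_event[keep])
  sf <- survival::survfit(surv ~ grp)
  sd <- survival::survdiff(surv ~ grp)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  strata <- if (is.null(sf$strata)) setNames(length(sf$time), levels(grp)[1]) else sf$strata
  curves <- data.frame(
    group = rep(sub("^grp=", "", names(strata)), strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, stringsAsFactors = FALSE)
  list(curves = curves, chisq = unname(sd$chisq), df = df, p = p)
}

#' Select an expression panel tracking arm copy number
#'
#' Ranks candidate genes on an arm by their DNA-RNA concordance
#' (Spearman correlation of gene copy number with its own expression
#' across samples) and returns the top `k`; the resulting panel lets arm
#' status be inferred from expression alone in cohorts without DNA copy
#' number (default: 50 genes for chromosome 1q). Ties in concordance
#' break lexicographically by gene symbol, so the panel is deterministic.
#'
#' @param cn_gene gene-level `CopyNumberProfile` (reference cohort DNA).
#' @param expr genes x samples expression matrix (same cohort).
#' @param gene_arms optional named vector gene -> arm used to restrict
#'   candidates to `arm`; `NULL` treats every shared gene as a candidate.
#' @param arm arm label the panel targets (default `"1q"`).
#' @param k panel size (default 50).
#' @return character vector of `k` gene symbols; attribute `concordance`
#'   carries their correlations.
#' @export
select_1q_panel <- function(cn_gene, expr, gene_arms = NULL, arm = "1q",
                            k = 50) {
  kt_assert(cn_gene$level == "gene", "cn_gene must be gene-level")
  genes <- intersect(feature_ids(cn_gene), rownames(expr))
  if (!is.null(gene_arms))
    genes <- genes[!is.na(gene_arms[genes]) & gene_arms[genes] == arm]
  ids <- intersect(sample_ids(cn_gene), colnames(expr))
  kt_assert(length(ids) >= 4, "need >= 4 shared samples")
  rho <- vapply(genes, function(g) {
    dna <- cn_gene$values[ids, g]; rna <- expr[g, ids]
    ok <- !is.na(dna) & !is.na(rna)
    if (sum(ok) < 4 || stats::sd(dna[ok]) == 0 || stats::sd(rna[ok]) == 0)
      return(NA_real_)
    suppressWarnings(stats::cor(dna[ok], rna[ok], method = "spearman"))
  }, 0.0)
  eligible <- genes[!is.na(rho)]
  if (length(eligible) < k)
    kt_stop(sprintf("only %d eligible genes on %s (need %d)",
                    length(eligible), arm, k),
            "karyotme_validation_error")
  ord <- order(-rho[eligible], eligible)
  panel <- eligible[ord][seq_len(k)]
  structure(panel, concordance = rho[panel])
}

#' Expression-based arm-gain score
#'
#' Scores each sample as the mean z-score (across samples, of log1p
#' expression) over a copy-number-concordant gene panel, then classifies
#' the top ceiling(n/4) samples — the top quartile — as arm-gain.
#' Constant genes are dropped with a warning; up to `1 - min_present` of
#' the panel may be absent from the expression matrix, with absent genes
#' contributing a z of 0.
#'
#' @param expr genes x samples expression matrix.
#' @param panel character vector of panel genes (see [select_1q_panel()]).
#' @param min_present minimum fraction of panel genes that must be present
#'   (default 0.8).
#' @return data.frame (`ExpressionScore1q`) with `sample_id`, `score`,
#'   and logical `gain` (top-quartile flag); the panel actually used is an
#'   attribute.
#' @export
score_1q_from_expression <- function(expr, panel, min_present = 0.8) {
  kt_assert(ncol(expr) >= 4, "need >= 4 samples")
  present <- intersect(panel, rownames(expr))
  kt_assert(length(present) >= min_present * length(panel),
            sprintf("only %d/%d panel genes present", length(present),
                    length(panel)))
  lg <- log1p(expr[present, , drop = FALSE])
  sds <- apply(lg, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant panel gene(s): %s",
                    paste(present[sds == 0], collapse = ", ")))
    present <- present[sds > 0]
    lg <- lg[present, , drop = FALSE]
  }
  z <- (lg - rowMeans(lg)) / apply(lg, 1, stats::sd)
  # absent genes contribute 0 z: divide the column sums by the panel size used
  score <- colSums(z) / max(length(present), 1)
  n <- ncol(expr)
  n_gain <- ceiling(n / 4)
  ord <- order(-score, colnames(expr))
  gain <- colnames(expr) %in% colnames(expr)[ord][seq_len(n_gain)]
  structure(data.frame(sample_id = colnames(expr), score = score,
                       gain = gain, stringsAsFactors = FALSE,
                       row.names = NULL),
            panel = present,
            class = c("ExpressionScore1q", "data.frame"))
}

#' Multivariate Cox model for ICB-treated cohorts
#'
#' Joint Cox proportional-hazards fit of overall survival on binary-coded
#' covariates: arm-1q gain status, high CD8 T-cell fraction, high B-cell
#' fraction, high tumor mutational burden, and PD-L1 positivity. TMB is
#' dichotomized at `tmb_cut` mut/Mb inclusive (>= 10 by default); the
#' cell fractions split at the cohort median by default. Only complete
#' cases enter; their count is reported. A constant or duplicated
#' covariate is an error naming the offender.
#'
#' @param clinical `ClinicalTable` with `os_time`, `os_event`, and the
#'   optional columns `tmb`, `pdl1_positive`, `cd8_fraction`,
#'   `b_fraction`.
#' @param gain_1q logical vector (aligned with `clinical$sample_id`, or
#'   named by sample id) of arm-1q gain status, e.g. the `gain` column of
#'   [score_1q_from_expression()].
#' @param tmb_cut TMB high/low cutpoint, inclusive (default 10 mut/Mb).
#' @param fraction_quantile quantile splitting the cell fractions into
#'   high vs low (default 0.5 = median; "high" means >= the quantile).
#' @return data.frame (`CoxResult`) with one row per term: `term`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p`, `n`, `n_events`; 1q gain
#'   first, matching the forest-plot order.
#' @export
multivariate_cox <- function(clinical, gain_1q, tmb_cut = 10,
                             fraction_quantile = 0.5) {
  if (!is.null(names(gain_1q))) gain_1q <- gain_1q[clinical$sample_id]
  kt_assert(length(gain_1q) == nrow(clinical),
            "gain_1q must align with clinical samples")
  covs <- data.frame(
    gain_1q = as.logical(gain_1q),
    cd8_high = clinical$cd8_fraction >=
      stats::quantile(clinical$cd8_fraction, fraction_quantile, na.rm = TRUE),
    b_high = clinical$b_fraction >=
      stats::quantile(clinical$b_fraction, fraction_quantile, na.rm = TRUE),
    tmb_high = clinical$tmb >= tmb_cut,
    pdl1_positive = as.logical(clinical$pdl1_positive)
  )
  keep <- stats::complete.cases(covs) & !is.na(clinical$os_time) &
    !is.na(clinical$os_event)
  kt_assert(sum(keep) >= 10, "fewer than 10 complete cases")
  cc <- covs[keep, ]
  const <- names(cc)[vapply(cc, function(v) length(unique(v)) < 2, TRUE)]
  if (length(const) > 0)
    kt_stop(sprintf("constant covariate(s): %s", paste(const, collapse = ", ")),
            "karyotme_validation_error")
  for (i in seq_len(ncol(cc) - 1)) for (j in seq(i + 1, ncol(cc)))
    if (all(cc[[i]] == cc[[j]]))
      kt_stop(sprintf("collinear covariates: %s duplicates %s",
                      names(cc)[j], names(cc)[i]),
              "karyotme_validation_error")
  surv <- survival::Surv(clinical$os_time[keep], clinical$os_event[keep])
  dat <- data.frame(lapply(cc, as.integer))
  fit <- survival::coxph(surv ~ ., data = dat, ties = "efron")
  sm <- summary(fit)
  terms <- rownames(sm$coefficients)
  res <- data.frame(
    term = sub("TRUE$", "", terms),
    hazard_ratio = unname(sm$conf.int[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, "lower .95"]),
    ci_high = unname(sm$conf.int[, "upper .95"]),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    n = sum(keep), n_events = sum(clinical$os_event[keep]),
    stringsAsFactors = FALSE, row.names = NULL)
  want <- c("gain_1q", "cd8_high", "b_high", "tmb_high", "pdl1_positive")
  res <- res[order(match(res$term, want)), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("CoxResult", "data.frame")
  res
}
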