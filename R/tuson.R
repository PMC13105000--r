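# Gene-level prediction of tumor immune suppressor genes (TiSG) and immune
# oncogenes (iOG) from three per-gene correlation parameters:
#   DNA:IS  -- gene copy number vs the cohort Immune Score
#   RNA:IS  -- gene expression vs the Immune Score
#   DNA:RNA -- gene copy number vs its own expression (dosage coupling)

#' Per-gene DNA:IS, RNA:IS and DNA:RNA correlations
#'
#' Computes, for every gene shared between the gene-level copy-number
#' profile and the expression matrix, Spearman correlations (default) of
#' copy number vs Immune Score, expression vs Immune Score, and copy
#' number vs expression, over the samples shared by all three inputs. The
#' IS enters as its rank value. P-values are BH-adjusted per parameter
#' across genes (one cohort = one adjustment group). A constant input
#' vector yields missing correlations with a reason code.
#'
#' @param cn_gene gene-level `CopyNumberProfile`.
#' @param expr genes x samples expression matrix.
#' @param is_table `ImmuneScoreTable` for the same cohort.
#' @param method `"spearman"` (default, consistent with the rank-based IS)
#'   or `"pearson"`.
#' @param min_samples minimum shared samples (default 10).
#' @param tumor_type cohort label.
#' @return data.frame (`GeneImmuneStats`) with per-gene `rho_dna_is`,
#'   `rho_rna_is`, `rho_dna_rna`, matching `p_*` and `q_*` columns, and a
#'   `reason` column for degenerate genes.
#' @export
gene_immune_correlations <- function(cn_gene, expr, is_table,
                                     method = c("spearman", "pearson"),
                                     min_samples = 10,
                                     tumor_type = "cohort") {
  method <- match.arg(method)
  kt_assert(cn_gene$level == "gene", "cn_gene must be a gene-level profile")
  ids <- Reduce(intersect, list(sample_ids(cn_gene), colnames(expr),
                                is_table$sample_id))
  kt_assert(length(ids) >= min_samples,
            sprintf("only %d shared samples (< %d)", length(ids), min_samples))
  genes <- intersect(feature_ids(cn_gene), rownames(expr))
  kt_assert(length(genes) > 0, "no genes shared between copy number and expression")
  is_vec <- setNames(is_table$is_rank, is_table$sample_id)[ids]

  cor_one <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }
  rows <- lapply(genes, function(g) {
    dna <- cn_gene$values[ids, g]
    rna <- expr[g, ids]
    a <- cor_one(dna, is_vec); b <- cor_one(rna, is_vec); d <- cor_one(dna, rna)
    reason <- if (anyNA(c(a[1], b[1], d[1]))) "constant_or_sparse_input" else NA_character_
    data.frame(tumor_type = tumor_type, gene_id = g,
               rho_dna_is = a[1], p_dna_is = a[2],
               rho_rna_is = b[1], p_rna_is = b[2],
               rho_dna_rna = d[1], p_dna_rna = d[2],
               reason = reason, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  for (par in c("dna_is", "rna_is", "dna_rna")) {
    p <- stats[[paste0("p_", par)]]
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    stats[[paste0("q_", par)]] <- q
  }
  class(stats) <- c("GeneImmuneStats", "data.frame")
  stats
}

#' Classify genes as residing in amplified or deleted regions
#'
#' A gene is eligible for iOG calling when amplified and for TiSG calling
#' when deleted. Eligibility is frequency-based: `amplified` if called
#' gain in at least `freq_thr` of cohort samples, `deleted` if called loss
#' in at least `freq_thr`; when both thresholds are met the more frequent
#' direction wins (an exact tie is `neither`).
#'
#' @param calls_gene gene-level `SCNACallTable`.
#' @param freq_thr minimum alteration frequency (default 0.10).
#' @return named character vector gene -> `"amplified"`, `"deleted"`, or
#'   `"neither"`.
#' @export
classify_gene_regions <- function(calls_gene, freq_thr = 0.10) {
  kt_assert(freq_thr > 0 && freq_thr <= 1, "freq_thr must be in (0, 1]",
            "karyotme_config_error")
  apply(calls_gene, 2, function(cl) {
    n <- sum(!is.na(cl))
    if (n == 0) return("neither")
    fg <- sum(cl == "gain", na.rm = TRUE) / n
    fl <- sum(cl == "loss", na.rm = TRUE) / n
    if (fg >= freq_thr && (fl < freq_thr || fg > fl)) "amplified"
    else if (fl >= freq_thr && (fg < freq_thr || fl > fg)) "deleted"
    else "neither"
  })
}

#' Call immune oncogenes and tumor immune suppressor genes
#'
#' Applies the sign-and-threshold rules to per-gene correlation statistics:
#' an `iOG` is a gene in an amplified region with adjusted p < `q_thr` and
#' positive rho for all three parameters; a `TiSG` is a gene in a deleted
#' region with adjusted p < `q_thr` for all three parameters, positive
#' DNA:RNA rho, and negative DNA:IS and RNA:IS rho. All inequalities are
#' strict; everything else is `none`.
#'
#' As printed, the TiSG rule asks a deleted immune-suppressor to correlate
#' negatively with the IS on both DNA and RNA; `flip_is_sign = TRUE`
#' applies the opposite (positive DNA:IS / RNA:IS) convention instead.
#'
#' @param stats `GeneImmuneStats` from [gene_immune_correlations()].
#' @param region_class named vector from [classify_gene_regions()] (or a
#'   `region_class` column already present in `stats`).
#' @param q_thr adjusted-p threshold (default 0.05).
#' @param flip_is_sign reverse the required sign of the two IS correlations
#'   in the TiSG rule (default `FALSE`: literal rule).
#' @return `stats` with added `region_class` and `call` columns
#'   (`iOG` / `TiSG` / `none`).
#' @export
call_iog_tisg <- function(stats, region_class = NULL, q_thr = 0.05,
                          flip_is_sign = FALSE) {
  if (!is.null(region_class))
    stats$region_class <- unname(region_class[stats$gene_id])
  kt_assert("region_class" %in% names(stats),
            "region_class required (see classify_gene_regions)")
  stats$region_class[is.na(stats$region_class)] <- "neither"
  q_ok <- !is.na(stats$q_dna_is) & !is.na(stats$q_rna_is) &
    !is.na(stats$q_dna_rna) &
    stats$q_dna_is < q_thr & stats$q_rna_is < q_thr & stats$q_dna_rna < q_thr
  is_sign <- if (flip_is_sign) -1 else 1
  iog <- q_ok & stats$region_class == "amplified" &
    stats$rho_dna_is > 0 & stats$rho_rna_is > 0 & stats$rho_dna_rna > 0
  tisg <- q_ok & stats$region_class == "deleted" &
    stats$rho_dna_rna > 0 &
    (is_sign * stats$rho_dna_is) < 0 & (is_sign * stats$rho_rna_is) < 0
  stats$call <- "none"
  stats$call[which(iog)] <- "iOG"
  stats$call[which(tisg)] <- "TiSG"
  stats
}

#' LASSO selection of predictive gene-level parameters
#'
#' L1-penalized logistic classification of a binary gene label (e.g. known
#' immune-driver vs background) on standardized candidate features, with
#' the penalty chosen by seeded cross-validation. Features with nonzero
#' coefficients at the selected penalty are returned, strongest first.
#' With duplicated (collinear) informative features the LASSO keeps at
#' least one of the pair but the specific survivor is arbitrary.
#'
#' @param features numeric data.frame or matrix, genes x candidate
#'   features (>= 2 columns).
#' @param labels binary vector (0/1 or logical), both classes present.
#' @param seed RNG seed for the cross-validation folds.
#' @param lambda `"lambda.1se"` (default, parsimonious) or `"lambda.min"`.
#' @param nfolds cross-validation folds (default 10).
#' @return character vector of selected feature names ordered by
#'   decreasing absolute coefficient; attribute `coefficients` carries the
#'   values.
#' @export
lasso_select_parameters <- function(features, labels, seed = 1,
                                    lambda = c("lambda.1se", "lambda.min"),
                                    nfolds = 10) {
  lambda <- match.arg(lambda)
  x <- as.matrix(features)
  kt_assert(ncol(x) >= 2, "need >= 2 candidate features")
  y <- as.integer(as.logical(labels))
  kt_assert(length(unique(y)) == 2, "labels must contain both classes")
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = TRUE, nfolds = nfolds)
  beta <- as.matrix(stats::coef(cv, s = lambda))[-1, 1]  # drop intercept
  sel <- beta[beta != 0]
  sel <- sel[order(-abs(sel))]
  structure(names(sel), coefficients = sel)
}

#' Train a random-forest TiSG classifier against a gold standard
#'
#' Trains a seeded random forest to separate gold-standard genes
#' (e.g. CRISPR-screen-validated immune suppressors) from background
#' genes, with negatives sampled at a fixed ratio from the non-gold
#' universe. Reports AUROC from stratified cross-validation on the
#' training split and on a held-out test split.
#'
#' @param features numeric data.frame/matrix, genes x features, rownames =
#'   gene ids.
#' @param gold_standard character vector of positive gene ids (>= 10 must
#'   be present in `features`).
#' @param neg_ratio negatives sampled per positive (default 5).
#' @param test_frac fraction of genes held out for the test AUROC
#'   (default 0.3, stratified).
#' @param cv_folds folds for the cross-validated AUROC (default 5).
#' @param ntree random-forest trees (default 500).
#' @param seed RNG seed; the same seed reproduces identical AUROCs.
#' @return list with `model` (randomForest fit on the training split),
#'   `cv_auroc`, `test_auroc`, and a `metadata` list (seed, class ratio,
#'   feature names, gene sets).
#' @export
train_tisg_classifier <- function(features, gold_standard, neg_ratio = 5,
                                  test_frac = 0.3, cv_folds = 5,
                                  ntree = 500, seed = 1) {
  x <- as.matrix(features)
  pos <- intersect(rownames(x), gold_standard)
  kt_assert(length(pos) >= 10,
            sprintf("only %d gold-standard positives present (< 10)", length(pos)))
  set.seed(seed)
  neg_pool <- setdiff(rownames(x), gold_standard)
  n_neg <- min(length(neg_pool), neg_ratio * length(pos))
  neg <- sample(neg_pool, n_neg)
  genes <- c(pos, neg)
  y <- factor(ifelse(genes %in% pos, "pos", "neg"), levels = c("neg", "pos"))

  split_strat <- function(g, frac) {
    unlist(lapply(split(g, y[match(g, genes)]), function(s)
      sample(s, round(frac * length(s)))), use.names = FALSE)
  }
  test_genes <- split_strat(genes, test_frac)
  train_genes <- setdiff(genes, test_genes)
  ytr <- y[match(train_genes, genes)]

  # stratified CV on the training split: pool out-of-fold scores
  fold_of <- integer(length(train_genes))
  for (cls in levels(ytr)) {
    idx <- which(ytr == cls)
    fold_of[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  oof <- rep(NA_real_, length(train_genes))
  for (k in seq_len(cv_folds)) {
    tr <- which(fold_of != k); te <- which(fold_of == k)
    if (length(te) == 0) next
    rf <- randomForest::randomForest(x[train_genes[tr], , drop = FALSE],
                                     ytr[tr], ntree = ntree)
    oof[te] <- stats::predict(rf, x[train_genes[te], , drop = FALSE],
                              type = "prob")[, "pos"]
  }
  cv_auroc <- as.numeric(pROC::auc(pROC::roc(ytr, oof, quiet = TRUE,
                                             direction = "<", levels = c("neg", "pos"))))
  model <- randomForest::randomForest(x[train_genes, , drop = FALSE], ytr,
                                      ntree = ntree)
  yte <- y[match(test_genes, genes)]
  pte <- stats::predict(model, x[test_genes, , drop = FALSE],
                        type = "prob")[, "pos"]
  test_auroc <- as.numeric(pROC::auc(pROC::roc(yte, pte, quiet = TRUE,
                                               direction = "<", levels = c("neg", "pos"))))
  list(model = model, cv_auroc = cv_auroc, test_auroc = test_auroc,
       metadata = list(seed = seed, neg_ratio = neg_ratio,
                       features = colnames(x), positives = pos,
                       negatives = neg, test_genes = test_genes))
}

#' Cross-tumor recurrence of iOG/TiSG calls
#'
#' Counts, per gene, the number of tumor types in which it is called iOG
#' or TiSG, and tallies recurrent genes (called in at least `min_types`
#' tumor types) per chromosome arm. Genes without an arm assignment are
#' tallied under `"unassigned"` with a warning.
#'
#' @param calls_by_type named list (tumor type -> data.frame with
#'   `gene_id` and `call` columns, as from [call_iog_tisg()]).
#' @param gene_arms named character vector gene -> arm (e.g. `"1q"`).
#' @param min_types minimum number of tumor types for a gene to count as
#'   recurrent (default 3).
#' @return list with `per_gene` (gene, arm, n_iog, n_tisg) and `per_arm`
#'   (arm, call, n recurrent genes).
#' @export
recurrence_summary <- function(calls_by_type, gene_arms, min_types = 3) {
  kt_assert(length(calls_by_type) > 0, "no call tables supplied")
  all_calls <- do.call(rbind, lapply(names(calls_by_type), function(tt) {
    df <- calls_by_type[[tt]]
    data.frame(tumor_type = tt, gene_id = df$gene_id, call = df$call,
               stringsAsFactors = FALSE)
  }))
  called <- all_calls[all_calls$call %in% c("iOG", "TiSG"), , drop = FALSE]
  genes <- sort(unique(called$gene_id))
  per_gene <- data.frame(
    gene_id = genes,
    arm = unname(gene_arms[genes]),
    n_iog = vapply(genes, function(g)
      sum(called$gene_id == g & called$call == "iOG"), 0L),
    n_tisg = vapply(genes, function(g)
      sum(called$gene_id == g & called$call == "TiSG"), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (anyNA(per_gene$arm)) {
    warning(sprintf("%d recurrent gene(s) lack an arm assignment",
                    sum(is.na(per_gene$arm))))
    per_gene$arm[is.na(per_gene$arm)] <- "unassigned"
  }
  rec <- per_gene[pmax(per_gene$n_iog, per_gene$n_tisg) >= min_types, ,
                  drop = FALSE]
  per_arm <- do.call(rbind, lapply(split(rec, rec$arm), function(b)
    data.frame(arm = b$arm[1],
               n_iog = sum(b$n_iog >= min_types),
               n_tisg = sum(b$n_tisg >= min_types),
               stringsAsFactors = FALSE)))
  rownames(per_arm) <- NULL
  list(per_gene = per_gene, per_arm = per_arm %||%
         data.frame(arm = character(0), n_iog = integer(0),
                    n_tisg = integer(0)))
}
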