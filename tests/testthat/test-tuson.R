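test_that("gene correlations recover perfect monotone relationships", {
  set.seed(21)
  n <- 30
  cn <- matrix(rnorm(n * 2, sd = 0.3), n, 2,
               dimnames = list(sprintf("S%02d", 1:n), c("GENEA", "GENEB")))
  prof <- copy_number_profile(cn, "gene")
  # GENEA expression is a monotone transform of its copy number;
  # GENEB expression is anti-monotone to the immune score
  is_rank <- rank(rnorm(n))
  expr <- rbind(GENEA = exp(cn[, "GENEA"]),
                GENEB = max(is_rank) - is_rank + 1)
  colnames(expr) <- rownames(cn)
  is_tab <- data.frame(sample_id = rownames(cn), is_rank = is_rank)
  st <- gene_immune_correlations(prof, expr, is_tab)
  expect_equal(st$rho_dna_rna[st$gene_id == "GENEA"], 1)
  expect_equal(st$rho_rna_is[st$gene_id == "GENEB"], -1)

  # constant copy number -> missing rho with reason
  cn[, "GENEB"] <- 0
  st2 <- gene_immune_correlations(copy_number_profile(cn, "gene"), expr, is_tab)
  expect_true(is.na(st2$rho_dna_is[st2$gene_id == "GENEB"]))
  expect_equal(st2$reason[st2$gene_id == "GENEB"], "constant_or_sparse_input")
})

test_that("null gene correlations have roughly uniform p-values", {
  set.seed(77)
  n <- 200; g <- 100
  cn <- matrix(rnorm(n * g, sd = 0.3), n, g,
               dimnames = list(sprintf("S%03d", 1:n), sprintf("GENE%03d", 1:g)))
  expr <- matrix(rexp(g * n), g, n,
                 dimnames = list(colnames(cn), rownames(cn)))
  is_tab <- data.frame(sample_id = rownames(cn), is_rank = rank(rnorm(n)))
  st <- gene_immune_correlations(copy_number_profile(cn, "gene"), expr, is_tab)
  frac <- mean(st$p_dna_is < 0.05)
  expect_lt(abs(frac - 0.05), 0.06)
})

test_that("iOG/TiSG calls match a truth-table oracle over all sign/q patterns", {
  grid <- expand.grid(region = c("amplified", "deleted", "neither"),
                      s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1),
                      q1 = c(0.01, 0.06), q2 = c(0.01, 0.06),
                      q3 = c(0.01, 0.06), stringsAsFactors = FALSE)
  stats <- data.frame(
    gene_id = sprintf("GENE%03d", seq_len(nrow(grid))),
    rho_dna_is = 0.5 * grid$s1, rho_rna_is = 0.5 * grid$s2,
    rho_dna_rna = 0.5 * grid$s3,
    q_dna_is = grid$q1, q_rna_is = grid$q2, q_dna_rna = grid$q3,
    region_class = grid$region, stringsAsFactors = FALSE)
  called <- call_iog_tisg(stats)
  want <- vapply(seq_len(nrow(grid)), function(i)
    iog_tisg_oracle(grid$region[i],
                    0.5 * c(grid$s1[i], grid$s2[i], grid$s3[i]),
                    c(grid$q1[i], grid$q2[i], grid$q3[i])), "")
  expect_identical(called$call, want)
  # spot checks straight from the rules
  expect_equal(iog_tisg_oracle("amplified", c(0.4, 0.3, 0.5), rep(0.01, 3)), "iOG")
  expect_equal(iog_tisg_oracle("amplified", c(0.4, 0.3, 0.5), c(0.01, 0.06, 0.01)), "none")
  expect_equal(iog_tisg_oracle("deleted", c(-0.4, -0.3, 0.5), rep(0.01, 3)), "TiSG")

  # flipped IS-sign convention reverses the required TiSG signs
  del <- stats[stats$region_class == "deleted" & stats$rho_dna_rna > 0 &
                 stats$q_dna_is < 0.05 & stats$q_rna_is < 0.05 &
                 stats$q_dna_rna < 0.05, ]
  flipped <- call_iog_tisg(del, flip_is_sign = TRUE)
  expect_true(all((flipped$call == "TiSG") ==
                    (del$rho_dna_is > 0 & del$rho_rna_is > 0)))
})

test_that("Spearman correlations equal the rank-definition oracle on short vectors", {
  set.seed(31)
  for (n in 4:8) {
    for (rep in 1:10) {
      x <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01)
      y <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01)
      cn <- matrix(x, n, 1, dimnames = list(paste0("S", 1:n), "GENEA"))
      expr <- matrix(y, 1, n, dimnames = list("GENEA", paste0("S", 1:n)))
      is_tab <- data.frame(sample_id = paste0("S", 1:n), is_rank = rank(y))
      st <- gene_immune_correlations(copy_number_profile(cn, "gene"), expr,
                                     is_tab, min_samples = 4)
      expect_equal(st$rho_dna_rna, spearman_oracle(x, y), tolerance = 1e-12)
    }
  }
})

test_that("region classification follows alteration frequencies", {
  calls <- structure(matrix(c(rep("gain", 3), rep("neutral", 7),
                              rep("loss", 5), rep("neutral", 5),
                              rep("gain", 2), rep("loss", 1), rep("neutral", 7)),
                            10, 3,
                            dimnames = list(paste0("S", 1:10),
                                            c("GENEA", "GENEB", "GENEC"))),
                     class = c("SCNACallTable", "matrix", "array"))
  rc <- classify_gene_regions(calls, freq_thr = 0.10)
  expect_equal(unname(rc), c("amplified", "deleted", "amplified"))
  rc2 <- classify_gene_regions(calls, freq_thr = 0.40)
  expect_equal(unname(rc2), c("neither", "deleted", "neither"))
})

test_that("LASSO keeps planted features and stays sparse on noise", {
  planted_hits <- 0
  null_small <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    x <- matrix(rnorm(300 * 10), 300, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rbinom(300, 1, plogis(2 * x[, 1] + 2 * x[, 2] - 2 * x[, 3]))
    sel <- lasso_select_parameters(x, y, seed = 600 + s)
    if (all(c("f1", "f2", "f3") %in% sel)) planted_hits <- planted_hits + 1

    y0 <- rbinom(300, 1, 0.5)
    sel0 <- lasso_select_parameters(x, y0, seed = 600 + s)
    if (length(sel0) <= 1) null_small <- null_small + 1
  }
  expect_gte(planted_hits, 9)
  expect_gte(null_small, 8)

  # duplicated informative feature: at least one of the pair survives
  set.seed(99)
  x <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[, 2] <- x[, 1]
  y <- rbinom(300, 1, plogis(3 * x[, 1]))
  sel <- lasso_select_parameters(x, y, seed = 99)
  expect_true(any(c("f1", "f2") %in% sel))

  expect_error(lasso_select_parameters(x, rep(1, 300), seed = 1), "both classes")
})

test_that("random-forest classifier separates a shifted gold standard", {
  gs <- simulate_gold_standard(n_genes = 300, n_positives = 30,
                               separation = 3, seed = 17)
  clf <- train_tisg_classifier(gs$features, gs$positives, seed = 17)
  expect_gte(clf$cv_auroc, 0.9)
  expect_gte(clf$test_auroc, 0.9)

  # same seed twice -> identical AUROCs
  clf2 <- train_tisg_classifier(gs$features, gs$positives, seed = 17)
  expect_identical(clf$cv_auroc, clf2$cv_auroc)
  expect_identical(clf$test_auroc, clf2$test_auroc)

  # label shuffling destroys the signal
  set.seed(18)
  shuffled <- sample(rownames(gs$features), length(gs$positives))
  clf0 <- train_tisg_classifier(gs$features, shuffled, seed = 18)
  expect_gte(clf0$cv_auroc, 0.35)
  expect_lte(clf0$cv_auroc, 0.65)

  expect_error(train_tisg_classifier(gs$features, gs$positives[1:5]), "10")
})

test_that("zero separation in the gold-standard generator yields chance AUROC", {
  gs0 <- simulate_gold_standard(n_genes = 300, n_positives = 30,
                                separation = 0, seed = 23)
  expect_true(all(gs0$positives %in% rownames(gs0$features)))
  clf <- train_tisg_classifier(gs0$features, gs0$positives, seed = 23)
  expect_gte(clf$cv_auroc, 0.35)
  expect_lte(clf$cv_auroc, 0.65)
  expect_error(simulate_gold_standard(separation = -1, seed = 1), "separation")
})

test_that("recurrence summaries count calls per gene and arm", {
  mk <- function(calls) data.frame(gene_id = names(calls), call = unname(calls),
                                   stringsAsFactors = FALSE)
  tabs <- list(
    T1 = mk(c(GENEA = "iOG", GENEB = "TiSG", GENEC = "none")),
    T2 = mk(c(GENEA = "iOG", GENEB = "none", GENEC = "none")),
    T3 = mk(c(GENEA = "iOG", GENEB = "TiSG", GENEC = "iOG")),
    T4 = mk(c(GENEA = "iOG", GENEB = "TiSG", GENEC = "none")))
  arms <- c(GENEA = "1q", GENEB = "9p", GENEC = "1q")
  rs <- recurrence_summary(tabs, arms, min_types = 3)
  pg <- rs$per_gene
  expect_equal(pg$n_iog[pg$gene_id == "GENEA"], 4)
  expect_equal(pg$n_tisg[pg$gene_id == "GENEB"], 3)
  # GENEC called once: below min_types, excluded from arm tallies
  expect_equal(rs$per_arm$n_iog[rs$per_arm$arm == "1q"], 1)
  expect_equal(rs$per_arm$n_tisg[rs$per_arm$arm == "9p"], 1)
  # raising the threshold excludes a count-3 gene
  rs5 <- recurrence_summary(tabs, arms, min_types = 5)
  expect_equal(nrow(rs5$per_arm), 0)
  # missing arm assignment is tallied as unassigned with a warning
  expect_warning(rs_un <- recurrence_summary(tabs, arms[-2], min_types = 3),
                 "arm assignment")
  expect_true("unassigned" %in% rs_un$per_gene$arm)
})
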