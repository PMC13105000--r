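cohort_fixture <- function(seed = 42, n = 300, n_arms = 8, effect = 1.0,
                           feature = "1q", direction = "gain") {
  cfg <- simulation_config(
    n_samples = n, n_arms = n_arms,
    planted_is_effects = data.frame(feature = feature, direction = direction,
                                    effect = effect),
    seed = seed)
  sim <- simulate_cohort(cfg)
  sim$is_tab <- binarize_immune_score(cytotoxic_immune_score(sim$expression))
  sim$calls <- call_scna(sim$arm_profile)
  sim$as_tab <- aneuploidy_score(sim$arm_profile)
  sim
}

test_that("a planted gain-to-cold arm effect is detected with the right sign", {
  sim <- cohort_fixture(seed = 42)
  res <- bh_adjust(fit_is_logistic(sim$arm_profile, sim$calls, sim$is_tab,
                                   sim$as_tab, "gain", "cold"))
  planted <- res[res$feature_id == "1q", ]
  expect_gt(planted$effect, 0)
  expect_lt(planted$q, 0.05)
})

test_that("opposite-direction samples are excluded from each model", {
  sim <- cohort_fixture(seed = 7, n = 60, n_arms = 4)
  # exclusion parity: gain-model n_used = cohort minus loss-called samples
  res <- fit_is_logistic(sim$arm_profile, sim$calls, sim$is_tab, sim$as_tab,
                         "gain", "cold", min_n = 5)
  for (f in colnames(sim$calls)) {
    n_loss <- sum(sim$calls[, f] == "loss", na.rm = TRUE)
    expect_equal(res$n_used[res$feature_id == f], 60 - n_loss)
  }

  # a feature where every sample carries a loss is excluded entirely
  v <- sim$arm_profile$values
  v[, "2p"] <- -0.5
  prof <- copy_number_profile(v, "arm")
  calls <- call_scna(prof)
  res2 <- fit_is_logistic(prof, calls, sim$is_tab, sim$as_tab, "gain", "cold",
                          min_n = 5)
  row <- res2[res2$feature_id == "2p", ]
  expect_equal(row$n_used, 0)
  expect_equal(row$reason, "all_excluded")
  expect_true(is.na(row$p))
})

test_that("BH adjustment matches a brute-force step-up oracle and respects groups", {
  # hand case: p = (.01, .02, .03), m = 3 -> q = (.03, .03, .03)
  df <- data.frame(direction = "gain", p = c(0.01, 0.02, 0.03))
  expect_equal(bh_adjust(df)$q, c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(data.frame(p = 0.04))$q, 0.04)

  set.seed(9)
  for (rep in 1:20) {
    p <- runif(sample(1:200, 1))
    got <- bh_adjust(data.frame(p = p))$q
    expect_equal(got, bh_oracle(p))
  }

  # independent groups: enlarging group A never changes group B's q
  a <- data.frame(direction = "gain", p = runif(10))
  b <- data.frame(direction = "loss", p = runif(8))
  q_b <- bh_adjust(rbind(a, b))$q[11:18]
  a2 <- rbind(a, data.frame(direction = "gain", p = runif(30)))
  q_b2 <- bh_adjust(rbind(a2, b))$q[41:48]
  expect_equal(q_b2, q_b)

  expect_error(bh_adjust(data.frame(p = 1.2)), "0, 1")
})

test_that("signed landscape signs, reduces by min-q, and is antisymmetric", {
  cold <- data.frame(feature_id = c("1q", "2p", "3p"), direction = "gain",
                     q = c(0.5, 0.001, 1))
  hot <- data.frame(feature_id = c("1q", "2p", "3p"), direction = "gain",
                    q = c(0.01, 0.9, 1))
  ls <- build_signed_landscape(cold, hot)
  ls <- ls[order(ls$feature_id), ]
  expect_equal(ls$signed_score[ls$feature_id == "1q"], 2)    # hot q=0.01
  expect_equal(ls$signed_score[ls$feature_id == "2p"], -3)   # cold q=0.001
  expect_equal(ls$signed_score[ls$feature_id == "3p"], 0)    # both q=1
  expect_equal(ls$winner[ls$feature_id == "3p"], "cold")     # ties go cold

  swapped <- build_signed_landscape(hot, cold)
  swapped <- swapped[order(swapped$feature_id), ]
  keep <- ls$q_cold != ls$q_hot  # strict antisymmetry away from ties
  expect_equal(swapped$signed_score[keep], -ls$signed_score[keep])
})

test_that("planted cell-type slope is recovered and filters apply sign logic", {
  cfg <- simulation_config(
    n_samples = 300, n_arms = 6,
    planted_celltype_effects = data.frame(feature = "1q", cell_type = "NK",
                                          slope = -3),
    seed = 11)
  sim <- simulate_cohort(cfg)
  calls <- call_scna(sim$arm_profile)
  as_tab <- aneuploidy_score(sim$arm_profile)
  res <- bh_adjust(fit_celltype_linear(sim$arm_profile, calls, sim$celltypes,
                                       as_tab, "gain"))
  planted <- res[res$feature_id == "1q" & res$phenotype == "NK", ]
  expect_lt(planted$effect, 0)
  expect_lt(planted$q, 0.05)

  gain <- data.frame(feature_id = c("1q", "1q", "2p"),
                     phenotype = c("NK", "B", "NK"), direction = "gain",
                     effect = c(-0.5, 0.3, -0.4), p = c(0.01, 0.25, 0.05))
  loss <- data.frame(feature_id = c("1q", "2p"),
                     phenotype = c("NK", "NK"), direction = "loss",
                     effect = c(0.4, -0.3), p = c(0.05, 0.01))
  kept <- filter_celltype_associations(gain, loss)
  # p = 0.25 row dropped
  expect_false(any(kept$phenotype == "B"))
  # opposite signs retained
  expect_true(any(kept$feature_id == "1q" & kept$direction == "gain"))
  expect_true(any(kept$feature_id == "1q" & kept$direction == "loss"))
  # same-sign gain/loss pair dropped on both sides
  expect_false(any(kept$feature_id == "2p"))
})

test_that("significant-association counts split by direction and abundance", {
  res <- data.frame(
    feature_id = c("1q", "2p", "3p", "4q", "5p"),
    direction = c("gain", "gain", "gain", "loss", "gain"),
    phenotype = c("NK", "NK", "NK", "CD8_T", "NK"),
    effect = c(-1, -2, -0.5, 0.8, 1),
    q = c(0.01, 0.001, 0.04, 0.02, 0.2))
  counts <- count_significant_by_celltype(res)
  expect_equal(counts$n[counts$cell_type == "NK" & counts$direction == "gain" &
                          counts$abundance == "low"], 3)
  expect_equal(sum(counts$n), sum(res$q < 0.05))
  empty <- count_significant_by_celltype(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("proportion comparisons are Welch t-tests with symmetric labels", {
  # identical degenerate groups -> t = 0, p = 1
  prop <- c(rep(0.2, 3), rep(0.2, 3))
  status <- rep(c(TRUE, FALSE), each = 3)
  cmp <- compare_proportions_by_scna(prop, status)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)

  # clearly separated groups with tiny jitter: closed-form Welch t
  a <- c(0.1, 0.1, 0.1) + c(0.001, -0.001, 0)
  u <- c(0.5, 0.5, 0.5) + c(-0.002, 0.002, 0)
  cmp2 <- compare_proportions_by_scna(c(a, u), status)
  tt <- t.test(a, u)
  expect_equal(cmp2$t, unname(tt$statistic))
  expect_equal(cmp2$p, tt$p.value)
  expect_lt(cmp2$p, 0.01)

  # swapping labels flips t, keeps p
  cmp3 <- compare_proportions_by_scna(c(a, u), !status)
  expect_equal(cmp3$t, -cmp2$t)
  expect_equal(cmp3$p, cmp2$p)

  expect_error(compare_proportions_by_scna(c(a, u), c(TRUE, rep(FALSE, 5))),
               ">= 2 patients")
})

test_that("null cohorts give roughly uniform p-values in the IS models", {
  set.seed(202)
  pvals <- c()
  for (s in 1:12) {
    cfg <- simulation_config(n_samples = 150, n_arms = 10, seed = 5000 + s)
    sim <- simulate_cohort(cfg)
    is_tab <- binarize_immune_score(cytotoxic_immune_score(sim$expression))
    calls <- call_scna(sim$arm_profile)
    as_tab <- aneuploidy_score(sim$arm_profile)
    res <- fit_is_logistic(sim$arm_profile, calls, is_tab, as_tab,
                           "gain", "cold")
    pvals <- c(pvals, res$p[!is.na(res$p)])
  }
  frac <- mean(pvals < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / length(pvals))
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})
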