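surv_fixture <- function(seed = 1, n = 500, log_hr = log(2), feature = "3p") {
  cfg <- simulation_config(
    n_samples = n, n_arms = 8,
    planted_survival_effects = data.frame(feature = feature,
                                          direction = "gain",
                                          log_hr = log_hr),
    seed = seed)
  simulate_cohort(cfg)
}

test_that("survival categorization uses strict +/-0.3 thresholds", {
  prof <- make_profile(matrix(c(0.35, 0.3, -0.35, 0.1, -0.3, NA), 2, 3), "arm")
  cat <- categorize_for_survival(prof)
  expect_equal(cat["S01", "1p"], "Gain")     # 0.35 > 0.3
  expect_equal(cat["S02", "1p"], "Neutral")  # exactly 0.3
  expect_equal(cat["S01", "1q"], "Loss")     # -0.35 < -0.3
  expect_equal(cat["S02", "1q"], "Neutral")  # 0.1
  expect_equal(cat["S01", "2p"], "Neutral")  # exactly -0.3
  expect_true(is.na(cat["S02", "2p"]))
  expect_error(categorize_for_survival(prof, gain_thr = -1), "thresholds")

  # elementwise oracle on random values
  set.seed(12)
  v <- matrix(round(rnorm(60, sd = 0.5), 2), 10, 6)
  got <- categorize_for_survival(make_profile(v, "arm"))
  want <- ifelse(v > 0.3, "Gain", ifelse(v < -0.3, "Loss", "Neutral"))
  expect_identical(as.vector(unclass(got)), as.vector(want))
})

test_that("a planted hazard ratio is recovered with positive signed score", {
  sim <- surv_fixture(seed = 1)
  cats <- categorize_for_survival(sim$arm_profile)
  cl <- cox_landscape(sim$clinical, cats)
  planted <- cl[cl$feature_id == "3p" & cl$direction == "gain", ]
  expect_gte(planted$hazard_ratio, 1.6)
  expect_lte(planted$hazard_ratio, 2.5)
  expect_gt(planted$signed_score, 0)
  expect_lt(planted$q, 0.05)

  # null arms: confidence intervals cover HR 1 most of the time
  covered <- 0; total <- 0
  for (s in 1:10) {
    sim_s <- surv_fixture(seed = 100 + s, n = 300)
    cl_s <- cox_landscape(sim_s$clinical,
                          categorize_for_survival(sim_s$arm_profile))
    null_rows <- cl_s[cl_s$feature_id != "3p" & is.na(cl_s$reason), ]
    covered <- covered + sum(null_rows$ci_low <= 1 & null_rows$ci_high >= 1)
    total <- total + nrow(null_rows)
  }
  expect_gte(covered / total, 0.9)
})

test_that("degenerate arms are skipped with reasons", {
  sim <- surv_fixture(seed = 3, n = 80)
  v <- sim$arm_profile$values
  v[, "2p"] <- 0  # all Neutral
  cl <- cox_landscape(sim$clinical,
                      categorize_for_survival(copy_number_profile(v, "arm")))
  skipped <- cl[cl$feature_id == "2p", ]
  expect_true(all(skipped$reason == "no_group_variation"))
  expect_true(all(is.na(skipped$p)))
})

test_that("log-rank test matches the hand O-E oracle and KM the empirical survival", {
  # textbook toy: group A events at 1,2,3; group B events at 4,5,6
  clin <- clinical_table(data.frame(
    sample_id = paste0("S", 1:6), os_time = 1:6, os_event = TRUE))
  grp <- rep(c("A", "B"), each = 3)
  km <- km_logrank(clin, grp)
  chisq_oracle <- logrank_oracle(clin$os_time, clin$os_event, grp)
  expect_equal(km$chisq, chisq_oracle, tolerance = 1e-8)
  expect_equal(km$p, pchisq(chisq_oracle, 1, lower.tail = FALSE))

  # KM with no censoring equals the empirical survival function
  a <- km$curves[km$curves$group == "A", ]
  expect_equal(a$surv, c(2 / 3, 1 / 3, 0))

  # identical groups -> statistic ~ 0
  clin2 <- clinical_table(data.frame(
    sample_id = paste0("S", 1:8), os_time = rep(1:4, 2), os_event = TRUE))
  km2 <- km_logrank(clin2, rep(c("A", "B"), each = 4))
  expect_lt(km2$chisq, 1e-10)

  # all of one group censored at t0 -> its curve stays at 1
  clin3 <- clinical_table(data.frame(
    sample_id = paste0("S", 1:8), os_time = c(1:4, rep(5, 4)),
    os_event = c(rep(TRUE, 4), rep(FALSE, 4))))
  km3 <- km_logrank(clin3, rep(c("A", "B"), each = 4))
  b <- km3$curves[km3$curves$group == "B", ]
  expect_true(all(b$surv == 1))

  expect_error(km_logrank(clin, rep("A", 6)), ">= 2 groups")
})

test_that("1q panel selection returns k concordance-ranked genes deterministically", {
  set.seed(41)
  n <- 100; n_genes <- 200
  cn <- matrix(rnorm(n * n_genes, sd = 0.3), n, n_genes,
               dimnames = list(sprintf("S%03d", 1:n),
                               sprintf("GENE%03d", 1:n_genes)))
  # 60 planted concordant genes, 140 with independent expression
  expr <- matrix(rexp(n_genes * n), n_genes, n,
                 dimnames = list(colnames(cn), rownames(cn)))
  planted <- sprintf("GENE%03d", 1:60)
  expr[planted, ] <- t(2^(5 + 2 * cn[, planted])) *
    matrix(exp(rnorm(60 * n, sd = 0.2)), 60, n)
  prof <- copy_number_profile(cn, "gene")
  panel <- select_1q_panel(prof, expr)
  expect_length(panel, 50)
  expect_true(all(panel %in% planted))
  # deterministic: same inputs, same panel
  expect_identical(select_1q_panel(prof, expr), panel)

  # shortfall is an error naming the deficit
  small <- copy_number_profile(cn[, 1:49], "gene")
  expect_error(select_1q_panel(small, expr), "49")
})

test_that("expression score classifies exactly the top quartile as gain", {
  set.seed(43)
  n <- 200
  panel <- sprintf("PG%02d", 1:20)
  expr <- matrix(rexp(20 * n, rate = 0.1), 20, n,
                 dimnames = list(panel, sprintf("S%03d", 1:n)))
  sc <- score_1q_from_expression(expr, panel)
  expect_equal(sum(sc$gain), 50)  # ceil(200/4)

  # minimal cohort: 4 samples -> exactly 1 gain
  sc4 <- score_1q_from_expression(expr[, 1:4], panel)
  expect_equal(sum(sc4$gain), 1)

  # per-gene shifts on the log scale leave the z-based classes unchanged
  shift <- exp(seq(-1, 1, length.out = 20))
  sc_shift <- score_1q_from_expression((1 + expr) * shift - 1, panel)
  expect_equal(sc_shift$gain, sc$gain)

  # constant gene dropped with warning
  expr2 <- rbind(expr, PGCONST = 1)
  expect_warning(scc <- score_1q_from_expression(expr2, c(panel, "PGCONST")),
                 "constant")
  expect_equal(sum(scc$gain), 50)
})

test_that("multivariate Cox codes TMB inclusively and finds the planted 1q term", {
  # TMB (5, 10, 15) -> high coding (0, 1, 1) under the >= 10 rule
  expect_equal(c(5, 10, 15) >= 10, c(FALSE, TRUE, TRUE))

  sim <- surv_fixture(seed = 8, n = 1000, log_hr = log(1.8), feature = "1q")
  gain <- sim$altered[, "1q"] == "gain"
  res <- multivariate_cox(sim$clinical, gain)
  expect_equal(res$term[1], "gain_1q")
  r1q <- res[res$term == "gain_1q", ]
  expect_lt(r1q$p, 0.05)
  expect_gt(r1q$hazard_ratio, 1)
  expect_true(r1q$ci_low <= r1q$hazard_ratio & r1q$hazard_ratio <= r1q$ci_high)
  # null covariates mostly stay quiet across replicates
  quiet_hits <- 0
  for (s in 1:5) {
    sim_s <- surv_fixture(seed = 300 + s, n = 1000, log_hr = log(1.8),
                          feature = "1q")
    res_s <- multivariate_cox(sim_s$clinical, sim_s$altered[, "1q"] == "gain")
    null_p <- res_s$p[res_s$term != "gain_1q"]
    quiet_hits <- quiet_hits + sum(null_p > 0.05)
  }
  expect_gte(quiet_hits / 20, 0.8)

  # constant or duplicated covariates are named in the error
  clin <- sim$clinical
  clin$pdl1_positive <- TRUE
  expect_error(multivariate_cox(clin, gain), "pdl1_positive")
  clin2 <- sim$clinical
  clin2$b_fraction <- clin2$cd8_fraction
  expect_error(multivariate_cox(clin2, gain), "collinear|duplicates")
})

test_that("landscape flips sign when hazards invert", {
  sim_del <- surv_fixture(seed = 9, log_hr = log(2))
  sim_pro <- surv_fixture(seed = 9, log_hr = -log(2))
  cl_del <- cox_landscape(sim_del$clinical,
                          categorize_for_survival(sim_del$arm_profile))
  cl_pro <- cox_landscape(sim_pro$clinical,
                          categorize_for_survival(sim_pro$arm_profile))
  s_del <- cl_del$signed_score[cl_del$feature_id == "3p" &
                                 cl_del$direction == "gain"]
  s_pro <- cl_pro$signed_score[cl_pro$feature_id == "3p" &
                                 cl_pro$direction == "gain"]
  expect_gt(s_del, 0)
  expect_lt(s_pro, 0)
})
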