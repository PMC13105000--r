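# Shared fixture builders and independent oracles. Oracles are written
# from first principles and never call the implementation they check.

make_profile <- function(values, level = "arm",
                         samples = sprintf("S%02d", seq_len(nrow(values))),
                         features = NULL) {
  if (is.null(features))
    features <- switch(level,
      arm = HUMAN_ARMS_FIXTURE[seq_len(ncol(values))],
      cytoband = paste0("1q", 20 + seq_len(ncol(values))),
      gene = sprintf("GENE%02d", seq_len(ncol(values))))
  dimnames(values) <- list(samples, features)
  copy_number_profile(values, level = level)
}

HUMAN_ARMS_FIXTURE <- {
  acro <- paste0(c(13, 14, 15, 21, 22), "p")
  arms <- paste0(rep(1:22, each = 2), c("p", "q"))
  arms[!(arms %in% acro)]
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Spearman rho as Pearson correlation of average ranks, from the definition
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-group log-rank statistic from the O-E / hypergeometric-variance sums
logrank_oracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  U <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g1)
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Per-base average of segment means over an interval (for small instances)
per_base_oracle <- function(seg, chrom, start, end) {
  vals <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(seg))) {
    if (seg$chromosome[i] != chrom) next
    lo <- max(seg$start[i], start); hi <- min(seg$end[i], end)
    if (lo < hi) vals[(lo - start + 1):(hi - start)] <- seg$log2_cn[i]
  }
  list(mean = mean(vals, na.rm = TRUE),
       coverage = mean(!is.na(vals)))
}

# Truth-table rule for iOG/TiSG calls, written independently as nested ifs
iog_tisg_oracle <- function(region, rho, q, q_thr = 0.05) {
  all_sig <- all(q < q_thr)
  if (region == "amplified" && all_sig &&
      rho[1] > 0 && rho[2] > 0 && rho[3] > 0) return("iOG")
  if (region == "deleted" && all_sig &&
      rho[1] < 0 && rho[2] < 0 && rho[3] > 0) return("TiSG")
  "none"
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# Simulate a cohort and write every layer as the TSV formats the readers accept
write_sim_inputs <- function(dir, seed = 13, n = 120, n_arms = 5,
                             n_genes_per_arm = 6) {
  cfg <- simulation_config(
    n_samples = n, n_arms = n_arms, n_genes_per_arm = n_genes_per_arm,
    planted_is_effects = data.frame(feature = "1q", direction = "gain",
                                    effect = 1),
    seed = seed)
  sim <- simulate_cohort(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expr = file.path(dir, "expression.tsv"),
    cn_arm = file.path(dir, "cn_arm.tsv"),
    cn_gene = file.path(dir, "cn_gene.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    celltypes = file.path(dir, "celltypes.tsv"))
  write_expression_matrix(sim$expression, paths$expr)
  write_copy_number_table(sim$arm_profile, paths$cn_arm)
  write_copy_number_table(sim$gene_profile, paths$cn_gene)
  write_table(sim$clinical, paths$clinical)
  ct <- data.frame(sample_id = rownames(sim$celltypes),
                   unclass(sim$celltypes), check.names = FALSE)
  write_table(ct, paths$celltypes)
  paths
}
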