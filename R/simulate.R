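# Seeded generator of linked copy-number / expression / immune / cell-type /
# survival data with planted effects. The generator is the test bed for the
# whole pipeline: every statistical stage has a corresponding plantable
# effect whose recovery can be checked without access to patient data.

HUMAN_ARMS <- {
  acrocentric_p <- paste0(c(13, 14, 15, 21, 22), "p")
  arms <- paste0(rep(1:22, each = 2), c("p", "q"))
  arms[!(arms %in% acrocentric_p)]
}

#' Build and validate a simulation configuration
#'
#' Defines a synthetic cohort: its dimensions, the copy-number mixture, the
#' noise scales of each data layer, and the planted effects each pipeline
#' stage should recover. Alterations are drawn per sample and arm from a
#' mixture of a copy-neutral state (small Gaussian jitter around 0) and an
#' altered state with |log2 CN| uniform on `alt_range`; gene copy number
#' inherits its arm value plus focal noise.
#'
#' Planted effects, all expressed in interpretable units:
#' \describe{
#'   \item{`planted_is_effects`}{data.frame `feature`, `direction`,
#'     `effect`: samples altered in `direction` at `feature` have their
#'     latent immune infiltration shifted by `effect` standard deviations
#'     toward the cold pole. The shift propagates into the cytotoxic
#'     signature genes, so the Immune Score computed downstream responds;
#'     for moderate effects the induced log-odds of cold classification is
#'     roughly 1.6 times the planted shift.}
#'   \item{`planted_celltype_effects`}{data.frame `feature`, `cell_type`,
#'     `slope`: linear effect of the feature's continuous log2 CN on that
#'     cell-type score.}
#'   \item{`planted_genes`}{data.frame `gene` (an index within the arm's
#'     genes is assigned automatically when the column `arm` is given),
#'     `arm`, `role` (`"iOG"` or `"TiSG"`), `dna_rna_slope`,
#'     `rna_is_slope`: the gene's expression follows its copy number with
#'     slope `dna_rna_slope`, and its (standardized) expression feeds the
#'     latent infiltration with weight `rna_is_slope`. An iOG should use
#'     positive/positive slopes on a gained arm; a TiSG positive/negative
#'     slopes on a lost arm.}
#'   \item{`planted_survival_effects`}{data.frame `feature`, `direction`,
#'     `log_hr`: samples altered in `direction` at `feature` have their
#'     exponential hazard multiplied by `exp(log_hr)`.}
#' }
#' Arms named with a `direction` in any planted effect are altered
#' predominantly (probability `direction_bias`) in that direction, as
#' recurrently gained or lost arms are in tumors.
#'
#' @param n_samples cohort size (default 300).
#' @param n_arms number of chromosome arms, taken from the human arm list
#'   (default 20).
#' @param n_genes_per_arm genes simulated per arm (default 20).
#' @param alt_prob per-sample probability that an arm is altered
#'   (default 0.4, the order of recurrent arm-level SCNA frequencies).
#' @param alt_range magnitude range of |log2 CN| in the altered state
#'   (default c(0.2, 0.8)).
#' @param arm_noise_sd,gene_noise_sd Gaussian jitter on arm values and
#'   focal gene deviations (defaults 0.05).
#' @param direction_bias probability that an alteration at a planted
#'   directional arm matches the planted direction (default 0.9).
#' @param expr_noise_sd residual sd of log2 expression (default 0.5).
#' @param signature_noise_sd residual sd of the cytotoxic signature genes
#'   around the latent infiltration (default 0.3).
#' @param immune_noise_sd sd of the latent infiltration noise (default 1).
#' @param celltype_base,celltype_noise_sd baseline and residual sd of
#'   cell-type scores (defaults 2 and 1; scores are floored at 0).
#' @param baseline_hazard exponential event hazard per time unit
#'   (default 0.02; time in months).
#' @param censor_rate target fraction of censored samples (default 0.3).
#' @param cell_types cell-type vocabulary (default [CELL_TYPES]).
#' @param planted_is_effects,planted_celltype_effects,planted_genes,planted_survival_effects
#'   planted-effect tables as described above (default none).
#' @param seed mandatory RNG seed.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 300, n_arms = 20,
                              n_genes_per_arm = 20,
                              alt_prob = 0.4, alt_range = c(0.2, 0.8),
                              arm_noise_sd = 0.05, gene_noise_sd = 0.05,
                              direction_bias = 0.9,
                              expr_noise_sd = 0.5, signature_noise_sd = 0.3,
                              immune_noise_sd = 1,
                              celltype_base = 2, celltype_noise_sd = 1,
                              baseline_hazard = 0.02, censor_rate = 0.3,
                              cell_types = CELL_TYPES,
                              planted_is_effects = NULL,
                              planted_celltype_effects = NULL,
                              planted_genes = NULL,
                              planted_survival_effects = NULL,
                              seed) {
  kt_assert(!missing(seed) && is.numeric(seed), "a numeric seed is mandatory",
            "karyotme_config_error")
  kt_assert(n_arms >= 1 && n_arms <= length(HUMAN_ARMS),
            sprintf("n_arms must be in 1..%d", length(HUMAN_ARMS)),
            "karyotme_config_error")
  kt_assert(censor_rate >= 0 && censor_rate < 1,
            "censor_rate must be in [0, 1)", "karyotme_config_error")
  kt_assert(alt_prob >= 0 && alt_prob <= 1, "alt_prob must be in [0, 1]",
            "karyotme_config_error")
  arms <- HUMAN_ARMS[seq_len(n_arms)]
  check_feats <- function(df, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    bad <- setdiff(df$feature, arms)
    kt_assert(length(bad) == 0,
              sprintf("%s references undeclared feature(s): %s", what,
                      paste(bad, collapse = ", ")), "karyotme_config_error")
    df
  }
  planted_is_effects <- check_feats(planted_is_effects, "planted_is_effects")
  planted_celltype_effects <- check_feats(planted_celltype_effects,
                                          "planted_celltype_effects")
  planted_survival_effects <- check_feats(planted_survival_effects,
                                          "planted_survival_effects")
  if (!is.null(planted_genes)) {
    planted_genes <- as.data.frame(planted_genes, stringsAsFactors = FALSE)
    bad <- setdiff(planted_genes$arm, arms)
    kt_assert(length(bad) == 0,
              sprintf("planted_genes references undeclared arm(s): %s",
                      paste(bad, collapse = ", ")), "karyotme_config_error")
  }
  structure(list(
    n_samples = n_samples, n_arms = n_arms, arms = arms,
    n_genes_per_arm = n_genes_per_arm, alt_prob = alt_prob,
    alt_range = alt_range, arm_noise_sd = arm_noise_sd,
    gene_noise_sd = gene_noise_sd, direction_bias = direction_bias,
    expr_noise_sd = expr_noise_sd, signature_noise_sd = signature_noise_sd,
    immune_noise_sd = immune_noise_sd, celltype_base = celltype_base,
    celltype_noise_sd = celltype_noise_sd, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, cell_types = cell_types,
    planted_is_effects = planted_is_effects,
    planted_celltype_effects = planted_celltype_effects,
    planted_genes = planted_genes,
    planted_survival_effects = planted_survival_effects,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate a linked multi-layer cohort
#'
#' Draws a cohort from a [simulation_config()]: arm-level log2 copy number
#' from the neutral/altered mixture, gene-level copy number inheriting arm
#' values, log-normal expression coupled to gene copy number, a latent
#' immune infiltration carrying every planted immune effect that drives
#' the seven cytotoxic signature genes, cell-type scores from linear
#' planted models, and exponential proportional-hazards survival with
#' uniform-rate censoring. The same seed reproduces bitwise-identical
#' output.
#'
#' @param config a `SimulationConfig`.
#' @return list with elements `arm_profile` and `gene_profile`
#'   (`CopyNumberProfile`s), `expression` (genes x samples, includes the
#'   signature genes), `celltypes` (`CellTypeScoreTable`), `clinical`
#'   (`ClinicalTable` with purity/ploidy/TMB/PD-L1/cell-fraction columns),
#'   `altered` (samples x arms character matrix of true alteration states),
#'   `gene_arms` (named vector gene -> arm), `latent_immune`, and `config`.
#' @export
simulate_cohort <- function(config) {
  kt_assert(inherits(config, "SimulationConfig"), "not a SimulationConfig")
  set.seed(config$seed)
  n <- config$n_samples
  arms <- config$arms
  samples <- sprintf("S%04d", seq_len(n))

  # planted per-arm direction bias
  dir_of <- function(df) if (is.null(df) || is.null(df$direction)) NULL else
    setNames(tolower(df$direction), df$feature)
  planted_dir <- c(dir_of(config$planted_is_effects),
                   dir_of(config$planted_survival_effects))
  # iOGs live on recurrently gained arms, TiSGs on recurrently lost ones
  if (!is.null(config$planted_genes))
    planted_dir <- c(planted_dir,
                     setNames(ifelse(config$planted_genes$role == "iOG",
                                     "gain", "loss"),
                              config$planted_genes$arm))

  altered <- matrix(NA_character_, n, length(arms),
                    dimnames = list(samples, arms))
  arm_cn <- matrix(0, n, length(arms), dimnames = list(samples, arms))
  for (a in arms) {
    is_alt <- stats::rbinom(n, 1, config$alt_prob) == 1
    p_gain <- if (!is.null(planted_dir) && a %in% names(planted_dir)) {
      if (planted_dir[[a]] == "gain") config$direction_bias
      else 1 - config$direction_bias
    } else 0.5
    sign_gain <- stats::rbinom(n, 1, p_gain) == 1
    mag <- stats::runif(n, config$alt_range[1], config$alt_range[2])
    v <- ifelse(is_alt, ifelse(sign_gain, mag, -mag), 0)
    arm_cn[, a] <- v + stats::rnorm(n, 0, config$arm_noise_sd)
    altered[is_alt & sign_gain, a] <- "gain"
    altered[is_alt & !sign_gain, a] <- "loss"
    altered[!is_alt, a] <- "none"
  }

  genes <- as.vector(vapply(arms, function(a)
    sprintf("G%s_%02d", gsub("[pq]", toupper(substr(a, nchar(a), nchar(a))), a),
            seq_len(config$n_genes_per_arm)),
    character(config$n_genes_per_arm)))
  gene_arms <- setNames(rep(arms, each = config$n_genes_per_arm), genes)
  gene_cn <- arm_cn[, gene_arms, drop = FALSE] +
    matrix(stats::rnorm(n * length(genes), 0, config$gene_noise_sd),
           n, length(genes))
  dimnames(gene_cn) <- list(samples, genes)

  # expression: log2 scale, baseline + dosage coupling + noise
  mu <- stats::runif(length(genes), 3, 8)
  slope <- rep(1, length(genes))
  names(mu) <- names(slope) <- genes
  pg <- config$planted_genes
  if (!is.null(pg)) {
    pg$gene_id <- vapply(seq_len(nrow(pg)), function(i) {
      arm_genes <- genes[gene_arms == pg$arm[i]]
      arm_genes[(i - 1) %% length(arm_genes) + 1]
    }, "")
    slope[pg$gene_id] <- pg$dna_rna_slope
  }
  log_expr <- t(mu + slope * t(gene_cn)) +
    matrix(stats::rnorm(n * length(genes), 0, config$expr_noise_sd),
           n, length(genes))

  # latent immune infiltration (higher = hotter)
  latent <- stats::rnorm(n, 0, config$immune_noise_sd)
  pie <- config$planted_is_effects
  if (!is.null(pie)) for (i in seq_len(nrow(pie)))
    latent <- latent - pie$effect[i] *
      (altered[, pie$feature[i]] == tolower(pie$direction[i]))
  if (!is.null(pg)) for (i in seq_len(nrow(pg)))
    latent <- latent + pg$rna_is_slope[i] *
      as.vector(scale(log_expr[, pg$gene_id[i]]))

  sig_mu <- stats::runif(length(CYTOTOXIC_SIGNATURE), 4, 7)
  sig_expr <- vapply(seq_along(CYTOTOXIC_SIGNATURE), function(k)
    sig_mu[k] + latent + stats::rnorm(n, 0, config$signature_noise_sd),
    numeric(n))
  colnames(sig_expr) <- CYTOTOXIC_SIGNATURE
  expression <- 2^t(cbind(log_expr, sig_expr))  # genes x samples, linear scale
  colnames(expression) <- samples

  # cell-type scores: linear planted models, floored at zero
  ct <- matrix(stats::rnorm(n * length(config$cell_types), config$celltype_base,
                            config$celltype_noise_sd),
               n, length(config$cell_types),
               dimnames = list(samples, config$cell_types))
  pce <- config$planted_celltype_effects
  if (!is.null(pce)) for (i in seq_len(nrow(pce)))
    ct[, pce$cell_type[i]] <- ct[, pce$cell_type[i]] +
      pce$slope[i] * arm_cn[, pce$feature[i]]
  ct <- pmax(ct, 0)

  # survival: exponential PH with planted log hazard ratios
  log_hr <- rep(0, n)
  pse <- config$planted_survival_effects
  if (!is.null(pse)) for (i in seq_len(nrow(pse)))
    log_hr <- log_hr + pse$log_hr[i] *
      (altered[, pse$feature[i]] == tolower(pse$direction[i] %||% "gain"))
  event_time <- stats::rexp(n, config$baseline_hazard * exp(log_hr))
  if (config$censor_rate > 0) {
    cens_rate <- config$baseline_hazard * config$censor_rate /
      (1 - config$censor_rate)
    cens_time <- stats::rexp(n, cens_rate)
  } else cens_time <- rep(Inf, n)
  os_time <- pmin(event_time, cens_time)
  os_event <- event_time <= cens_time

  clinical <- clinical_table(data.frame(
    sample_id = samples, tumor_type = "SIM",
    os_time = os_time, os_event = os_event,
    tmb = stats::rlnorm(n, log(5), 0.8),
    pdl1_positive = stats::rbinom(n, 1, 0.4) == 1,
    cd8_fraction = stats::rbeta(n, 2, 8),
    b_fraction = stats::rbeta(n, 2, 10),
    purity = stats::runif(n, 0.4, 0.95),
    ploidy = pmax(stats::rnorm(n, 2, 0.2), 1.5),
    stringsAsFactors = FALSE))

  list(arm_profile = copy_number_profile(arm_cn, "arm"),
       gene_profile = copy_number_profile(gene_cn, "gene"),
       expression = expression,
       celltypes = celltype_scores(ct, allowed = NULL),
       clinical = clinical,
       altered = altered,
       gene_arms = gene_arms,
       planted_gene_ids = if (!is.null(pg))
         setNames(pg$gene_id, pg$role) else NULL,
       latent_immune = setNames(latent, samples),
       config = config)
}

#' Simulate a gold-standard gene set with separable features
#'
#' Draws a gene-by-feature table in which `n_positives` gold-standard
#' genes have their feature means shifted by `separation` (in feature
#' standard deviations) relative to the background, supporting classifier
#' validation: zero separation should yield chance AUROC, large
#' separation near-perfect AUROC.
#'
#' @param n_genes total genes (default 500).
#' @param n_positives gold-standard positives (>= 10; default 50).
#' @param n_features features per gene (default 6).
#' @param separation mean shift of positives, in SD units (>= 0).
#' @param seed mandatory RNG seed.
#' @return list with `features` (matrix genes x features) and `positives`
#'   (character vector of gold-standard gene ids).
#' @export
simulate_gold_standard <- function(n_genes = 500, n_positives = 50,
                                   n_features = 6, separation = 1, seed) {
  kt_assert(!missing(seed), "a seed is mandatory", "karyotme_config_error")
  kt_assert(separation >= 0, "separation must be >= 0", "karyotme_config_error")
  kt_assert(n_positives >= 10, "need >= 10 positives", "karyotme_config_error")
  kt_assert(n_positives < n_genes, "n_positives must be < n_genes",
            "karyotme_config_error")
  set.seed(as.integer(seed))
  genes <- sprintf("GS%04d", seq_len(n_genes))
  feats <- matrix(stats::rnorm(n_genes * n_features), n_genes, n_features,
                  dimnames = list(genes, sprintf("f%02d", seq_len(n_features))))
  positives <- sample(genes, n_positives)
  feats[positives, ] <- feats[positives, ] + separation
  list(features = feats, positives = positives)
}
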