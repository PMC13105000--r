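# karyotme

Linking somatic copy-number alterations (SCNAs) to the tumor immune
microenvironment and to survival under immune-checkpoint blockade.

Aneuploidy correlates with immune evasion, but *which* arm, cytoband, or
gene carries the association is the actionable question. `karyotme` takes
segmented or GISTIC2-style copy-number data, bulk expression, cell-type
deconvolution scores (e.g. xCell), and clinical follow-up, and provides:

* a **rank-sum cytotoxic Immune Score** (IS) over seven cytotoxic genes
  (*CD247, CD2, CD3E, GZMH, NKG7, PRF1, GZMK*): each gene ranked across
  samples, ranks summed per sample and re-ranked; bottom/top 30 % of the
  IS are *immune cold* / *immune hot*;
* **SCNA calling** (gain iff log2 CN > 0.2, loss iff < −0.2, strict) and
  the per-sample **aneuploidy score** AS = Σ|log2 CN|, used as a
  chromosomal-instability covariate in every model;
* a **direction-stratified association engine**: per feature, logistic
  models of cold/hot (and linear models of cell-type abundance) on
  continuous log2 CN + AS, where loss-called samples are excluded from
  gain models and vice versa; Benjamini–Hochberg adjustment within each
  (tumor type, level, direction, phenotype) stratum; signed
  −log10(q) landscapes with hot above and cold below the axis;
* a **gene-level iOG / TiSG caller**: Spearman DNA:IS, RNA:IS and
  DNA:RNA correlations per gene; an immune oncogene (iOG) is an
  amplified gene with all three positive at q < 0.05, a tumor immune
  suppressor gene (TiSG) a deleted gene with positive DNA:RNA and
  negative IS correlations — plus LASSO parameter selection and a seeded
  random-forest classifier interface with CV/test AUROC;
* **survival analysis**: per-arm Cox landscapes (Gain > 0.3 / Loss
  < −0.3 vs Neutral, Efron ties), Kaplan–Meier curves with log-rank
  tests, an expression-based chromosome-1q inference score (50-gene
  DNA–RNA-concordance panel, top-quartile gain rule), and a multivariate
  Cox model with CD8/B-cell fractions, PD-L1 status and TMB ≥ 10 mut/Mb;
* a **seeded synthetic-cohort generator** with planted immune, cell-type,
  gene and survival effects, so every stage is testable end-to-end
  without patient data.

## Worked example

Simulate a 300-sample cohort in which gaining chromosome arm 1q pushes
tumors toward the immune-cold pole, then recover that association:

```r
library(karyotme)

cfg <- simulation_config(
  n_samples = 300, n_arms = 8,
  planted_is_effects = data.frame(feature = "1q", direction = "gain",
                                  effect = 1),
  seed = 42)
sim <- simulate_cohort(cfg)

is_tab <- binarize_immune_score(cytotoxic_immune_score(sim$expression))
table(is_tab$is_class)
#>         cold intermediate          hot
#>           90          120           90

calls  <- call_scna(sim$arm_profile)          # gain / neutral / loss at ±0.2
as_tab <- aneuploidy_score(sim$arm_profile)   # Σ|log2 CN| per sample

cold <- bh_adjust(fit_is_logistic(sim$arm_profile, calls, is_tab, as_tab,
                                  direction = "gain", phenotype = "cold"))
head(cold[order(cold$q), c("feature_id", "effect", "p", "q", "n_used")], 3)
#>   feature_id effect        p        q n_used
#> 2         1q   3.25 1.44e-09 1.15e-08    288
#> 3         2p  -1.52 3.55e-02 1.42e-01    239
#> 5         3p  -1.11 1.33e-01 3.35e-01    236
```

The planted arm tops the table: a positive coefficient means higher 1q
copy number raises the odds of an immune-cold tumor (q ≈ 1e−8), with
loss-called samples excluded (`n_used` 288 of 300) and the aneuploidy
score held constant. Combining the cold and hot models gives the signed
landscape:

```r
hot <- bh_adjust(fit_is_logistic(sim$arm_profile, calls, is_tab, as_tab,
                                 "gain", "hot"))
ls <- build_signed_landscape(cold, hot)
head(ls[order(-abs(ls$signed_score)), ], 3)
#>   feature_id direction   q_cold    q_hot winner signed_score
#> 2         1q      gain 1.15e-08 3.96e-05   cold       -7.939
#> 5         3p      gain 3.35e-01 2.58e-03    hot        2.588
#> 3         2p      gain 1.42e-01 3.32e-01   cold       -0.847
```

1q gain plots far below the axis (cold-associated, −log10 q ≈ 7.9).
The same engine runs at cytoband and gene level, for cell-type scores
(`fit_celltype_linear`), for gene calling
(`gene_immune_correlations` → `call_iog_tisg`), and for survival
(`categorize_for_survival` → `cox_landscape`, `km_logrank`,
`select_1q_panel` → `score_1q_from_expression` → `multivariate_cox`).

A command-line front end is installed as `exec/karyotme`
(subcommands `simulate`, `score-immune`, `call-scna`, `associate`,
`tuson`, `survival`, `infer-1q`, `run`), and `run_pipeline()` executes
all stages with a manifest of input/output digests.

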