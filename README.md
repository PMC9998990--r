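# mutpanel

Mutation-count gene panels for predicting survival benefit from immune
checkpoint inhibitor (ICI) therapy in non-small cell lung cancer.

Only a minority of NSCLC patients respond durably to anti-PD-(L)1
therapy, and the established genomic markers (tumor mutational burden,
single-gene mutations, co-mutation rules) separate responders weakly.
`mutpanel` is for computational oncologists who want to discover and
evaluate a different kind of biomarker from somatic mutation calls alone:
a small gene panel whose per-patient *mutation count* stratifies
survival. A patient is called **MT** (mutant-type) when at least *k*
panel genes carry a retained nonsynonymous mutation, **WT** otherwise —
a rule simple enough for a clinical report.

## What the package does

- **Cohort I/O and filtering** — read MAF-like mutation tables and
  clinical survival tables; apply the standard variant-level filters
  (intronic, population frequency > 1%, common dbSNP polymorphisms,
  synonymous variants, < 50 supporting reads, structural records) with a
  conserving, attribution-ordered filter report.
- **Feature construction** — binary gene-by-sample mutation matrix, gene
  prevalence filter (mutated in ≥ 3 samples), TMB with the ≥ 10/Mb
  TMB-H/TMB-L grouping.
- **Panel discovery** — `mutpanel(x, y)` ranks genes by random-forest
  variable importance and prunes them by a sequential backward search
  under stratified 10-fold cross-validation, with an adaptive step
  schedule (remove 100 genes per round above 400 features, then 50, then
  20, then 1 from 50 down). The chosen panel is the smallest subset with
  maximal mean CV accuracy. Returns a fitted object with
  `print`/`summary`/`coef`/`plot`/`predict` methods.
- **Classification and comparators** — count-threshold MT/WT calls,
  count strata (0, 1, 2, ... mutated panel genes), and rule-based
  comparator biomarkers: KEAP1-driven co-mutation (≥ 2 of KEAP1, STK11,
  PBRM1, SMARCA4), the 5-gene DDR signature (≥ 1 of MSH2, MSH6, PMS2,
  POLE, BRCA2), and an APOBEC gene-status rule (explicit gene list
  required).
- **Survival evaluation** — Kaplan-Meier curves with "not reached"
  medians, two-group log-rank tests, univariate/multivariate
  proportional-hazards regression (Breslow ties; hazard ratios oriented
  WT-vs-MT so HR > 1 means the MT group benefits), ROC/AUC, and Wilcoxon
  comparisons.
- **Synthetic cohorts** — `simulate_cohort()` generates cohorts with a
  planted panel signature (sparse Bernoulli mutations at a 1-11%
  prevalence spectrum, exponential survival with a 5-fold hazard
  reduction for samples reaching the count threshold, administrative
  censoring), and `make_null_cohort()` the matching no-signal control,
  so the whole pipeline is testable without any external data.

A bundled 18-gene NSCLC panel (`default_panel()`) with k = 2 ships as a
JSON asset and can be applied to any cohort via `run_validation()`.

## Worked example

Discover a panel on a simulated training cohort with an 8-gene planted
signature, then validate it on an independent cohort from the same truth:

```r
library(mutpanel)

cfg <- sim_config(n_samples = 300, n_genes = 80, planted_genes = 8,
                  planted_prevalence_range = c(0.06, 0.15), seed = 42)
train <- simulate_cohort(cfg)
run <- run_discovery(train$cohort, rf = rf_config(n_trees = 200, seed = 42))
print(run$panel)
#> Panel model: 11 genes, MT when count >= 2
#>   BG0005, BG0019, BG0030, BG0034, BG0038, BG0052, SIG004, SIG005,
#>   SIG006, SIG007, SIG008
print(run$evaluation)
#> Panel evaluation: n = 300 (MT 99 / WT 201), k = 2
#>   median survival: MT 16.363 vs WT 9.8538 months
#>   log-rank: chi-square 22.599, p = 1.996e-06
#>   HR (WT vs MT reference): 1.947 [1.473, 2.575], p = 2.964e-06
#>   AUC (count vs alive_at_horizon outcome): 0.6302

vcfg <- cfg; vcfg$seed <- 43L
val <- simulate_cohort(vcfg)
print(run_validation(val$cohort, run$panel))
#> Panel evaluation: n = 300 (MT 89 / WT 211), k = 2
#>   median survival: MT 19.0191 vs WT 9.7735 months
#>   log-rank: chi-square 17.750, p = 2.519e-05
#>   HR (WT vs MT reference): 1.819 [1.372, 2.413], p = 3.272e-05
#>   AUC (count vs alive_at_horizon outcome): 0.6309
```

The discovered 11-gene panel contains five of the eight planted signal
genes (`SIG004`-`SIG008`); its MT group shows roughly double the median
survival of the WT group on a cohort the discovery never saw, with a
WT-vs-MT hazard ratio of 1.8 (HR > 1 means MT is protective). The
accuracy-versus-size trace is available as `plot(run$fit)`.

Real data enter through the readers instead of the simulator:

```r
mut <- read_mutation_table("cohort.maf.tsv", maf_dialect())
cli <- read_clinical_table("clinical.tsv")
cohort <- assemble_cohort(mut, cli)
run <- run_discovery(cohort, rf = rf_config(seed = 1))
```

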