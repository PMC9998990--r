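---
title: "Discovering mutation-count gene panels for immunotherapy survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering mutation-count gene panels for immunotherapy survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Immune checkpoint inhibitors (ICIs) help a minority of non-small cell lung
cancer (NSCLC) patients dramatically and the rest little. Established
genomic predictors — tumor mutational burden (TMB), single-gene markers,
co-mutation rules — are only weakly informative. `mutpanel` implements a
panel-based alternative: find a small set of genes whose *mutation count*
per patient stratifies post-ICI survival, and classify a patient as
mutant-type (MT) when at least *k* panel genes carry a somatic
nonsynonymous mutation, wild-type (WT) otherwise. The package covers the
full loop: reading and filtering annotated variant tables, building the
binary gene-by-sample matrix, discovering the panel, classifying, and
evaluating against survival with the standard machinery (Kaplan-Meier,
log-rank, proportional hazards, ROC).

## The model and the discovery procedure

Gene mutations are binarized per sample: entry $(s, g)$ of the mutation
matrix is 1 iff sample $s$ carries at least one retained variant in gene
$g$. Survival is binarized to a label per sample (below). Discovery then
runs a sequential backward search (SBS) driven by random-forest variable
importance:

1. fit 10 stratified cross-validation forests on the current gene set;
2. record the mean held-out classification accuracy;
3. remove the `step` genes with the lowest variable importance, where
   importance is averaged over the 10 fold forests;
4. repeat until one gene remains.

The step size follows an adaptive schedule — 100 genes per round while
more than 400 remain, then 50, then 20, and one at a time from 50 genes
down — so the search spends its resolution where it matters. The winning
subset is the one with the fewest genes among those attaining the maximal
mean CV accuracy (ties broken toward fewer genes, then earlier
iterations). The fitted object is returned by `mutpanel()` with the usual
`print`/`summary`/`coef`/`plot`/`predict` methods; `plot()` shows the
accuracy-versus-size trace, which on signal-bearing data rises as noise
genes leave and falls once informative genes start being discarded.

Counting mutated panel genes against the threshold $k$ (default 2) is the
entire classifier — deliberately simple enough to apply in a clinical
report. The comparator biomarkers are implemented as gene-set rules:
KEAP1-driven co-mutation (at least two mutated among KEAP1, STK11, PBRM1,
SMARCA4), the five-gene DNA-damage-repair signature (at least one mutated
among MSH2, MSH6, PMS2, POLE, BRCA2), and an APOBEC gene-status rule that
requires an explicit gene list because no canonical one exists.

## Design choices that were genuinely open

**Outcome binarization.** "Survival status" admits two readings, and both
are implemented. `event_indicator` uses the death/progression flag at last
follow-up. `alive_at_horizon` uses vital status at a landmark, excluding
samples censored before it. The pipeline default is `alive_at_horizon`
with a 12-month landmark, for a statistical reason worth spelling out:
under the survival regimes this model targets (median OS near 9-12 months
for non-benefiting patients, several-fold hazard reduction for
benefiting ones, follow-up of 3-4 years), nearly every non-benefiting
patient has died by last follow-up, so the event indicator is 85-95%
positive and plain classification accuracy — the quantity the backward
search maximizes — degenerates to the majority rate. At a 1-year landmark
the two classes are close to balanced and accuracy regains a gradient.
One year is also a standard OS milestone in ICI trials.

**Importance estimator.** `rf_config()` defaults to the debiased
actual-impurity-reduction importance (`"impurity_corrected"`), averaged
across the 10 cross-validation forests. Averaging uses fits that are
needed anyway and reduces the ranking noise of any single forest by about
$\sqrt{10}$; the debiased estimator avoids the preference of plain Gini
importance for high-prevalence binary features. Permutation and plain
impurity importance remain available.

**Common random numbers.** Every fold forest uses the same seed at every
SBS iteration, and fold assignment is drawn once per run. Accuracy
differences between successive subsets therefore reflect the genes
removed rather than forest-to-forest randomness.

**Ties and boundaries.** The prevalence filter keeps genes mutated in
*at least* `min_samples` samples (boundary inclusive). TMB-high is
*at least* 10 mutations/Mb. A variant with exactly 50 supporting reads is
retained (strictly fewer are removed). The accuracy tie tolerance in
`choose_best_subset()` defaults to 0. Tied event times in the hazards
model use the Breslow approximation. The KM median is the smallest event
time with $S(t) \le 0.5$, reported as `"not reached"` when the curve
never falls that far; a plateau at exactly 0.5 resolves to its left edge.

**Hazard-ratio orientation.** Reports fit the hazard of the WT group
relative to MT, so HR > 1 means the MT group fares better; the reference
group is printed in every output row.

**AUC definition.** The ROC outcome is the binarized survival label used
for training, with the favorable class (alive) positive and the panel
mutation count as score, so a protective panel scores above 0.5. The
scheme is recorded in every report. Published AUCs for this model family
were computed against unstated outcome definitions, so they are not
comparable targets.

**Filter semantics.** Variant filters run in a fixed order (structural,
intronic, population frequency > 1%, common dbSNP flag, synonymous, read
support < 50) with each removed record attributed to the first rule that
caught it, making the filter report a deterministic partition of the
input. Rules whose underlying column is absent are skipped fail-open with
a log line, because public-cohort MAFs routinely lack read-support and
population-frequency columns. Gene symbols are trimmed and upper-cased
only; the single built-in alias maps the recurring literature typo
"BRAC2" to BRCA2.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the structure the analysis assumes:

* independent per-gene Bernoulli mutations; 18 planted signal genes with
  prevalences drawn uniformly from 1-11% (the spectrum of the bundled
  panel, whose printed per-gene values are available via
  `use_panel_spectrum = TRUE`); background genes at 0.5-15%;
* exponential survival with baseline hazard 1/12 events per month (WT
  median about 8.3 months) and hazard divided by 5 once the planted
  mutation count reaches $k = 2$ (`threshold_group` mode, exactly the
  count-threshold model form; `per_gene_additive` spreads the same log
  effect per mutated gene to probe robustness when the truth deviates);
* administrative censoring at 40 months.

Defaults are a 400-sample, 300-gene cohort. `make_null_cohort()` keeps
the mutation process and severs the survival link — the specificity
control emulating a non-ICI cohort, where the panel should find nothing.

What the generator does *not* emulate: mutational multiplicity per gene,
gene-gene co-occurrence (each gene is independent), non-exponential
survival shapes, staggered accrual (censoring is a single administrative
horizon), covariate effects (age, histology, line of therapy), and
panel/exome territory differences. Passing tests on these cohorts
therefore demonstrate the machinery and its calibration, not clinical
performance on real data.

## What discovery can and cannot recover at this scale

Under the default conditions the per-gene marginal association is weak:
a 4%-prevalence planted gene has ~16 carriers in 400 samples, whose
12-month death rate differs from non-carriers by roughly 0.17 — a one-to-
two-sigma effect competing against 282 background genes. Univariate
screening (an upper bound for any marginal ranking, forests included)
places only about 11-14 of the 18 planted genes in the top 40. Forests
also cannot reassemble the count-threshold interaction from rare binary
features: given the planted count directly as a feature, held-out
accuracy reaches ~0.80; on the 18 binary genes it reaches ~0.72. The
practical consequence, measured over ten fixed generator seeds, is that
the chosen subset (anywhere from ~15 to ~100 genes, reflecting how flat
the accuracy curve is) contains 4-14 of the 18 planted genes: clearly better than chance (the random-draw 95th percentile of the
Jaccard overlap is exceeded in every run), but not a faithful
reconstruction of the full signature. Recovery becomes reliable when the
marginal signal is stronger — the scaled test conditions (50-80 genes,
planted prevalences 6-16%) recover most of the signature and validate
with log-rank p < 1e-4 on an independent cohort. Real cohorts in which
such panels were found presumably carry per-gene marginal effects
stronger than the pure threshold interaction simulated here.

## Problem sizes used by the test suite and acceptance script

Calibration checks run at the scale their statistics need: 1000 null
simulations at n = 200 for the log-rank rejection rate, 50 replicates at
n = 400 for hazard-ratio CI coverage and null specificity, ten full
discovery runs at n = 400, G = 300 (with 250-tree forests) for signature
recovery, and scaled planted cohorts (n = 150-300, G = 30-80) for
mechanism tests and byte-level determinism checks. The acceptance script
performs one full-scale discovery plus independent validation, an oracle-
panel reference evaluation, and a null-cohort specificity run.

## Known limitations

* Mutation independence in the generator understates the co-mutation
  structure real comparator rules exploit.
* The backward search inherits the selection optimism of reusing the same
  folds for elimination and scoring; small surviving subsets can show
  inflated CV accuracy, which the minimal-size tie-break then favors.
* No alias resolution beyond one hard-coded fix; cross-panel gene-symbol
  harmonization is out of scope.
* Panel genes absent from a cohort's sequencing universe are treated as
  unmutated (and warned about once per run): counts are then lower bounds,
  which silently weakens cross-panel validation.
* MSI scoring, neoantigen burden, expression-based immune deconvolution
  and trinucleotide-context APOBEC enrichment are out of scope; only the
  gene-status APOBEC rule is provided, and it requires a user-supplied
  gene list.
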