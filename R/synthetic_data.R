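# Synthetic NSCLC-like cohorts with a planted mutation-panel signature.
#
# Mutations are independent per-gene Bernoulli draws at gene-specific
# prevalences; survival is exponential with the hazard reduced for samples
# whose planted-gene mutation count reaches the threshold (the MT group),
# and follow-up is administratively censored at a fixed horizon. This is
# the statistical structure the discovery pipeline assumes: sparse binary
# features, a prevalence spectrum of roughly 1-11% for signal genes, and a
# count-threshold survival benefit.

#' Simulation configuration
#'
#' Defaults emulate a 400-patient targeted-panel cohort: 18 planted signal
#' genes with prevalences drawn uniformly from 1-11% (the prevalence
#' spectrum of the bundled panel; set `use_panel_spectrum = TRUE` to use its
#' printed per-gene values instead),
#' background genes at 0.5-15% prevalence, exponential survival with a
#' baseline hazard of 1/12 events per month (median about 8.3 months for
#' the WT group), a hazard ratio of 5 favouring samples with >= 2 planted
#' mutations, and administrative censoring at 40 months.
#'
#' @param n_samples Cohort size (default 400).
#' @param n_genes Total genes (default 300).
#' @param planted_genes Number of signal genes (default 18).
#' @param planted_prevalence_range Range the planted prevalences are drawn
#'   from when not using the bundled spectrum (default `c(0.01, 0.11)`).
#' @param background_prevalence_range Range for background genes
#'   (default `c(0.005, 0.15)`).
#' @param baseline_hazard Events per month for the WT group (default 1/12).
#' @param log_hr_per_group Log hazard ratio of WT relative to MT (default
#'   `log(5)`); the MT group's hazard is
#'   `baseline_hazard * exp(-log_hr_per_group)`.
#' @param effect_mode `"threshold_group"` (hazard drops once the planted
#'   count reaches `threshold_k`; the generative truth matches the
#'   count-threshold model exactly) or `"per_gene_additive"` (each planted
#'   mutated gene contributes `log_hr_per_group / threshold_k` to the log
#'   hazard reduction; truth deviates from the threshold form).
#' @param threshold_k Planted count threshold (default 2).
#' @param censoring_months Administrative censoring horizon (default 40).
#' @param use_panel_spectrum When `TRUE` and `planted_genes == 18`, the
#'   planted genes take the bundled panel's names and printed prevalences;
#'   by default (`FALSE`) prevalences are drawn uniformly from
#'   `planted_prevalence_range` and genes are named `SIG001`, ...
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 400L, n_genes = 300L, planted_genes = 18L,
                       planted_prevalence_range = c(0.01, 0.11),
                       background_prevalence_range = c(0.005, 0.15),
                       baseline_hazard = 1 / 12,
                       log_hr_per_group = log(5),
                       effect_mode = c("threshold_group", "per_gene_additive"),
                       threshold_k = 2L, censoring_months = 40,
                       use_panel_spectrum = FALSE, seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(planted_genes <= n_genes, n_samples >= 2,
            baseline_hazard > 0, censoring_months > 0, threshold_k >= 1,
            all(planted_prevalence_range > 0),
            all(planted_prevalence_range < 1),
            all(background_prevalence_range > 0),
            all(background_prevalence_range < 1))
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 planted_genes = as.integer(planted_genes),
                 planted_prevalence_range = planted_prevalence_range,
                 background_prevalence_range = background_prevalence_range,
                 baseline_hazard = baseline_hazard,
                 log_hr_per_group = log_hr_per_group,
                 effect_mode = effect_mode,
                 threshold_k = as.integer(threshold_k),
                 censoring_months = censoring_months,
                 use_panel_spectrum = isTRUE(use_panel_spectrum),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a cohort with a planted panel signature
#'
#' @param cfg A [sim_config()].
#' @return A list with `cohort` (a `"cohort"` that round-trips through
#'   [write_cohort()] / [read_cohort()]) and `truth` (class
#'   `"simulated_truth"`: `planted_genes`, per-sample `count`, `group`
#'   (`MT`/`WT` at the planted threshold), `hazard`, `prevalence` (the
#'   sampled per-gene prevalences), and the generating `config`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  if (cfg$use_panel_spectrum && cfg$planted_genes == 18L) {
    panel <- default_panel()
    planted <- panel$genes
    p_planted <- unname(attr(panel, "prevalence")[planted])
  } else {
    planted <- sprintf("SIG%03d", seq_len(cfg$planted_genes))
    p_planted <- stats::runif(cfg$planted_genes,
                              cfg$planted_prevalence_range[1],
                              cfg$planted_prevalence_range[2])
  }
  n_bg <- cfg$n_genes - cfg$planted_genes
  background <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character()
  p_bg <- stats::runif(n_bg, cfg$background_prevalence_range[1],
                       cfg$background_prevalence_range[2])
  genes <- c(planted, background)
  prev <- stats::setNames(c(p_planted, p_bg), genes)

  m <- matrix(stats::rbinom(n * length(genes), 1L,
                            rep(prev, each = n)),
              nrow = n, ncol = length(genes),
              dimnames = list(sample_ids, genes))

  count <- as.integer(rowSums(m[, planted, drop = FALSE]))
  group <- factor(ifelse(count >= cfg$threshold_k, "MT", "WT"),
                  levels = c("WT", "MT"))
  effect <- switch(cfg$effect_mode,
    threshold_group = cfg$log_hr_per_group * (count >= cfg$threshold_k),
    per_gene_additive = (cfg$log_hr_per_group / cfg$threshold_k) * count)
  hazard <- cfg$baseline_hazard * exp(-effect)
  if (all(count < cfg$threshold_k))
    warning("no simulated sample reached the planted count threshold ",
            cfg$threshold_k, " (group sizes: WT = ", sum(group == "WT"),
            ", MT = 0)")

  t_event <- stats::rexp(n, rate = hazard)
  time <- pmin(t_event, cfg$censoring_months)
  event <- as.integer(t_event <= cfg$censoring_months)

  mutations <- matrix_to_records(m)
  clinical <- data.frame(sample_id = sample_ids,
                         time_months = round(time, 4), event = event,
                         endpoint = "OS", stringsAsFactors = FALSE)
  cohort <- assemble_cohort(mutations, clinical,
                            provenance = paste0("simulated (seed ", cfg$seed,
                                                ", effect_mode ",
                                                cfg$effect_mode, ")"))
  truth <- structure(list(planted_genes = planted,
                          count = stats::setNames(count, sample_ids),
                          group = stats::setNames(group, sample_ids),
                          hazard = stats::setNames(hazard, sample_ids),
                          prevalence = prev, config = cfg),
                     class = "simulated_truth")
  list(cohort = cohort, truth = truth)
}

matrix_to_records <- function(m) {
  hits <- which(m == 1L, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  n_rec <- nrow(hits)
  data.frame(sample_id = rownames(m)[hits[, 1]],
             gene = colnames(m)[hits[, 2]],
             variant_classification = rep("missense", n_rec),
             variant_type = rep("SNV", n_rec),
             supporting_reads = rep(NA_integer_, n_rec),
             population_af = rep(NA_real_, n_rec),
             dbsnp_common = rep(NA, n_rec),
             stringsAsFactors = FALSE)
}

#' Simulate a null cohort (no survival signal)
#'
#' Same mutation process as [simulate_cohort()] but survival is independent
#' of every gene (log hazard ratio forced to 0) — the specificity control
#' emulating a non-immunotherapy cohort in which the panel should show no
#' MT/WT survival difference.
#'
#' @param cfg A [sim_config()]; its `log_hr_per_group` is ignored.
#' @return A list with `cohort` and `truth`, as [simulate_cohort()].
#' @export
make_null_cohort <- function(cfg = sim_config()) {
  cfg$log_hr_per_group <- 0
  simulate_cohort(cfg)
}
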