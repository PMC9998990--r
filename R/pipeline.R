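# Orchestrated discovery and validation runs.
#
# run_discovery(): variant filters -> binary matrix -> prevalence filter ->
# outcome binarization -> backward search -> panel choice -> evaluation on
# the training cohort. run_validation(): apply a fixed panel to an unseen
# cohort (no refitting) and evaluate, including the comparator rules.
# Both are deterministic under a fixed config + seed, and can snapshot
# their artifacts as JSON.

#' Evaluate a panel on a cohort
#'
#' Computes the MT/WT split, per-group Kaplan-Meier medians, the log-rank
#' comparison, the WT-vs-MT hazard ratio, count-stratum sizes, the AUC of
#' the panel count against the binarized survival outcome (positive class =
#' alive at the chosen scheme), and, optionally, comparator gene-set rule
#' calls with their own survival comparisons.
#'
#' @param matrix Binary mutation matrix for the cohort.
#' @param clinical Clinical data frame (`sample_id`, `time_months`,
#'   `event`).
#' @param panel A [panel_model()].
#' @param rules Optional list of [gene_set_rule()] objects.
#' @param scheme,horizon Outcome binarization for the AUC (see
#'   [binarize_outcome()]).
#' @return A list of class `"panel_evaluation"`.
#' @export
evaluate_panel <- function(matrix, clinical, panel, rules = list(),
                           scheme = "alive_at_horizon", horizon = 12) {
  stopifnot(inherits(panel, "panel_model"))
  clinical <- clinical[match(rownames(matrix), clinical$sample_id), ,
                       drop = FALSE]
  if (anyNA(clinical$sample_id))
    stop("matrix contains samples absent from the clinical table")
  counts <- count_panel_mutations(matrix, panel)
  groups <- classify_mt_wt(counts, panel)
  mt <- groups == "MT"

  km_mt <- if (any(mt)) km_estimate(clinical$time_months[mt],
                                    clinical$event[mt]) else NULL
  km_wt <- if (any(!mt)) km_estimate(clinical$time_months[!mt],
                                     clinical$event[!mt]) else NULL
  lr <- if (any(mt) && any(!mt))
    logrank_test(clinical$time_months[mt], clinical$event[mt],
                 clinical$time_months[!mt], clinical$event[!mt]) else NULL
  hz <- if (any(mt) && any(!mt))
    hazard_wt_vs_mt(clinical$time_months, clinical$event, groups) else NULL

  auc <- tryCatch({
    lbl <- binarize_outcome(clinical, scheme = scheme, horizon = horizon)
    common <- intersect(names(lbl), names(counts))
    # positive class = favourable outcome (alive), so a protective panel
    # scores above 0.5
    roc_auc(counts[common], 1L - lbl[common])$auc
  }, error = function(e) NA_real_)

  strata <- table(factor(counts, levels = 0:max(counts)))
  rule_results <- lapply(rules, function(rule) {
    labels <- evaluate_gene_set_rule(matrix, rule)
    pos <- labels == rule$positive_label
    lr_rule <- if (any(pos) && any(!pos))
      logrank_test(clinical$time_months[pos], clinical$event[pos],
                   clinical$time_months[!pos], clinical$event[!pos]) else NULL
    list(name = rule$name, n_positive = sum(pos), n_negative = sum(!pos),
         labels = labels, logrank = lr_rule)
  })
  if (length(rule_results))
    names(rule_results) <- vapply(rules, `[[`, character(1), "name")

  structure(list(
    panel = panel,
    n = nrow(matrix),
    n_mt = sum(mt), n_wt = sum(!mt),
    counts = counts, groups = groups,
    median_mt = if (is.null(km_mt)) NA else km_median(km_mt),
    median_wt = if (is.null(km_wt)) NA else km_median(km_wt),
    km_mt = km_mt, km_wt = km_wt,
    logrank = lr, hazard = hz,
    auc = auc, auc_scheme = scheme,
    strata_sizes = as.integer(strata),
    rules = rule_results
  ), class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("Panel evaluation: n = ", x$n, " (MT ", x$n_mt, " / WT ", x$n_wt,
      "), k = ", x$panel$k, "\n", sep = "")
  cat("  median survival: MT ", format(x$median_mt), " vs WT ",
      format(x$median_wt), " months\n", sep = "")
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank: chi-square %.3f, p = %.4g\n",
                x$logrank$chi_square, x$logrank$p_value))
  if (!is.null(x$hazard))
    cat(sprintf("  HR (WT vs MT reference): %.3f [%.3f, %.3f], p = %.4g\n",
                x$hazard$hr, x$hazard$ci_low, x$hazard$ci_high,
                x$hazard$p_value))
  cat(sprintf("  AUC (count vs %s outcome): %.4f\n", x$auc_scheme, x$auc))
  for (r in x$rules)
    cat("  rule ", r$name, ": ", r$n_positive, " positive / ",
        r$n_negative, " negative",
        if (!is.null(r$logrank))
          sprintf(", log-rank p = %.4g", r$logrank$p_value) else "",
        "\n", sep = "")
  invisible(x)
}

#' Run panel discovery on a training cohort
#'
#' @param cohort A raw `"cohort"` (unfiltered mutations).
#' @param k MT count threshold carried into the discovered panel.
#' @param filter_cfg A [filter_config()].
#' @param min_samples Gene-prevalence floor (default 3).
#' @param rf An [rf_config()]; its seed governs all randomness of the run.
#' @param schedule A [step_schedule()].
#' @param scheme,horizon Outcome binarization (see [binarize_outcome()]).
#' @param tol Accuracy tie tolerance for subset choice.
#' @param out_dir Optional directory; when given, writes `panel.json`,
#'   `trace.json`, `report.json` and `config.json` (byte-identical across
#'   reruns with the same config and seed).
#' @return A list of class `"discovery_run"` with `panel`, `fit` (the
#'   `"mutpanel"` object), `evaluation`, `filter_report`, `n_genes_entered`.
#' @export
run_discovery <- function(cohort, k = 2L, filter_cfg = filter_config(),
                          min_samples = 3L, rf = rf_config(),
                          schedule = step_schedule(),
                          scheme = "alive_at_horizon", horizon = 12,
                          tol = 0, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  flt <- apply_variant_filters(cohort$mutations, filter_cfg)
  cohort$mutations <- flt$records
  m <- prevalence_filter(build_binary_matrix(cohort), min_samples)
  y <- binarize_outcome(cohort$clinical, scheme = scheme, horizon = horizon)
  fit <- mutpanel(m, y, k = k, cfg = rf, schedule = schedule, tol = tol)
  panel <- panel_model(fit$genes, k = k)
  evaluation <- evaluate_panel(m, cohort$clinical, panel,
                               scheme = scheme, horizon = horizon)
  run <- structure(list(panel = panel, fit = fit, evaluation = evaluation,
                        filter_report = flt$report,
                        n_genes_entered = ncol(m),
                        seed = rf$seed),
                   class = "discovery_run")
  if (!is.null(out_dir)) write_discovery_run(run, rf, schedule, filter_cfg,
                                             out_dir)
  run
}

write_discovery_run <- function(run, rf, schedule, filter_cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_panel_json(run$panel, file.path(out_dir, "panel.json"))
  tr <- run$fit$trace
  jsonlite::write_json(
    list(iterations = lapply(seq_len(nrow(tr)), function(i) list(
      n_features = tr$n_features[i],
      mean_cv_accuracy = tr$mean_cv_accuracy[i],
      step_size = tr$step_size[i],
      retained_genes = tr$genes[[i]]))),
    file.path(out_dir, "trace.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(evaluation_as_list(run$evaluation),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(seed = run$seed, rf = unclass(rf),
                            schedule = unclass(schedule),
                            filter = unclass(filter_cfg),
                            filter_report = unclass(run$filter_report)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

evaluation_as_list <- function(ev) {
  list(n = ev$n, n_mt = ev$n_mt, n_wt = ev$n_wt,
       k = ev$panel$k, genes = ev$panel$genes,
       median_mt = ev$median_mt, median_wt = ev$median_wt,
       logrank = ev$logrank,
       hazard = if (!is.null(ev$hazard)) as.list(ev$hazard) else NULL,
       auc = ev$auc, auc_scheme = ev$auc_scheme,
       strata_sizes = ev$strata_sizes,
       rules = lapply(ev$rules, function(r)
         list(name = r$name, n_positive = r$n_positive,
              n_negative = r$n_negative, logrank = r$logrank)))
}

#' Validate a fixed panel on an unseen cohort
#'
#' Applies the same variant filters and grouping criteria as discovery but
#' refits nothing: the panel is taken as given, samples are classified
#' MT/WT, and the survival evaluation (KM, log-rank, hazard ratio, AUC,
#' count strata) plus the comparator rules are computed. The gene-prevalence
#' filter is not applied: dropping rarely mutated panel genes would silently
#' change validation counts.
#'
#' @param cohort A raw `"cohort"`.
#' @param panel A [panel_model()] (discovered, or [default_panel()]).
#' @param filter_cfg A [filter_config()].
#' @param rules Comparator rules (default: KEAP1-driven co-mutation and the
#'   DDR five-gene signature).
#' @param scheme,horizon Outcome binarization for the AUC.
#' @param out_dir Optional directory for `report.json`.
#' @return A `"panel_evaluation"` with the filter report attached as
#'   attribute `"filter_report"`.
#' @export
run_validation <- function(cohort, panel, filter_cfg = filter_config(),
                           rules = list(keap1_comutation_rule(), ddr_rule()),
                           scheme = "alive_at_horizon", horizon = 12,
                           out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(panel, "panel_model"))
  flt <- apply_variant_filters(cohort$mutations, filter_cfg)
  cohort$mutations <- flt$records
  m <- build_binary_matrix(cohort)
  ev <- evaluate_panel(m, cohort$clinical, panel, rules = rules,
                       scheme = scheme, horizon = horizon)
  attr(ev, "filter_report") <- flt$report
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(evaluation_as_list(ev),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  ev
}
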