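# Kaplan-Meier, log-rank, proportional hazards, ROC/AUC, Wilcoxon.
#
# All survival machinery is delegated to the 'survival' package; the
# wrappers fix the conventions used throughout the reports: median survival
# is "not reached" when the curve never falls to 0.5, tied event times use
# the Breslow approximation, and hazard ratios for the MT/WT comparison are
# oriented as hazard(WT) / hazard(MT), so HR > 1 means the MT group fares
# better.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Nonnegative follow-up times (months).
#' @param event 0/1 event indicators (1 = event observed).
#' @return An object of class `"km_curve"`: `time` (event times, increasing),
#'   `surv` (non-increasing survival probabilities), `n_risk`, `n_event`,
#'   and `median` (smallest time with survival <= 0.5, or `NA` when the
#'   median is not reached; see `print()`).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (length(time) == 0L) stop("no observations for the KM estimate")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  # median convention: smallest event time with S(t) <= 0.5 ("not reached"
  # when the curve never falls that far); plateaus at exactly 0.5 resolve
  # to the left edge rather than survfit's midpoint rule
  at_half <- fit$time[fit$n.event > 0 & fit$surv <= 0.5 + 1e-12]
  med <- if (length(at_half)) min(at_half) else NA_real_
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median = med, n = length(time), events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " samples, ", x$events, " events\n",
      sep = "")
  cat("  median survival: ",
      if (is.na(x$median)) "not reached" else paste(x$median, "months"),
      "\n", sep = "")
  invisible(x)
}

#' Format a KM median for reports
#' @param km A `"km_curve"`.
#' @return The numeric median, or the string `"not reached"`.
#' @export
km_median <- function(km) {
  if (is.na(km$median)) "not reached" else km$median
}

#' Two-group log-rank test
#'
#' @param time_a,event_a Follow-up and event indicator for group A.
#' @param time_b,event_b Same for group B.
#' @return List with `chi_square`, `df` (1) and `p_value` (chi-square, 1 df).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) {
    warning("no events in either group; log-rank statistic is 0")
    return(list(chi_square = 0, df = 1L, p_value = 1))
  }
  if (sum(event_a) == 0 || sum(event_b) == 0)
    warning("a group has zero events; the log-rank statistic is still defined")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  list(chi_square = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Proportional-hazards regression (univariate or multivariate)
#'
#' Univariate mode fits one model per covariate; multivariate mode fits all
#' covariates jointly. Ties are handled by the Breslow approximation. Rows
#' with missing covariate values are dropped with a log message.
#'
#' @param clinical Data frame with `time_months`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return A data frame with one row per estimated coefficient: `covariate`,
#'   `term`, `hr`, `ci_low`, `ci_high`, `p_value`, `mode`. For factor
#'   covariates the reference level is the factor's first level.
#' @export
cox_fit <- function(clinical, covariates,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  stopifnot(all(c("time_months", "event") %in% names(clinical)),
            all(covariates %in% names(clinical)))
  if (sum(clinical$event) < 1) stop("no events; hazards model undefined")
  fit_one <- function(covs) {
    dat <- clinical[, c("time_months", "event", covs), drop = FALSE]
    cc <- stats::complete.cases(dat)
    if (any(!cc)) message(sum(!cc), " row(s) with missing covariate values ",
                          "dropped from the hazards fit")
    dat <- dat[cc, , drop = FALSE]
    fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                   paste(sprintf("`%s`", covs),
                                         collapse = " + ")))
    fit <- tryCatch(
      survival::coxph(fml, data = dat, ties = "breslow"),
      error = function(e) stop("hazards fit failed for covariate(s) ",
                               paste(covs, collapse = ", "), ": ",
                               conditionMessage(e)))
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(covariate = rep(paste(covs, collapse = "+"), nrow(co)),
               term = rownames(co),
               hr = unname(co[, "exp(coef)"]),
               ci_low = unname(ci[, "lower .95"]),
               ci_high = unname(ci[, "upper .95"]),
               p_value = unname(co[, "Pr(>|z|)"]),
               mode = mode, stringsAsFactors = FALSE, row.names = NULL)
  }
  if (mode == "univariate") {
    out <- do.call(rbind, lapply(covariates, fit_one))
  } else {
    out <- fit_one(covariates)
  }
  out
}

#' Hazard ratio of WT relative to MT
#'
#' Convenience wrapper fixing the report orientation: the fitted coefficient
#' is the log-hazard of the WT group relative to the MT reference, so
#' `hr > 1` means the MT group has the lower hazard (is protective).
#'
#' @param time,event Survival data.
#' @param group Factor or character with levels `MT`/`WT`.
#' @return One-row data frame: `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `reference_group` (`"MT"`).
#' @export
hazard_wt_vs_mt <- function(time, event, group) {
  dat <- data.frame(time_months = time, event = event,
                    wt = as.integer(as.character(group) == "WT"))
  res <- cox_fit(dat, "wt", mode = "univariate")
  data.frame(hr = res$hr, ci_low = res$ci_low, ci_high = res$ci_high,
             p_value = res$p_value, reference_group = "MT",
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive sample outscores a random
#' negative one, with ties counted one half; for a binary score this reduces
#' to (sensitivity + specificity) / 2.
#'
#' @param score Numeric score per sample (higher = more positive).
#' @param outcome 0/1 outcome per sample; both classes must be present.
#' @return List of class `"roc_result"`: `auc`, `thresholds`, `sensitivity`,
#'   `specificity`.
#' @export
roc_auc <- function(score, outcome) {
  stopifnot(length(score) == length(outcome))
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present to compute an ROC curve")
  r <- pROC::roc(response = outcome, predictor = as.numeric(score),
                 direction = "<", levels = c(0, 1), quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 thresholds = r$thresholds,
                 sensitivity = r$sensitivities,
                 specificity = r$specificities),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' @param values_a,values_b Numeric samples.
#' @return List with `statistic` (rank-sum W for the first sample) and
#'   `p_value`.
#' @export
compare_groups_wilcoxon <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
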