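# Random-forest importance ranking and sequential backward search (SBS).
#
# The search starts from all prevalence-filtered genes, repeatedly drops the
# lowest-importance genes (step size set by an adaptive schedule), rescores
# each visited subset by stratified 10-fold cross-validated accuracy, and
# returns the smallest subset attaining the maximal mean accuracy.

#' Binarize survival outcome for classifier training
#'
#' Two schemes are supported. `event_indicator` uses the event flag at last
#' follow-up directly (1 = death/progression observed). `alive_at_horizon`
#' labels a sample 1 if the event occurred by `horizon` months and 0 if
#' follow-up passed the horizon event-free; samples censored before the
#' horizon carry no information about vital status at the horizon and are
#' excluded (the exclusion count is logged).
#'
#' @param clinical Clinical data frame with `sample_id`, `time_months`,
#'   `event`.
#' @param scheme `"event_indicator"` or `"alive_at_horizon"`.
#' @param horizon Landmark in months for `alive_at_horizon` (default 12).
#' @return A named integer vector of 0/1 labels (names = sample IDs).
#' @export
binarize_outcome <- function(clinical,
                             scheme = c("event_indicator", "alive_at_horizon"),
                             horizon = 12) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("sample_id", "time_months", "event") %in% names(clinical)))
  if (scheme == "event_indicator") {
    labels <- as.integer(clinical$event)
    names(labels) <- clinical$sample_id
  } else {
    stopifnot(is.numeric(horizon), horizon > 0)
    dead_by_h <- clinical$event == 1L & clinical$time_months <= horizon
    alive_at_h <- clinical$time_months > horizon
    excluded <- !dead_by_h & !alive_at_h
    if (any(excluded))
      message(sum(excluded), " sample(s) censored before the ", horizon,
              "-month horizon were excluded from outcome binarization")
    keep <- !excluded
    labels <- ifelse(dead_by_h[keep], 1L, 0L)
    names(labels) <- clinical$sample_id[keep]
  }
  if (length(unique(labels)) < 2L)
    stop("outcome binarization produced a single class; ",
         "a classifier is undefined")
  labels
}

#' Random-forest configuration
#'
#' @param n_trees Number of trees per forest (default 500).
#' @param importance `"impurity_corrected"` (default: the debiased
#'   actual-impurity-reduction importance, computed during training at no
#'   extra cost and unbiased for binary features of unequal prevalence),
#'   `"permutation"`, or `"impurity"`.
#' @param cv_folds Cross-validation folds (default 10, stratified by label).
#' @param class_weighting `"balanced"` (default; inverse class frequency) or
#'   `"none"`.
#' @param mtry Features tried per split; `NULL` (default) uses ranger's
#'   `sqrt(p)`.
#' @param seed Integer seed governing fold assignment and every forest.
#' @return A list of class `"rf_config"`.
#' @export
rf_config <- function(n_trees = 500L,
                      importance = c("impurity_corrected", "permutation",
                                     "impurity"),
                      cv_folds = 10L,
                      class_weighting = c("balanced", "none"),
                      mtry = NULL,
                      seed = 1L) {
  importance <- match.arg(importance)
  class_weighting <- match.arg(class_weighting)
  stopifnot(n_trees >= 1, cv_folds >= 2)
  structure(list(n_trees = as.integer(n_trees), importance = importance,
                 cv_folds = as.integer(cv_folds),
                 class_weighting = class_weighting,
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Adaptive step schedule for the backward search
#'
#' While more than `thresholds[i]` features remain, `steps[i]` features are
#' removed per iteration. The default removes 100 at a time above 400
#' features, then 50, then 20, and one at a time once 50 or fewer genes
#' remain.
#'
#' @param thresholds Strictly decreasing feature-count thresholds.
#' @param steps Positive step sizes, one per threshold.
#' @return A list of class `"step_schedule"`.
#' @export
step_schedule <- function(thresholds = c(400L, 150L, 51L, 1L),
                          steps = c(100L, 50L, 20L, 1L)) {
  stopifnot(length(thresholds) == length(steps),
            all(diff(thresholds) < 0), all(steps >= 1))
  structure(list(thresholds = as.integer(thresholds),
                 steps = as.integer(steps)),
            class = "step_schedule")
}

schedule_step <- function(n, schedule) {
  i <- which(n > schedule$thresholds)
  if (!length(i)) return(0L)  # n at or below the last threshold: stop
  schedule$steps[min(i)]
}

#' Subset sizes visited by the backward search
#'
#' @param n_start Starting feature count.
#' @param schedule A [step_schedule()].
#' @return Integer vector of visited subset sizes, from `n_start` down to 1.
#' @export
sbs_sizes <- function(n_start, schedule = step_schedule()) {
  sizes <- integer(0)
  n <- as.integer(n_start)
  repeat {
    sizes <- c(sizes, n)
    step <- schedule_step(n, schedule)
    if (step == 0L || n <= 1L) break
    n <- n - min(step, n - 1L)
  }
  sizes
}

align_labels <- function(x, labels) {
  stopifnot(is.matrix(x))
  if (!is.null(names(labels)) && !is.null(rownames(x))) {
    missing_x <- setdiff(rownames(x), names(labels))
    missing_y <- setdiff(names(labels), rownames(x))
    if (length(missing_x) || length(missing_y))
      stop("samples not shared between matrix and labels: ",
           paste(utils::head(c(missing_x, missing_y), 10), collapse = ", "))
    labels <- labels[rownames(x)]
  } else if (length(labels) != nrow(x)) {
    stop("labels length (", length(labels), ") does not match matrix rows (",
         nrow(x), ")")
  }
  y <- factor(labels, levels = sort(unique(as.integer(labels))))
  if (nlevels(y) < 2L) stop("labels contain a single class")
  y
}

ranger_class_weights <- function(y, weighting) {
  if (weighting == "none") return(NULL)
  tab <- table(y)
  w <- as.numeric(length(y) / (nlevels(y) * tab))
  names(w) <- names(tab)
  w
}

fit_forest <- function(x, y, cfg, seed, importance = "none") {
  ranger::ranger(x = x, y = y, num.trees = cfg$n_trees,
                 importance = importance,
                 mtry = if (!is.null(cfg$mtry)) min(cfg$mtry, ncol(x)),
                 class.weights = ranger_class_weights(y, cfg$class_weighting),
                 num.threads = 1L, seed = seed, verbose = FALSE)
}

#' Rank genes by random-forest variable importance
#'
#' Fits one forest on the full data and returns the per-gene importance
#' scores (permutation importance by default). Reproducible under the
#' configured seed.
#'
#' @param x Binary mutation matrix (samples x genes).
#' @param labels Named 0/1 outcome labels (see [binarize_outcome()]).
#' @param cfg An [rf_config()].
#' @return A named numeric vector of importance scores, one per gene, in
#'   column order.
#' @export
rank_features <- function(x, labels, cfg = rf_config()) {
  y <- align_labels(x, labels)
  fit <- fit_forest(x, y, cfg, seed = cfg$seed, importance = cfg$importance)
  imp <- fit$variable.importance
  imp[colnames(x)]
}

stratified_folds <- function(y, k) {
  # Permute within class, then deal samples round-robin into k folds.
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One CV pass: mean held-out accuracy plus per-gene importance averaged
# over the fold forests (averaging tames the ranking noise of any single
# forest at no extra fitting cost for impurity-based importance).
cv_pass <- function(x, y, fold, cfg, seed_base) {
  k <- max(fold)
  acc <- numeric(k)
  imp <- matrix(0, nrow = ncol(x), ncol = k,
                dimnames = list(colnames(x), NULL))
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_forest(x[!test, , drop = FALSE], y[!test], cfg,
                      seed = seed_base + f, importance = cfg$importance)
    # ranger advises refitting without importance before predicting; the
    # AIR importance does not alter the grown trees, so the advice is
    # cosmetic here and the warning is silenced
    pred <- withCallingHandlers(
      stats::predict(fit, data = x[test, , drop = FALSE])$predictions,
      warning = function(w) {
        if (grepl("impurity_corrected", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    acc[f] <- mean(pred == y[test])
    imp[, f] <- fit$variable.importance[colnames(x)]
  }
  list(mean_accuracy = mean(acc), importance = rowMeans(imp))
}

#' Sequential backward search over gene subsets
#'
#' Starting from every column of `x`, each iteration (i) refits the
#' cross-validation forests on the current subset, (ii) records the subset's
#' mean held-out accuracy, and (iii) removes the `step` genes with the
#' lowest variable importance, where importance is recomputed each iteration
#' as the average across the fold forests and `step` follows the adaptive
#' [step_schedule()]. Fold assignment is stratified by label, drawn once per
#' run from the configured seed, and shared by all iterations so subset
#' scores are comparable.
#'
#' @inheritParams rank_features
#' @param schedule A [step_schedule()].
#' @return A data frame of class `"selection_trace"` with one row per
#'   visited subset size: `n_features`, `mean_cv_accuracy`, `step_size`
#'   (features removed after scoring; 0 on the final row) and a list column
#'   `genes` holding each retained subset.
#' @export
sbs_select <- function(x, labels, cfg = rf_config(),
                       schedule = step_schedule()) {
  y <- align_labels(x, labels)
  if (ncol(x) < 2L) stop("need at least 2 genes to run the backward search")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  fold <- stratified_folds(y, cfg$cv_folds)
  genes <- colnames(x)
  rows <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- length(genes)
    xg <- x[, genes, drop = FALSE]
    # common random numbers: the same forest seed per fold at every
    # iteration, so accuracy differences between subsets reflect the genes
    # removed, not forest-to-forest noise
    pass <- cv_pass(xg, y, fold, cfg, seed_base = cfg$seed)
    step <- if (p > 1L) schedule_step(p, schedule) else 0L
    drop_n <- min(step, p - 1L)
    rows[[iter]] <- list(n_features = p,
                         mean_cv_accuracy = pass$mean_accuracy,
                         step_size = drop_n, genes = genes)
    if (drop_n == 0L) break
    # stable order: ties broken by current gene order
    drop_idx <- order(pass$importance)[seq_len(drop_n)]
    genes <- genes[-drop_idx]
  }
  trace <- data.frame(
    n_features = vapply(rows, `[[`, integer(1), "n_features"),
    mean_cv_accuracy = vapply(rows, `[[`, numeric(1), "mean_cv_accuracy"),
    step_size = vapply(rows, `[[`, integer(1), "step_size")
  )
  trace$genes <- lapply(rows, `[[`, "genes")
  class(trace) <- c("selection_trace", "data.frame")
  trace
}

#' Choose the winning subset from a selection trace
#'
#' Among all visited subsets whose mean CV accuracy is within `tol` of the
#' maximum, returns the one with the fewest genes; remaining ties go to the
#' earliest iteration.
#'
#' @param trace A `"selection_trace"` from [sbs_select()].
#' @param tol Accuracy tie tolerance (default 0).
#' @return Character vector of the chosen genes, with the winning trace row
#'   index in attribute `"iteration"`.
#' @export
choose_best_subset <- function(trace, tol = 0) {
  stopifnot(inherits(trace, "selection_trace"), nrow(trace) >= 1)
  best <- max(trace$mean_cv_accuracy)
  cand <- which(trace$mean_cv_accuracy >= best - tol)
  cand <- cand[trace$n_features[cand] == min(trace$n_features[cand])]
  pick <- cand[1L]
  structure(trace$genes[[pick]], iteration = pick)
}

#' Fit a mutation-count panel model
#'
#' The front door of the package: ranks genes by random-forest importance,
#' prunes them by sequential backward search under cross-validation, keeps
#' the smallest subset with maximal mean CV accuracy, and packages it with a
#' count threshold `k` as an MT/WT classifier (a sample is MT when at least
#' `k` panel genes are mutated).
#'
#' @param x Binary mutation matrix (samples x genes), e.g. from
#'   [build_binary_matrix()] after [prevalence_filter()].
#' @param y Named 0/1 outcome labels from [binarize_outcome()].
#' @param k Count threshold for the MT call (default 2).
#' @param cfg An [rf_config()]; `seed` there governs all randomness.
#' @param schedule A [step_schedule()].
#' @param tol Accuracy tie tolerance passed to [choose_best_subset()].
#' @return An object of class `"mutpanel"`: list with `genes`, `k`, `trace`,
#'   `cv_accuracy` (of the chosen subset), `importance` (scores of the
#'   chosen genes, decreasing), `n_samples`, `cfg`, `call`.
#' @seealso [predict.mutpanel()], [panel_model()]
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 120, n_genes = 40,
#'                                   planted_genes = 4, seed = 7))
#' m <- prevalence_filter(build_binary_matrix(sim$cohort), 3)
#' y <- binarize_outcome(sim$cohort$clinical)
#' fit <- mutpanel(m, y, cfg = rf_config(n_trees = 50, seed = 7))
#' print(fit)
#' head(predict(fit, m))
#' @export
mutpanel <- function(x, y, k = 2L, cfg = rf_config(),
                     schedule = step_schedule(), tol = 0) {
  cl <- match.call()
  trace <- sbs_select(x, y, cfg = cfg, schedule = schedule)
  genes <- choose_best_subset(trace, tol = tol)
  it <- attr(genes, "iteration")
  imp_cfg <- cfg
  imp_cfg$seed <- cfg$seed + 999983L
  imp <- rank_features(x[, genes, drop = FALSE], y, imp_cfg)
  imp <- sort(imp, decreasing = TRUE)
  structure(list(genes = as.character(genes), k = as.integer(k),
                 trace = trace,
                 cv_accuracy = trace$mean_cv_accuracy[it],
                 importance = imp, n_samples = nrow(x),
                 cfg = cfg, call = cl),
            class = "mutpanel")
}

#' @export
print.mutpanel <- function(x, ...) {
  cat("Mutation-count panel model (", length(x$genes), " genes, k = ",
      x$k, ")\n", sep = "")
  cat("  mean CV accuracy: ", sprintf("%.4f", x$cv_accuracy),
      "  (", nrow(x$trace), " search iterations, n = ", x$n_samples,
      ")\n", sep = "")
  cat("  genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mutpanel <- function(object, ...) {
  tr <- object$trace
  cat("Sequential backward search over",
      tr$n_features[1], "genes:\n")
  cat("  visited subset sizes:", length(tr$n_features), "\n")
  cat(sprintf("  accuracy range: %.4f - %.4f\n",
              min(tr$mean_cv_accuracy), max(tr$mean_cv_accuracy)))
  cat(sprintf("  chosen subset: %d genes at accuracy %.4f (threshold k = %d)\n",
              length(object$genes), object$cv_accuracy, object$k))
  cat("  importance of chosen genes:\n")
  print(round(object$importance, 5))
  invisible(object)
}

#' @export
coef.mutpanel <- function(object, ...) object$importance

#' Plot the backward-search accuracy trace
#'
#' @param x A `"mutpanel"` fit.
#' @param ... Passed to [plot()].
#' @export
plot.mutpanel <- function(x, ...) {
  tr <- x$trace
  plot(tr$n_features, tr$mean_cv_accuracy, type = "b", pch = 16,
       xlim = rev(range(tr$n_features)),
       xlab = "Number of genes retained",
       ylab = "Mean 10-fold CV accuracy", ...)
  graphics::abline(v = length(x$genes), lty = 2, col = "grey40")
  invisible(x)
}

#' Classify new samples with a fitted panel
#'
#' @param object A `"mutpanel"` fit.
#' @param newdata Binary mutation matrix with samples as rows.
#' @param type `"group"` (factor MT/WT), `"count"` (panel mutation count),
#'   or `"data.frame"` (sample_id, panel_count, group).
#' @param ... Unused.
#' @export
predict.mutpanel <- function(object, newdata,
                             type = c("group", "count", "data.frame"), ...) {
  type <- match.arg(type)
  panel <- panel_model(object$genes, k = object$k)
  counts <- count_panel_mutations(newdata, panel)
  if (type == "count") return(counts)
  groups <- classify_mt_wt(counts, panel)
  if (type == "group") return(groups)
  data.frame(sample_id = rownames(newdata), panel_count = counts,
             group = groups, stringsAsFactors = FALSE, row.names = NULL)
}
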