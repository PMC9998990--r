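# Outcome binarization, importance ranking, backward search, subset choice.

test_that("outcome binarization implements both schemes and their contracts", {
  cli <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                    time_months = c(9, 14, 6, 20),
                    event = c(1L, 1L, 0L, 0L))
  lab <- binarize_outcome(cli, "event_indicator")
  expect_equal(unname(lab), c(1L, 1L, 0L, 0L))

  # dead at 14 > 12 means alive at the 12-month landmark
  expect_message(lab <- binarize_outcome(cli, "alive_at_horizon", 12),
                 "excluded")
  expect_equal(lab, c(S1 = 1L, S2 = 0L, S4 = 0L))  # S3 censored before 12

  one_class <- data.frame(sample_id = c("A", "B"), time_months = c(1, 2),
                          event = c(1L, 1L))
  expect_error(binarize_outcome(one_class, "event_indicator"),
               "single class")
})

test_that("step schedule arithmetic matches the adaptive tiers", {
  # 10 genes, unit steps: visits 10, 9, ..., 1
  expect_equal(sbs_sizes(10, step_schedule(1L, 1L)), 10:1)
  # default schedule: above 400 features the step is 100
  sizes <- sbs_sizes(430)
  expect_equal(sizes[1:2], c(430L, 330L))
  expect_equal(diff(sizes[2:3]), -50L)   # then 50
  expect_true(all(diff(sizes[sizes <= 51]) == -1L))  # unit steps at the end
  expect_equal(sizes[length(sizes)], 1L)
  expect_true(all(diff(sizes) < 0))
})

test_that("a strongly associated gene ranks at the top across seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 400
    x <- matrix(rbinom(n * 100, 1, 0.1), n, 100,
                dimnames = list(sprintf("S%03d", 1:n),
                                sprintf("G%03d", 1:100)))
    # label follows gene 1 with 25% flips
    y <- ifelse(runif(n) < 0.25, 1L - x[, 1], x[, 1])
    names(y) <- rownames(x)
    imp <- rank_features(x, y, rf_config(n_trees = 200, seed = s))
    hits <- hits + (rank(-imp)["G001"] <= 5)
  }
  expect_gte(hits, 18L)
})

test_that("importance is null-calibrated under label permutation", {
  set.seed(99)
  n <- 150; p <- 30
  x <- matrix(rbinom(n * p, 1, 0.15), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("G%02d", 1:p)))
  y0 <- stats::setNames(rbinom(n, 1, 0.5), rownames(x))
  cfg <- rf_config(n_trees = 150, seed = 7)
  null_imp <- sapply(1:50, function(i) {
    yp <- stats::setNames(sample(y0), names(y0))
    rank_features(x, yp, cfg)
  })
  q95 <- apply(null_imp, 1, quantile, 0.95)
  yp <- stats::setNames(sample(y0), names(y0))
  imp <- rank_features(x, yp, cfg)
  expect_lte(mean(imp > q95), 0.10)
})

test_that("a constant all-zero gene sits in the minimal importance tier", {
  set.seed(4)
  n <- 200
  x <- cbind(matrix(rbinom(n * 10, 1, 0.2), n, 10), 0L)
  dimnames(x) <- list(sprintf("S%03d", 1:n), c(sprintf("G%02d", 1:10), "ZERO"))
  y <- stats::setNames(ifelse(runif(n) < 0.3, 1L - x[, 1], x[, 1]),
                       rownames(x))
  imp <- rank_features(x, y, rf_config(n_trees = 200, seed = 4))
  expect_lte(imp["ZERO"], median(imp))
  expect_lte(imp["ZERO"], 1e-12)  # never split on: no impurity reduction
})

test_that("sample mismatch between matrix and labels is a hard error", {
  x <- matrix(0:1, 2, 1, dimnames = list(c("S1", "S2"), "G1"))
  y <- c(S1 = 0L, S9 = 1L)
  expect_error(rank_features(x, y, rf_config(n_trees = 50)), "S9")
})

test_that("backward-search trace follows the schedule and is deterministic", {
  set.seed(10)
  n <- 80
  x <- matrix(rbinom(n * 10, 1, 0.3), n, 10,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("G%02d", 1:10)))
  y <- stats::setNames(ifelse(runif(n) < 0.3, 1L - x[, 1], x[, 1]),
                       rownames(x))
  cfg <- rf_config(n_trees = 50, seed = 3)
  tr1 <- sbs_select(x, y, cfg, step_schedule(1L, 1L))
  expect_equal(tr1$n_features, 10:1)
  expect_true(all(tr1$mean_cv_accuracy >= 0 & tr1$mean_cv_accuracy <= 1))
  # nested subsets: each retained set contains the next
  for (i in seq_len(nrow(tr1) - 1))
    expect_true(all(tr1$genes[[i + 1]] %in% tr1$genes[[i]]))
  # bit-for-bit determinism under identical config + seed
  tr2 <- sbs_select(x, y, cfg, step_schedule(1L, 1L))
  expect_identical(tr1, tr2)
  # a different seed changes at least the accuracy estimates
  tr3 <- sbs_select(x, y, rf_config(n_trees = 50, seed = 4),
                    step_schedule(1L, 1L))
  expect_false(identical(tr1$mean_cv_accuracy, tr3$mean_cv_accuracy))
})

test_that("subset choice takes max accuracy, then fewest genes, then earliest", {
  mk <- function(n_features, acc) {
    tr <- data.frame(n_features = n_features, mean_cv_accuracy = acc,
                     step_size = 0L)
    tr$genes <- lapply(n_features, function(k) sprintf("G%d_%d", k, seq_len(k)))
    class(tr) <- c("selection_trace", "data.frame")
    tr
  }
  tr <- mk(c(5, 4, 3, 2), c(0.70, 0.74, 0.74, 0.69))
  expect_length(choose_best_subset(tr), 3L)

  single <- mk(7, 0.5)
  expect_length(choose_best_subset(single), 7L)

  # exact tie: fewest variables wins
  tie <- mk(c(20, 18), c(0.7368, 0.7368))
  expect_length(choose_best_subset(tie, tol = 0), 18L)

  # remaining tie at equal size: earliest iteration
  tr2 <- mk(c(4, 4), c(0.6, 0.6))
  expect_equal(attr(choose_best_subset(tr2), "iteration"), 1L)
})

test_that("null labels give chosen-subset accuracy near the majority rate", {
  set.seed(17)
  n <- 200; p <- 30
  x <- matrix(rbinom(n * p, 1, 0.2), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("G%02d", 1:p)))
  y <- stats::setNames(rbinom(n, 1, 0.5), rownames(x))  # pure noise
  tr <- sbs_select(x, y, rf_config(n_trees = 100, seed = 17))
  best <- max(tr$mean_cv_accuracy)
  maj <- max(table(y)) / n
  se <- sqrt(maj * (1 - maj) / n)
  expect_lt(abs(best - maj), 3 * se + 0.02)  # 0.02 = max-over-subsets slack
})

test_that("the fitted panel recovers a planted signature better than chance", {
  cfg <- sim_config(n_samples = 300, n_genes = 80, planted_genes = 8,
                    planted_prevalence_range = c(0.06, 0.15), seed = 42)
  sim <- simulate_cohort(cfg)
  coh <- sim$cohort
  flt <- apply_variant_filters(coh$mutations, filter_config())
  coh$mutations <- flt$records
  m <- prevalence_filter(build_binary_matrix(coh), 3)
  y <- binarize_outcome(coh$clinical, "alive_at_horizon", 12)
  fit <- mutpanel(m, y, cfg = rf_config(n_trees = 200, seed = 42))
  planted <- sim$truth$planted_genes
  jac <- length(intersect(fit$genes, planted)) /
    length(union(fit$genes, planted))
  set.seed(1)
  rand_jac <- replicate(200, {
    g <- sample(colnames(m), length(fit$genes))
    length(intersect(g, planted)) / length(union(g, planted))
  })
  expect_gt(jac, quantile(rand_jac, 0.95))

  # mutpanel object contract and methods
  expect_s3_class(fit, "mutpanel")
  expect_true(all(fit$genes %in% colnames(m)))
  expect_equal(sort(names(coef(fit)), method = "radix"),
               sort(fit$genes, method = "radix"))
  pred <- predict(fit, m, type = "data.frame")
  expect_equal(nrow(pred), nrow(m))
  expect_true(all(pred$group[pred$panel_count >= fit$k] == "MT"))
  out <- capture.output({ print(fit); summary(fit) })
  expect_true(any(grepl("CV accuracy", out)))
})
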