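# Hand-computed oracles for the survival machinery.

# textbook two-group log-rank: observed-minus-expected over shared risk sets
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  g1 <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("KM equals the empirical survival function on uncensored data", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$time, c(1, 2, 3, 4))
  expect_equal(km$surv, c(0.75, 0.50, 0.25, 0.00))
  expect_equal(km$median, 2)

  # machine-precision agreement with the ecdf complement at event times
  set.seed(5)
  t <- round(rexp(40, 1 / 10), 3)
  km <- km_estimate(t, rep(1, 40))
  emp <- 1 - ecdf(t)(km$time)
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("censoring reduces the risk set without steps (hand product-limit)", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  # by hand: S(1) = 2/3; censoring at 2 leaves 1 at risk; S(3) = 2/3 * 0 = 0
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2 / 3, 0), tolerance = 1e-12)
})

test_that("an all-censored sample has a flat curve and unreached median", {
  km <- km_estimate(c(5, 8, 13), c(0, 0, 0))
  expect_length(km$time, 0L)           # no event steps
  expect_true(is.na(km$median))
  expect_equal(km_median(km), "not reached")
})

test_that("log-rank is symmetric, null on identical groups, and matches the
           hand risk-set summation on the 6-patient toy set", {
  t <- c(3, 5, 9, 11); e <- c(1, 0, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chi_square, 0, tolerance = 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  ta <- c(1, 3, 5); tb <- c(2, 4, 6)
  ab <- logrank_test(ta, rep(1, 3), tb, rep(1, 3))
  ba <- logrank_test(tb, rep(1, 3), ta, rep(1, 3))
  expect_equal(ab$chi_square, ba$chi_square, tolerance = 1e-12)
  expect_equal(ab$chi_square,
               logrank_oracle(ta, rep(1, 3), tb, rep(1, 3)),
               tolerance = 1e-9)
  expect_equal(ab$p_value, pchisq(ab$chi_square, 1, lower.tail = FALSE))

  # oracle also agrees on a censored configuration
  ea <- c(1, 1, 0); eb <- c(1, 0, 1)
  expect_equal(logrank_test(ta, ea, tb, eb)$chi_square,
               logrank_oracle(ta, ea, tb, eb), tolerance = 1e-9)
})

test_that("log-rank warns but is defined when one group has no events", {
  expect_warning(res <- logrank_test(c(1, 2, 3), c(0, 0, 0),
                                     c(1, 2, 3), c(1, 1, 1)),
                 "zero events")
  expect_true(is.finite(res$chi_square))
})

test_that("hazards fit: identical groups give HR 1 with CI spanning 1", {
  dat <- data.frame(time_months = rep(c(2, 4, 6, 8, 10), 2),
                    event = rep(c(1, 1, 0, 1, 1), 2),
                    grp = rep(c(0, 1), each = 5))
  res <- cox_fit(dat, "grp")
  expect_equal(res$hr, 1, tolerance = 1e-6)
  expect_true(res$ci_low <= 1 && res$ci_high >= 1)
})

test_that("univariate mode equals separate single-covariate fits", {
  set.seed(8)
  n <- 80
  dat <- data.frame(time_months = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                    a = rbinom(n, 1, 0.5), b = rnorm(n))
  uni <- cox_fit(dat, c("a", "b"), mode = "univariate")
  expect_equal(uni[uni$covariate == "a", c("hr", "p_value")],
               cox_fit(dat, "a")[, c("hr", "p_value")],
               ignore_attr = TRUE)
  expect_equal(uni[uni$covariate == "b", "hr"], cox_fit(dat, "b")$hr)
  multi <- cox_fit(dat, c("a", "b"), mode = "multivariate")
  expect_equal(nrow(multi), 2L)  # one joint fit, two coefficients
})

test_that("hazards fit recovers a planted log-HR with small bias", {
  set.seed(12)
  lhr <- 1.6; reps <- 30; n <- 2000
  est <- replicate(reps, {
    x <- rbinom(n, 1, 0.25)
    t <- rexp(n, rate = (1 / 12) * exp(lhr * (1 - x)))  # x = 1 protective
    obs <- pmin(t, 40); ev <- as.integer(t <= 40)
    dat <- data.frame(time_months = obs, event = ev, wt = 1 - x)
    log(cox_fit(dat, "wt")$hr)
  })
  expect_lt(abs(mean(est) - lhr), 0.05)
})

test_that("the WT-vs-MT wrapper fixes the protective orientation", {
  set.seed(13)
  n <- 400
  mt <- rbinom(n, 1, 0.3)
  t <- rexp(n, rate = (1 / 12) * exp(-1.6 * mt))   # MT protective
  res <- hazard_wt_vs_mt(pmin(t, 40), as.integer(t <= 40),
                         ifelse(mt == 1, "MT", "WT"))
  expect_gt(res$hr, 1)                  # HR > 1 <=> MT protective
  expect_equal(res$reference_group, "MT")
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)
})

test_that("AUC equals the brute-force concordant-pair fraction", {
  score <- c(0.9, 0.8, 0.7, 0.6, 0.6, 0.3, 0.2, 0.1)
  outcome <- c(1, 1, 0, 1, 0, 0, 1, 0)
  pairs_oracle <- function(score, outcome) {
    pos <- score[outcome == 1]; neg <- score[outcome == 0]
    total <- 0
    for (p in pos) for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(score, outcome)$auc, pairs_oracle(score, outcome),
               tolerance = 1e-12)

  # random fixtures
  set.seed(30)
  for (i in 1:10) {
    s <- sample(1:5, 30, replace = TRUE)  # heavy ties
    o <- rbinom(30, 1, 0.5)
    if (length(unique(o)) < 2) next
    expect_equal(roc_auc(s, o)$auc, pairs_oracle(s, o), tolerance = 1e-12)
  }
})

test_that("AUC hits its boundary cases and monotone invariance", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(4, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  set.seed(31)
  s <- rnorm(50); o <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(exp(2 * s) + 5, o)$auc, roc_auc(s, o)$auc,
               tolerance = 1e-12)
  expect_error(roc_auc(s, rep(1, 50)), "both outcome classes")
})

test_that("binary-score AUC reduces to (sensitivity + specificity) / 2", {
  score <- c(1, 1, 1, 0, 0, 0, 1, 0)
  outcome <- c(1, 1, 0, 0, 0, 1, 1, 0)
  sens <- sum(score == 1 & outcome == 1) / sum(outcome == 1)
  spec <- sum(score == 0 & outcome == 0) / sum(outcome == 0)
  expect_equal(roc_auc(score, outcome)$auc, (sens + spec) / 2,
               tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum matches exact enumeration and is symmetric", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- compare_groups_wilcoxon(a, b)
  # exact enumeration oracle over all C(6,3) group assignments
  vals <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  combos <- combn(6, 3)
  u_null <- apply(combos, 2, function(ix) u_stat(vals[ix], vals[-ix]))
  p_exact <- mean(abs(u_null - 4.5) >= abs(u_obs - 4.5))  # two-sided about E[U]
  expect_equal(unname(res$statistic), u_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)

  swapped <- compare_groups_wilcoxon(b, a)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(unname(swapped$statistic), 9 - u_obs)  # mirrored statistic

  same <- compare_groups_wilcoxon(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gte(same$p_value, 0.99)
})
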