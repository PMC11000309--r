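# Classification metrics and survival-based segmentation evaluation.

test_that("classification metrics match a hand-worked confusion matrix", {
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$mse, 0.25)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1.0)
  expect_length(m$undefined, 0)

  perfect <- classification_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$specificity, 1)

  expect_error(classification_metrics(c(1, 0), c(1, 0, 1)),
               class = "respseg_data_error")
})

test_that("accuracy + MSE = 1 exactly on all binary predictions", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    m <- classification_metrics(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    expect_identical(m$accuracy + m$mse, 1)
  }
})

test_that("zero-denominator metrics are flagged and reported as 0", {
  m <- classification_metrics(c(0, 0, 0), c(1, 0, 1))  # no predicted positives
  expect_equal(m$precision, 0)
  expect_true("precision" %in% m$undefined)
  m2 <- classification_metrics(c(1, 1), c(1, 1))       # no true negatives
  expect_true("specificity" %in% m2$undefined)
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1), rep("all", 3))
  expect_equal(km$curves$surv[km$curves$time == 1], 2 / 3)
  # at t=3 the risk set is a single subject: S(3) = 2/3 * (1 - 1/1) = 0
  expect_equal(km$curves$surv[km$curves$time == 3], 0)

  # all censored: flat survival at 1, undefined median
  km_c <- km_estimate(c(5, 6, 7), c(0, 0, 0), rep("g", 3))
  expect_true(all(km_c$curves$surv == 1))
  expect_true(is.na(km_c$medians$median))

  # no censoring: complements the empirical CDF
  set.seed(9)
  tt <- rexp(40)
  km_e <- km_estimate(tt, rep(1, 40), rep("g", 40))
  expect_equal(km_e$curves$surv,
               1 - ecdf(tt)(sort(unique(tt))), tolerance = 1e-12)
  # survival is non-increasing and starts at or below 1
  expect_true(all(diff(km_e$curves$surv) <= 0))
  expect_lte(max(km_e$curves$surv), 1)

  expect_error(km_estimate(numeric(0), numeric(0), character(0)),
               class = "respseg_data_error")
})

test_that("log-rank: identical groups give statistic 0, p 1", {
  tt <- c(1, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 1)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(tt, ev, rep("a", 5)), class = "respseg_data_error")
  expect_error(logrank_test(c(tt, tt), c(ev, 0, 0, 0, 0, 0),
                            rep(c("a", "b"), each = 5)),
               "event", class = "respseg_data_error")
})

test_that("log-rank detects a true hazard ratio of 0.5 with high power", {
  set.seed(31)
  rejections <- vapply(1:200, function(i) {
    t0 <- rexp(300, 1)
    t1 <- rexp(300, 0.5)
    lr <- logrank_test(c(t0, t1), rep(1, 600), rep(0:1, each = 300))
    lr$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.9)
})

test_that("Cox fit is invariant to duplicating every subject", {
  set.seed(12)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, exp(-0.5 * x))
  ev <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(tt, ev, data.frame(group = x))
  # duplication turns every event time into a tie; under the Efron tie
  # correction the partial likelihood is invariant only up to the tie
  # approximation, so equality is asserted to that order
  f2 <- cox_fit(c(tt, tt), c(ev, ev), data.frame(group = c(x, x)))
  expect_equal(f1$group_effect$estimate, f2$group_effect$estimate,
               tolerance = 0.01)
  expect_equal(f2$n, 2 * f1$n)
})

test_that("Cox CI covers the null in most null replicates", {
  set.seed(57)
  covered <- vapply(1:100, function(i) {
    x <- rbinom(400, 1, 0.5)
    tt <- rexp(400)                 # survival independent of x
    f <- cox_fit(tt, rbinom(400, 1, 0.85), data.frame(group = x))
    f$group_effect$ci_low <= 1 && f$group_effect$ci_high >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("rank-deficient covariates raise a named error", {
  tt <- rexp(50); ev <- rep(1, 50); x <- rnorm(50)
  expect_error(cox_fit(tt, ev, data.frame(a = x, b = 2 * x)),
               "aliased", class = "respseg_model_error")
  expect_error(cox_fit(tt, rep(0, 50), data.frame(a = x)),
               class = "respseg_data_error")
})

test_that("AFT time ratios are equivariant to time rescaling", {
  set.seed(71)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tt <- exp(5 + log(1.3) * x + 0.7 * log(rexp(n)))  # Weibull AFT truth
  ev <- rbinom(n, 1, 0.8)
  f1 <- aft_fit(tt, ev, data.frame(group = x))
  f2 <- aft_fit(tt * 3.7, ev, data.frame(group = x))
  expect_equal(f1$group_effect$estimate, f2$group_effect$estimate,
               tolerance = 1e-6)
  expect_equal(f1$table$p_value, f2$table$p_value, tolerance = 1e-6)
  # lognormal alternative is exposed and comparable via AIC
  fl <- aft_fit(tt, ev, data.frame(group = x), distribution = "lognormal")
  expect_identical(fl$distribution, "lognormal")
  expect_true(is.finite(fl$aic))
})

test_that("AFT CI covers a null group effect in most replicates", {
  set.seed(90)
  covered <- vapply(1:100, function(i) {
    x <- rbinom(300, 1, 0.5)
    tt <- exp(4 + 0.8 * log(rexp(300)))
    f <- aft_fit(tt, rbinom(300, 1, 0.85), data.frame(group = x))
    f$group_effect$ci_low <= 1 && f$group_effect$ci_high >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("AIC comparison declares the lower-AIC fit the winner", {
  mk <- function(kind, aic) structure(
    list(model_kind = kind, table = data.frame(), group_effect = NULL,
         aic = aic, n = 10, n_events = 8),
    class = "surv_fit_summary")
  cmp <- compare_models(mk("cox", 10), mk("cox", 12))
  expect_equal(cmp$winner, "novel")
  expect_equal(cmp$delta_aic, -2)
  expect_equal(compare_models(mk("cox", 5), mk("cox", 5))$winner, "tie")
  expect_error(compare_models(mk("cox", 1), mk("aft", 1)),
               class = "respseg_config_error")
})
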