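# CV grid enumeration, split generation, out-of-fold probabilities and the
# F1-optimal cutoff search.

test_that("the default technique grid enumerates 47 specifications in order", {
  grid <- cv_grid()
  expect_length(grid, 47)  # 1+1+1 + 8 + 24 + 3 + 9
  fams <- vapply(grid, `[[`, character(1), "family")
  expect_equal(as.vector(table(factor(fams, levels = unique(fams)))),
               c(1, 1, 1, 8, 24, 3, 9))
  expect_equal(fams[1:3], c("LOOCV", "LpOCV", "HoldOut"))
  # deterministic lexicographic ordering within repeated families
  rep_specs <- grid[fams == "RepeatedKFold"]
  ks <- vapply(rep_specs, `[[`, numeric(1), "k")
  rs <- vapply(rep_specs, `[[`, numeric(1), "repeats")
  expect_equal(order(ks, rs), seq_along(rep_specs))

  expect_length(cv_grid(families = "KFold", kfold_k = 5), 1)
  expect_length(cv_grid(families = "RepeatedKFold", repeated_k = 10,
                        repeated_repeats = 2:4), 3)
  expect_error(cv_grid(families = character(0)), class = "respseg_config_error")
})

test_that("split generation matches each family's definition", {
  y <- c(1, 0, 1, 0)
  loo <- generate_splits(cv_spec("LOOCV"), y)
  expect_length(loo, 4)
  expect_setequal(vapply(loo, `[[`, numeric(1), "test"), 1:4)

  lpo <- generate_splits(cv_spec("LpOCV"), y)
  expect_length(lpo, choose(4, 2))
  pairs <- vapply(lpo, function(s) paste(sort(s$test), collapse = "-"), character(1))
  expect_length(unique(pairs), 6)

  ho <- generate_splits(cv_spec("HoldOut"), rep(0:1, 20), seed = 3)
  expect_length(ho, 1)
  expect_equal(length(ho[[1]]$test), 10)  # 25% of 40
  expect_length(intersect(ho[[1]]$train, ho[[1]]$test), 0)

  kf <- generate_splits(cv_spec("KFold", k = 5), rep(0:1, 11), seed = 9)
  sizes <- lengths(lapply(kf, `[[`, "test"))
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(unlist(lapply(kf, `[[`, "test")), 1:22)
})

test_that("stratified folds preserve class counts within one member", {
  y <- rep(c(1, 0), c(6, 3))
  folds <- generate_splits(cv_spec("StratifiedKFold", k = 3), y, seed = 1)
  for (f in folds) {
    expect_equal(sum(y[f$test] == 1), 2)
    expect_equal(sum(y[f$test] == 0), 1)
  }
  # property over random label vectors
  set.seed(10)
  for (rep_i in 1:10) {
    n <- sample(30:80, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    k <- sample(3:5, 1)
    if (min(table(y)) < k) next
    folds <- generate_splits(cv_spec("StratifiedKFold", k = k), y,
                             seed = rep_i)
    for (cls in 0:1) {
      per_fold <- vapply(folds, function(f) sum(y[f$test] == cls), numeric(1))
      expect_lte(diff(range(per_fold)), 1)
      expect_equal(sum(per_fold), sum(y == cls))
    }
  }
  expect_error(generate_splits(cv_spec("StratifiedKFold", k = 4), rep(c(0, 1), c(3, 9))),
               "stratification", class = "respseg_data_error")
})

test_that("the leave-pair-out cap draws distinct seeded pairs", {
  y <- rbinom(40, 1, 0.5)
  sp <- generate_splits(cv_spec("LpOCV"), y, seed = 5, lpo_cap = 50)
  expect_length(sp, 50)
  keys <- vapply(sp, function(s) paste(sort(s$test), collapse = "-"), character(1))
  expect_length(unique(keys), 50)
  sp2 <- generate_splits(cv_spec("LpOCV"), y, seed = 5, lpo_cap = 50)
  expect_identical(sp, sp2)
})

test_that("logistic fitting recovers known truths", {
  # intercept-only, balanced labels: intercept 0, predicted probability 0.5
  X0 <- matrix(numeric(0), 20, 0)
  fit0 <- fit_logistic(X0, rep(c(0, 1), 10))
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-8)
  expect_equal(unname(predict_logistic(fit0, X0)[1]), 0.5)

  # null design: slopes within 3 standard errors of zero
  d_null <- sim_logit_design(2000, beta = c(0, 0, 0), seed = 21)
  fit_null <- fit_logistic(d_null$X, d_null$y)
  g <- glm(d_null$y ~ d_null$X, family = binomial())
  se <- summary(g)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(fit_null$coefficients[-1]) < 3 * se))

  # parameter recovery: within 10% relative error and within 3 SE
  beta <- c(2, -1.5, 1)
  d <- sim_logit_design(2000, beta = beta, intercept = -0.4, seed = 4)
  fit <- fit_logistic(d$X, d$y)
  expect_lt(max(abs(fit$coefficients[-1] - beta) / abs(beta)), 0.10)
  se_b <- summary(glm(d$y ~ d$X, family = binomial()))$coefficients[-1, "Std. Error"]
  expect_true(all(abs(fit$coefficients[-1] - beta) < 3 * se_b))

  expect_error(fit_logistic(d$X, rep(1, 2000)), class = "respseg_model_error")
})

test_that("perfect separation falls back to finite ridge coefficients", {
  X <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_logistic(X, y), "ridge")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(fit$separation)
  # still orders the classes correctly
  expect_true(all(predict_logistic(fit, X)[4:6] > 0.5))
})

test_that("out-of-fold probabilities aggregate and stay deterministic", {
  d <- sim_logit_design(40, beta = c(1, -1), intercept = -0.3, seed = 2)
  # KFold with k = n reproduces LOOCV exactly
  loo <- out_of_fold_probabilities(d$X, d$y,
                                   generate_splits(cv_spec("LOOCV"), d$y))
  kfn <- out_of_fold_probabilities(d$X, d$y,
                                   generate_splits(cv_spec("KFold", k = 40), d$y, seed = 8))
  expect_equal(kfn$prob, loo$prob, tolerance = 1e-12)

  # repeated K-fold: every patient validated once per repetition
  sp <- generate_splits(cv_spec("RepeatedKFold", k = 5, repeats = 2), d$y, seed = 4)
  oof <- out_of_fold_probabilities(d$X, d$y, sp)
  expect_true(all(oof$coverage == 2))

  # purity: identical inputs give bit-identical output
  expect_identical(oof, out_of_fold_probabilities(d$X, d$y, sp))

  # single-class training folds are skipped with a warning
  y_rare <- c(1, rep(0, 19))
  sp_rare <- list(list(train = 2:20, test = 1L),       # single-class train
                  list(train = c(1:10), test = 11:20))
  expect_warning(oof_r <- out_of_fold_probabilities(d$X[1:20, ], y_rare, sp_rare),
                 "skipped")
  expect_true(is.na(oof_r$prob[1]))
  expect_error(
    suppressWarnings(out_of_fold_probabilities(d$X[1:20, ], y_rare, sp_rare[1])),
    class = "respseg_model_error")
})

test_that("F1 at a cutoff matches hand-worked confusion matrices", {
  probs <- c(0.9, 0.8, 0.3, 0.2)
  y <- c(1, 1, 0, 1)
  expect_equal(f1_at_cutoff(probs, y, 0.5), 0.8)  # TP=2 FP=0 FN=1
  # perfectly separating probabilities give F1 = 1 at any cutoff between
  expect_equal(f1_at_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5), 1)
  # cutoff 1: nothing predicted positive, convention F1 = 0
  expect_equal(f1_at_cutoff(probs, y, 1), 0)
  expect_error(f1_at_cutoff(probs, y, 1.2), class = "respseg_config_error")
  expect_error(f1_at_cutoff(probs, y, -0.1), class = "respseg_config_error")

  # random cases agree with the direct confusion-matrix oracle
  set.seed(14)
  for (i in 1:25) {
    p <- runif(30); yy <- rbinom(30, 1, 0.4); ct <- runif(1)
    expect_equal(f1_at_cutoff(p, yy, ct), f1_direct(p, yy, ct))
  }
})

test_that("best_cutoff maximises F1 over the candidate set", {
  res <- best_cutoff(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1))
  expect_equal(res$cutoff, 0.4)  # strict >: predictions 0,0,1,1
  expect_equal(res$f1, 1)

  # all-equal probabilities: only the 0 candidate predicts anything
  res_eq <- best_cutoff(rep(0.7, 6), c(1, 0, 1, 0, 1, 1))
  expect_equal(res_eq$cutoff, 0)
  expect_equal(res_eq$f1, f1_direct(rep(0.7, 6), c(1, 0, 1, 0, 1, 1), 0))

  expect_error(best_cutoff(runif(5), rep(1, 5)), class = "respseg_model_error")

  # returned F1 is attained at the returned cutoff, and beats a dense grid
  set.seed(8)
  for (i in 1:20) {
    p <- round(runif(60), 2); yy <- rbinom(60, 1, 0.3)
    if (length(unique(yy)) < 2) next
    res <- best_cutoff(p, yy)
    expect_equal(f1_at_cutoff(p, yy, res$cutoff), res$f1)
    grid_best <- max(vapply(seq(0, 1, by = 0.005), f1_direct, numeric(1),
                            probs = p, y = yy))
    expect_gte(res$f1 + 1e-12, grid_best)
  }
})

test_that("technique selection applies the rule and deterministic tie-breaks", {
  d <- sim_logit_design(60, beta = c(1.5, -1), intercept = -1, seed = 6)
  one <- select_cv_technique(d$X, d$y, grid = cv_grid(families = "KFold", kfold_k = 5),
                             seed = 11)
  expect_length(one$per_technique, 1)
  expect_equal(one$chosen$label, "KFold(k=5)")

  # duplicated deterministic spec: identical OOF probabilities, earlier
  # entry wins the tie-break
  grid2 <- list(cv_spec("LOOCV"), cv_spec("LOOCV"))
  sel2 <- select_cv_technique(d$X, d$y, grid = grid2, seed = 11)
  expect_equal(sel2$per_technique[[1]]$cutoff, sel2$per_technique[[2]]$cutoff)
  expect_identical(sel2$chosen, sel2$per_technique[[1]])

  # max_f1 rule picks the F1 maximiser; max_cutoff the cutoff maximiser
  grid3 <- cv_grid(families = c("KFold", "StratifiedKFold"),
                   kfold_k = c(3, 5, 10), stratified_k = 3:5)
  sel_c <- select_cv_technique(d$X, d$y, grid = grid3, seed = 11, rule = "max_cutoff")
  sel_f <- select_cv_technique(d$X, d$y, grid = grid3, seed = 11, rule = "max_f1")
  cuts <- vapply(sel_c$per_technique, `[[`, numeric(1), "cutoff")
  f1s <- vapply(sel_c$per_technique, `[[`, numeric(1), "f1")
  expect_equal(sel_c$chosen$cutoff, max(cuts))
  expect_equal(sel_f$chosen$f1, max(f1s))

  # deterministic under a fixed master seed
  sel_again <- select_cv_technique(d$X, d$y, grid = grid3, seed = 11)
  expect_equal(sel_again$chosen$cutoff, sel_c$chosen$cutoff)
  expect_identical(vapply(sel_again$per_technique, `[[`, numeric(1), "cutoff"),
                   cuts)
})
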