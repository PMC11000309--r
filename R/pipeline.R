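# End-to-end orchestration: train the novel (CV-selected cutoff) and
# standard (fixed 0.5) scoring systems on two training trials, segment a
# test trial with each, and evaluate the segmentations side by side.

# Complete-case modeling view of one trial: trajectory matrix, responder
# labels, and the subject IDs they are aligned on.
prepare_training <- function(ds) {
  mf <- model_frame(ds, require_bor = TRUE)
  traj_all <- trajectory_matrix(ds)
  ids <- mf$data$subject_id
  traj <- traj_all[ids, , drop = FALSE]
  y <- bor_to_binary(mf$data$bor)
  if (length(unique(y)) < 2) {
    stop_data("trial ", ds$trial_id, " has a single responder class; cannot train")
  }
  list(ids = ids, traj = traj, y = y, data = mf$data,
       n_excluded = mf$n_excluded)
}

design_from <- function(ds, ids, pca) {
  X <- build_design_matrix(ds, pca)
  X[ids, , drop = FALSE]
}

# Design matrix for the test trial under the configured PCA basis:
# either one PCA fitted on the pooled training trajectories (default), or
# the mean of the two per-trial projections.
test_design <- function(model, test_ds) {
  if (model$pca_basis == "pooled") {
    build_design_matrix(test_ds, model$pca$pooled)
  } else {
    Xa <- build_design_matrix(test_ds, model$pca$per_trial[[1]])
    Xb <- build_design_matrix(test_ds, model$pca$per_trial[[2]])
    (Xa + Xb) / 2
  }
}

#' Train the novel (CV-optimised cutoff) scoring system
#'
#' Per training trial: compute percent-change trajectories, fit that trial's
#' PCA, assemble the design matrix, run the full CV-technique grid to select
#' the technique with the largest F1-optimal cutoff, then refit the logistic
#' model on the full trial. The two trials' coefficients are averaged into
#' the pooled scoring system and the two best cutoffs averaged into the
#' pooled threshold.
#'
#' @param train_a,train_b Training `trial_dataset`s (BOR required for fitting).
#' @param n_components Retained principal components (default 2).
#' @param grid CV technique grid from [cv_grid()].
#' @param rule Technique selection rule, `"max_cutoff"` (default) or `"max_f1"`.
#' @param seed Master seed; all CV randomness derives from it.
#' @param pca_basis How test patients are projected: `"pooled"` (default;
#'   one PCA on the pooled training trajectories) or `"per_trial"` (average
#'   of the two per-trial projections).
#' @param lpo_cap Leave-pair-out pair cap.
#' @return A `pooled_model` (method `"novel"`) carrying the test-projection
#'   PCA, the per-trial CV selections, and provenance.
#' @export
train_novel <- function(train_a, train_b, n_components = 2, grid = cv_grid(),
                        rule = "max_cutoff", seed = 20240408L,
                        pca_basis = c("pooled", "per_trial"), lpo_cap = 2000L) {
  pca_basis <- match.arg(pca_basis)
  prep <- list(prepare_training(train_a), prepare_training(train_b))
  fits <- vector("list", 2)
  sels <- vector("list", 2)
  pcas <- vector("list", 2)
  for (i in 1:2) {
    pcas[[i]] <- fit_pca(prep[[i]]$traj, n_components)
    ds <- if (i == 1) train_a else train_b
    X <- design_from(ds, prep[[i]]$ids, pcas[[i]])
    sels[[i]] <- select_cv_technique(X, prep[[i]]$y, grid = grid,
                                     seed = derive_seed(seed, i), rule = rule,
                                     lpo_cap = lpo_cap)
    fits[[i]] <- fit_logistic(X, prep[[i]]$y)
  }
  provenance <- list(
    training_trials = c(train_a$trial_id, train_b$trial_id),
    chosen_technique = vapply(sels, function(s) s$chosen$label, character(1)),
    training_cutoffs = vapply(sels, function(s) s$chosen$cutoff, numeric(1)),
    training_f1 = vapply(sels, function(s) s$chosen$f1, numeric(1)),
    rule = rule, seed = seed, n_components = n_components
  )
  model <- pool_models(fits[[1]], fits[[2]],
                       cutoff1 = sels[[1]]$chosen$cutoff,
                       cutoff2 = sels[[2]]$chosen$cutoff,
                       method = "novel", provenance = provenance)
  model$pca_basis <- pca_basis
  model$pca <- list(pooled = fit_pca(rbind(prep[[1]]$traj, prep[[2]]$traj),
                                     n_components),
                    per_trial = pcas)
  model$selection <- sels
  model$n_components <- n_components
  model
}

#' Train the standard (fixed 0.5 cutoff) scoring system
#'
#' Same features and pooling as [train_novel()] but with no resampling:
#' each training trial contributes one full-data logistic fit, and the
#' segmentation threshold is fixed at 0.5.
#'
#' @inheritParams train_novel
#' @return A `pooled_model` (method `"standard"`, `bcut = 0.5`).
#' @export
train_standard <- function(train_a, train_b, n_components = 2,
                           pca_basis = c("pooled", "per_trial")) {
  pca_basis <- match.arg(pca_basis)
  prep <- list(prepare_training(train_a), prepare_training(train_b))
  pcas <- lapply(prep, function(p) fit_pca(p$traj, n_components))
  Xa <- design_from(train_a, prep[[1]]$ids, pcas[[1]])
  Xb <- design_from(train_b, prep[[2]]$ids, pcas[[2]])
  model <- standard_train(Xa, prep[[1]]$y, Xb, prep[[2]]$y,
                          provenance = list(
                            training_trials = c(train_a$trial_id, train_b$trial_id),
                            n_components = n_components))
  model$pca_basis <- pca_basis
  model$pca <- list(pooled = fit_pca(rbind(prep[[1]]$traj, prep[[2]]$traj),
                                     n_components),
                    per_trial = pcas)
  model$n_components <- n_components
  model
}

#' Segment a test trial with a trained pooled model
#'
#' @param model A `pooled_model` from [train_novel()] or [train_standard()].
#' @param test_ds Test `trial_dataset` (BOR not required).
#' @return Data frame: `subject_id`, `score`, `probability`, `group`.
#' @export
segment_test <- function(model, test_ds) {
  if (is.null(model$pca)) {
    stop_config("model carries no PCA basis; train it with train_novel()/train_standard()")
  }
  X <- test_design(model, test_ds)
  segment_patients(score_patients(model, X), model$bcut)
}

evaluate_method <- function(model, test_ds, aft_dist) {
  X <- test_design(model, test_ds)
  seg <- segment_patients(score_patients(model, X), model$bcut)
  d <- test_ds$data[match(seg$subject_id, test_ds$data$subject_id), , drop = FALSE]

  metrics <- NULL
  has_bor <- !is.na(d$bor)
  if (any(has_bor)) {
    metrics <- classification_metrics(seg$group[has_bor] == "responder",
                                      bor_to_binary(d$bor[has_bor]))
  }

  covars <- as.data.frame(X)
  covars$group <- as.integer(seg$group == "responder")

  km <- tryCatch(km_estimate(d$os_days, d$os_event, seg$group),
                 error = function(e) NULL)
  cox <- tryCatch(cox_fit(d$os_days, d$os_event, covars),
                  error = function(e) structure(conditionMessage(e), class = "eval_failure"))
  aft <- tryCatch(aft_fit(d$os_days, d$os_event, covars, distribution = aft_dist),
                  error = function(e) structure(conditionMessage(e), class = "eval_failure"))
  list(model = model, segmentation = seg, metrics = metrics, km = km,
       cox = cox, aft = aft,
       group_sizes = table(seg$group))
}

#' Run both methods end to end and compare them
#'
#' Trains the novel and standard scoring systems on the two training trials,
#' segments the test trial with each, and evaluates both segmentations:
#' classification metrics against BOR (when available in the test trial),
#' Kaplan-Meier curves with the log-rank test, and Cox / AFT regressions
#' adjusted for sex, age, weight, smoking, race and the PC scores, with an
#' AIC comparison between the two methods' fits.
#'
#' @inheritParams train_novel
#' @param test Test `trial_dataset`.
#' @param aft_dist AFT distribution, `"weibull"` (default) or `"lognormal"`.
#' @return Object of class `segmentation_report`: `methods` (per-method
#'   evaluation: model, segmentation, metrics, km, cox, aft), `comparison`
#'   (AIC comparisons for Cox and AFT), `config`.
#' @export
run_and_compare <- function(train_a, train_b, test, n_components = 2,
                            grid = cv_grid(), rule = "max_cutoff",
                            seed = 20240408L, aft_dist = "weibull",
                            pca_basis = "pooled", lpo_cap = 2000L) {
  novel <- train_novel(train_a, train_b, n_components = n_components,
                       grid = grid, rule = rule, seed = seed,
                       pca_basis = pca_basis, lpo_cap = lpo_cap)
  standard <- train_standard(train_a, train_b, n_components = n_components,
                             pca_basis = pca_basis)
  evals <- list(novel = evaluate_method(novel, test, aft_dist),
                standard = evaluate_method(standard, test, aft_dist))
  cmp <- list()
  for (kind in c("cox", "aft")) {
    fa <- evals$novel[[kind]]; fb <- evals$standard[[kind]]
    cmp[[kind]] <- if (inherits(fa, "surv_fit_summary") &&
                       inherits(fb, "surv_fit_summary")) {
      compare_models(fa, fb)
    } else NULL
  }
  structure(list(methods = evals, comparison = cmp,
                 config = list(n_components = n_components, rule = rule,
                               seed = seed, aft_dist = aft_dist,
                               pca_basis = pca_basis,
                               test_trial = test$trial_id)),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat("== Responder segmentation report ==\n")
  cat(sprintf("test trial: %s | seed %s | rule %s | %d PC(s)\n\n",
              x$config$test_trial, x$config$seed, x$config$rule,
              x$config$n_components))
  for (m in names(x$methods)) {
    e <- x$methods[[m]]
    cat(sprintf("-- %s method (bcut = %.4f) --\n", m, e$model$bcut))
    if (m == "novel") {
      prov <- e$model$provenance
      cat(sprintf("  chosen CV: %s (cutoff %.3f) / %s (cutoff %.3f)\n",
                  prov$chosen_technique[1], prov$training_cutoffs[1],
                  prov$chosen_technique[2], prov$training_cutoffs[2]))
    }
    cat(sprintf("  groups: %d non-responder / %d responder\n",
                e$group_sizes[["non-responder"]], e$group_sizes[["responder"]]))
    if (!is.null(e$metrics)) { cat("  "); print(e$metrics) }
    if (!is.null(e$km) && !is.null(e$km$logrank)) {
      cat(sprintf("  log-rank: chisq %.3f, p %.4g\n",
                  e$km$logrank$statistic, e$km$logrank$p_value))
    }
    for (kind in c("cox", "aft")) {
      f <- e[[kind]]
      if (inherits(f, "surv_fit_summary") && !is.null(f$group_effect)) {
        cat(sprintf("  %s group effect: %.3f [%.3f, %.3f], p %.4g; AIC %.3f\n",
                    toupper(kind), f$group_effect$estimate,
                    f$group_effect$ci_low, f$group_effect$ci_high,
                    f$group_effect$p_value, f$aic))
      } else if (inherits(f, "eval_failure")) {
        cat(sprintf("  %s fit failed: %s\n", toupper(kind), unclass(f)))
      }
    }
    cat("\n")
  }
  for (kind in names(x$comparison)) {
    cmp <- x$comparison[[kind]]
    if (!is.null(cmp)) {
      cat(sprintf("%s AIC: novel %.3f vs standard %.3f -> %s (dAIC %.3f)\n",
                  toupper(kind), cmp$aic[1], cmp$aic[2], cmp$winner,
                  cmp$delta_aic))
    }
  }
  invisible(x)
}

# plain-list rendering of a report for JSON serialization
report_to_list <- function(report) {
  meth <- lapply(report$methods, function(e) {
    list(
      method = e$model$method,
      bcut = e$model$bcut,
      coefficients = as.list(e$model$coefficients),
      provenance = e$model$provenance,
      group_sizes = as.list(e$group_sizes),
      metrics = if (!is.null(e$metrics)) unclass(e$metrics) else NULL,
      logrank = if (!is.null(e$km)) e$km$logrank else NULL,
      km_medians = if (!is.null(e$km)) e$km$medians else NULL,
      cox = if (inherits(e$cox, "surv_fit_summary")) unclass(e$cox) else
        list(error = unclass(e$cox)),
      aft = if (inherits(e$aft, "surv_fit_summary")) unclass(e$aft) else
        list(error = unclass(e$aft))
    )
  })
  list(schema = "respseg/report/1",
       package_version = as.character(utils::packageVersion("respseg")),
       config = report$config, methods = meth,
       comparison = report$comparison)
}

#' Write an evaluation report as JSON
#' @param report A `segmentation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "segmentation_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Export Kaplan-Meier curve data as CSV
#'
#' Columns: `group`, `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper` —
#' ready for external plotting.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(km, path) {
  stopifnot(inherits(km, "km_curve"))
  utils::write.csv(km$curves, path, row.names = FALSE)
  invisible(path)
}
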