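# Segmentation quality: classification metrics against the known responder
# label, and survival separation between the segmented groups via
# Kaplan-Meier / log-rank, Cox proportional hazards and accelerated failure
# time models, with AIC to compare methods. Survival machinery is delegated
# to the survival package (survfit/survdiff/coxph/survreg).

#' Binary classification metrics
#'
#' Accuracy, MSE (the mean squared 0/1 error, i.e. the misclassification
#' rate, so accuracy + MSE = 1), specificity, precision and recall. A metric
#' whose denominator is zero (e.g. precision with no predicted positives) is
#' reported as 0 and flagged in `undefined` rather than returned as NaN.
#'
#' @param pred Predicted binary labels (0/1 or logical).
#' @param y True binary labels.
#' @return Object of class `classification_metrics`: a list with `accuracy`,
#'   `mse`, `specificity`, `precision`, `recall`, and `undefined` (character
#'   vector of zero-denominator metrics).
#' @export
classification_metrics <- function(pred, y) {
  pred <- as.integer(pred); y <- as.integer(y)
  if (length(pred) != length(y)) stop_data("pred and y lengths differ")
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  structure(list(
    accuracy = mean(pred == y),
    mse = mean((pred - y)^2),
    specificity = ratio(tn, tn + fp, "specificity"),
    precision = ratio(tp, tp + fp, "precision"),
    recall = ratio(tp, tp + fn, "recall"),
    undefined = undefined
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | mse %.3f | specificity %.3f | precision %.3f | recall %.3f\n",
              x$accuracy, x$mse, x$specificity, x$precision, x$recall))
  if (length(x$undefined)) {
    cat("  (zero-denominator, reported as 0:", paste(x$undefined, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit survival curves per group with 95% confidence intervals on
#' the log(-log) scale, group medians, and (for exactly two groups) the
#' log-rank test.
#'
#' @param times Nonnegative event/censoring times.
#' @param events Binary event indicators (1 = event observed).
#' @param groups Group labels (any vector; coerced to factor).
#' @return Object of class `km_curve`: `curves` (data frame with `group`,
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`), `medians`
#'   (data frame with `group`, `median`, `ci_low`, `ci_high`; NA when the
#'   curve never reaches 0.5), and `logrank` (list with `statistic`,
#'   `p_value`, or NULL if not two groups).
#' @export
km_estimate <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) == 0) || nlevels(groups) < 1) {
    stop_data("every group must contain at least one subject")
  }
  df <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df,
                           conf.type = "log-log")
  strata <- if (is.null(fit$strata)) {
    rep(levels(groups)[1], length(fit$time))
  } else {
    rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper,
                       stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list(levels(groups)[1], names(tab)))
  medians <- data.frame(group = sub("^groups=", "", rownames(tab)),
                        median = tab[, "median"],
                        ci_low = tab[, "0.95LCL"], ci_high = tab[, "0.95UCL"],
                        row.names = NULL, stringsAsFactors = FALSE)
  lr <- if (nlevels(groups) == 2 && all(tapply(events, groups, sum) > 0)) {
    logrank_test(times, events, groups)
  } else NULL
  structure(list(curves = curves, medians = medians, logrank = lr),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>\n")
  print(x$medians)
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank chisq = %.3f, p = %.4g\n",
                x$logrank$statistic, x$logrank$p_value))
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times,events Survival times and event indicators.
#' @param groups Two-level grouping; each group needs at least one event.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) {
    stop_data("log-rank test requires exactly 2 non-empty groups, got ",
              nlevels(groups))
  }
  if (any(tapply(events, groups, sum) == 0)) {
    stop_data("each group needs at least one observed event")
  }
  df <- data.frame(times = times, events = events, groups = groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# Shared scaffolding for the two regression summaries.
check_covariates <- function(covariates) {
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_model("covariate matrix is rank deficient; aliased term(s): ",
               paste(aliased, collapse = ", "))
  }
  covariates
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling) of survival on the
#' supplied covariates, typically including the segmentation `group`.
#' Reports per-covariate hazard ratios with 95% Wald intervals and p-values,
#' and `AIC = -2 logPL + 2 * n_coefficients`.
#'
#' @param times,events Survival times and event indicators.
#' @param covariates Data frame (or matrix) of covariates; a column named
#'   `group` is summarised as the group effect.
#' @return Object of class `surv_fit_summary` with `model_kind = "cox"`,
#'   `table` (term, estimate = hazard ratio, ci_low, ci_high, p_value),
#'   `group_effect`, `aic`, `n`, `n_events`.
#' @export
cox_fit <- function(times, events, covariates) {
  if (sum(events) < 2) stop_data("need at least 2 observed events")
  covariates <- check_covariates(covariates)
  df <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    estimate = s$conf.int[, "exp(coef)"],
                    ci_low = s$conf.int[, 3], ci_high = s$conf.int[, 4],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  new_surv_summary("cox", tab, aic = stats::AIC(fit),
                   n = length(times), n_events = sum(events))
}

#' Accelerated failure-time fit
#'
#' Parametric AFT regression by maximum likelihood with right censoring
#' (Weibull by default, lognormal selectable). Covariate effects are
#' reported as time ratios `exp(coef)` — a ratio above 1 stretches survival
#' time — with 95% Wald intervals and p-values, plus the model AIC.
#'
#' @param times,events Survival times (> 0 for events) and event indicators.
#' @param covariates Data frame of covariates (see [cox_fit()]).
#' @param distribution `"weibull"` (default) or `"lognormal"`.
#' @return A `surv_fit_summary` with `model_kind = "aft"`; estimates are
#'   time ratios.
#' @export
aft_fit <- function(times, events, covariates,
                    distribution = c("weibull", "lognormal")) {
  distribution <- match.arg(distribution)
  if (sum(events) < 2) stop_data("need at least 2 observed events")
  covariates <- check_covariates(covariates)
  df <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::survreg(fml, data = df, dist = distribution)
  if (is.null(fit$coefficients) || anyNA(fit$coefficients)) {
    stop_model("AFT fit failed to converge")
  }
  s <- summary(fit)$table
  terms <- setdiff(rownames(s), c("(Intercept)", "Log(scale)"))
  est <- s[terms, "Value"]; se <- s[terms, "Std. Error"]
  tab <- data.frame(term = terms,
                    estimate = exp(est),
                    ci_low = exp(est - 1.959964 * se),
                    ci_high = exp(est + 1.959964 * se),
                    p_value = s[terms, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  new_surv_summary("aft", tab, aic = stats::AIC(fit),
                   n = length(times), n_events = sum(events),
                   distribution = distribution)
}

new_surv_summary <- function(kind, tab, aic, n, n_events, distribution = NULL) {
  ge <- tab[tab$term == "group", , drop = FALSE]
  structure(list(model_kind = kind, table = tab,
                 group_effect = if (nrow(ge)) ge else NULL,
                 aic = aic, n = n, n_events = n_events,
                 distribution = distribution),
            class = "surv_fit_summary")
}

#' @export
print.surv_fit_summary <- function(x, ...) {
  label <- if (x$model_kind == "cox") "hazard ratio" else "time ratio"
  cat(sprintf("<surv_fit_summary> %s (n = %d, events = %d, AIC = %.3f); estimates are %ss\n",
              toupper(x$model_kind), x$n, x$n_events, x$aic, label))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare two survival fits of the same kind by AIC
#'
#' @param fit_a,fit_b `surv_fit_summary` objects of the same `model_kind`
#'   fitted to the same data (e.g. novel- vs standard-method grouping).
#' @param labels Length-2 character labels for the two fits.
#' @return List with `labels`, `aic` (named vector), `delta_aic`
#'   (`fit_a - fit_b`), `winner` (label of the lower-AIC fit, or `"tie"`),
#'   and `group_effects` (both group rows side by side).
#' @export
compare_models <- function(fit_a, fit_b, labels = c("novel", "standard")) {
  if (!identical(fit_a$model_kind, fit_b$model_kind)) {
    stop_config("cannot compare fits of different kinds (",
                fit_a$model_kind, " vs ", fit_b$model_kind, ")")
  }
  aic <- stats::setNames(c(fit_a$aic, fit_b$aic), labels)
  winner <- if (fit_a$aic < fit_b$aic) labels[1]
            else if (fit_b$aic < fit_a$aic) labels[2]
            else "tie"
  ge <- rbind(
    if (!is.null(fit_a$group_effect)) cbind(method = labels[1], fit_a$group_effect),
    if (!is.null(fit_b$group_effect)) cbind(method = labels[2], fit_b$group_effect)
  )
  list(model_kind = fit_a$model_kind, labels = labels, aic = aic,
       delta_aic = fit_a$aic - fit_b$aic, winner = winner, group_effects = ge)
}
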