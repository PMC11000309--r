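# Cross-validation technique grid, out-of-fold logistic probabilities, and
# the F1-optimal probability cutoff search. This is the core of the method:
# each CV technique yields its own out-of-fold probabilities, hence its own
# best cutoff; the technique with the largest best cutoff is selected.

CV_FAMILIES <- c("LOOCV", "LpOCV", "HoldOut", "KFold", "RepeatedKFold",
                 "StratifiedKFold", "RepeatedStratifiedKFold")

#' Construct a single cross-validation technique specification
#'
#' @param family One of `LOOCV`, `LpOCV`, `HoldOut`, `KFold`,
#'   `RepeatedKFold`, `StratifiedKFold`, `RepeatedStratifiedKFold`.
#' @param k Number of folds (K-fold families only).
#' @param repeats Number of repetitions (repeated families only).
#' @param p Validation-set size for leave-pair-out (fixed at 2).
#' @param holdout_fraction Test fraction for the hold-out split (default 0.25).
#' @return Object of class `cv_spec`.
#' @export
cv_spec <- function(family, k = NULL, repeats = NULL, p = NULL,
                    holdout_fraction = NULL) {
  family <- match.arg(family, CV_FAMILIES)
  if (family %in% c("KFold", "RepeatedKFold", "StratifiedKFold",
                    "RepeatedStratifiedKFold")) {
    if (is.null(k) || k < 2) stop_config(family, " requires k >= 2")
  }
  if (family %in% c("RepeatedKFold", "RepeatedStratifiedKFold")) {
    if (is.null(repeats) || repeats < 1) stop_config(family, " requires repeats >= 1")
  }
  if (family == "LpOCV") p <- if (is.null(p)) 2L else as.integer(p)
  if (family == "HoldOut") {
    holdout_fraction <- if (is.null(holdout_fraction)) 0.25 else holdout_fraction
    if (holdout_fraction <= 0 || holdout_fraction >= 1) {
      stop_config("holdout_fraction must be in (0,1)")
    }
  }
  structure(list(family = family, k = k, repeats = repeats, p = p,
                 holdout_fraction = holdout_fraction),
            class = "cv_spec")
}

#' Human-readable label for a CV specification
#' @param spec A `cv_spec`.
#' @return Character scalar, e.g. `"RepeatedKFold(k=10, repeats=2)"`.
#' @export
cv_spec_label <- function(spec) {
  switch(spec$family,
    LOOCV = "LOOCV",
    LpOCV = sprintf("LpOCV(p=%d)", spec$p),
    HoldOut = sprintf("HoldOut(test=%.2f)", spec$holdout_fraction),
    KFold = sprintf("KFold(k=%d)", spec$k),
    RepeatedKFold = sprintf("RepeatedKFold(k=%d, repeats=%d)", spec$k, spec$repeats),
    StratifiedKFold = sprintf("StratifiedKFold(k=%d)", spec$k),
    RepeatedStratifiedKFold =
      sprintf("RepeatedStratifiedKFold(k=%d, repeats=%d)", spec$k, spec$repeats)
  )
}

#' @export
print.cv_spec <- function(x, ...) {
  cat("<cv_spec>", cv_spec_label(x), "\n")
  invisible(x)
}

#' Enumerate the cross-validation technique grid
#'
#' Defaults span the seven technique families at their standard grids:
#' LOOCV; leave-pair-out (p = 2); a single 75/25 hold-out split; K-fold with
#' K = 3..10; repeated K-fold with K = 3..10 and 2..4 repeats; stratified
#' K-fold with K = 3..5; repeated stratified K-fold with K = 3..5 and 2..4
#' repeats — 47 specifications in total. Ordering is deterministic: LOOCV,
#' LpOCV, HoldOut, then each K-fold family with (k, repeats) ascending.
#'
#' @param kfold_k Integer vector of K values for plain K-fold.
#' @param repeated_k,repeated_repeats Grids for repeated K-fold.
#' @param stratified_k Grid for stratified K-fold.
#' @param repeated_stratified_k,repeated_stratified_repeats Grids for
#'   repeated stratified K-fold.
#' @param families Subset of the seven family names to include.
#' @param holdout_fraction Hold-out test fraction (default 0.25).
#' @param p Leave-pair-out validation size (default 2).
#' @return List of `cv_spec` objects.
#' @export
cv_grid <- function(kfold_k = 3:10,
                    repeated_k = 3:10, repeated_repeats = 2:4,
                    stratified_k = 3:5,
                    repeated_stratified_k = 3:5,
                    repeated_stratified_repeats = 2:4,
                    families = CV_FAMILIES,
                    holdout_fraction = 0.25, p = 2) {
  if (!length(families)) stop_config("empty CV grid")
  families <- match.arg(families, CV_FAMILIES, several.ok = TRUE)
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  if ("LOOCV" %in% families) add(cv_spec("LOOCV"))
  if ("LpOCV" %in% families) add(cv_spec("LpOCV", p = p))
  if ("HoldOut" %in% families) add(cv_spec("HoldOut", holdout_fraction = holdout_fraction))
  if ("KFold" %in% families) {
    for (k in sort(kfold_k)) add(cv_spec("KFold", k = k))
  }
  if ("RepeatedKFold" %in% families) {
    for (k in sort(repeated_k)) for (r in sort(repeated_repeats)) {
      add(cv_spec("RepeatedKFold", k = k, repeats = r))
    }
  }
  if ("StratifiedKFold" %in% families) {
    for (k in sort(stratified_k)) add(cv_spec("StratifiedKFold", k = k))
  }
  if ("RepeatedStratifiedKFold" %in% families) {
    for (k in sort(repeated_stratified_k)) for (r in sort(repeated_stratified_repeats)) {
      add(cv_spec("RepeatedStratifiedKFold", k = k, repeats = r))
    }
  }
  if (!length(specs)) stop_config("empty CV grid")
  specs
}

# Assign n indices to k near-equal folds after a seeded shuffle.
kfold_assign <- function(idx, k, seed) {
  idx <- with_seed(seed, sample(idx))
  fold <- rep(seq_len(k), length.out = length(idx))
  split(idx, fold)
}

#' Generate train/validation splits for a CV specification
#'
#' @param spec A `cv_spec`.
#' @param y Binary label vector (used for sizes and stratification).
#' @param seed Integer seed; repeated families derive one seed per repeat.
#' @param lpo_cap Maximum number of leave-pair-out pairs; when `choose(n, 2)`
#'   exceeds the cap, that many distinct pairs are drawn at random (seeded).
#' @return List of splits, each `list(train = <idx>, test = <idx>)`.
#' @export
generate_splits <- function(spec, y, seed = 1L, lpo_cap = 2000L) {
  n <- length(y)
  if (n < 3) stop_data("need at least 3 observations")
  one_pass <- function(k, stratified, pass_seed) {
    if (k > n) stop_data("k = ", k, " exceeds n = ", n)
    if (stratified) {
      classes <- split(seq_len(n), y)
      short <- names(classes)[vapply(classes, length, 1L) < k]
      if (length(short)) {
        stop_data("stratification impossible: class ", paste(short, collapse = ","),
                  " has fewer than k = ", k, " members")
      }
      folds <- vector("list", k)
      for (ci in seq_along(classes)) {
        assign_ci <- kfold_assign(classes[[ci]], k, derive_seed(pass_seed, ci))
        for (f in seq_len(k)) {
          folds[[f]] <- c(folds[[f]], assign_ci[[f]])
        }
      }
      folds <- lapply(folds, sort)
    } else {
      folds <- kfold_assign(seq_len(n), k, pass_seed)
    }
    lapply(folds, function(te) list(train = setdiff(seq_len(n), te), test = te))
  }

  switch(spec$family,
    LOOCV = lapply(seq_len(n), function(i) {
      list(train = setdiff(seq_len(n), i), test = i)
    }),
    LpOCV = {
      n_pairs <- choose(n, 2)
      if (n_pairs <= lpo_cap) {
        pairs <- utils::combn(n, 2)
      } else {
        # exhaustive enumeration is infeasible at trial scale; draw a seeded
        # subsample of distinct pairs
        pairs <- with_seed(seed, {
          seen <- new.env(hash = TRUE)
          out <- matrix(0L, 2, lpo_cap)
          got <- 0L
          while (got < lpo_cap) {
            cand <- sort(sample.int(n, 2))
            key <- paste(cand, collapse = "-")
            if (is.null(seen[[key]])) {
              seen[[key]] <- TRUE
              got <- got + 1L
              out[, got] <- cand
            }
          }
          out
        })
      }
      lapply(seq_len(ncol(pairs)), function(j) {
        te <- pairs[, j]
        list(train = setdiff(seq_len(n), te), test = te)
      })
    },
    HoldOut = {
      n_test <- max(1L, round(n * spec$holdout_fraction))
      te <- with_seed(seed, sort(sample.int(n, n_test)))
      list(list(train = setdiff(seq_len(n), te), test = te))
    },
    KFold = one_pass(spec$k, FALSE, seed),
    StratifiedKFold = one_pass(spec$k, TRUE, seed),
    RepeatedKFold = do.call(c, lapply(seq_len(spec$repeats), function(r) {
      one_pass(spec$k, FALSE, derive_seed(seed, 1000L + r))
    })),
    RepeatedStratifiedKFold = do.call(c, lapply(seq_len(spec$repeats), function(r) {
      one_pass(spec$k, TRUE, derive_seed(seed, 1000L + r))
    }))
  )
}

#' Fit an (unpenalized) logistic regression
#'
#' Maximum-likelihood logistic regression with intercept, convergence
#' tolerance 1e-8. Under complete or quasi-complete separation the MLE
#' diverges; in that case the fit falls back to a tiny ridge penalty (1e-6
#' on slope coefficients only) so coefficients stay finite, with a warning.
#'
#' @param X Numeric covariate matrix (no intercept column).
#' @param y Binary 0/1 response.
#' @return Object of class `logit_fit` with element `coefficients`
#'   (named vector: `(intercept)` then the columns of `X`) and `separation`
#'   (logical).
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop_model("response has a single class")
  if (anyNA(X) || anyNA(y)) stop_data("missing values in design matrix or response")
  Xi <- cbind("(intercept)" = 1, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- fit$coefficients
  big_slope <- length(coefs) > 1 && max(abs(coefs[-1])) > 50
  if (separated || !fit$converged || anyNA(coefs) || big_slope) {
    warning("separation or non-convergence detected; using ridge (1e-6) fallback",
            call. = FALSE)
    coefs <- ridge_logistic(Xi, y, lambda = 1e-6)
    separated <- TRUE
  }
  structure(list(coefficients = coefs, separation = separated),
            class = "logit_fit")
}

# Newton-Raphson for logistic log-likelihood with an L2 penalty on slopes
# (the intercept is unpenalized). Used only as the separation fallback.
ridge_logistic <- function(Xi, y, lambda = 1e-6, maxit = 200, tol = 1e-10) {
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xi, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Xi * w, Xi) + pen + diag(1e-12, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(Xi))
}

#' Predicted probabilities from a logistic fit
#' @param fit A `logit_fit`.
#' @param X Covariate matrix with the same columns the model was fit on.
#' @return Vector of probabilities.
#' @export
predict_logistic <- function(fit, X) {
  stopifnot(inherits(fit, "logit_fit"))
  drop(stats::plogis(cbind(1, as.matrix(X)) %*% fit$coefficients))
}

#' Out-of-fold predicted probabilities
#'
#' For each split, fits the logistic model on the training indices and
#' predicts probabilities on the validation indices. A patient appearing in
#' several validation sets (repeated CV, leave-pair-out) gets the arithmetic
#' mean of their predictions. Splits whose training part is single-class are
#' skipped with a warning; if every split is skipped, an error is raised.
#'
#' @param X Design matrix.
#' @param y Binary response.
#' @param splits List of splits from [generate_splits()].
#' @return List with `prob` (length-n vector, NA where never validated) and
#'   `coverage` (number of validation appearances per patient).
#' @export
out_of_fold_probabilities <- function(X, y, splits) {
  X <- as.matrix(X)
  n <- length(y)
  prob_sum <- numeric(n)
  coverage <- integer(n)
  n_skipped <- 0L
  for (sp in splits) {
    tr <- sp$train; te <- sp$test
    if (length(unique(y[tr])) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- suppressWarnings(fit_logistic(X[tr, , drop = FALSE], y[tr]))
    p <- predict_logistic(fit, X[te, , drop = FALSE])
    prob_sum[te] <- prob_sum[te] + p
    coverage[te] <- coverage[te] + 1L
  }
  if (n_skipped == length(splits)) {
    stop_model("all ", length(splits), " splits had single-class training folds")
  }
  if (n_skipped > 0) {
    warning(n_skipped, " split(s) skipped (single-class training fold)",
            call. = FALSE)
  }
  prob <- ifelse(coverage > 0, prob_sum / pmax(coverage, 1L), NA_real_)
  list(prob = prob, coverage = coverage)
}

# F1 at each cutoff in `cutoffs`, with the strict ">" prediction rule.
# Uses sorted-count arithmetic: for cutoff c, predicted positives are the
# probs > c, so TP = n1 - #(positive probs <= c), PP = n - #(probs <= c),
# and F1 = 2*TP / (PP + n1). F1 is 0 when no positives are predicted.
f1_curve <- function(probs, y, cutoffs) {
  sp_all <- sort(probs)
  sp_pos <- sort(probs[y == 1])
  n <- length(probs)
  n1 <- length(sp_pos)
  tp <- n1 - findInterval(cutoffs, sp_pos)
  pp <- n - findInterval(cutoffs, sp_all)
  f1 <- ifelse(pp + n1 > 0, 2 * tp / (pp + n1), 0)
  f1[pp == 0] <- 0
  f1
}

#' F1 score at a probability cutoff
#'
#' Predicts responder iff `prob > cutoff` (strict inequality) and returns
#' `F1 = 2 * precision * recall / (precision + recall)`, defined as 0 when
#' no positives are predicted.
#'
#' @param probs Probabilities in `[0, 1]`.
#' @param y Binary 0/1 labels.
#' @param cutoff Cutoff in `[0, 1]`.
#' @return F1 score.
#' @export
f1_at_cutoff <- function(probs, y, cutoff) {
  if (!is.finite(cutoff) || cutoff < 0 || cutoff > 1) {
    stop_config("cutoff must be in [0, 1], got ", cutoff)
  }
  if (any(probs < 0 | probs > 1)) stop_data("probabilities outside [0, 1]")
  f1_curve(probs, y, cutoff)
}

#' F1-optimal probability cutoff
#'
#' Evaluates F1 at every candidate cutoff — the sorted unique probability
#' values plus 0 — and returns the maximiser. Ties are broken toward the
#' smallest maximising cutoff (favouring sensitivity).
#'
#' @param probs Out-of-fold probabilities.
#' @param y Binary labels, both classes present.
#' @return List with `cutoff`, `f1`, and `curve` (data frame of candidate
#'   cutoffs and their F1).
#' @export
best_cutoff <- function(probs, y) {
  keep <- !is.na(probs)
  probs <- probs[keep]; y <- y[keep]
  if (length(unique(y)) < 2) stop_model("both classes required to search a cutoff")
  candidates <- sort(unique(c(0, probs)))
  f1 <- f1_curve(probs, y, candidates)
  i <- which.max(f1)  # candidates ascending, so first max = smallest cutoff
  list(cutoff = candidates[i], f1 = f1[i],
       curve = data.frame(cutoff = candidates, f1 = f1))
}

#' Run the cutoff search under every CV technique and select one
#'
#' For each technique in the grid: generate splits (with a seed derived
#' deterministically from the master seed and the technique's position),
#' compute out-of-fold probabilities, and find the F1-optimal cutoff on the
#' pooled out-of-fold predictions. Under the default `max_cutoff` rule the
#' technique with the largest best cutoff is selected (ties: larger F1, then
#' grid order); under `max_f1` the criteria swap.
#'
#' @param X Design matrix.
#' @param y Binary response.
#' @param grid List of `cv_spec` (default [cv_grid()]).
#' @param seed Master integer seed.
#' @param rule `"max_cutoff"` (default) or `"max_f1"`.
#' @param lpo_cap Leave-pair-out pair cap (see [generate_splits()]).
#' @return Object of class `cv_selection`: `per_technique` (list of search
#'   results, each with `spec`, `label`, `cutoff`, `f1`, `oof`, `curve`),
#'   `chosen` (the selected entry), `rule`.
#' @export
select_cv_technique <- function(X, y, grid = cv_grid(), seed = 1L,
                                rule = c("max_cutoff", "max_f1"),
                                lpo_cap = 2000L) {
  rule <- match.arg(rule)
  if (!length(grid)) stop_config("empty CV grid")
  results <- vector("list", length(grid))
  failures <- character(0)
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    res <- tryCatch({
      splits <- generate_splits(spec, y, seed = derive_seed(seed, i),
                                lpo_cap = lpo_cap)
      oof <- suppressWarnings(out_of_fold_probabilities(X, y, splits))
      covered <- oof$coverage > 0
      bc <- best_cutoff(oof$prob[covered], y[covered])
      list(spec = spec, label = cv_spec_label(spec), cutoff = bc$cutoff,
           f1 = bc$f1, oof = oof, curve = bc$curve)
    }, error = function(e) {
      failures <<- c(failures, paste0(cv_spec_label(spec), ": ",
                                      conditionMessage(e)))
      NULL
    })
    results[[i]] <- res
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    stop_model("every CV technique failed:\n  ", paste(failures, collapse = "\n  "))
  }
  if (length(failures)) {
    warning(length(failures), " technique(s) skipped: ",
            paste(failures, collapse = "; "), call. = FALSE)
  }
  results <- results[ok]
  cuts <- vapply(results, `[[`, numeric(1), "cutoff")
  f1s <- vapply(results, `[[`, numeric(1), "f1")
  ord <- if (rule == "max_cutoff") {
    order(-cuts, -f1s, seq_along(results))
  } else {
    order(-f1s, -cuts, seq_along(results))
  }
  structure(list(per_technique = results, chosen = results[[ord[1]]],
                 rule = rule),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("<cv_selection> %d technique(s), rule = %s\n",
              length(x$per_technique), x$rule))
  cat(sprintf("  chosen: %s  (best cutoff %.4f, F1 %.4f)\n",
              x$chosen$label, x$chosen$cutoff, x$chosen$f1))
  invisible(x)
}
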