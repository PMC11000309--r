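# Tumor-trajectory features: percent change from baseline at the four early
# visits, principal-component scores of those trajectories, and the fixed
# design-matrix layout shared by training and test data.

#' Percent tumor-size change from baseline
#'
#' Element i is `100 * (visit_sizes[i] - baseline) / baseline`, the percent
#' change of the sum of longest diameters at visit i relative to baseline.
#'
#' @param baseline Baseline tumor size (mm), > 0.
#' @param visit_sizes Numeric vector of per-visit tumor sizes (mm).
#' @return Numeric vector of percent changes, same length as `visit_sizes`.
#' @export
percent_change_trajectory <- function(baseline, visit_sizes) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop_data("baseline tumor size must be positive, got ", baseline)
  }
  100 * (visit_sizes - baseline) / baseline
}

# patients x 4 matrix of percent changes, rownames = subject_id.
# Rows are restricted to patients with a complete baseline + 4 visits.
trajectory_matrix <- function(ds) {
  mf <- model_frame(ds, require_bor = FALSE)
  d <- mf$data
  m <- t(vapply(seq_len(nrow(d)), function(i) {
    percent_change_trajectory(d$base_size[i],
                              as.numeric(d[i, VISIT_COLS]))
  }, numeric(4)))
  if (nrow(d) == 0) m <- matrix(numeric(0), 0, 4)
  dimnames(m) <- list(d$subject_id, paste0("v", 1:4))
  m
}

#' Fit a PCA of percent-change trajectories
#'
#' Centers the patients-by-4 matrix of percent changes by its column means
#' and extracts the leading eigenvectors of the sample covariance. A
#' deterministic sign convention is applied: within each loading vector the
#' largest-magnitude element is made positive, so results are reproducible
#' across linear-algebra backends.
#'
#' @param traj Numeric matrix (patients x 4) of percent changes.
#' @param n_components Number of components to retain (1-4, default 2).
#' @return Object of class `traj_pca` with elements `center` (length-4
#'   column means), `loadings` (4 x n_components orthonormal matrix),
#'   `explained_variance` (per-component variances), `n_components`.
#' @export
fit_pca <- function(traj, n_components = 2) {
  traj <- as.matrix(traj)
  if (ncol(traj) != 4) stop_data("trajectory matrix must have 4 columns")
  if (n_components < 1 || n_components > 4) {
    stop_config("n_components must be between 1 and 4")
  }
  if (nrow(traj) < n_components + 1) {
    stop_data("need at least n_components + 1 patients to fit the PCA")
  }
  pc <- stats::prcomp(traj, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-10)
  if (rank < n_components) {
    stop_data("trajectory covariance has rank ", rank,
              " < n_components = ", n_components,
              " (constant or collinear visit columns)")
  }
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|.| element of each component positive
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  colnames(loadings) <- paste0("pc_", seq_len(n_components))
  structure(list(center = pc$center,
                 loadings = loadings,
                 explained_variance = ev[seq_len(n_components)],
                 n_components = n_components),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  cat(sprintf("<traj_pca> %d component(s); variance explained: %s\n",
              x$n_components,
              paste(signif(x$explained_variance, 4), collapse = ", ")))
  invisible(x)
}

#' Project trajectories onto a fitted PCA basis
#'
#' Computes `(traj - center) %*% loadings` with the training center and
#' loadings held fixed; projecting test data never alters the fitted model.
#'
#' @param model A `traj_pca` from [fit_pca()].
#' @param traj Numeric matrix (patients x 4) of percent changes.
#' @return Scores matrix (patients x n_components).
#' @export
project_pca <- function(model, traj) {
  stopifnot(inherits(model, "traj_pca"))
  traj <- as.matrix(traj)
  if (ncol(traj) != length(model$center)) {
    stop_data("trajectory matrix has ", ncol(traj), " columns; expected ",
              length(model$center))
  }
  scores <- sweep(traj, 2, model$center) %*% model$loadings
  rownames(scores) <- rownames(traj)
  scores
}

# Fixed covariate encodings shared by every model in the package:
# sex female=0/male=1; age ordinal 0/1/2; weight <=75=0/>75=1;
# smoking never=0/former=1/current=2; race caucasian=0/non-caucasian=1.
encode_covariates <- function(d) {
  enc <- cbind(
    sex     = as.integer(d$sex) - 1L,
    age     = as.integer(d$age) - 1L,
    weight  = as.integer(d$weight) - 1L,
    smoking = as.integer(d$smoking) - 1L,
    race    = as.integer(d$race) - 1L
  )
  bad <- which(apply(enc, 1, anyNA))
  if (length(bad)) {
    stop_data("unencodable categorical value(s) for patient(s): ",
              paste(d$subject_id[bad], collapse = ", "))
  }
  rownames(enc) <- d$subject_id
  enc
}

#' Build the model design matrix
#'
#' Assembles the fixed-order covariate matrix used by every logistic fit:
#' `sex, age, weight, smoking, race, pc_1..pc_k`. Encodings: sex female=0 /
#' male=1; age ordinal 0/1/2 for the bins 18-<65 / 65-75 / >75; weight
#' <=75 kg = 0 / >75 kg = 1; smoking ordinal never=0 < former=1 < current=2;
#' race caucasian=0 / non-caucasian=1. The intercept is handled by the
#' fitter. Column order is identical for training and test builds.
#'
#' @param ds A `trial_dataset`. Patients lacking a complete trajectory are
#'   excluded (with a message).
#' @param pca A fitted `traj_pca` used to compute the PC score columns.
#' @return Numeric matrix with rownames = subject IDs.
#' @export
build_design_matrix <- function(ds, pca) {
  traj <- trajectory_matrix(ds)
  mf <- ds$data[match(rownames(traj), ds$data$subject_id), , drop = FALSE]
  enc <- if (nrow(mf)) encode_covariates(mf) else
    matrix(numeric(0), 0, 5,
           dimnames = list(NULL, c("sex", "age", "weight", "smoking", "race")))
  scores <- project_pca(pca, traj)
  X <- cbind(enc, scores)
  storage.mode(X) <- "double"
  X
}
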