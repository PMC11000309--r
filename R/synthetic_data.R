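# Synthetic small-cell-lung-cancer-like trials: categorical baseline
# covariates, correlated four-visit percent tumor-size changes driven by a
# latent per-patient shrinkage rate, a logistic best-overall-response model
# on covariates + trajectory, and Weibull overall survival whose hazard
# depends on responder status plus covariates, with independent uniform
# administrative right censoring. Ground truth is returned alongside every
# simulated trial so recovery tests can compare against it.

#' Simulation configuration
#'
#' Defaults emulate the covariate mix of late-stage lung-cancer trial
#' populations (predominantly male, mostly current/former smokers, mostly
#' caucasian) and a moderate responder prevalence, with tumor shrinkage
#' informative for response and responders surviving longer (hazard ratio
#' 0.668 by default).
#'
#' @param n_patients Patients per trial (>= 20).
#' @param prev_male,prev_noncaucasian,prev_weight_gt75 Covariate prevalences.
#' @param prob_smoking Length-3 probabilities for never/former/current.
#' @param prob_age Length-3 probabilities for the 18-<65 / 65-75 / >75 bins.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline tumor size (mm).
#' @param shrink_mean,shrink_sd Latent per-visit percent-change rate:
#'   patient i's expected percent change at visit j is `rate_i * j`.
#' @param traj_noise_sd Gaussian noise (percent points) added per visit.
#' @param bor_coefs Named true log-odds coefficients on the encoded
#'   covariates `sex, age, weight, smoking, race` plus `traj` (the mean
#'   percent change across the four visits; negative means shrinkage raises
#'   the response probability).
#' @param responder_prev Target marginal responder prevalence; the intercept
#'   is calibrated by root finding to hit it on the drawn covariates.
#' @param surv_shape,surv_scale Baseline Weibull shape and scale (days).
#' @param loghr_responder True log hazard ratio for responder status
#'   (default `log(0.668)`).
#' @param loghr_covariates Named true log-HRs for the encoded covariates.
#' @param censor_frac Target administrative censoring fraction in `[0, 1)`;
#'   censoring times are Uniform(0, tau) with tau calibrated to the target.
#' @param null_model If TRUE, all BOR and survival coefficients (including
#'   the responder effect) are zeroed: labels and survival are independent
#'   of covariates and trajectory. Used for type-I-error studies.
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 600,
                       prev_male = 0.78,
                       prev_noncaucasian = 0.05,
                       prev_weight_gt75 = 0.60,
                       prob_smoking = c(never = 0.15, former = 0.40, current = 0.45),
                       prob_age = c(0.55, 0.36, 0.09),
                       baseline_meanlog = log(60), baseline_sdlog = 0.4,
                       shrink_mean = -4, shrink_sd = 6,
                       traj_noise_sd = 5,
                       bor_coefs = c(sex = -0.3, age = 0.15, weight = 0.1,
                                     smoking = -0.2, race = 0.2, traj = -0.10),
                       responder_prev = 0.3,
                       surv_shape = 1.2, surv_scale = 420,
                       loghr_responder = log(0.668),
                       loghr_covariates = c(sex = 0.10, age = 0.15,
                                            weight = -0.05, smoking = 0.10,
                                            race = 0.10),
                       censor_frac = 0.25,
                       null_model = FALSE,
                       seed = 20240408L) {
  cfg <- as.list(environment())
  if (n_patients < 20) stop_config("n_patients must be >= 20")
  if (any(c(prev_male, prev_noncaucasian, prev_weight_gt75) < 0 |
          c(prev_male, prev_noncaucasian, prev_weight_gt75) > 1)) {
    stop_config("prevalences must lie in [0, 1]")
  }
  if (censor_frac < 0 || censor_frac >= 1) stop_config("censor_frac must be in [0, 1)")
  if (responder_prev <= 0 || responder_prev >= 1) {
    stop_config("responder_prev must be in (0, 1)")
  }
  if (null_model) {
    cfg$bor_coefs[] <- 0
    cfg$loghr_responder <- 0
    cfg$loghr_covariates[] <- 0
  }
  structure(cfg, class = "sim_config")
}

# uniform administrative censoring horizon tau calibrated so the expected
# censored fraction E[1{C < T}] = E[min(T, tau)] / tau hits the target.
calibrate_censor_tau <- function(times, target) {
  f <- function(tau) mean(pmin(times, tau)) / tau - target
  upper <- max(times) * 2
  if (f(upper) > 0) return(upper)  # heavy-tail guard: best achievable
  stats::uniroot(f, lower = min(times) / 1e3, upper = upper, tol = 1e-8)$root
}

#' Simulate one trial
#'
#' @param cfg A [sim_config()].
#' @param trial_id Trial identifier for the generated dataset.
#' @param role `"training"` or `"test"`.
#' @param seed Seed override (defaults to `cfg$seed`).
#' @return List with `dataset` (a [trial_dataset()]) and `truth` (list:
#'   calibrated intercept `eta`, `bor_coefs`, per-patient response
#'   probabilities and responder labels, `loghr_responder`).
#' @export
simulate_trial <- function(cfg, trial_id = "SIM", role = "training",
                           seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- cfg$n_patients
    sex <- factor(ifelse(stats::runif(n) < cfg$prev_male, "male", "female"),
                  levels = SEX_LEVELS)
    age <- factor(sample(AGE_LEVELS, n, TRUE, prob = cfg$prob_age), levels = AGE_LEVELS)
    weight <- factor(ifelse(stats::runif(n) < cfg$prev_weight_gt75, ">75", "<=75"),
                     levels = WEIGHT_LEVELS)
    smoking <- factor(sample(SMOKING_LEVELS, n, TRUE, prob = cfg$prob_smoking),
                      levels = SMOKING_LEVELS)
    race <- factor(ifelse(stats::runif(n) < cfg$prev_noncaucasian,
                          "non-caucasian", "caucasian"), levels = RACE_LEVELS)
    base_size <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)

    # latent shrinkage rate -> correlated percent changes across visits
    rate <- stats::rnorm(n, cfg$shrink_mean, cfg$shrink_sd)
    pct <- sapply(1:4, function(j) rate * j + stats::rnorm(n, 0, cfg$traj_noise_sd))
    pct <- pmax(pct, -95)  # tumors cannot shrink below ~zero size
    visit_sizes <- base_size * (1 + pct / 100)

    enc <- cbind(sex = as.integer(sex) - 1, age = as.integer(age) - 1,
                 weight = as.integer(weight) - 1,
                 smoking = as.integer(smoking) - 1,
                 race = as.integer(race) - 1)
    traj_summary <- rowMeans(pct)
    lp <- drop(enc %*% cfg$bor_coefs[colnames(enc)]) +
      cfg$bor_coefs[["traj"]] * traj_summary
    eta <- stats::uniroot(function(e) mean(stats::plogis(lp + e)) - cfg$responder_prev,
                          lower = -50, upper = 50, tol = 1e-10)$root
    p_resp <- stats::plogis(lp + eta)
    responder <- stats::rbinom(n, 1, p_resp)
    bor <- ifelse(responder == 1,
                  ifelse(stats::runif(n) < 0.2, "CR", "PR"),
                  ifelse(stats::runif(n) < 0.5, "SD", "PD"))

    # Weibull proportional-hazards survival: responders live longer when
    # loghr_responder < 0
    lp_surv <- cfg$loghr_responder * responder +
      drop(enc %*% cfg$loghr_covariates[colnames(enc)])
    u <- stats::runif(n)
    T <- cfg$surv_scale * (-log(u) / exp(lp_surv))^(1 / cfg$surv_shape)
    if (cfg$censor_frac > 0) {
      tau <- calibrate_censor_tau(T, cfg$censor_frac)
      C <- stats::runif(n, 0, tau)
      os_days <- pmin(T, C)
      os_event <- as.numeric(T <= C)
    } else {
      os_days <- T
      os_event <- rep(1, n)
    }

    d <- data.frame(subject_id = sprintf("%s-%04d", trial_id, seq_len(n)),
                    sex = sex, age = age, weight = weight, smoking = smoking,
                    race = race, base_size = base_size,
                    size_v1 = visit_sizes[, 1], size_v2 = visit_sizes[, 2],
                    size_v3 = visit_sizes[, 3], size_v4 = visit_sizes[, 4],
                    bor = bor, os_days = os_days, os_event = os_event,
                    stringsAsFactors = FALSE)
    list(dataset = trial_dataset(d, trial_id = trial_id, role = role),
         truth = list(eta = eta, bor_coefs = cfg$bor_coefs,
                      response_prob = p_resp, responder = responder,
                      loghr_responder = cfg$loghr_responder))
  })
}

#' Simulate two training trials and one test trial
#'
#' All three trials share the same generating process and ground-truth
#' coefficients; per-trial seeds are derived deterministically from the
#' master seed, and subject IDs are disjoint across trials.
#'
#' @param cfg A [sim_config()] (its `n_patients` is overridden per trial).
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param sizes Named integer vector `c(train_a, train_b, test)`.
#' @return List with `train_a`, `train_b`, `test` (each a `trial_dataset`)
#'   and `truth` (shared generating coefficients plus per-trial truths).
#' @export
make_trial_triplet <- function(cfg = sim_config(), seed = cfg$seed,
                               sizes = c(train_a = 600, train_b = 140, test = 600)) {
  stopifnot(inherits(cfg, "sim_config"))
  roles <- c(train_a = "training", train_b = "training", test = "test")
  out <- list()
  truths <- list()
  for (i in seq_along(roles)) {
    nm <- names(roles)[i]
    cfg_i <- cfg
    cfg_i$n_patients <- as.integer(sizes[[nm]])
    sim <- simulate_trial(cfg_i, trial_id = toupper(nm), role = roles[[nm]],
                          seed = derive_seed(seed, i))
    out[[nm]] <- sim$dataset
    truths[[nm]] <- sim$truth
  }
  out$truth <- list(bor_coefs = cfg$bor_coefs,
                    loghr_responder = cfg$loghr_responder,
                    per_trial = truths)
  out
}
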