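# Shared fixtures: a tiny hand-written trial and small simulated designs.

tiny_trial_df <- function() {
  data.frame(
    subject_id = c("P1", "P2", "P3"),
    sex = c("male", "female", "male"),
    age = c(55, 70, 80),              # numeric ages, binned on entry
    weight = c(80, 70, 76),
    smoking = c("current", "never", "former"),
    race = c("caucasian", "caucasian", "non-caucasian"),
    base_size = c(50, 40, 60),
    size_v1 = c(50, 44, 66),
    size_v2 = c(45, 48, 72),
    size_v3 = c(40, 40, 60),
    size_v4 = c(35, 20, 30),
    bor = c("PR", "CR", "PD"),
    os_days = c(300, 720, 150),
    os_event = c(1, 0, 1),
    stringsAsFactors = FALSE
  )
}

tiny_trial <- function(role = "training") {
  trial_dataset(tiny_trial_df(), trial_id = "TINY", role = role)
}

# simulated logistic design with known coefficients
sim_logit_design <- function(n, beta, intercept = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  p <- plogis(intercept + drop(X %*% beta))
  list(X = X, y = rbinom(n, 1, p), p = p)
}

# confusion-matrix F1 computed the slow, direct way (independent oracle)
f1_direct <- function(probs, y, cutoff) {
  pred <- as.integer(probs > cutoff)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  if (tp + fp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

small_cfg <- function(...) {
  sim_config(n_patients = 120, seed = 42L, ...)
}

# deterministic per-replicate seeds for simulation studies
derive_seed_for_test <- function(base, r) {
  as.integer((base + 7919 * r) %% 2147483647)
}
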