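# Classed conditions so callers (and the CLI) can map failures to exit codes:
# config_error -> 2, data_error -> 3, model_error -> 4.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("respseg_config_error", "respseg_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("respseg_data_error", "respseg_error")))
}

stop_model <- function(...) {
  stop(errorCondition(paste0(...), class = c("respseg_model_error", "respseg_error")))
}

#' @keywords internal
#' Derive a per-component seed from a master seed.
#'
#' Keeps every derived seed strictly below 2^31 so it is a valid R integer.
#' @noRd
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}
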