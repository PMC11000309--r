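# Patient/trial data model: one row per patient, with baseline covariates,
# a four-visit tumor-size trajectory, best overall response (BOR) and
# right-censored overall survival.

SEX_LEVELS     <- c("female", "male")
AGE_LEVELS     <- c("18-<65", "65-75", ">75")
WEIGHT_LEVELS  <- c("<=75", ">75")
SMOKING_LEVELS <- c("never", "former", "current")
RACE_LEVELS    <- c("caucasian", "non-caucasian")
BOR_LEVELS     <- c("CR", "PR", "SD", "PD")

VISIT_COLS <- paste0("size_v", 1:4)

#' Canonical trial table columns
#'
#' Column names of the delimited (CSV) trial format read and written by the
#' package: `subject_id`, `sex`, `age`, `weight`, `smoking`, `race`,
#' `base_size`, `size_v1`..`size_v4`, `bor`, `os_days`, `os_event`.
#'
#' `age` may be numeric years (binned to `18-<65` / `65-75` / `>75`) or an
#' already-binned label; `weight` numeric kg (binned at 75) or a bin label.
#'
#' @return Character vector of canonical column names.
#' @export
trial_columns <- function() {
  c("subject_id", "sex", "age", "weight", "smoking", "race",
    "base_size", VISIT_COLS, "bor", "os_days", "os_event")
}

bin_age <- function(age_years) {
  cut(age_years, breaks = c(18, 65, 75, Inf), labels = AGE_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

bin_weight <- function(weight_kg) {
  factor(ifelse(weight_kg <= 75, "<=75", ">75"), levels = WEIGHT_LEVELS)
}

# Case-insensitive mapping of raw labels onto a fixed level set; returns a
# factor with NA where the label is unknown (callers report those rows).
normalize_category <- function(x, levels) {
  x <- trimws(as.character(x))
  idx <- match(tolower(x), tolower(levels))
  out <- levels[idx]
  out[!nzchar(x) | is.na(x)] <- NA
  factor(out, levels = levels)
}

#' Construct a trial dataset
#'
#' Validates a per-patient data frame in the canonical column layout (see
#' [trial_columns()]) and wraps it with trial metadata. Categorical columns
#' are normalised case-insensitively onto their enumerated levels.
#'
#' @param data Data frame with the canonical columns. `age`/`weight` may be
#'   numeric (binned on entry) or bin labels.
#' @param trial_id Trial identifier string.
#' @param role `"training"` or `"test"`. Training trials must supply BOR for
#'   every patient used in model fitting (enforced at fit time; patients with
#'   missing BOR or incomplete visit data are excluded there with a count).
#' @return An object of class `trial_dataset`: a list with elements `data`
#'   (validated data frame), `trial_id`, `role`.
#' @export
trial_dataset <- function(data, trial_id, role = c("training", "test")) {
  role <- match.arg(role)
  data <- as.data.frame(data)
  missing_cols <- setdiff(trial_columns(), names(data))
  if (length(missing_cols)) {
    stop_data("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- data[trial_columns()]
  data$subject_id <- as.character(data$subject_id)

  dup <- unique(data$subject_id[duplicated(data$subject_id)])
  if (length(dup)) {
    stop_data("duplicated subject_id in trial '", trial_id, "': ",
              paste(dup, collapse = ", "))
  }

  problems <- character(0)
  note <- function(rows, field, msg) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d (%s): %s [%s]", rows,
                                       data$subject_id[rows], msg, field))
    }
  }

  data$sex <- normalize_category(data$sex, SEX_LEVELS)
  note(which(is.na(data$sex)), "sex", "unknown or missing sex label")

  if (is.numeric(data$age)) data$age <- bin_age(data$age)
  else data$age <- normalize_category(data$age, AGE_LEVELS)
  note(which(is.na(data$age)), "age", "unparseable age")

  if (is.numeric(data$weight)) data$weight <- bin_weight(data$weight)
  else data$weight <- normalize_category(data$weight, WEIGHT_LEVELS)
  note(which(is.na(data$weight)), "weight", "unparseable weight")

  data$smoking <- normalize_category(data$smoking, SMOKING_LEVELS)
  note(which(is.na(data$smoking)), "smoking", "unknown smoking label")

  data$race <- normalize_category(data$race, RACE_LEVELS)
  note(which(is.na(data$race)), "race", "unknown race label")

  # BOR may be missing (NA); only enumerated values otherwise.
  bor_raw <- trimws(as.character(data$bor))
  bor_missing <- is.na(bor_raw) | !nzchar(bor_raw)
  data$bor <- normalize_category(data$bor, BOR_LEVELS)
  note(which(is.na(data$bor) & !bor_missing), "bor", "unknown BOR label")

  data$base_size <- as.numeric(data$base_size)
  note(which(!is.finite(data$base_size) | data$base_size <= 0),
       "base_size", "baseline tumor size must be a positive number")
  for (v in VISIT_COLS) {
    data[[v]] <- as.numeric(data[[v]])
    bad <- which(!is.na(data[[v]]) & (!is.finite(data[[v]]) | data[[v]] <= 0))
    note(bad, v, "visit tumor size must be positive when present")
  }

  data$os_days <- as.numeric(data$os_days)
  note(which(!is.finite(data$os_days) | data$os_days < 0),
       "os_days", "overall-survival time must be >= 0")
  data$os_event <- as.numeric(data$os_event)
  note(which(!(data$os_event %in% c(0, 1))),
       "os_event", "event indicator must be 0 or 1")

  if (length(problems)) {
    stop_data("invalid patient record(s) in trial '", trial_id, "':\n  ",
              paste(problems, collapse = "\n  "))
  }

  rownames(data) <- NULL
  structure(list(data = data, trial_id = trial_id, role = role),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %s (%s): %d patients, %d with BOR, %d events\n",
              x$trial_id, x$role, nrow(x$data), sum(!is.na(x$data$bor)),
              sum(x$data$os_event)))
  invisible(x)
}

#' Number of patients in a trial dataset
#' @param ds A `trial_dataset`.
#' @return Integer patient count.
#' @export
n_patients <- function(ds) nrow(ds$data)

#' Read a trial table from a delimited file
#'
#' Reads a UTF-8, comma-delimited file with a header row into a validated
#' [trial_dataset()]. Column names other than the canonical ones (see
#' [trial_columns()]) can be absorbed through `col_map`.
#'
#' @param path Path to a CSV file.
#' @param trial_id Trial identifier; defaults to the file name.
#' @param role `"training"` or `"test"`.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(subject_id = "USUBJID")`.
#' @return A `trial_dataset`.
#' @export
read_trial_table <- function(path, trial_id = NULL, role = "training",
                             col_map = NULL) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  if (file.size(path) == 0) stop_data("empty file (no header row): ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) stop_data("empty file: ", path)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src)) {
      stop_data("column(s) named in col_map absent from file: ",
                paste(missing_src, collapse = ", "))
    }
    for (canonical in names(col_map)) {
      names(raw)[names(raw) == col_map[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(trial_columns(), names(raw))
  if (length(missing_cols)) {
    stop_data("file ", path, " lacks required column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  if (is.null(trial_id)) trial_id <- sub("\\.[^.]*$", "", basename(path))
  trial_dataset(raw, trial_id = trial_id, role = role)
}

#' Write a trial table
#'
#' Writes the canonical CSV representation of a trial dataset. Numeric
#' columns are written at full double precision so that
#' `read_trial_table(write_trial_table(ds))` reproduces `ds` exactly.
#'
#' @param ds A `trial_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  out <- ds$data
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_full(out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Full-precision decimal rendering (round-trips doubles exactly).
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Map best overall response to the binary responder label
#'
#' Responders are patients whose best overall response is complete (CR) or
#' partial (PR); stable (SD) and progressive (PD) disease are non-responders.
#'
#' @param bor Character or factor vector of BOR categories.
#' @return Integer vector: 1 = responder, 0 = non-responder.
#' @export
bor_to_binary <- function(bor) {
  bor <- normalize_category(bor, BOR_LEVELS)
  if (anyNA(bor)) {
    stop_data("missing or unknown BOR label at position(s): ",
              paste(which(is.na(bor)), collapse = ", "))
  }
  as.integer(bor %in% c("CR", "PR"))
}

#' Write per-patient segmentation assignments
#'
#' Emits a CSV with columns `subject_id`, `score`, `probability`, `group`.
#' Scores and probabilities are written at full double precision, so reading
#' the file back reproduces the stored values exactly.
#'
#' @param assignments Data frame with columns `subject_id`, `score`,
#'   `probability`, `group` (as produced by [segment_patients()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(assignments, path) {
  need <- c("subject_id", "score", "probability", "group")
  missing_cols <- setdiff(need, names(assignments))
  if (length(missing_cols)) {
    stop_data("assignments lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- assignments[need]
  out$score <- fmt_full(out$score)
  out$probability <- fmt_full(out$probability)
  out$group <- as.character(out$group)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_config("cannot write segmentation file: ", path)
  invisible(path)
}

#' Read segmentation assignments written by [write_segmentation()]
#' @param path CSV path.
#' @return Data frame with `subject_id`, `score`, `probability`, `group`.
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$group <- factor(out$group, levels = c("non-responder", "responder"))
  out
}

# Patients usable for model fitting: complete baseline + 4 visits, and (for
# fitting) a non-missing BOR. Exclusions are counted, never silent.
model_frame <- function(ds, require_bor = TRUE) {
  d <- ds$data
  complete_traj <- is.finite(d$base_size) &
    Reduce(`&`, lapply(VISIT_COLS, function(v) is.finite(d[[v]])))
  keep <- complete_traj
  if (require_bor) keep <- keep & !is.na(d$bor)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("trial %s: excluding %d/%d patient(s) without complete visits%s",
                    ds$trial_id, n_excluded, nrow(d),
                    if (require_bor) " or BOR" else ""))
  }
  list(data = d[keep, , drop = FALSE], n_excluded = n_excluded)
}
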