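# Pooled scoring system and segmentation. Coefficients fitted on the two
# training trials are averaged element-wise into one linear score per test
# patient; the pooled threshold is the mean of the two training trials'
# best cutoffs (novel method) or the fixed 0.5 (standard method).

#' Pool two trained models into a scoring system
#'
#' Averages the two coefficient vectors element-wise (including the
#' intercept) and pools the decision threshold: the mean of the two
#' training-trial best cutoffs for the novel method, the fixed 0.5 for the
#' standard method.
#'
#' @param fit1,fit2 `logit_fit` objects with identical coefficient layouts.
#' @param cutoff1,cutoff2 Best cutoffs of the two training trials (novel
#'   method only; ignored for the standard method).
#' @param method `"novel"` or `"standard"`.
#' @param provenance Optional list recording trial IDs and chosen CV
#'   techniques; stored verbatim.
#' @return Object of class `pooled_model`: `coefficients` (named mean
#'   vector), `bcut`, `method`, `provenance`.
#' @export
pool_models <- function(fit1, fit2, cutoff1 = NULL, cutoff2 = NULL,
                        method = c("novel", "standard"), provenance = list()) {
  method <- match.arg(method)
  c1 <- fit1$coefficients
  c2 <- fit2$coefficients
  if (length(c1) != length(c2) || !identical(names(c1), names(c2))) {
    stop_model("coefficient layouts differ between the two training models")
  }
  if (method == "novel") {
    if (is.null(cutoff1) || is.null(cutoff2)) {
      stop_config("novel pooling requires both training cutoffs")
    }
    bcut <- (cutoff1 + cutoff2) / 2
  } else {
    bcut <- 0.5
  }
  if (!all(is.finite(c1)) || !all(is.finite(c2))) {
    stop_model("non-finite coefficients cannot be pooled")
  }
  structure(list(coefficients = (c1 + c2) / 2, bcut = bcut, method = method,
                 provenance = provenance),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("<pooled_model> method = %s, bcut = %.4f\n", x$method, x$bcut))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score patients with a pooled model
#'
#' The score is the pooled linear predictor (log-odds scale):
#' mean-coefficient times covariate, summed over sex, age, weight, smoking,
#' race and the PC scores, plus the mean intercept. The probability is its
#' inverse logit.
#'
#' @param model A `pooled_model`.
#' @param X Design matrix whose columns match the model layout.
#' @return Data frame: `subject_id`, `score`, `probability`.
#' @export
score_patients <- function(model, X) {
  stopifnot(inherits(model, "pooled_model"))
  X <- as.matrix(X)
  expected <- names(model$coefficients)[-1]
  if (!identical(colnames(X), expected)) {
    stop_data("design-matrix columns (", paste(colnames(X), collapse = ","),
              ") do not match the model layout (", paste(expected, collapse = ","), ")")
  }
  score <- drop(cbind(1, X) %*% model$coefficients)
  data.frame(subject_id = if (is.null(rownames(X))) as.character(seq_len(nrow(X)))
                          else rownames(X),
             score = score,
             probability = stats::plogis(score),
             stringsAsFactors = FALSE)
}

#' Segment scored patients against a pooled cutoff
#'
#' A patient is assigned to the responder group iff their probability
#' strictly exceeds `bcut`; a probability exactly equal to the cutoff is a
#' non-responder.
#'
#' @param scores Data frame from [score_patients()].
#' @param bcut Probability cutoff in (0, 1).
#' @return `scores` with an added factor column `group`
#'   (`non-responder`/`responder`).
#' @export
segment_patients <- function(scores, bcut) {
  if (!is.finite(bcut) || bcut <= 0 || bcut >= 1) {
    stop_config("bcut must be in (0, 1), got ", bcut)
  }
  scores$group <- factor(ifelse(scores$probability > bcut,
                                "responder", "non-responder"),
                         levels = c("non-responder", "responder"))
  scores
}

#' Train the standard (fixed 0.5 cutoff) comparator
#'
#' Fits an ordinary logistic regression on each full training design (no
#' resampling), pools the coefficients, and fixes the cutoff at 0.5.
#'
#' @param X1,y1 Design matrix and binary response of the first training trial.
#' @param X2,y2 Same for the second training trial.
#' @param provenance Optional provenance list.
#' @return A `pooled_model` with `method = "standard"` and `bcut = 0.5`.
#' @export
standard_train <- function(X1, y1, X2, y2, provenance = list()) {
  fit1 <- fit_logistic(X1, y1)
  fit2 <- fit_logistic(X2, y2)
  pool_models(fit1, fit2, method = "standard", provenance = provenance)
}

#' Serialize a pooled model to JSON
#'
#' Writes a versioned JSON document with the method, coefficient names and
#' values, the pooled cutoff and the provenance record.
#'
#' @param model A `pooled_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "pooled_model"))
  doc <- list(
    schema = "respseg/pooled_model/1",
    package_version = as.character(utils::packageVersion("respseg")),
    method = model$method,
    coefficients = as.list(model$coefficients),
    bcut = model$bcut,
    provenance = model$provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pooled model written by [write_model_json()]
#' @param path JSON path.
#' @return A `pooled_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !startsWith(doc$schema, "respseg/pooled_model/")) {
    stop_data("not a pooled-model document: ", path)
  }
  structure(list(coefficients = unlist(doc$coefficients),
                 bcut = doc$bcut, method = doc$method,
                 provenance = doc$provenance),
            class = "pooled_model")
}
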