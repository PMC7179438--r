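#' Predict activity from a QSAR model
#'
#' Evaluates `intercept + sum(coefficient * descriptor)` for each row of
#' `newdata`. Works identically for refitted models ([fit_qsar()]) and
#' explicit-coefficient models ([qsar_model()], [a2a_models()]).
#'
#' @param object A `qsar_model`.
#' @param newdata A tibble containing every descriptor column the model
#'   uses. If omitted for a fitted model, the training fitted values are
#'   returned.
#' @param ... Unused.
#' @return Numeric vector of predicted activities (pEC50 scale for the
#'   packaged models).
#' @examples
#' predict(a2a_models()$penta, a2a_screening())
#' @export
predict.qsar_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (!is.null(object$fitted)) return(object$fitted)
    abort("newdata is required for a coefficient-only model")
  }
  missing_cols <- setdiff(object$descriptors, names(newdata))
  if (length(missing_cols)) {
    abort(paste0("newdata lacks descriptor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(newdata[object$descriptors])
  if (anyNA(x)) abort("missing descriptor values in newdata")
  drop(object$intercept + x %*% object$coefficients)
}

#' Validate a model against measured activities
#'
#' Applies the model to every compound in the table and reports the
#' residual `experimental - predicted` wherever a measured activity is
#' present (the sign convention of the study's validation tables). Used
#' for both internal validation (training compounds) and external
#' validation (held-out test set).
#'
#' @param model A `qsar_model`.
#' @param table A compound tibble.
#' @param activity Activity column (default `"pec50"`).
#' @return A tibble ordered as the input with `compound_id`,
#'   `experimental`, `predicted`, `residual`, plus a `"summary"`
#'   attribute (one-row tibble: `n`, `mean_residual`, `max_abs_residual`).
#' @examples
#' validate_qsar(a2a_models()$tetra, a2a_test())
#' @export
validate_qsar <- function(model, table, activity = "pec50") {
  if (nrow(table) == 0) abort("empty table")
  experimental <- if (activity %in% names(table)) table[[activity]] else
    rep(NA_real_, nrow(table))
  out <- tibble(
    compound_id = table$compound_id,
    experimental = experimental,
    predicted = predict(model, table),
  ) %>%
    mutate(residual = .data$experimental - .data$predicted)
  ok <- !is.na(out$residual)
  attr(out, "summary") <- tibble(
    n = sum(ok),
    mean_residual = if (any(ok)) mean(out$residual[ok]) else NA_real_,
    max_abs_residual = if (any(ok)) max(abs(out$residual[ok])) else NA_real_
  )
  out
}

#' Classify predicted potency against an activity cutoff
#'
#' A screened compound is called active when its predicted pEC50 strictly
#' exceeds the cutoff. The default cutoff, 5.64936, is the potency of the
#' weakest training agonist, so "active" means "predicted at least as
#' potent as every compound known to activate the receptor". The
#' comparison is strict: a prediction exactly at the cutoff is inactive.
#'
#' @param predicted Numeric predicted pEC50 values (vectorised).
#' @param cutoff Activity threshold on the pEC50 scale (default 5.64936).
#' @return Logical vector.
#' @examples
#' classify_active(c(7.54, 5.64936, 3.16))
#' @export
classify_active <- function(predicted, cutoff = 5.64936) {
  predicted > cutoff
}

#' Screen compounds with a set of QSAR models
#'
#' Predicts activity for each compound under every supplied model and
#' classifies compounds as active/inactive with [classify_active()] on
#' the predictions of one designated model.
#'
#' @param table A compound tibble (descriptors required, activity not).
#' @param models Named list of `qsar_model` objects (default
#'   [a2a_models()]).
#' @param cutoff Activity cutoff on the pEC50 scale (default 5.64936).
#' @param decide_with Name of the model whose predictions drive the
#'   active call (default `"penta"`, the best-validated reference model).
#' @return A tibble with `compound_id`, one `pred_<model>` column per
#'   model, `active`, and the cutoff in the `"cutoff"` attribute.
#' @examples
#' screen_compounds(a2a_screening())
#' @export
screen_compounds <- function(table, models = a2a_models(),
                             cutoff = 5.64936, decide_with = "penta") {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    abort("models must be a named list")
  }
  if (!decide_with %in% names(models)) {
    abort(paste0("decide_with must name one of the models: ",
                 paste(names(models), collapse = ", ")))
  }
  preds <- purrr::map(models, predict, newdata = table)
  out <- tibble(compound_id = table$compound_id)
  for (nm in names(preds)) out[[paste0("pred_", nm)]] <- preds[[nm]]
  out$active <- classify_active(preds[[decide_with]], cutoff)
  attr(out, "cutoff") <- cutoff
  out
}
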