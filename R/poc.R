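#' Fit the probability-of-cancer (POC) model over the 7-marker panel
#'
#' A binomial generalized linear model with logit link on the log10-scaled
#' concentrations of AFP, CA125, CA15-3, CA19-9, CA72-4, CEA and CYFRA 21-1,
#' producing a probability-of-cancer index in `[0, 1]`. Marker values are
#' winsorized at the 99.9th percentile of the pooled training cohort before
#' the log transform, because clinical analyzers saturate and a handful of
#' extreme concentrations would otherwise dominate the fit; the caps are
#' stored in the model so scoring applies the identical transform.
#'
#' If the fit detects complete separation (non-convergence or fitted
#' probabilities pinned at 0/1), the model is refit with a small ridge
#' penalty and flagged `separable = TRUE`; the returned object still scores.
#'
#' @param cohort Training cohort with both groups (see [generate_cohort()]).
#' @param seed Integer recorded in the model for provenance; the fit itself
#'   is deterministic given the data.
#' @return An object of class `poc_model`: `intercept`, named `coefficients`
#'   (log10-marker scale), `caps`, `transform`, `separable`.
#' @export
fit_poc <- function(cohort, seed = 0L) {
  check_cohort(cohort)
  if (length(unique(cohort$group)) < 2) {
    stopf("training cohort must contain both cancer and noncancer records")
  }
  x <- as.matrix(cohort[, PTM_MARKERS])
  caps <- apply(x, 2, quantile, probs = 0.999, type = 7)
  xw <- log10(pmin(x, rep(caps, each = nrow(x))))
  y <- as.integer(cohort$group == "cancer")
  df <- data.frame(y = y, xw)

  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  fitted_p <- fit$fitted.values
  separable <- !fit$converged ||
    any(fitted_p > 1 - 1e-8 & y == 1) && any(fitted_p < 1e-8 & y == 0) &&
    all((fitted_p >= 0.5) == y) ||
    any(abs(coef(fit)[-1]) > 25)

  if (separable) {
    # ridge fallback keeps coefficients finite under complete separation
    rf <- glmnet::glmnet(xw, y, family = "binomial", alpha = 0,
                         lambda = 1e-2, standardize = TRUE)
    beta <- as.numeric(rf$beta)
    names(beta) <- rownames(rf$beta)
    intercept <- as.numeric(rf$a0)
  } else {
    beta <- coef(fit)[-1]
    intercept <- unname(coef(fit)[1])
  }

  structure(
    list(intercept = intercept,
         coefficients = setNames(as.numeric(beta), PTM_MARKERS),
         caps = setNames(as.numeric(caps), PTM_MARKERS),
         transform = "log10", separable = separable,
         seed = as.integer(seed), n_train = nrow(cohort)),
    class = "poc_model"
  )
}

#' Score records with a POC model
#'
#' Applies the stored winsorization caps and log10 transform, then the
#' logistic linear predictor. Monotone non-decreasing in any marker with a
#' positive coefficient (flat above its cap).
#'
#' @param model A `poc_model` from [fit_poc()].
#' @param records Cohort data frame (any rows) carrying all 7 markers.
#' @return Numeric POC vector in `[0, 1]`, one per record.
#' @export
score_poc <- function(model, records) {
  if (!inherits(model, "poc_model")) stopf("model must be a poc_model")
  missing_cols <- setdiff(PTM_MARKERS, names(records))
  if (length(missing_cols)) {
    stopf("records are missing marker(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(records[, PTM_MARKERS, drop = FALSE])
  if (any(!is.finite(x)) || any(x <= 0)) {
    stopf("marker concentrations must be strictly positive (log undefined)")
  }
  xw <- log10(pmin(x, rep(model$caps, each = nrow(x))))
  eta <- model$intercept + drop(xw %*% model$coefficients)
  plogis(eta)
}

#' Classify a POC index
#'
#' Screen-positive means a POC at or above the cutoff; the boundary itself
#' is positive.
#'
#' @param poc POC value(s) in `[0, 1]`.
#' @param cutoff Decision cutoff, default 0.5.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_poc <- function(poc, cutoff = 0.5) {
  if (any(!is.finite(poc)) || any(poc < 0) || any(poc > 1)) {
    stopf("poc must lie in [0, 1]")
  }
  ifelse(poc >= cutoff, "positive", "negative")
}

#' @export
print.poc_model <- function(x, ...) {
  cat("POC model (binomial GLM on log10 marker panel)\n")
  cat(sprintf("  trained on %d records%s\n", x$n_train,
              if (x$separable) " [separable: ridge fallback]" else ""))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Serialize a POC model to JSON and back
#'
#' @param model A `poc_model`.
#' @param path File path.
#' @return `write_poc_model` returns `path` invisibly; `read_poc_model` the
#'   model.
#' @export
write_poc_model <- function(model, path) {
  if (!inherits(model, "poc_model")) stopf("model must be a poc_model")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_poc_model
#' @export
read_poc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- setNames(as.numeric(obj$coefficients), PTM_MARKERS)
  obj$caps <- setNames(as.numeric(obj$caps), PTM_MARKERS)
  structure(obj, class = "poc_model")
}
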