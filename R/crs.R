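CRS_FEATURES <- c("cna", "fs", "endmotif", "virus", "ptm")

#' Construct CRS weights
#'
#' The cancer risk score is the weighted linear combination
#' `CRS = a*CNA + b*FS + c*endmotif + d*virus + e*PTM`, with the PTM feature
#' being the POC index of the marker panel. Weights are constrained to the
#' unit simplex (nonnegative, summing to 1): the AUC criterion used to pick
#' them is invariant to positive rescaling, so only the direction of the
#' weight vector is identifiable.
#'
#' @param a,b,c,d,e Nonnegative weights for CNA, fragment size, end motif,
#'   virus and PTM, summing to 1.
#' @return An object of class `crs_weights` (named numeric of length 5).
#' @export
crs_weights <- function(a, b, c, d, e) {
  w <- c(cna = a, fs = b, endmotif = c, virus = d, ptm = e)
  if (any(!is.finite(w)) || any(w < 0)) stopf("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) {
    stopf("weights must sum to 1 (got %.10f)", sum(w))
  }
  structure(w, class = "crs_weights")
}

#' Raw (uncalibrated) CRS: dot product of weights and features
#'
#' @param weights A [crs_weights()] object or nonnegative 5-vector.
#' @param features Numeric 5-vector `(cna, fs, endmotif, virus, ptm)` or an
#'   n-by-5 matrix/data frame with those columns.
#' @return The weighted sum(s), exactly.
#' @export
raw_crs <- function(weights, features) {
  w <- as.numeric(weights)
  if (length(w) != 5L) stopf("weights must have length 5")
  if (is.data.frame(features)) features <- as.matrix(features[, CRS_FEATURES])
  if (is.matrix(features)) {
    if (ncol(features) != 5L) stopf("feature matrix must have 5 columns")
    if (any(!is.finite(features))) stopf("features must be finite")
    return(drop(features %*% w))
  }
  if (length(features) != 5L) stopf("features must have length 5")
  if (any(!is.finite(features))) stopf("features must be finite")
  sum(w * features)
}

# all nonnegative 5-part compositions of `k` on the 1/k lattice, in
# lexicographic order on (a, b, c, d, e); rows sum to exactly k
simplex_lattice <- function(k) {
  comp4 <- function(total) {
    out <- list()
    for (i in 0:total) for (j in 0:(total - i)) for (l in 0:(total - i - j)) {
      out[[length(out) + 1L]] <- c(i, j, l, total - i - j - l)
    }
    do.call(rbind, out)
  }
  rows <- lapply(0:k, function(a) cbind(a, comp4(k - a)))
  lat <- do.call(rbind, rows)
  colnames(lat) <- CRS_FEATURES
  lat
}

#' Grid search for the AUC-maximizing CRS weights
#'
#' Enumerates every nonnegative weight 5-tuple on the step-lattice of the
#' unit simplex and returns the tuple whose raw CRS maximizes the empirical
#' (Mann-Whitney) AUC. Ties are broken deterministically in favour of the
#' lexicographically smallest tuple in `(a, b, c, d, e)` order.
#'
#' @param features n-by-5 matrix or data frame with columns
#'   `cna, fs, endmotif, virus, ptm`.
#' @param labels Positive-class indicator (logical or `"cancer"`/`"noncancer"`).
#' @param step Lattice step; `1/step` must be a whole number. Default 0.05
#'   (10,626 candidate tuples).
#' @return A `crs_weights` object with attributes `auc` (the achieved AUC)
#'   and `leaderboard` (top 10 tuples by AUC, for audit).
#' @export
grid_search_weights <- function(features, labels, step = 0.05) {
  labels <- as_positive(labels)
  if (is.data.frame(features)) features <- as.matrix(features[, CRS_FEATURES])
  if (nrow(features) != length(labels)) stopf("features/labels length mismatch")
  if (sum(labels) < 2 || sum(!labels) < 2) {
    stopf("need at least 2 subjects in each class")
  }
  k <- 1 / step
  if (abs(k - round(k)) > 1e-9) stopf("step must divide 1 evenly")
  k <- as.integer(round(k))
  lat <- simplex_lattice(k)

  # score all subjects against all tuples in one multiply, then get each
  # column's AUC from midranks
  s <- features %*% t(lat) # n x n_tuples
  n1 <- sum(labels)
  n0 <- sum(!labels)
  aucs <- apply(s, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  best <- which.max(aucs) # first max = lexicographically smallest tuple
  w <- lat[best, ] / k
  ord <- order(-aucs)
  top <- utils::head(ord, 10L)
  leaderboard <- data.frame(lat[top, , drop = FALSE] / k, auc = aucs[top],
                            row.names = NULL)
  out <- crs_weights(w[["cna"]], w[["fs"]], w[["endmotif"]], w[["virus"]],
                     w[["ptm"]])
  attr(out, "auc") <- aucs[best]
  attr(out, "leaderboard") <- leaderboard
  out
}

#' Calibrate the CRS scale so the 98%-specificity cutoff sits at 2.0
#'
#' The published score is reported on a scale where the cutoff achieving the
#' target specificity in noncancer training subjects equals 2.0. Only that
#' one (percentile, cutoff) pair pins the scale, so a second anchor is
#' needed for identifiability: the noncancer median is mapped to 0. The
#' result is the affine map `score -> scale * score + offset` with
#' `scale > 0`; percentiles are type-7 interpolated order statistics.
#'
#' @param raw_noncancer_scores Raw CRS values of the noncancer training
#'   subjects; at least 50, so the upper-tail percentile is resolvable.
#' @param target_specificity Upper-tail anchor, default 0.98.
#' @param cutoff Score the anchor maps to, default 2.0.
#' @return An object of class `crs_calibration`: `scale`, `offset`,
#'   `cutoff`, `target_specificity`.
#' @export
calibrate_crs <- function(raw_noncancer_scores, target_specificity = 0.98,
                          cutoff = 2.0) {
  x <- as.numeric(raw_noncancer_scores)
  if (length(x) < 50) stopf("need >= 50 noncancer scores (got %d)", length(x))
  if (any(!is.finite(x))) stopf("scores must be finite")
  assert_prob(target_specificity, "target_specificity", open_left = TRUE,
              open_right = TRUE)
  q_hi <- unname(quantile(x, probs = target_specificity, type = 7))
  q_mid <- unname(median(x))
  if (q_hi - q_mid < .Machine$double.eps^0.5 * max(1, abs(q_hi))) {
    stopf("degenerate noncancer scores: upper percentile equals the median")
  }
  scale <- cutoff / (q_hi - q_mid)
  structure(list(scale = scale, offset = -scale * q_mid, cutoff = cutoff,
                 target_specificity = target_specificity),
            class = "crs_calibration")
}

apply_calibration <- function(calibration, raw) {
  calibration$scale * raw + calibration$offset
}

#' Classify a calibrated CRS
#'
#' A CRS at or above the cutoff (default 2.0) is cancer-positive; the
#' boundary is positive.
#'
#' @param crs Calibrated score(s).
#' @param cutoff Decision cutoff, default 2.0.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_crs <- function(crs, cutoff = 2.0) {
  if (any(!is.finite(crs))) stopf("crs must be finite")
  ifelse(crs >= cutoff, "positive", "negative")
}

#' Fit the full CRS model on a cohort
#'
#' Builds the five-feature matrix (four genomic scores plus the POC index as
#' the PTM feature), z-scores each feature against the noncancer training
#' mean and SD so the simplex weights are comparable across scales, grid
#' searches the weights, and calibrates the scale to put the
#' target-specificity cutoff at 2.0.
#'
#' @param cohort Training cohort with both groups.
#' @param poc_model A fitted [fit_poc()] model supplying the PTM feature.
#' @param step Grid-search lattice step, default 0.05.
#' @param target_specificity,cutoff Calibration anchors, defaults 0.98 / 2.0.
#' @return An object of class `crs_model`: `weights`, `centers`, `scales`
#'   (noncancer standardization), `calibration`, `auc`, `leaderboard`.
#' @export
fit_crs <- function(cohort, poc_model, step = 0.05,
                    target_specificity = 0.98, cutoff = 2.0) {
  check_cohort(cohort)
  labels <- cohort$group == "cancer"
  if (!any(labels) || all(labels)) stopf("cohort must contain both groups")
  feats <- crs_feature_matrix(cohort, score_poc(poc_model, cohort))
  centers <- colMeans(feats[!labels, , drop = FALSE])
  scales <- apply(feats[!labels, , drop = FALSE], 2, sd)
  if (any(scales <= 0)) stopf("a feature is constant in noncancer subjects")
  z <- sweep(sweep(feats, 2, centers), 2, scales, "/")
  weights <- grid_search_weights(z, labels, step = step)
  raw <- raw_crs(weights, z)
  calibration <- calibrate_crs(raw[!labels], target_specificity, cutoff)
  structure(
    list(weights = weights, centers = centers, scales = scales,
         calibration = calibration, auc = attr(weights, "auc"),
         leaderboard = attr(weights, "leaderboard"), step = step),
    class = "crs_model"
  )
}

crs_feature_matrix <- function(records, poc) {
  f <- as.matrix(records[, GENOMIC_FEATURES, drop = FALSE])
  cbind(f, ptm = poc)
}

#' Score records with a fitted CRS model
#'
#' @param model A `crs_model` from [fit_crs()].
#' @param records Cohort data frame carrying the genomic feature columns.
#' @param poc POC index per record (the PTM feature), e.g. from
#'   [score_poc()].
#' @return Calibrated CRS per record.
#' @export
score_crs <- function(model, records, poc) {
  if (!inherits(model, "crs_model")) stopf("model must be a crs_model")
  if (length(poc) != nrow(records)) stopf("poc/records length mismatch")
  feats <- crs_feature_matrix(records, poc)
  z <- sweep(sweep(feats, 2, model$centers), 2, model$scales, "/")
  apply_calibration(model$calibration, raw_crs(model$weights, z))
}

#' @export
print.crs_model <- function(x, ...) {
  cat("CRS model (grid-searched simplex weights, step", format(x$step), ")\n")
  cat("  weights:", paste(sprintf("%s %.2f", CRS_FEATURES,
                                  as.numeric(x$weights)), collapse = ", "), "\n")
  cat(sprintf("  training AUC: %.3f\n", x$auc))
  cat(sprintf("  calibration: scale %.4f, offset %.4f (cutoff %.1f at %.0f%% specificity)\n",
              x$calibration$scale, x$calibration$offset, x$calibration$cutoff,
              100 * x$calibration$target_specificity))
  invisible(x)
}

#' Serialize a CRS model to JSON and back
#'
#' @param model A `crs_model`.
#' @param path File path.
#' @return `write_crs_model` returns `path` invisibly; `read_crs_model` the
#'   model.
#' @export
write_crs_model <- function(model, path) {
  if (!inherits(model, "crs_model")) stopf("model must be a crs_model")
  obj <- list(weights = as.list(setNames(as.numeric(model$weights),
                                         CRS_FEATURES)),
              centers = as.list(model$centers),
              scales = as.list(model$scales),
              calibration = unclass(model$calibration),
              auc = model$auc, step = model$step,
              leaderboard = model$leaderboard)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_crs_model
#' @export
read_crs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  weights <- crs_weights(w[["cna"]], w[["fs"]], w[["endmotif"]], w[["virus"]],
                         w[["ptm"]])
  structure(
    list(weights = weights,
         centers = setNames(as.numeric(obj$centers), CRS_FEATURES),
         scales = setNames(as.numeric(obj$scales), CRS_FEATURES),
         calibration = structure(as.list(obj$calibration),
                                 class = "crs_calibration"),
         auc = obj$auc, leaderboard = obj$leaderboard, step = obj$step),
    class = "crs_model"
  )
}
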