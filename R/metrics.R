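#' Empirical AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive-class score exceeds a randomly
#' chosen negative-class score, counting ties as one half — the
#' nonparametric area under the empirical ROC curve.
#'
#' @param scores_pos,scores_neg Numeric score vectors for the positive
#'   (cancer) and negative (noncancer) class; both non-empty.
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(2, 3), c(1, 2))  # 0.875
#' @export
empirical_auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stopf("both classes must be non-empty")
  }
  if (any(!is.finite(c(scores_pos, scores_neg)))) {
    stopf("scores must be finite")
  }
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values for the DeLong covariance: V10[i] = mean_j psi(x_i, y_j),
# V01[j] = mean_i psi(x_i, y_j), computed from midranks (Sun & Xu identity)
delong_placements <- function(scores_pos, scores_neg) {
  m <- length(scores_pos)
  n <- length(scores_neg)
  all_r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  rx <- rank(scores_pos, ties.method = "average")
  ry <- rank(scores_neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' DeLong placement-value covariance; the z statistic is the AUC difference
#' over its estimated standard error, with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Paired numeric scores on the same subjects.
#' @param labels Logical (or coercible) vector, `TRUE`/`"cancer"` = positive.
#' @return A list with `auc_a`, `auc_b`, `z`, `p`, and `se` of the
#'   difference. When the placement variance is zero (e.g. both scores
#'   constant or identical), `z` and `p` are `NA` with `degenerate = TRUE`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_positive(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stopf("scores and labels must have equal length")
  }
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  pa <- delong_placements(scores_a[labels], scores_a[!labels])
  pb <- delong_placements(scores_b[labels], scores_b[!labels])
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  out <- list(auc_a = pa$auc, auc_b = pb$auc, se = sqrt(max(var_diff, 0)))
  if (var_diff <= 0) {
    if (isTRUE(all.equal(pa$auc, pb$auc))) {
      # identical scores: difference is exactly zero, not degenerate
      out$z <- 0
      out$p <- 1
      out$degenerate <- FALSE
    } else {
      out$z <- NA_real_
      out$p <- NA_real_
      out$degenerate <- TRUE
    }
    return(out)
  }
  out$z <- (pa$auc - pb$auc) / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out$degenerate <- FALSE
  out
}

#' Sensitivity and specificity at a cutoff with exact binomial intervals
#'
#' A score at or above the cutoff is called positive, matching the decision
#' rules of the POC and CRS classifiers. Confidence intervals are exact
#' Clopper-Pearson.
#'
#' @param scores Numeric scores.
#' @param labels Positive-class indicator (logical or `"cancer"`/`"noncancer"`).
#' @param cutoff Decision threshold.
#' @param conf_level Interval coverage, default 0.95.
#' @return List with `sensitivity`, `specificity`, their `*_ci` bounds, and
#'   the underlying counts.
#' @export
sens_spec_at <- function(scores, labels, cutoff, conf_level = 0.95) {
  labels <- as_positive(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  tp <- sum(scores[labels] >= cutoff)
  fn <- sum(labels) - tp
  tn <- sum(scores[!labels] < cutoff)
  fp <- sum(!labels) - tn
  sens_ci <- stats::binom.test(tp, tp + fn, conf.level = conf_level)$conf.int
  spec_ci <- stats::binom.test(tn, tn + fp, conf.level = conf_level)$conf.int
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       sensitivity_ci = as.numeric(sens_ci),
       specificity_ci = as.numeric(spec_ci),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Threshold achieving a target specificity
#'
#' The type-7 interpolated percentile of the negative-class scores at
#' `target_spec` — the smallest threshold under the "\eqn{\ge} is positive"
#' convention at which at least that fraction of negatives falls below.
#'
#' @param scores_neg Negative-class scores.
#' @param target_spec Target specificity in `[0, 1)` (or 0.5 for the median).
#' @return The threshold.
#' @export
threshold_at_specificity <- function(scores_neg, target_spec) {
  assert_prob(target_spec, "target_spec")
  n <- length(scores_neg)
  if (target_spec < 1 && n < 1 / max(1 - target_spec, .Machine$double.eps)) {
    stopf("need at least %d negatives to resolve specificity %.3f",
          ceiling(1 / (1 - target_spec)), target_spec)
  }
  unname(quantile(scores_neg, probs = target_spec, type = 7))
}

# coerce group labels to a positive-class logical
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("cancer", "noncancer"))
    if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
    return(labels == "cancer")
  }
  if (is.numeric(labels)) return(labels != 0)
  stopf("labels must be logical, character or numeric")
}
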