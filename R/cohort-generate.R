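#' Mean separation for a unit-variance binormal ROC model
#'
#' Under the binormal model with unit variances in both classes, a
#' case/control mean separation \eqn{\delta} gives a theoretical AUC of
#' \eqn{\Phi(\delta/\sqrt{2})}. This inverts that map: it returns the
#' \eqn{\delta} whose theoretical AUC equals `auc_target`, the calibration
#' device that lets generated feature scores hit a requested discriminative
#' power.
#'
#' @param auc_target Target AUC in `[0.5, 1)`.
#' @return The nonnegative mean shift `sqrt(2) * qnorm(auc_target)`.
#' @examples
#' binormal_shift(0.5)    # 0: no separation
#' binormal_shift(0.877)  # end-motif-like separation
#' @export
binormal_shift <- function(auc_target) {
  if (!is.numeric(auc_target) || length(auc_target) != 1L ||
      !is.finite(auc_target) || auc_target < 0.5 || auc_target >= 1) {
    stopf("auc_target must be a single value in [0.5, 1); got %s",
          format(auc_target))
  }
  sqrt(2) * qnorm(auc_target)
}

#' Generate a seeded synthetic case-control cohort
#'
#' Draws `n_cancer + n_noncancer` participant records. Genomic feature scores
#' are unit-variance Gaussian: mean 0 in controls and mean
#' [binormal_shift()] of the per-feature AUC target in cases, with the cancer
#' scores sharing an equicorrelated latent severity (`feature_cor`). Protein
#' tumor markers are log-normal around healthy baselines; a case elevates
#' each marker with a stage-increasing probability (co-elevation driven by
#' the same latent severity), multiplying the concentration by the marker's
#' shift. Demographics follow the target group means but feed no classifier.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same spec and seed always reproduce the same
#'   cohort, and the caller's RNG stream is left untouched.
#' @return A data frame with one row per participant and columns
#'   `id, group, stage, age, sex`, the 7 marker concentrations, and the 4
#'   genomic feature scores. Controls have `NA` stage.
#' @export
generate_cohort <- function(spec, seed) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  with_seed(seed, {
    cancer <- generate_group(spec, spec$n_cancer, cancer = TRUE)
    noncancer <- generate_group(spec, spec$n_noncancer, cancer = FALSE)
    out <- rbind(cancer, noncancer)
    out$id <- sprintf("S%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, COHORT_COLUMNS]
  })
}

generate_group <- function(spec, n, cancer) {
  grp <- if (cancer) "cancer" else "noncancer"
  pp <- spec$ptm_params
  mk <- pp$markers

  stage <- if (cancer) {
    sample(STAGE_LEVELS, n, replace = TRUE, prob = spec$stage_probs)
  } else {
    rep(NA_character_, n)
  }

  age <- round(rnorm(n, spec$age_mean[[grp]], spec$age_sd[[grp]]))
  age <- pmin(pmax(age, 18), 99)
  sex <- ifelse(rbinom(n, 1, spec$male_prob[[grp]]) == 1, "male", "female")

  # a latent tumour severity per subject drives marker co-elevation; a
  # partially correlated second latent drives the genomic feature scores
  z <- rnorm(n)
  cc <- spec$channel_cor
  zg <- cc * z + sqrt(1 - cc^2) * rnorm(n)

  # marker elevation: probit threshold on sqrt(r)*z + sqrt(1-r)*noise keeps
  # the marginal per-marker probability while co-elevating within a subject
  elev_p <- if (cancer) pp$stage_elev_prob[stage] else
    rep(pp$noncancer_elev_prob, n)
  re <- pp$elev_cor
  ptm <- matrix(NA_real_, n, length(PTM_MARKERS),
                dimnames = list(NULL, PTM_MARKERS))
  drift <- if (cancer) pp$stage_drift[stage] else rep(0, n)
  shift_frac <- if (cancer) 1 else pp$noncancer_shift_frac
  for (j in seq_along(PTM_MARKERS)) {
    u <- sqrt(re) * z + sqrt(1 - re) * rnorm(n)
    elevated <- u > qnorm(1 - elev_p)
    logc <- rnorm(n, mk$log_mu[j], mk$log_sd[j]) +
      drift * mk$log_sd[j] +
      ifelse(elevated, shift_frac * mk$log_shift[j], 0)
    ptm[, j] <- 10^logc
  }

  rf <- spec$feature_cor
  feat <- matrix(NA_real_, n, length(GENOMIC_FEATURES),
                 dimnames = list(NULL, GENOMIC_FEATURES))
  for (j in seq_along(GENOMIC_FEATURES)) {
    noise <- if (cancer) sqrt(rf) * zg + sqrt(1 - rf) * rnorm(n) else rnorm(n)
    delta <- if (cancer) binormal_shift(spec$feature_auc_targets[[j]]) else 0
    feat[, j] <- delta + noise
  }

  data.frame(id = NA_character_, group = grp, stage = stage, age = age,
             sex = sex, ptm, feat, stringsAsFactors = FALSE)
}

#' Marker positivity against upper reference limits
#'
#' Fraction of records whose concentration exceeds the assay's conventional
#' upper reference limit, per marker or for "any marker" — a descriptive
#' summary of how loud the simulated tumours are by stage.
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param ptm_params Marker parameters holding `ref_upper`.
#' @return Named vector: per-marker positivity plus `any`.
#' @export
ptm_positivity <- function(cohort, ptm_params = default_ptm_params()) {
  check_cohort(cohort)
  ref <- setNames(ptm_params$markers$ref_upper, ptm_params$markers$marker)
  pos <- vapply(PTM_MARKERS, function(m) mean(cohort[[m]] > ref[[m]]),
                numeric(1))
  any_pos <- mean(Reduce(`|`, lapply(PTM_MARKERS,
                                     function(m) cohort[[m]] > ref[[m]])))
  c(pos, any = any_pos)
}
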