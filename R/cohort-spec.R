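#' @importFrom stats qnorm rnorm rbinom quantile median glm binomial coef
#'   plogis pnorm setNames predict sd
NULL

PTM_MARKERS <- c("afp", "ca125", "ca153", "ca199", "ca724", "cea", "cyfra211")
GENOMIC_FEATURES <- c("cna", "fs", "endmotif", "virus")
STAGE_LEVELS <- c("I", "II", "III", "IV", "not_staged", "missing")
COHORT_COLUMNS <- c("id", "group", "stage", "age", "sex", PTM_MARKERS,
                    GENOMIC_FEATURES)

#' Default protein-tumor-marker simulation parameters
#'
#' Baselines are log-normal per marker, centred on typical healthy-adult
#' medians of the clinical immunoassays (AFP, CEA in ng/mL; CA125, CA15-3,
#' CA19-9, CA72-4 in U/mL; CYFRA 21-1 in ng/mL). A cancer case elevates each
#' marker with a stage-increasing Bernoulli probability; elevation multiplies
#' the concentration by `10^log_shift`. Elevation events share a subject-level
#' latent severity (correlation `elev_cor`), so markers co-elevate within a
#' patient, and a small fraction of noncancer subjects carry benign
#' elevations (`noncancer_elev_prob`), milder than malignant ones by the
#' factor `noncancer_shift_frac`; benign elevations are what keep the marker
#' panel's screen-positive rate in controls realistically nonzero.
#'
#' On top of the elevation mixture, every cancer subject's markers carry a
#' mild continuous drift (`stage_drift`, in units of each marker's log-scale
#' SD) that grows with stage: tumor-marker levels track tumor burden even
#' below frank positivity, which is what gives the marker panel graded
#' ranking power among the cases that never cross a reference limit.
#'
#' `ref_upper` records each assay's conventional upper reference limit and is
#' used only for descriptive positivity summaries, never by a classifier.
#'
#' @return A list with elements `markers` (data frame: `marker`, `log_mu`,
#'   `log_sd`, `log_shift`, `ref_upper`), `stage_elev_prob` and `stage_drift`
#'   (named per stage label), `noncancer_elev_prob`, and `elev_cor`.
#' @export
default_ptm_params <- function() {
  markers <- data.frame(
    marker = PTM_MARKERS,
    log_mu = log10(c(3, 12, 14, 9, 1.5, 1.8, 1.8)),
    log_sd = c(0.25, 0.30, 0.25, 0.35, 0.35, 0.30, 0.25),
    log_shift = c(1.50, 1.80, 1.50, 2.10, 2.10, 1.80, 1.50),
    ref_upper = c(7, 35, 25, 27, 6.9, 5, 3.3),
    stringsAsFactors = FALSE
  )
  list(
    markers = markers,
    stage_elev_prob = c(I = 0.17, II = 0.24, III = 0.32, IV = 0.40,
                        not_staged = 0.27, missing = 0.27),
    stage_drift = c(I = 0.18, II = 0.28, III = 0.37, IV = 0.46,
                    not_staged = 0.32, missing = 0.32),
    noncancer_elev_prob = 0.045,
    noncancer_shift_frac = 1.0,
    elev_cor = 0.90
  )
}

#' Specify a synthetic case-control cohort
#'
#' The defaults emulate the published case-control cohort: 617 cancer and 580
#' noncancer participants, the printed stage mix, and genomic feature scores
#' whose discriminative power matches the reported per-feature AUCs (CNA
#' 0.797, fragment size 0.865, end motif 0.877, oncogenic virus 0.654) under
#' a unit-variance binormal model. `feature_cor` is the shared-severity
#' correlation among a cancer subject's genomic feature scores (controls are
#' independent noise); it is what keeps the integrated score's AUC in the
#' empirically observed range rather than the much higher value four
#' independent features would yield.
#'
#' @param n_cancer,n_noncancer Group sizes (positive integers).
#' @param stage_probs Named probabilities over stage labels
#'   `I, II, III, IV, not_staged, missing`; must sum to 1.
#' @param feature_auc_targets Named AUC targets in (0.5, 1) for
#'   `cna, fs, endmotif, virus`.
#' @param feature_cor Equicorrelation of cancer genomic feature scores in
#'   `[0, 1)`, via a shared latent tumour severity.
#' @param channel_cor Correlation in `[0, 1]` between the latent severity
#'   driving marker elevation and the one driving the genomic features, so
#'   the protein and sequencing channels partly — not fully — agree on who
#'   the "loud" tumours are.
#' @param ptm_params Marker simulation parameters, see [default_ptm_params()].
#' @param age_mean,age_sd,male_prob Length-2 vectors `(cancer, noncancer)`
#'   for the demographic draw; demographics are descriptive only and feed no
#'   classifier.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec()
#' cohort <- generate_cohort(spec, seed = 1)
#' table(cohort$group)
#' @export
cohort_spec <- function(n_cancer = 617L,
                        n_noncancer = 580L,
                        stage_probs = c(I = 0.263, II = 0.186, III = 0.214,
                                        IV = 0.222, not_staged = 0.053,
                                        missing = 0.062),
                        feature_auc_targets = c(cna = 0.797, fs = 0.865,
                                                endmotif = 0.877,
                                                virus = 0.654),
                        feature_cor = 0.94,
                        channel_cor = 0.8,
                        ptm_params = default_ptm_params(),
                        age_mean = c(cancer = 56.0, noncancer = 48.3),
                        age_sd = c(cancer = 13.7, noncancer = 12.9),
                        male_prob = c(cancer = 0.569, noncancer = 0.510)) {
  n_cancer <- assert_count(n_cancer, "n_cancer")
  n_noncancer <- assert_count(n_noncancer, "n_noncancer")

  if (!setequal(names(stage_probs), STAGE_LEVELS)) {
    stopf("stage_probs must be named with: %s", paste(STAGE_LEVELS, collapse = ", "))
  }
  stage_probs <- stage_probs[STAGE_LEVELS]
  if (any(stage_probs < 0) || abs(sum(stage_probs) - 1) > 1e-9) {
    stopf("stage_probs must be nonnegative and sum to 1 (got %.10f)",
          sum(stage_probs))
  }

  if (!setequal(names(feature_auc_targets), GENOMIC_FEATURES)) {
    stopf("feature_auc_targets must be named with: %s",
          paste(GENOMIC_FEATURES, collapse = ", "))
  }
  feature_auc_targets <- feature_auc_targets[GENOMIC_FEATURES]
  if (any(feature_auc_targets < 0.5) || any(feature_auc_targets >= 1)) {
    stopf("all feature AUC targets must lie in [0.5, 1)")
  }
  assert_prob(feature_cor, "feature_cor", open_right = TRUE)
  assert_prob(channel_cor, "channel_cor")
  validate_ptm_params(ptm_params)

  structure(
    list(n_cancer = n_cancer, n_noncancer = n_noncancer,
         stage_probs = stage_probs,
         feature_auc_targets = feature_auc_targets,
         feature_cor = feature_cor, channel_cor = channel_cor,
         ptm_params = ptm_params,
         age_mean = age_mean, age_sd = age_sd, male_prob = male_prob),
    class = "cohort_spec"
  )
}

validate_ptm_params <- function(p) {
  need <- c("markers", "stage_elev_prob", "stage_drift",
            "noncancer_elev_prob", "noncancer_shift_frac", "elev_cor")
  if (!is.list(p) || !all(need %in% names(p))) {
    stopf("ptm_params must contain: %s", paste(need, collapse = ", "))
  }
  m <- p$markers
  cols <- c("marker", "log_mu", "log_sd", "log_shift")
  if (!is.data.frame(m) || !all(cols %in% names(m)) ||
      !identical(m$marker, PTM_MARKERS)) {
    stopf("ptm_params$markers must describe the 7 markers %s in order",
          paste(PTM_MARKERS, collapse = ", "))
  }
  if (any(m$log_sd <= 0)) stopf("marker log_sd must be positive")
  sp <- p$stage_elev_prob
  if (!setequal(names(sp), STAGE_LEVELS)) {
    stopf("stage_elev_prob must be named with stage labels")
  }
  for (s in STAGE_LEVELS) assert_prob(sp[[s]], paste0("stage_elev_prob[", s, "]"))
  if (!setequal(names(p$stage_drift), STAGE_LEVELS) ||
      any(p$stage_drift < 0)) {
    stopf("stage_drift must be nonnegative and named with stage labels")
  }
  if (sp[["I"]] > sp[["II"]] || sp[["II"]] > sp[["III"]] ||
      sp[["III"]] > sp[["IV"]]) {
    stopf("stage elevation probabilities must be non-decreasing I -> IV")
  }
  assert_prob(p$noncancer_elev_prob, "noncancer_elev_prob")
  assert_prob(p$noncancer_shift_frac, "noncancer_shift_frac")
  assert_prob(p$elev_cor, "elev_cor", open_right = TRUE)
  invisible(p)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic case-control cohort specification\n")
  cat(sprintf("  cancer: %d  noncancer: %d\n", x$n_cancer, x$n_noncancer))
  cat("  stage mix:",
      paste(sprintf("%s %.1f%%", names(x$stage_probs), 100 * x$stage_probs),
            collapse = ", "), "\n")
  cat("  feature AUC targets:",
      paste(sprintf("%s %.3f", names(x$feature_auc_targets),
                    x$feature_auc_targets), collapse = ", "), "\n")
  cat(sprintf("  feature_cor: %.2f  channel_cor: %.2f\n", x$feature_cor,
              x$channel_cor))
  invisible(x)
}
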