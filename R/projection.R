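#' Specify a screening scenario
#'
#' One strategy's inputs to the population-scale projection: the screened
#' population, the cancer incidence (pretest probability), the case-control
#' operating point, and whether the sensitivity is adjusted downward
#' proportionally to emulate a prospective (real-world) setting.
#'
#' @param label Strategy name.
#' @param population Number of individuals screened.
#' @param incidence Cancer incidence among them (pretest probability).
#' @param sensitivity_case_control Sensitivity at the strategy's cutoff in
#'   the case-control setting.
#' @param specificity Specificity at the cutoff (used as-is; prospective and
#'   retrospective specificities are empirically near-identical).
#' @param adjustment `"proportional"` to scale sensitivity by the
#'   prospective/retrospective reference ratio, `"none"` to use it as-is.
#' @param sens_retrospective_ref,sens_prospective_ref Reference sensitivities
#'   anchoring the proportional adjustment (defaults: the comparator test's
#'   retrospective 51.5% and prospective 28.9%).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, population, incidence,
                          sensitivity_case_control, specificity,
                          adjustment = c("proportional", "none"),
                          sens_retrospective_ref = 0.515,
                          sens_prospective_ref = 0.289) {
  adjustment <- match.arg(adjustment)
  population <- assert_count(population, "population")
  assert_prob(incidence, "incidence")
  assert_prob(sensitivity_case_control, "sensitivity_case_control",
              open_left = TRUE)
  assert_prob(specificity, "specificity")
  assert_prob(sens_retrospective_ref, "sens_retrospective_ref", open_left = TRUE)
  assert_prob(sens_prospective_ref, "sens_prospective_ref", open_left = TRUE)
  structure(
    list(label = as.character(label), population = population,
         incidence = incidence,
         sensitivity_case_control = sensitivity_case_control,
         specificity = specificity, adjustment = adjustment,
         sens_retrospective_ref = sens_retrospective_ref,
         sens_prospective_ref = sens_prospective_ref),
    class = "scenario_spec"
  )
}

#' Proportional real-world sensitivity adjustment
#'
#' Case-control (retrospective) sensitivities overstate prospective
#' screening performance. The adjustment scales the case-control sensitivity
#' by the ratio of a reference test's prospective to retrospective
#' sensitivity, then rounds to one decimal place in percent — the precision
#' at which the projection tables are stated, applied before count
#' projection so the printed counts are internally consistent.
#'
#' @param sens_cc Case-control sensitivity in (0, 1].
#' @param ref_retro,ref_prosp Reference retrospective and prospective
#'   sensitivities, `ref_retro >= ref_prosp > 0`.
#' @return Adjusted sensitivity as a proportion with 3 decimals (one decimal
#'   in percent).
#' @examples
#' adjust_sensitivity(0.499, 0.515, 0.289)  # 0.280
#' @export
adjust_sensitivity <- function(sens_cc, ref_retro = 0.515,
                               ref_prosp = 0.289) {
  assert_prob(sens_cc, "sens_cc", open_left = TRUE)
  assert_prob(ref_retro, "ref_retro", open_left = TRUE)
  assert_prob(ref_prosp, "ref_prosp", open_left = TRUE)
  if (ref_retro < ref_prosp) {
    stopf("ref_retro (%.3f) must be >= ref_prosp (%.3f)", ref_retro, ref_prosp)
  }
  round_half_up(sens_cc * ref_prosp / ref_retro, 3)
}

#' Project a scenario onto the screening population
#'
#' Closed-form 2x2 projection: the cancer count is `population * incidence`;
#' true positives apply the (adjusted) sensitivity to it and false positives
#' apply `1 - specificity` to the rest, with half-up rounding to whole
#' people. Predictive values, likelihood ratios, pre/post-test
#' probabilities, and the number needed to screen (`1 / (incidence * sens)`)
#' follow from the counts and rates.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `projection_result` with fields
#'   `label, sensitivity_adjusted, specificity, tp, fp, tn, fn, ppv, npv,
#'   lr_pos, lr_neg, pretest, posttest_pos, posttest_neg, nns, population,
#'   incidence`.
#' @export
project <- function(spec) {
  if (!inherits(spec, "scenario_spec")) stopf("spec must be a scenario_spec")
  sens <- if (spec$adjustment == "proportional") {
    adjust_sensitivity(spec$sensitivity_case_control,
                       spec$sens_retrospective_ref,
                       spec$sens_prospective_ref)
  } else {
    spec$sensitivity_case_control
  }
  pop <- spec$population
  n_cancer <- round_half_up(pop * spec$incidence)
  n_noncancer <- pop - n_cancer
  tp <- round_half_up(n_cancer * sens)
  fn <- n_cancer - tp
  fp <- round_half_up(n_noncancer * (1 - spec$specificity))
  tn <- n_noncancer - fp
  ppv <- tp / (tp + fp)
  npv <- tn / (tn + fn)
  structure(
    list(label = spec$label, sensitivity_adjusted = sens,
         specificity = spec$specificity,
         tp = tp, fp = fp, tn = tn, fn = fn,
         ppv = ppv, npv = npv,
         lr_pos = sens / (1 - spec$specificity),
         lr_neg = (1 - sens) / spec$specificity,
         pretest = spec$incidence, posttest_pos = ppv, posttest_neg = 1 - npv,
         nns = round_half_up(1 / (spec$incidence * sens)),
         population = pop, incidence = spec$incidence),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Screening projection: %s (n = %s, incidence %.1f%%)\n",
              x$label, format(x$population, big.mark = ","),
              100 * x$incidence))
  cat(sprintf("  sens %.1f%%  spec %.1f%%\n", 100 * x$sensitivity_adjusted,
              100 * x$specificity))
  cat(sprintf("  TP %s  FP %s  TN %s  FN %s\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$tn, big.mark = ","), format(x$fn, big.mark = ",")))
  cat(sprintf("  PPV %.1f%%  NPV %.1f%%  LR+ %.1f  LR- %.1f  NNS %d\n",
              100 * x$ppv, 100 * x$npv, round_half_up(x$lr_pos, 1),
              round_half_up(x$lr_neg, 1), x$nns))
  invisible(x)
}

#' Compare projected scenarios
#'
#' Tabulates each scenario's projection plus the posttest-positive to
#' posttest-negative probability ratio, and pairwise fold changes of the
#' false-positive rate and of detected cases, each at the one-decimal
#' precision of the reported rates.
#'
#' @param results List of [project()] results (at least 2).
#' @return List with `table` (one row per scenario) and `pairwise` (rows
#'   `a, b, fp_rate_fold, case_fold, case_reduction_pct`).
#' @export
compare_scenarios <- function(results) {
  if (length(results) < 2) stopf("need at least two scenarios to compare")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label,
               sensitivity = r$sensitivity_adjusted,
               specificity = r$specificity,
               tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
               fp_rate_pct = round_half_up(100 * r$fp / (r$fp + r$tn), 1),
               ppv = r$ppv, npv = r$npv,
               lr_pos = r$lr_pos, lr_neg = r$lr_neg,
               posttest_ratio = round_half_up(r$posttest_pos / r$posttest_neg, 1),
               nns = r$nns, stringsAsFactors = FALSE)
  }))
  pairs <- expand.grid(a = seq_along(results), b = seq_along(results))
  pairs <- pairs[pairs$a != pairs$b, ]
  pairwise <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ra <- results[[pairs$a[i]]]
    rb <- results[[pairs$b[i]]]
    fpr_a <- round_half_up(100 * ra$fp / (ra$fp + ra$tn), 1)
    fpr_b <- round_half_up(100 * rb$fp / (rb$fp + rb$tn), 1)
    data.frame(a = ra$label, b = rb$label,
               fp_rate_fold = round_half_up(fpr_a / fpr_b, 1),
               case_fold = round_half_up(ra$tp / rb$tp, 1),
               case_reduction_pct = round_half_up(100 * (ra$tp - rb$tp) / ra$tp, 1),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, pairwise = pairwise)
}
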