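#' Specify per-test screening costs
#'
#' @param cost_step1_per_test Cost of the first-line test per individual
#'   (default $80, the marker-panel test).
#' @param cost_step2_per_test Incremental cost of the sequencing-based test
#'   when run as a follow-up that reuses the step-1 marker results (default
#'   $670).
#' @param cost_standalone Named costs per individual for standalone
#'   strategies (defaults: SeekInCare $750, Galleri $949).
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(cost_step1_per_test = 80,
                      cost_step2_per_test = 670,
                      cost_standalone = c(SeekInCare = 750, Galleri = 949)) {
  stopifnot(cost_step1_per_test >= 0, cost_step2_per_test >= 0,
            all(cost_standalone >= 0))
  structure(list(cost_step1_per_test = cost_step1_per_test,
                 cost_step2_per_test = cost_step2_per_test,
                 cost_standalone = cost_standalone),
            class = "cost_spec")
}

# ratios are stored exact; rounding happens only at display time
cost_result <- function(total, population, tp) {
  structure(
    list(total = total,
         per_case_detected = if (tp > 0) total / tp else NA_real_,
         per_individual_screened = total / population,
         total_millions = total / 1e6,
         population = population, tp = tp),
    class = "cost_result"
  )
}

#' Cost of a single-test screening strategy
#'
#' Every individual takes the one test: `total = population * per_test`.
#' Cost per case detected divides by true positives only (a screen's yield
#' is confirmed cancers); it is reported absent when no case is detected.
#'
#' @param population Individuals screened.
#' @param per_test Cost per individual.
#' @param tp Projected true positives (cases detected).
#' @return An object of class `cost_result`: `total`, `per_case_detected`,
#'   `per_individual_screened`, `total_millions`.
#' @export
one_step_cost <- function(population, per_test, tp) {
  population <- assert_count(population, "population")
  stopifnot(per_test >= 0, tp >= 0)
  cost_result(as.numeric(population) * per_test, population, tp)
}

#' Cost of the two-step cascade strategy
#'
#' Everyone takes the cheap first-line test; only step-1 positives take the
#' follow-up: `total = population * step1 + step1_positives * step2`.
#'
#' @param population Individuals screened.
#' @param step1_positive_count Individuals testing positive at step 1 (the
#'   projected TP + FP of the first-line scenario).
#' @param costs A [cost_spec()].
#' @param tp Projected true positives of the cascade.
#' @return A `cost_result`.
#' @export
two_step_cost <- function(population, step1_positive_count, costs, tp) {
  population <- assert_count(population, "population")
  if (!inherits(costs, "cost_spec")) stopf("costs must be a cost_spec")
  stopifnot(step1_positive_count >= 0, step1_positive_count <= population,
            tp >= 0)
  total <- as.numeric(population) * costs$cost_step1_per_test +
    as.numeric(step1_positive_count) * costs$cost_step2_per_test
  cost_result(total, population, tp)
}

#' Fold comparison of two strategies' costs
#'
#' @param result_a,result_b `cost_result` objects with positive totals.
#' @return List with `total_fold` and `per_case_fold`, each
#'   `a / b` to one decimal.
#' @export
cost_fold_comparison <- function(result_a, result_b) {
  if (result_a$total <= 0 || result_b$total <= 0) {
    stopf("both totals must be positive")
  }
  list(total_fold = round_half_up(result_a$total / result_b$total, 1),
       per_case_fold = round_half_up(
         result_a$per_case_detected / result_b$per_case_detected, 1))
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("Screening cost: total $%.1fM, per case detected $%s, per individual $%s\n",
              round_half_up(x$total_millions, 1),
              format(round_half_up(x$per_case_detected), big.mark = ","),
              format(round_half_up(x$per_individual_screened), big.mark = ",")))
  invisible(x)
}
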