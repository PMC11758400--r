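#' Run the two-step screening cascade
#'
#' Every subject gets the marker-panel POC. Subjects with `POC >= poc_cutoff`
#' are "initially positive" and proceed to the second, sequencing-based step,
#' where `CRS >= crs_cutoff` confirms the call; everyone else is predicted
#' noncancer. Subjects screened out at step 1 never receive a CRS.
#'
#' @param poc_model Fitted [fit_poc()] model.
#' @param crs_model Fitted [fit_crs()] model.
#' @param records Cohort data frame to screen.
#' @param poc_cutoff Step-1 cutoff, default 0.5 (the boundary is positive).
#' @param crs_cutoff Step-2 cutoff, default 2.0 (the boundary is positive).
#' @return A data frame of class `cascade_result` with one row per subject:
#'   `id, poc, step1_call, crs` (`NA` unless tested), `final_call`
#'   (`cancer_predicted`/`noncancer_predicted`), `step_reached`.
#' @export
run_cascade <- function(poc_model, crs_model, records,
                        poc_cutoff = 0.5, crs_cutoff = 2.0) {
  check_cohort(records)
  poc <- tryCatch(score_poc(poc_model, records), error = function(e) {
    stopf("POC scoring failed (first id %s): %s", records$id[1],
          conditionMessage(e))
  })
  step1 <- classify_poc(poc, poc_cutoff)
  crs <- rep(NA_real_, nrow(records))
  tested <- step1 == "positive"
  if (any(tested)) {
    crs[tested] <- score_crs(crs_model, records[tested, , drop = FALSE],
                             poc[tested])
  }
  final <- ifelse(tested & crs >= crs_cutoff & !is.na(crs),
                  "cancer_predicted", "noncancer_predicted")
  out <- data.frame(id = records$id, poc = poc, step1_call = step1,
                    crs = crs, final_call = final,
                    step_reached = ifelse(tested, 2L, 1L),
                    stringsAsFactors = FALSE)
  class(out) <- c("cascade_result", class(out))
  out
}

#' Summarize cascade performance against truth labels
#'
#' Sensitivity is computed over true cancer subjects (including unstaged and
#' missing-stage cancers — they are pathology-confirmed cases), specificity
#' over true noncancer subjects, and the second-step usage count is the
#' number of subjects who reached step 2. A class with no members yields
#' `NA` for its rate.
#'
#' @param results A `cascade_result` from [run_cascade()].
#' @param truth Data frame with columns `id` and `group`, or a cohort.
#' @return List: `sensitivity`, `specificity`, `n_second_step`, confusion
#'   counts, and the step-1 rates for comparison.
#' @export
cascade_performance <- function(results, truth) {
  if (!all(c("id", "group") %in% names(truth))) {
    stopf("truth must carry columns 'id' and 'group'")
  }
  if (!setequal(results$id, truth$id) || nrow(results) != nrow(truth)) {
    stopf("cascade results and truth labels do not align by id")
  }
  truth <- truth[match(results$id, truth$id), ]
  pos <- as_positive(truth$group)
  called <- results$final_call == "cancer_predicted"
  step1_pos <- results$step1_call == "positive"

  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    sensitivity = rate(sum(called & pos), sum(pos)),
    specificity = rate(sum(!called & !pos), sum(!pos)),
    n_second_step = sum(results$step_reached == 2L),
    tp = sum(called & pos), fp = sum(called & !pos),
    tn = sum(!called & !pos), fn = sum(!called & pos),
    step1_sensitivity = rate(sum(step1_pos & pos), sum(pos)),
    step1_specificity = rate(sum(!step1_pos & !pos), sum(!pos))
  )
}

#' Export cascade results as CSV
#'
#' @param results A `cascade_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cascade <- function(results, path) {
  out <- as.data.frame(results)
  out$poc <- formatC(out$poc, digits = 6, format = "g")
  out$crs <- ifelse(is.na(out$crs), "",
                    formatC(out$crs, digits = 6, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
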