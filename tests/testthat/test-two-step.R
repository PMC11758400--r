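make_cascade_df <- function(id, poc, crs) {
  step1 <- ifelse(poc >= 0.5, "positive", "negative")
  crs[step1 == "negative"] <- NA
  out <- data.frame(
    id = id, poc = poc, step1_call = step1, crs = crs,
    final_call = ifelse(step1 == "positive" & !is.na(crs) & crs >= 2,
                        "cancer_predicted", "noncancer_predicted"),
    step_reached = ifelse(step1 == "positive", 2L, 1L),
    stringsAsFactors = FALSE)
  class(out) <- c("cascade_result", class(out))
  out
}

test_that("cascade summary matches the hand-traced toy cohort", {
  # 4 cancers (POC .8/.8/.6/.2, CRS 2.5/1.5/3.0 for the three tested) and
  # 4 noncancers (POC .1/.6/.7/.4, CRS 1.0/2.2 for the two tested)
  res <- make_cascade_df(
    id = sprintf("P%d", 1:8),
    poc = c(0.8, 0.8, 0.6, 0.2, 0.1, 0.6, 0.7, 0.4),
    crs = c(2.5, 1.5, 3.0, NA, NA, 1.0, 2.2, NA))
  truth <- data.frame(id = sprintf("P%d", 1:8),
                      group = rep(c("cancer", "noncancer"), each = 4))
  perf <- cascade_performance(res, truth)
  expect_equal(perf$sensitivity, 2 / 4)
  expect_equal(perf$specificity, 3 / 4)
  expect_equal(perf$n_second_step, 5)
})

test_that("a one-class cohort reports the undefined rate as NA", {
  res <- make_cascade_df(id = c("a", "b"), poc = c(0.1, 0.2), crs = c(NA, NA))
  truth <- data.frame(id = c("a", "b"), group = "noncancer")
  perf <- cascade_performance(res, truth)
  expect_equal(perf$specificity, 1.0)
  expect_true(is.na(perf$sensitivity))
})

test_that("misaligned ids are rejected", {
  res <- make_cascade_df(id = c("a", "b"), poc = c(0.6, 0.2), crs = c(2.5, NA))
  truth <- data.frame(id = c("a", "x"), group = c("cancer", "noncancer"))
  expect_error(cascade_performance(res, truth), "align")
})

test_that("cascade structure holds on generated cohorts", {
  for (seed in c(3, 14)) {
    cohort <- generate_cohort(cohort_spec(n_cancer = 220, n_noncancer = 220),
                              seed = seed)
    poc_model <- fit_poc(cohort)
    crs_model <- fit_crs(cohort, poc_model, step = 0.1)
    res <- run_cascade(poc_model, crs_model, cohort)

    # CRS present exactly for step-1 positives
    expect_identical(is.na(res$crs), res$step1_call == "negative")
    expect_identical(res$step_reached == 2L, res$step1_call == "positive")
    expect_equal(sum(res$step_reached == 2L), sum(res$poc >= 0.5))

    # final positives are a subset of step-1 positives
    final_pos <- res$final_call == "cancer_predicted"
    expect_true(all(res$step1_call[final_pos] == "positive"))
    expect_true(all(res$crs[final_pos] >= 2.0))

    perf <- cascade_performance(res, cohort)
    expect_gte(perf$specificity, perf$step1_specificity)
    expect_lte(perf$sensitivity, perf$step1_sensitivity)
  }
})

test_that("the default cohort lands on the published cascade operating point", {
  perf <- sapply(1:3, function(s) {
    cohort <- generate_cohort(cohort_spec(), seed = s)
    poc_model <- fit_poc(cohort)
    crs_model <- fit_crs(cohort, poc_model)
    cp <- cascade_performance(run_cascade(poc_model, crs_model, cohort),
                              cohort)
    c(sens = cp$sensitivity, spec = cp$specificity)
  })
  # second-step triage trades sensitivity for near-perfect specificity
  expect_lt(abs(mean(perf["sens", ]) - 0.399), 0.06)
  expect_lt(abs(mean(perf["spec", ]) - 0.993), 0.007)
})

test_that("cascade results export to CSV with ids and calls intact", {
  cohort <- generate_cohort(small_cohort_spec(), seed = 23)
  poc_model <- fit_poc(cohort)
  crs_model <- fit_crs(cohort, poc_model, step = 0.25)
  res <- run_cascade(poc_model, crs_model, cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cascade(res, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$id, res$id)
  expect_equal(back$final_call, res$final_call)
  expect_equal(sum(back$step_reached == 2), sum(res$step_reached == 2))
})
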