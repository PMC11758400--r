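test_that("binormal shift inverts the theoretical AUC map", {
  expect_identical(binormal_shift(0.5), 0)
  # frozen from an independent inverse-normal oracle (scipy.stats.norm.ppf)
  expect_equal(binormal_shift(0.877), 1.64065727, tolerance = 1e-7)
  expect_equal(binormal_shift(0.654), 0.56022992, tolerance = 1e-7)
  expect_error(binormal_shift(0.49), "0.5")
  expect_error(binormal_shift(1), "0.5")
  expect_error(binormal_shift(NA_real_), "single")
})

test_that("binormal shift reproduces target AUC in Monte-Carlo", {
  # 1e6 simulated case/control pairs: empirical AUC within +-0.001
  set.seed(42)
  n <- 1e6
  for (target in c(0.654, 0.877)) {
    delta <- binormal_shift(target)
    mc <- mean(rnorm(n, mean = delta) > rnorm(n))
    expect_equal(mc, target, tolerance = 2e-3)
  }
})

test_that("generated cohorts have the requested size, groups and stages", {
  spec <- cohort_spec()
  cohort <- generate_cohort(spec, seed = 11)
  expect_equal(nrow(cohort), 1197)
  expect_equal(sum(cohort$group == "cancer"), 617)
  expect_equal(sum(cohort$group == "noncancer"), 580)
  expect_true(all(is.na(cohort$stage[cohort$group == "noncancer"])))
  expect_true(all(cohort$stage[cohort$group == "cancer"] %in%
                    c("I", "II", "III", "IV", "not_staged", "missing")))
  for (m in c("afp", "ca125", "ca153", "ca199", "ca724", "cea", "cyfra211")) {
    expect_true(all(cohort[[m]] > 0))
  }
})

test_that("cohort generation is deterministic given spec and seed", {
  spec <- small_cohort_spec()
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 8)
  expect_false(identical(a, c))
})

test_that("cohort generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_cohort(small_cohort_spec(), seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("feature scores hit their AUC calibration targets", {
  targets <- c(cna = 0.797, fs = 0.865, endmotif = 0.877, virus = 0.654)
  aucs <- sapply(1:3, function(s) {
    cohort <- generate_cohort(cohort_spec(), seed = s)
    lab <- cohort$group == "cancer"
    vapply(names(targets), function(f) {
      empirical_auc(cohort[[f]][lab], cohort[[f]][!lab])
    }, numeric(1))
  })
  expect_equal(rowMeans(aucs), targets, tolerance = 0.035)
})

test_that("null AUC targets yield uninformative features", {
  spec <- cohort_spec(feature_auc_targets = c(cna = 0.5, fs = 0.5,
                                              endmotif = 0.5, virus = 0.5))
  cohort <- generate_cohort(spec, seed = 21)
  lab <- cohort$group == "cancer"
  for (f in c("cna", "fs", "endmotif", "virus")) {
    auc <- empirical_auc(cohort[[f]][lab], cohort[[f]][!lab])
    expect_gt(auc, 0.45)
    expect_lt(auc, 0.55)
  }
})

test_that("cancer stage proportions follow the spec distribution", {
  spec <- cohort_spec(n_cancer = 10000, n_noncancer = 1)
  cohort <- generate_cohort(spec, seed = 5)
  props <- table(cohort$stage[cohort$group == "cancer"]) / 10000
  for (s in names(spec$stage_probs)) {
    expect_lt(abs(props[[s]] - spec$stage_probs[[s]]), 0.02)
  }
})

test_that("marker positivity is non-decreasing across stages I-IV", {
  spec <- cohort_spec(n_cancer = 8000, n_noncancer = 1)
  cohort <- generate_cohort(spec, seed = 13)
  cancer <- cohort[cohort$group == "cancer", ]
  pos_by_stage <- vapply(c("I", "II", "III", "IV"), function(s) {
    ptm_positivity(cancer[cancer$stage == s, ])[["any"]]
  }, numeric(1))
  expect_true(all(diff(pos_by_stage) >= 0))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_cancer = 0), "positive integer")
  expect_error(cohort_spec(stage_probs = c(I = 0.5, II = 0.5, III = 0,
                                           IV = 0, not_staged = 0,
                                           missing = 0.1)), "sum to 1")
  expect_error(cohort_spec(feature_auc_targets = c(cna = 1.0, fs = 0.8,
                                                   endmotif = 0.8,
                                                   virus = 0.6)),
               "AUC targets")
  expect_error(cohort_spec(feature_cor = 1.2), "unit interval")
})

test_that("cohort files round-trip at the stated precision", {
  cohort <- generate_cohort(small_cohort_spec(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$id, cohort$id)
  expect_equal(back$group, cohort$group)
  expect_equal(back$stage, cohort$stage)
  for (col in c("afp", "ca125", "ca153", "ca199", "ca724", "cea", "cyfra211",
                "cna", "fs", "endmotif", "virus")) {
    expect_equal(back[[col]], signif(cohort[[col]], 6), tolerance = 1e-6)
  }
  # second round trip is exact: 6-significant-digit text is a fixed point
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(read_cohort(path2), back)
})

test_that("an empty cohort writes a header-only file and reads back empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- generate_cohort(small_cohort_spec(), seed = 1)[0, ]
  write_cohort(empty, path)
  expect_identical(readLines(path)[1],
                   paste("id,group,stage,age,sex,afp,ca125,ca153,ca199,ca724",
                         "cea,cyfra211,cna,fs,endmotif,virus", sep = ","))
  back <- read_cohort(path)
  expect_equal(nrow(back), 0)
})

test_that("malformed cohort files fail with row/column context", {
  cohort <- generate_cohort(small_cohort_spec(n_cancer = 5, n_noncancer = 5),
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)

  lines <- readLines(path)
  # drop the cyfra211 column entirely
  broken <- gsub(",cyfra211", "", lines[1])
  drop_col <- sapply(strsplit(lines[-1], ","), function(x) {
    paste(x[-12], collapse = ",")
  })
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(broken, drop_col), path2)
  expect_error(read_cohort(path2), "cyfra211")

  # corrupt one numeric cell
  cells <- strsplit(lines, ",")
  cells[[4]][7] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sapply(cells, paste, collapse = ","), path3)
  expect_error(read_cohort(path3), "row 3, column 'ca125'")
})
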