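test_that("raw CRS is an exact dot product", {
  expect_equal(raw_crs(c(1, 0, 0, 0, 0), c(3.2, 9, -1, 4, 7)), 3.2)
  expect_equal(raw_crs(rep(0.2, 5), rep(1, 5)), 1.0)
  expect_equal(raw_crs(c(0.1, 0.4, 0.3, 0.1, 0.1), c(1, 2, 0, -1, 0.5)), 0.85)
  expect_error(raw_crs(rep(0.2, 5), c(1, 2, NA, 4, 5)), "finite")
  expect_error(raw_crs(c(0.5, 0.5), 1:5), "length 5")
})

test_that("crs_weights enforces the simplex constraint", {
  w <- crs_weights(0.2, 0.2, 0.2, 0.2, 0.2)
  expect_s3_class(w, "crs_weights")
  expect_error(crs_weights(0.5, 0.5, 0.5, 0, 0), "sum to 1")
  expect_error(crs_weights(-0.2, 0.4, 0.4, 0.2, 0.2), "nonnegative")
})

test_that("grid search puts maximal weight on a perfectly separating feature", {
  toy <- toy_crs_features(40, seed = 1, informative = "fs")
  toy$features[toy$labels, "fs"] <- toy$features[toy$labels, "fs"] + 50
  w <- grid_search_weights(toy$features, toy$labels, step = 0.25)
  expect_equal(attr(w, "auc"), 1.0)
  expect_gte(w[["fs"]], 0.25)
})

test_that("grid search equals exhaustive lattice enumeration", {
  for (seed in 1:3) {
    toy <- toy_crs_features(30 + 5 * seed, seed = seed)
    got <- grid_search_weights(toy$features, toy$labels, step = 0.25)
    oracle <- enumerate_grid_oracle(toy$features, toy$labels, step = 0.25)
    expect_equal(as.numeric(got), oracle$weights)
    expect_equal(attr(got, "auc"), oracle$auc)
  }
})

test_that("coarse grid search on a tiny printed table matches hand enumeration", {
  # 6 subjects, 2 features informative; step 0.5 lattice has 15 tuples
  features <- cbind(cna = c(2, 1, 3, -1, 0, -2),
                    fs = c(1, 2, 0.5, 0, -1, -0.5),
                    endmotif = c(0, 0, 0, 0, 0, 0),
                    virus = c(0.1, -0.1, 0.2, 0.1, -0.2, 0),
                    ptm = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- grid_search_weights(features, labels, step = 0.5)
  oracle <- enumerate_grid_oracle(features, labels, step = 0.5)
  expect_equal(as.numeric(got), oracle$weights)
  expect_equal(attr(got, "auc"), 1.0)
})

test_that("duplicated features tie back to the single-feature optimum", {
  toy <- toy_crs_features(40, seed = 9, informative = "cna")
  toy$features[, "fs"] <- toy$features[, "cna"]
  single_auc <- brute_force_auc(toy$features[toy$labels, "cna"],
                                toy$features[!toy$labels, "cna"])
  got <- grid_search_weights(toy$features, toy$labels, step = 0.25)
  expect_gte(attr(got, "auc") + 1e-12, single_auc)
  oracle <- enumerate_grid_oracle(toy$features, toy$labels, step = 0.25)
  expect_equal(attr(got, "auc"), oracle$auc)
})

test_that("grid-search ties break to the lexicographically smallest tuple", {
  # all features identical: every tuple scores the same AUC
  f <- matrix(rep(c(3, 2, 1, 0), 5), ncol = 5,
              dimnames = list(NULL, c("cna", "fs", "endmotif", "virus", "ptm")))
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  w <- grid_search_weights(f, labels, step = 0.5)
  expect_equal(as.numeric(w), c(0, 0, 0, 0, 1))
})

test_that("calibration maps the noncancer upper percentile to the cutoff", {
  raw <- seq(0.00, 0.99, by = 0.01)
  cal <- calibrate_crs(raw, target_specificity = 0.98, cutoff = 2.0)
  mapped <- cal$scale * raw + cal$offset
  expect_equal(unname(quantile(mapped, 0.98, type = 7)), 2.0)
  expect_equal(unname(median(mapped)), 0)
  expect_gt(cal$scale, 0)
})

test_that("calibration of already-calibrated scores is the identity", {
  set.seed(8)
  raw <- rnorm(400)
  cal <- calibrate_crs(raw)
  mapped <- cal$scale * raw + cal$offset
  cal2 <- calibrate_crs(mapped)
  expect_equal(cal2$scale, 1, tolerance = 1e-9)
  expect_equal(cal2$offset, 0, tolerance = 1e-9)
})

test_that("calibration rejects degenerate or underpowered input", {
  expect_error(calibrate_crs(rep(1, 100)), "degenerate")
  expect_error(calibrate_crs(rnorm(20)), ">= 50")
})

test_that("the 2.0 CRS cutoff boundary is inclusive", {
  expect_identical(classify_crs(2.0), "positive")
  expect_identical(classify_crs(1.999), "negative")
  expect_identical(classify_crs(-5), "negative")
})

test_that("fitted CRS dominates every single feature and controls the FPR", {
  cohort <- generate_cohort(cohort_spec(n_cancer = 250, n_noncancer = 250),
                            seed = 41)
  lab <- cohort$group == "cancer"
  poc_model <- fit_poc(cohort)
  model <- fit_crs(cohort, poc_model)
  crs <- score_crs(model, cohort, score_poc(poc_model, cohort))
  crs_auc <- empirical_auc(crs[lab], crs[!lab])

  single <- vapply(c("cna", "fs", "endmotif", "virus"), function(f) {
    empirical_auc(cohort[[f]][lab], cohort[[f]][!lab])
  }, numeric(1))
  # the lattice contains the pure projections, so the search can't do worse
  expect_gte(crs_auc, max(single) - 0.01)

  # training noncancer above the cutoff at most the calibrated tail + 1/n
  n_nc <- sum(!lab)
  expect_lte(mean(crs[!lab] >= 2.0), 0.02 + 1 / n_nc)
})

test_that("CRS models serialize and score identically after reload", {
  cohort <- generate_cohort(small_cohort_spec(), seed = 43)
  poc_model <- fit_poc(cohort)
  model <- fit_crs(cohort, poc_model, step = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_crs_model(model, path)
  back <- read_crs_model(path)
  poc <- score_poc(poc_model, cohort)
  expect_equal(score_crs(back, cohort, poc), score_crs(model, cohort, poc))
})
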