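# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: AUC by explicit all-pairs comparison, grid
# search by nested-loop enumeration.

brute_force_auc <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive enumeration of the simplex lattice with lexicographic
# tie-break, scoring each tuple by the all-pairs AUC
enumerate_grid_oracle <- function(features, labels, step) {
  k <- round(1 / step)
  best_auc <- -Inf
  best_w <- NULL
  for (a in 0:k) for (b in 0:(k - a)) for (cc in 0:(k - a - b)) {
    for (d in 0:(k - a - b - cc)) {
      e <- k - a - b - cc - d
      w <- c(a, b, cc, d, e) / k
      s <- as.matrix(features) %*% w
      auc <- brute_force_auc(s[labels], s[!labels])
      if (auc > best_auc + 1e-12) {
        best_auc <- auc
        best_w <- w
      }
    }
  }
  list(weights = best_w, auc = best_auc)
}

# small feature set with one strongly informative column
toy_crs_features <- function(n, seed, informative = "fs") {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), length.out = n)
  f <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("cna", "fs", "endmotif", "virus", "ptm")))
  f[labels, informative] <- f[labels, informative] + 2
  list(features = f, labels = labels)
}

# a down-scaled cohort spec so model-fitting tests stay fast
small_cohort_spec <- function(n_cancer = 120, n_noncancer = 120, ...) {
  cohort_spec(n_cancer = n_cancer, n_noncancer = n_noncancer, ...)
}

# hand-constructed POC model: given per-marker coefficients on the log10
# scale with no winsorization (caps at Inf)
hand_poc_model <- function(intercept, coefficients) {
  markers <- c("afp", "ca125", "ca153", "ca199", "ca724", "cea", "cyfra211")
  coefs <- stats::setNames(rep(0, 7), markers)
  coefs[names(coefficients)] <- coefficients
  structure(list(intercept = intercept, coefficients = coefs,
                 caps = stats::setNames(rep(Inf, 7), markers),
                 transform = "log10", separable = FALSE, seed = 0L,
                 n_train = 0L),
            class = "poc_model")
}

# one marker row template for building tiny cohorts by hand
blank_records <- function(n) {
  out <- data.frame(id = sprintf("T%03d", seq_len(n)),
                    group = rep("noncancer", n), stage = NA_character_,
                    age = 50, sex = "female", stringsAsFactors = FALSE)
  for (m in c("afp", "ca125", "ca153", "ca199", "ca724", "cea", "cyfra211")) {
    out[[m]] <- 1
  }
  for (f in c("cna", "fs", "endmotif", "virus")) out[[f]] <- 0
  out
}
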