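PIPELINE_SCHEMA <- list(
  seed = NULL,
  out_dir = NULL,
  cohort = list(n_cancer = NULL, n_noncancer = NULL, stage_probs = NULL,
                feature_auc_targets = NULL, feature_cor = NULL,
                channel_cor = NULL),
  model = list(grid_step = NULL, poc_cutoff = NULL, crs_cutoff = NULL,
               crs_target_specificity = NULL),
  projection = list(population = NULL, incidence = NULL,
                    sens_retrospective_ref = NULL,
                    sens_prospective_ref = NULL,
                    scenarios = NULL),
  cost = list(step1_per_test = NULL, step2_per_test = NULL,
              standalone = NULL),
  verbose = NULL
)

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with sections `seed`, `cohort`, `model`,
#' `projection` (including the scenario list), and `cost`. Unknown keys are
#' rejected so typos fail loudly before any stage runs; required fields are
#' checked with the offending name in the error.
#'
#' @param path YAML file path.
#' @return The validated config list.
#' @seealso [default_config()] for the bundled configuration reproducing the
#'   published five-million-person projection.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
default_config <- function() {
  read_pipeline_config(system.file("extdata", "default_config.yaml",
                                   package = "mcedsim", mustWork = TRUE))
}

validate_config <- function(config) {
  check_keys <- function(x, schema, where) {
    unknown <- setdiff(names(x), names(schema))
    if (length(unknown)) {
      stopf("unknown config key(s) under '%s': %s", where,
            paste(unknown, collapse = ", "))
    }
    for (k in names(x)) {
      if (is.list(schema[[k]]) && length(schema[[k]])) {
        if (!is.list(x[[k]])) stopf("config section '%s.%s' must be a mapping",
                                    where, k)
        check_keys(x[[k]], schema[[k]], paste(where, k, sep = "."))
      }
    }
  }
  check_keys(config, PIPELINE_SCHEMA, "config")
  need <- function(val, name) {
    if (is.null(val)) stopf("config is missing required field '%s'", name)
    val
  }
  need(config$seed, "seed")
  proj <- need(config$projection, "projection")
  need(proj$population, "projection.population")
  need(proj$incidence, "projection.incidence")
  scenarios <- need(proj$scenarios, "projection.scenarios")
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    for (f in c("label", "sensitivity_case_control", "specificity")) {
      need(sc[[f]], sprintf("projection.scenarios[%d].%s", i, f))
    }
    ok <- c("label", "sensitivity_case_control", "specificity", "adjustment",
            "cost_per_test", "two_step")
    unknown <- setdiff(names(sc), ok)
    if (length(unknown)) {
      stopf("unknown scenario key(s) for '%s': %s", sc$label,
            paste(unknown, collapse = ", "))
    }
  }
  config
}

config_cohort_spec <- function(config) {
  co <- config$cohort %||% list()
  args <- list()
  if (!is.null(co$n_cancer)) args$n_cancer <- co$n_cancer
  if (!is.null(co$n_noncancer)) args$n_noncancer <- co$n_noncancer
  if (!is.null(co$stage_probs)) args$stage_probs <- unlist(co$stage_probs)
  if (!is.null(co$feature_auc_targets)) {
    args$feature_auc_targets <- unlist(co$feature_auc_targets)
  }
  if (!is.null(co$feature_cor)) args$feature_cor <- co$feature_cor
  if (!is.null(co$channel_cor)) args$channel_cor <- co$channel_cor
  do.call(cohort_spec, args)
}

config_scenarios <- function(config) {
  proj <- config$projection
  lapply(proj$scenarios, function(sc) {
    scenario_spec(
      label = sc$label,
      population = proj$population,
      incidence = proj$incidence,
      sensitivity_case_control = sc$sensitivity_case_control,
      specificity = sc$specificity,
      adjustment = sc$adjustment %||% "proportional",
      sens_retrospective_ref = proj$sens_retrospective_ref %||% 0.515,
      sens_prospective_ref = proj$sens_prospective_ref %||% 0.289
    )
  })
}

#' Project all configured scenarios and their costs
#'
#' Runs the closed-form projection for every scenario in the config and
#' attaches each strategy's screening cost: standalone strategies pay their
#' per-test price for everyone; a scenario marked `two_step` pays the
#' first-line price for everyone plus the follow-up price for the projected
#' step-1 positives (the TP + FP of its designated first-line scenario).
#'
#' @param config A validated pipeline config (see [default_config()]).
#' @return List with `projections`, `costs` (parallel lists, named by
#'   label), and `comparison` from [compare_scenarios()].
#' @export
project_scenarios <- function(config) {
  config <- validate_config(config)
  specs <- config_scenarios(config)
  projections <- lapply(specs, project)
  names(projections) <- vapply(projections, `[[`, "", "label")

  cost_cfg <- config$cost %||% list()
  costs <- lapply(seq_along(specs), function(i) {
    sc <- config$projection$scenarios[[i]]
    pr <- projections[[i]]
    if (!is.null(sc$two_step) && !isFALSE(sc$two_step)) {
      step1_label <- if (is.character(sc$two_step)) sc$two_step else
        config$projection$scenarios[[1]]$label
      p1 <- projections[[step1_label]]
      if (is.null(p1)) stopf("two-step scenario '%s' references unknown step-1 scenario '%s'",
                             sc$label, step1_label)
      two_step_cost(pr$population, p1$tp + p1$fp,
                    cost_spec(cost_step1_per_test = cost_cfg$step1_per_test %||% 80,
                              cost_step2_per_test = cost_cfg$step2_per_test %||% 670),
                    pr$tp)
    } else {
      per_test <- sc$cost_per_test %||%
        cost_cfg$standalone[[sc$label]] %||%
        stopf("no cost configured for scenario '%s'", sc$label)
      one_step_cost(pr$population, per_test, pr$tp)
    }
  })
  names(costs) <- names(projections)
  list(projections = projections, costs = costs,
       comparison = compare_scenarios(projections))
}

#' Render the projection as a strategy-by-strategy table
#'
#' Rows follow the published report order — sensitivity through NNS, then
#' the cost block (total, per patient with cancer identified, per individual
#' screened) — one column per strategy. Percentages and likelihood ratios
#' are shown to one decimal, counts to whole people, totals in $ millions.
#'
#' @param projections Named list of [project()] results.
#' @param costs Parallel named list of cost results (optional).
#' @return List with `text` (character vector of rendered lines) and `data`
#'   (the same cells as a data frame, row labels in column 1).
#' @export
render_table3 <- function(projections, costs = NULL) {
  pct <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))
  num <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)
  one <- function(x) sprintf("%.1f", round_half_up(x, 1))
  millions <- function(x) {
    m <- round_half_up(x / 1e6, 1)
    if (abs(m - round(m)) < 1e-9) sprintf("$%s million", num(round(m)))
    else sprintf("$%s million", format(m, big.mark = ",", nsmall = 1))
  }
  rows <- list(
    "Sensitivity" = function(p, cst) pct(p$sensitivity_adjusted),
    "Specificity" = function(p, cst) pct(p$specificity),
    "Number of true positives" = function(p, cst) num(p$tp),
    "Number of false positives" = function(p, cst) num(p$fp),
    "Number of true negatives" = function(p, cst) num(p$tn),
    "Number of false negatives" = function(p, cst) num(p$fn),
    "PPV" = function(p, cst) pct(p$ppv),
    "Negative predictive value" = function(p, cst) pct(p$npv),
    "Positive likelihood ratio" = function(p, cst) one(p$lr_pos),
    "Negative likelihood ratio" = function(p, cst) one(p$lr_neg),
    "Pretest probability" = function(p, cst) pct(p$pretest),
    "Posttest probability for positive test" = function(p, cst) pct(p$posttest_pos),
    "Posttest probability for negative test" = function(p, cst) pct(p$posttest_neg),
    "NNS" = function(p, cst) num(p$nns)
  )
  cost_rows <- list(
    "Total" = function(p, cst) millions(cst$total),
    "Per patient with cancer identified" = function(p, cst)
      sprintf("$%s", num(round_half_up(cst$per_case_detected))),
    "Per individual screened" = function(p, cst)
      sprintf("$%s", num(round_half_up(cst$per_individual_screened)))
  )
  labels <- names(projections)
  cells <- function(rowset) {
    do.call(rbind, lapply(names(rowset), function(rn) {
      vals <- vapply(labels, function(l) {
        rowset[[rn]](projections[[l]], costs[[l]])
      }, character(1))
      data.frame(row = rn, t(vals), stringsAsFactors = FALSE,
                 check.names = FALSE)
    }))
  }
  df <- if (length(projections)) cells(rows) else
    data.frame(row = character(), stringsAsFactors = FALSE)
  if (!is.null(costs) && length(projections)) df <- rbind(df, cells(cost_rows))
  if (length(labels)) colnames(df) <- c("row", labels)

  widths <- c(max(nchar(c("", df$row)), 0),
              vapply(labels, function(l) max(nchar(c(l, df[[l]]))), numeric(1)))
  fmt_line <- function(vals) {
    paste(mapply(formatC, vals, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  }
  text <- c(fmt_line(c("", labels)),
            vapply(seq_len(nrow(df)), function(i) {
              fmt_line(unlist(df[i, , drop = TRUE]))
            }, character(1)))
  list(text = text, data = df)
}

#' Run the full simulation-to-report pipeline
#'
#' Executes the stages end to end: generate the synthetic cohort, fit the
#' POC marker model and the CRS integration, run the two-step cascade,
#' compute case-control metrics, project the configured screening scenarios,
#' and cost them. All outputs are written under `out_dir`: `cohort.csv`,
#' `poc_model.json`, `crs_model.json`, `cascade.csv`, `metrics.json`,
#' `projection.json`, `table3.txt`/`table3.csv`, and a `manifest.json`
#' recording the config hash, seed and versions. Identical config and seed
#' reproduce every output byte for byte.
#'
#' @param config Config list (see [read_pipeline_config()]) or a YAML path.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the cohort, fitted models, cascade
#'   results, metrics, projections, costs and output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    stopf("config is missing required field 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verbose <- isTRUE(config$verbose)
  say <- function(stage) if (verbose) message(sprintf("[mcedsim] %s", stage))
  seed <- config$seed
  model_cfg <- config$model %||% list()

  say("stage 1/6: generating cohort")
  spec <- config_cohort_spec(config)
  cohort <- generate_cohort(spec, seed = seed)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  say("stage 2/6: fitting POC marker model")
  poc_model <- fit_poc(cohort, seed = seed)
  write_poc_model(poc_model, file.path(out_dir, "poc_model.json"))

  say("stage 3/6: fitting CRS integration (grid search)")
  crs_model <- fit_crs(cohort, poc_model,
                       step = model_cfg$grid_step %||% 0.05,
                       target_specificity = model_cfg$crs_target_specificity %||% 0.98,
                       cutoff = model_cfg$crs_cutoff %||% 2.0)
  write_crs_model(crs_model, file.path(out_dir, "crs_model.json"))

  say("stage 4/6: running two-step cascade")
  cascade <- run_cascade(poc_model, crs_model, cohort,
                         poc_cutoff = model_cfg$poc_cutoff %||% 0.5,
                         crs_cutoff = model_cfg$crs_cutoff %||% 2.0)
  write_cascade(cascade, file.path(out_dir, "cascade.csv"))

  say("stage 5/6: case-control metrics")
  metrics <- cohort_metrics(cohort, poc_model, crs_model, cascade,
                            poc_cutoff = model_cfg$poc_cutoff %||% 0.5,
                            crs_cutoff = model_cfg$crs_cutoff %||% 2.0)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("stage 6/6: screening projection and costs")
  proj <- project_scenarios(config)
  jsonlite::write_json(
    list(projections = lapply(proj$projections, unclass),
         costs = lapply(proj$costs, unclass),
         comparison = proj$comparison),
    file.path(out_dir, "projection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  tab <- render_table3(proj$projections, proj$costs)
  writeLines(tab$text, file.path(out_dir, "table3.txt"))
  utils::write.csv(tab$data, file.path(out_dir, "table3.csv"),
                   row.names = FALSE)

  manifest <- list(
    config_sha = config_hash(config),
    seed = seed,
    package = "mcedsim",
    package_version = as.character(utils::packageVersion("mcedsim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = c("cohort.csv", "poc_model.json", "crs_model.json",
                "cascade.csv", "metrics.json", "projection.json",
                "table3.txt", "table3.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, cohort = cohort, poc_model = poc_model,
                 crs_model = crs_model, cascade = cascade, metrics = metrics,
                 projections = proj$projections, costs = proj$costs,
                 comparison = proj$comparison, table = tab,
                 out_dir = out_dir))
}

# case-control performance bundle for the metrics report
cohort_metrics <- function(cohort, poc_model, crs_model, cascade,
                           poc_cutoff = 0.5, crs_cutoff = 2.0) {
  labels <- cohort$group == "cancer"
  poc <- score_poc(poc_model, cohort)
  crs_all <- score_crs(crs_model, cohort, poc)
  feature_aucs <- vapply(GENOMIC_FEATURES, function(f) {
    empirical_auc(cohort[[f]][labels], cohort[[f]][!labels])
  }, numeric(1))
  dl <- delong_test(poc, crs_all, labels)
  poc_op <- sens_spec_at(poc, labels, poc_cutoff)
  crs_op <- sens_spec_at(crs_all, labels, crs_cutoff)
  casc <- cascade_performance(cascade, cohort)
  list(
    n = nrow(cohort), n_cancer = sum(labels), n_noncancer = sum(!labels),
    poc_auc = empirical_auc(poc[labels], poc[!labels]),
    crs_auc = empirical_auc(crs_all[labels], crs_all[!labels]),
    feature_aucs = as.list(feature_aucs),
    delong = list(z = dl$z, p = dl$p),
    poc_operating_point = poc_op[c("sensitivity", "specificity",
                                   "sensitivity_ci", "specificity_ci")],
    crs_operating_point = crs_op[c("sensitivity", "specificity",
                                   "sensitivity_ci", "specificity_ci")],
    cascade = casc
  )
}

# deterministic hash of the canonicalized config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
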