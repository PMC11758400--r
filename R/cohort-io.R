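#' Read and write cohort tables
#'
#' Cohorts are exchanged as comma-separated UTF-8 text with one header row
#' and the fixed column set
#' `id,group,stage,age,sex,afp,ca125,ca153,ca199,ca724,cea,cyfra211,cna,fs,endmotif,virus`.
#' Floating values are written at 6 significant digits; a write/read
#' round-trip reproduces every field at that precision. `read_cohort`
#' validates the schema and reports the first offending row and column on a
#' malformed file.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort, allow_empty = TRUE)
  out <- cohort[, COHORT_COLUMNS, drop = FALSE]
  for (col in c(PTM_MARKERS, GENOMIC_FEATURES)) {
    out[[col]] <- formatC(out[[col]], digits = 6, format = "g")
  }
  out$stage[is.na(out$stage)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stopf("cohort file %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra)) {
    stopf("cohort file %s has unknown column(s): %s", path,
          paste(extra, collapse = ", "))
  }
  raw <- raw[, COHORT_COLUMNS, drop = FALSE]
  if (nrow(raw) == 0) {
    out <- empty_cohort()
    return(out)
  }
  for (col in c("age", PTM_MARKERS, GENOMIC_FEATURES)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stopf("cohort file %s: non-numeric value '%s' at row %d, column '%s'",
            path, raw[[col]][bad[1]], bad[1], col)
    }
    raw[[col]] <- v
  }
  raw$stage[raw$stage == ""] <- NA_character_
  bad_grp <- which(!raw$group %in% c("cancer", "noncancer"))
  if (length(bad_grp)) {
    stopf("cohort file %s: invalid group '%s' at row %d", path,
          raw$group[bad_grp[1]], bad_grp[1])
  }
  bad_stage <- which(!is.na(raw$stage) & !raw$stage %in% STAGE_LEVELS)
  if (length(bad_stage)) {
    stopf("cohort file %s: invalid stage '%s' at row %d", path,
          raw$stage[bad_stage[1]], bad_stage[1])
  }
  check_cohort(raw, allow_empty = TRUE)
  raw
}

empty_cohort <- function() {
  out <- data.frame(id = character(), group = character(), stage = character(),
                    age = numeric(), sex = character(),
                    stringsAsFactors = FALSE)
  for (col in c(PTM_MARKERS, GENOMIC_FEATURES)) out[[col]] <- numeric()
  out[, COHORT_COLUMNS]
}

check_cohort <- function(cohort, allow_empty = FALSE) {
  if (!is.data.frame(cohort)) stopf("cohort must be a data frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!allow_empty && nrow(cohort) == 0) stopf("cohort has no rows")
  if (nrow(cohort)) {
    for (m in PTM_MARKERS) {
      if (any(!is.finite(cohort[[m]]) | cohort[[m]] <= 0)) {
        stopf("marker '%s' has nonpositive or missing concentrations", m)
      }
    }
    nc <- cohort$group == "noncancer"
    if (any(nc & !is.na(cohort$stage))) {
      stopf("noncancer records must not carry a stage")
    }
  }
  invisible(cohort)
}
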