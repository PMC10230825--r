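CONFIG_SCHEMA <- list(
  simulation = c("tickHours", "durationWeeks", "L", "nClones", "setPoints",
                 "rates", "odcCapacity", "seed"),
  disease = c("rates", "ebvRatePerYear", "ebvMagnitude"),
  grading = c("alcScale"),
  trial = c("name", "arms", "durationWeeks", "readoutStartWeek",
            "readoutWeek", "shared", "seed"),
  cohort = c("size", "demographics", "seed")
)

#' Load and validate a run configuration file
#'
#' Parses a YAML (or JSON) configuration, rejects unknown keys at both
#' levels, fills documented defaults and returns the validated bundle of
#' configuration objects.
#'
#' @param path configuration file path.
#' @return list(simulation = [SimConfig-class], disease =
#'   [DiseaseConfig-class], grading = [GradeConfig-class], trial =
#'   [TrialConfig-class] or NULL, cohort = list or NULL, raw = parsed list).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(y)) {
    bad <- setdiff(names(y[[sec]]), CONFIG_SCHEMA[[sec]])
    if (length(bad))
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  sim <- do.call(simConfig, modifyList(
    list(), lapply(y$simulation %||% list(), unlist_scalar)))
  dis <- do.call(diseaseConfig, lapply(y$disease %||% list(), unlist_scalar))
  grd <- do.call(gradeConfig, lapply(y$grading %||% list(), unlist_scalar))
  trl <- NULL
  if (!is.null(y$trial)) {
    args <- y$trial
    args$arms <- lapply(args$arms, function(a) list(arm = a$arm, n = a$n))
    trl <- do.call(trialConfig, args)
  }
  coh <- y$cohort
  if (!is.null(coh) && !is.null(coh$size) && coh$size <= 0)
    stop("cohort size must be positive")
  list(simulation = sim, disease = dis, grading = grd, trial = trl,
       cohort = coh, raw = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unlist_scalar <- function(x) if (is.list(x)) unlist(x) else x

#' Canonical digest of a configuration
#'
#' @param x any serializable configuration list/object.
#' @return md5 hex digest of the canonical JSON serialization.
#' @export
configDigest <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a trial report and run manifest
#'
#' Writes the report tables as CSVs (relapse table, relapse-free counts,
#' grade table, ARR estimates, relative reductions, Levene result,
#' per-patient records), a JSON summary, and a run manifest listing every
#' output file, the seeds used and the configuration digest — enough to
#' re-run the trial exactly.
#'
#' @param report a [TrialReport-class].
#' @param dir output directory (created if needed).
#' @param trial optional [TrialConfig-class] for seed/digest provenance.
#' @return list of written paths (the manifest last), invisibly.
#' @export
writeReport <- function(report, dir, trial = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = TRUE)
    paths <<- c(paths, p)
    p
  }
  wr(report@relapseTable, "relapse_table.csv")
  wr(data.frame(arm = names(report@relapseFree),
                relapse_free = as.numeric(report@relapseFree)),
     "relapse_free.csv")
  wr(report@gradeTable, "grade_table.csv")
  arrdf <- do.call(rbind, lapply(names(report@arr), function(an) {
    e <- report@arr[[an]]
    data.frame(arm = an, arr = e@rate, ci_low = e@ciLow, ci_high = e@ciHigh,
               model = e@model)
  }))
  if (is.null(arrdf)) arrdf <- data.frame()
  wr(arrdf, "arr.csv")
  wr(report@relativeReduction, "relative_reduction.csv")
  wr(data.frame(statistic = report@levene$statistic,
                p_value = report@levene$pValue,
                df1 = report@levene$df1, df2 = report@levene$df2),
     "levene.csv")
  wr(report@perPatient, "per_patient.csv")
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    relapse_free = as.list(report@relapseFree),
    arr = lapply(report@arr, function(e)
      list(rate = e@rate, ci = c(e@ciLow, e@ciHigh), model = e@model)),
    relative_reduction = report@relativeReduction,
    levene = report@levene[c("statistic", "pValue")]
  ), summary_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, summary_path)
  manifest <- list(
    outputs = paths,
    seeds = if (!is.null(trial)) trial@seed else NA,
    config_digest = if (!is.null(trial))
      configDigest(list(name = trial@name, arms = trial@arms,
                        durationWeeks = trial@durationWeeks,
                        seed = trial@seed)) else NA,
    version = as.character(utils::packageVersion("rrmsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(c(paths, manifest_path))
}
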