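#' @describeIn TrialConfig-class constructor.
#' @param name trial label.
#' @param arms list of `list(arm=, n=)` entries.
#' @param durationWeeks simulated horizon.
#' @param readoutStartWeek,readoutWeek endpoint window.
#' @param shared run all arms on the same patients (digital-twin mode).
#' @param seed integer.
#' @export
trialConfig <- function(name, arms, durationWeeks = 96,
                        readoutStartWeek = 0, readoutWeek = durationWeeks,
                        shared = TRUE, seed = 1L) {
  new("TrialConfig", name = name, arms = arms, durationWeeks = durationWeeks,
      readoutStartWeek = readoutStartWeek, readoutWeek = readoutWeek,
      shared = shared, seed = as.integer(seed))
}

#' Tabulate relapse counts by category
#'
#' @param relapses per-patient MRI relapse counts.
#' @param arms per-patient arm labels.
#' @return matrix of patient counts, categories 0/1/2/3/4+ by arm.
#' @export
relapseTable <- function(relapses, arms) {
  tab <- table(relapse_category(relapses), factor(arms, levels = unique(arms)))
  m <- as.matrix(unclass(tab))
  dimnames(m) <- list(category = rownames(tab), arm = colnames(tab))
  m
}

#' Negative-binomial annualized relapse rate
#'
#' Fits the intercept-only negative-binomial count model with a log
#' person-years offset; the ARR is the exponentiated intercept and the
#' confidence interval comes from its standard error. When the counts are
#' all zero the estimate is a flagged degenerate zero; when the dispersion
#' estimate collapses, the model falls back to Poisson and is flagged.
#'
#' @param counts per-patient relapse counts.
#' @param exposures per-patient exposure in years.
#' @param level confidence level (default 0.95).
#' @return An [ArrEstimate-class].
#' @export
computeArr <- function(counts, exposures, level = 0.95) {
  stopifnot(length(counts) == length(exposures), all(counts >= 0),
            all(exposures > 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (sum(counts) == 0)
    return(new("ArrEstimate", rate = 0, ciLow = 0, ciHigh = 0,
               model = "degenerate: all-zero counts"))
  off <- log(exposures)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(counts ~ 1 + offset(off))),
    error = function(e) NULL)
  model <- "negative-binomial, log person-years offset"
  if (is.null(fit) || !fit$converged) {
    fit <- stats::glm(counts ~ 1 + offset(off), family = stats::poisson())
    model <- "Poisson fallback (dispersion degenerate)"
  }
  b <- stats::coef(summary(fit))[1, ]
  new("ArrEstimate", rate = exp(b[["Estimate"]]),
      ciLow = exp(b[["Estimate"]] - z * b[["Std. Error"]]),
      ciHigh = exp(b[["Estimate"]] + z * b[["Std. Error"]]),
      model = model)
}

#' Rate ratio between two arms from a treatment-indicator NB model
#'
#' @param counts,exposures per-patient data across both arms.
#' @param treated logical indicator of the treated arm.
#' @return list(ratio, ciLow, ciHigh).
#' @export
arrRateRatio <- function(counts, exposures, treated) {
  off <- log(exposures)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(counts ~ treated + offset(off))),
    error = function(e)
      stats::glm(counts ~ treated + offset(off), family = stats::poisson()))
  b <- stats::coef(summary(fit))["treatedTRUE", ]
  list(ratio = exp(b[["Estimate"]]),
       ciLow = exp(b[["Estimate"]] - 1.96 * b[["Std. Error"]]),
       ciHigh = exp(b[["Estimate"]] + 1.96 * b[["Std. Error"]]))
}

#' Relative reduction between two annualized relapse rates
#'
#' `100 * (1 - treated / comparator)`, in percent.
#'
#' @param arrTreated,arrComparator [ArrEstimate-class] objects or plain rates.
#' @return Percent reduction.
#' @export
relativeReduction <- function(arrTreated, arrComparator) {
  rt <- if (is(arrTreated, "ArrEstimate")) arrTreated@rate else arrTreated
  rc <- if (is(arrComparator, "ArrEstimate")) arrComparator@rate
        else arrComparator
  if (rc <= 0) stop("comparator rate must be > 0")
  100 * (1 - rt / rc)
}

#' Levene's test for homogeneity of variances
#'
#' The classical W statistic on absolute deviations from group centers
#' (mean by default; median gives the Brown-Forsythe variant), with the
#' p-value from the F distribution on (k-1, N-k) degrees of freedom.
#'
#' @param groups list of numeric samples (>= 2 groups of >= 2 values).
#' @param center "mean" or "median".
#' @return list(statistic, pValue, df1, df2, degenerate).
#' @export
leveneHomogeneity <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  cf <- if (center == "mean") mean else median
  z <- lapply(groups, function(g) abs(g - cf(g)))
  k <- length(z)
  ni <- vapply(z, length, 1L)
  N <- sum(ni)
  zbar_i <- vapply(z, mean, 1)
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(ni * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                          1))
  if (ss_within == 0 && ss_between == 0)
    return(list(statistic = NA_real_, pValue = NA_real_, df1 = k - 1,
                df2 = N - k, degenerate = TRUE))
  W <- ((N - k) / (k - 1)) * ss_between / ss_within
  list(statistic = W, pValue = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k, degenerate = FALSE)
}

#' Run an in silico trial
#'
#' Assigns cohort patients to arms (shared digital-twin mode runs every arm
#' on the same patients), simulates each arm over the horizon, and builds
#' the full report: relapse-category table, relapse-free counts, worst
#' lymphocytopenia grade percentages, per-arm negative-binomial ARR, the
#' relative reduction of every arm versus the first (comparator) arm, and
#' Levene's homogeneity test across arms' relapse counts.
#'
#' @param trial a [TrialConfig-class].
#' @param cohort list of [DigitalPatient-class].
#' @param config,disease,grade engine/disease/grading configurations.
#' @param replicates repertoire replicates per patient.
#' @return A [TrialReport-class].
#' @export
runTrial <- function(trial, cohort, config = simConfig(),
                     disease = diseaseConfig(), grade = gradeConfig(),
                     replicates = 1L) {
  ns <- vapply(trial@arms, function(a) a$n, 1)
  need <- if (trial@shared) max(ns) else sum(ns)
  if (length(cohort) < need)
    stop("cohort too small: ", length(cohort), " < ", need, " required")
  recs <- list()
  offset <- 0L
  for (i in seq_along(trial@arms)) {
    a <- trial@arms[[i]]
    pats <- if (trial@shared) cohort[seq_len(a$n)]
            else cohort[offset + seq_len(a$n)]
    offset <- offset + a$n
    recs[[i]] <- simulateProfiles(
      pats, a$arm, config, disease, grade,
      durationWeeks = trial@durationWeeks,
      readoutStartWeek = trial@readoutStartWeek,
      readoutWeek = trial@readoutWeek,
      replicates = replicates, seed = trial@seed)
  }
  per <- do.call(rbind, recs)
  armNames <- vapply(trial@arms, function(a) a$arm, "")
  rt <- relapseTable(per$relapses, per$arm)
  rfree <- setNames(as.numeric(rt["0", ]), colnames(rt))
  gt <- vapply(armNames, function(an) {
    g <- factor(per$worst_grade[per$arm == an], levels = 0:4)
    100 * as.numeric(table(g)) / sum(per$arm == an)
  }, numeric(5))
  rownames(gt) <- as.character(0:4)
  arr <- lapply(armNames, function(an) {
    w <- per$arm == an
    computeArr(per$relapses[w], per$exposure_years[w])
  })
  names(arr) <- armNames
  rr <- if (length(armNames) > 1) {
    comp <- armNames[1]
    data.frame(
      treated = armNames[-1], comparator = comp,
      reduction_pct = vapply(armNames[-1], function(an)
        relativeReduction(arr[[an]], arr[[comp]]), 1))
  } else data.frame(treated = character(), comparator = character(),
                    reduction_pct = numeric())
  lev <- if (length(armNames) >= 2) {
    leveneHomogeneity(split(per$relapses, per$arm))
  } else if (replicates >= 2) {
    leveneHomogeneity(split(per$relapses, per$replicate))
  } else {
    list(statistic = NA_real_, pValue = NA_real_, df1 = NA, df2 = NA,
         degenerate = TRUE)
  }
  new("TrialReport", relapseTable = rt, relapseFree = rfree, gradeTable = gt,
      arr = arr, relativeReduction = rr, levene = lev, perPatient = per)
}
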