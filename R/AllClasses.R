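#' @import methods
NULL

#' Simulation engine configuration
#'
#' Holds the discrete-time engine's structural constants: tick length,
#' receptor length, clone-class count, homeostatic set-points, rate constants
#' and the oligodendrocyte capacity of the simulated white-matter volume
#' (3 mm^3 at 50e3 ODC/mm^3, i.e. 150e3 cells).
#'
#' @slot tickHours hours per tick (default 8).
#' @slot durationWeeks default simulation horizon in weeks.
#' @slot L receptor bit-string length.
#' @slot nClones number of clone classes per adaptive lineage.
#' @slot setPoints named numeric, homeostatic set-points per population key.
#' @slot rates named numeric, engine rate constants (per-tick probabilities
#'   and saturation constants).
#' @slot odcCapacity oligodendrocyte capacity of the simulated volume.
#' @slot seed integer seed recorded for provenance.
#' @export
setClass("SimConfig", representation(
  tickHours = "numeric", durationWeeks = "numeric", L = "integer",
  nClones = "integer", setPoints = "numeric", rates = "numeric",
  odcCapacity = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@durationWeeks <= 0) msg <- c(msg, "durationWeeks must be > 0")
  if (object@tickHours <= 0) msg <- c(msg, "tickHours must be > 0")
  if (object@L < 1L) msg <- c(msg, "L must be >= 1")
  if (object@odcCapacity < 1) msg <- c(msg, "odcCapacity must be >= 1")
  prob <- grepl("^(p_|d_|rec_|m0_|cyt_decay)", names(object@rates))
  bad <- object@rates[prob] < 0 | object@rates[prob] > 1
  if (any(bad))
    msg <- c(msg, paste("per-tick probabilities outside [0,1]:",
                        paste(names(object@rates[prob])[bad], collapse = ", ")))
  if (any(object@setPoints < 0)) msg <- c(msg, "set-points must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Scheduled EBV molecular-mimicry trigger
#'
#' @slot times integer ticks at which cross-reactive activation fires.
#' @slot magnitude fraction in [0,1] of affine naive clones activated per event.
#' @export
setClass("EbvTrigger", representation(times = "integer", magnitude = "numeric"),
  validity = function(object) {
    if (object@magnitude < 0 || object@magnitude > 1)
      return("magnitude must be in [0,1]")
    if (any(object@times < 1L)) return("trigger times must be positive ticks")
    TRUE
  })

#' MS disease-layer configuration
#'
#' Rate constants for the disease rules: antigen presentation, cytokine-gated
#' helper differentiation, B activation, blood-brain-barrier damage, CNS
#' migration and reactivation, and oligodendrocyte destruction/regeneration.
#' The IL-10 veto is a hard threshold (`il10_thr`); the remaining cytokine
#' gates are saturating level/(level+K) functions with shared constant
#' `gate_K` held in the SimConfig rates.
#'
#' @slot rates named numeric rate-constant table.
#' @slot ebvRatePerYear mean mimicry-trigger rate used when triggers are drawn
#'   per patient rather than scheduled explicitly.
#' @slot ebvMagnitude fraction of affine naive clones cross-activated per event.
#' @export
setClass("DiseaseConfig", representation(
  rates = "numeric", ebvRatePerYear = "numeric", ebvMagnitude = "numeric"
), validity = function(object) {
  if (any(object@rates < 0)) return("disease rates must be >= 0")
  if (object@ebvMagnitude < 0 || object@ebvMagnitude > 1)
    return("ebvMagnitude must be in [0,1]")
  TRUE
})

#' Immune-system state at one tick
#'
#' A flat named count vector over (cell type, status, compartment) keys,
#' cytokine levels per mediator and compartment, clonal naive pools, the
#' blood-brain-barrier permeability, the oligodendrocyte count and antigen
#' level. Access through the accessors, not the slot.
#'
#' @slot counts named numeric engine state vector.
#' @slot tick integer tick index.
#' @slot nClones clone classes per adaptive lineage.
#' @export
setClass("ImmuneState", representation(
  counts = "numeric", tick = "integer", nClones = "integer"
), validity = function(object) {
  ct <- object@counts
  if (any(ct < 0)) return("state counts/levels must be non-negative")
  bbb <- ct[["bbb_permeability"]]
  if (bbb < 0 || bbb > 1) return("bbb_permeability must be in [0,1]")
  TRUE
})

#' Randomized HLA profile of a digital patient
#'
#' @slot mhc1 list with loci A, B, C; each a character pair of allele codes
#'   (receptor bit strings).
#' @slot mhc2 list with loci DM, DO, DP, DQ, DR; pairs as in `mhc1`.
#' @export
setClass("HlaProfile", representation(mhc1 = "list", mhc2 = "list"),
  validity = function(object) {
    if (!identical(sort(names(object@mhc1)), c("A", "B", "C")))
      return("mhc1 must have loci A, B, C")
    if (!identical(sort(names(object@mhc2)), c("DM", "DO", "DP", "DQ", "DR")))
      return("mhc2 must have loci DM, DO, DP, DQ, DR")
    if (any(vapply(c(object@mhc1, object@mhc2), length, 1L) != 2L))
      return("each locus must carry an allele pair")
    TRUE
  })

#' A digital patient
#'
#' Demographics plus a randomized HLA/MHC repertoire and the derived
#' simulation traits (HLA match factor, autoreactive clone affinities, drug
#' sensitivity, baseline lymphocyte scale, mimicry-trigger rate). The traits
#' are a deterministic function of `repertoireSeed`.
#'
#' @slot id patient identifier.
#' @slot age years. @slot sex "F" or "M". @slot weight kg. @slot race category.
#' @slot hla HlaProfile.
#' @slot repertoireSeed integer seed the repertoire and traits derive from.
#' @slot traits list of derived simulation traits.
#' @export
setClass("DigitalPatient", representation(
  id = "character", age = "numeric", sex = "character", weight = "numeric",
  race = "character", hla = "HlaProfile", repertoireSeed = "integer",
  traits = "list"
), validity = function(object) {
  if (object@age <= 0) return("age must be > 0")
  if (object@weight <= 0) return("weight must be > 0")
  TRUE
})

#' Treatment course for one arm
#'
#' @slot armName arm label (e.g. "placebo", "cladribine_3.5", "ocrelizumab").
#' @slot drug one of "placebo", "cladribine", "ocrelizumab", "ifnb1a".
#' @slot doses data.frame with columns day, drug, amount, route, sorted by day.
#' @slot pdParams named numeric pharmacodynamic constants (effect half-life in
#'   ticks, per-tick kill-rate scales, modulation factors).
#' @export
setClass("TreatmentCourse", representation(
  armName = "character", drug = "character", doses = "data.frame",
  pdParams = "numeric"
), validity = function(object) {
  if (!object@drug %in% c("placebo", "cladribine", "ocrelizumab", "ifnb1a"))
    return("unknown drug")
  d <- object@doses
  if (nrow(d)) {
    if (is.unsorted(d$day)) return("doses must be sorted by day")
    if (any(d$amount < 0)) return("dose amounts must be >= 0")
  }
  TRUE
})

#' Lymphocytopenia grading configuration
#'
#' Grade bands on the absolute lymphocyte count (cells/ul): grade 0 >= 1000,
#' grade 1 800-999, grade 2 500-799, grade 3 200-499, grade 4 < 200.
#' `alcScale` maps the simulated circulating lymphocyte count to cells/ul.
#'
#' @slot cutoffs numeric lower bounds of grades 0..3 (grade 4 is below the last).
#' @slot alcScale scale factor to cells/ul.
#' @export
setClass("GradeConfig", representation(cutoffs = "numeric", alcScale = "numeric"),
  validity = function(object) {
    if (length(object@cutoffs) != 4L || is.unsorted(rev(object@cutoffs)))
      return("cutoffs must be 4 decreasing lower bounds")
    if (object@alcScale <= 0) return("alcScale must be > 0")
    TRUE
  })

#' Calibration target for cohort selection
#'
#' @slot relapseDist named proportions over relapse categories "0","1","2","3","4+".
#' @slot gradeDist optional named proportions over grades "0".."4" (length 0 to skip).
#' @slot arrTarget optional annualized relapse rate target (NA to skip).
#' @slot arrTol tolerance on the ARR target.
#' @slot tolerance total-variation tolerance on matched distributions.
#' @export
setClass("CalibrationTarget", representation(
  relapseDist = "numeric", gradeDist = "numeric", arrTarget = "numeric",
  arrTol = "numeric", tolerance = "numeric"
), validity = function(object) {
  if (abs(sum(object@relapseDist) - 1) > 1e-6)
    return("relapseDist must sum to 1")
  if (length(object@gradeDist) && abs(sum(object@gradeDist) - 1) > 1e-6)
    return("gradeDist must sum to 1")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  TRUE
})

#' Annualized relapse rate estimate
#'
#' @slot rate relapses per patient-year. @slot ciLow,ciHigh 95% interval.
#' @slot model "negative-binomial, log person-years offset" or the flagged
#'   Poisson/degenerate fallback.
#' @export
setClass("ArrEstimate", representation(
  rate = "numeric", ciLow = "numeric", ciHigh = "numeric", model = "character"
), validity = function(object) {
  if (object@rate < 0) return("rate must be >= 0")
  if (!(object@ciLow <= object@rate && object@rate <= object@ciHigh))
    return("need ciLow <= rate <= ciHigh")
  TRUE
})

#' In silico trial configuration
#'
#' @slot name trial label.
#' @slot arms list of list(arm=<arm name>, n=<patients>).
#' @slot durationWeeks simulated horizon.
#' @slot readoutStartWeek,readoutWeek endpoint counting window (weeks).
#' @slot shared if TRUE all arms run on the same patients (digital-twin mode);
#'   otherwise patients are partitioned across arms.
#' @slot seed integer.
#' @export
setClass("TrialConfig", representation(
  name = "character", arms = "list", durationWeeks = "numeric",
  readoutStartWeek = "numeric", readoutWeek = "numeric", shared = "logical",
  seed = "integer"
), validity = function(object) {
  if (!length(object@arms)) return("at least one arm required")
  ns <- vapply(object@arms, function(a) a$n, 1)
  if (any(ns <= 0)) return("arm n must be > 0")
  if (object@readoutWeek > object@durationWeeks)
    return("readout window must lie within the simulated horizon")
  TRUE
})

#' In silico trial report
#'
#' @slot relapseTable matrix of patient counts by relapse category x arm.
#' @slot relapseFree named count of relapse-free patients per arm.
#' @slot gradeTable matrix of worst lymphocytopenia grade percentages x arm.
#' @slot arr named list of ArrEstimate per arm.
#' @slot relativeReduction data.frame of percent rate reductions per arm pair.
#' @slot levene list(statistic, pValue, ...) homogeneity-of-variance result.
#' @slot perPatient per-patient outcome records.
#' @export
setClass("TrialReport", representation(
  relapseTable = "matrix", relapseFree = "numeric", gradeTable = "matrix",
  arr = "list", relativeReduction = "data.frame", levene = "list",
  perPatient = "data.frame"
), validity = function(object) {
  if (nrow(object@perPatient)) {
    sums <- colSums(object@relapseTable)
    n <- table(object@perPatient$arm)[colnames(object@relapseTable)]
    if (any(abs(sums - as.numeric(n)) > 0.5))
      return("relapse categories must partition each arm")
    gs <- colSums(object@gradeTable)
    if (any(abs(gs - 100) > 0.1))
      return("grade percentages must sum to 100")
  }
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: tick", object@tickHours, "h,", object@durationWeeks,
      "weeks, L =", object@L, ",", object@nClones, "clones/lineage, ODC capacity",
      object@odcCapacity, "\n")
})
setMethod("show", "ImmuneState", function(object) {
  cat("ImmuneState at tick", object@tick, "| ODC",
      object@counts[["ODC.resting.CNS"]], "| BBB",
      round(object@counts[["bbb_permeability"]], 3), "\n")
})
setMethod("show", "DigitalPatient", function(object) {
  cat("DigitalPatient", object@id, "|", object@age, "y", object@sex, "|",
      object@weight, "kg | seed", object@repertoireSeed, "\n")
})
setMethod("show", "TreatmentCourse", function(object) {
  cat("TreatmentCourse", object@armName, "(", object@drug, "),",
      nrow(object@doses), "doses\n")
})
setMethod("show", "ArrEstimate", function(object) {
  cat(sprintf("ARR %.3f (%.3f-%.3f) [%s]\n", object@rate, object@ciLow,
              object@ciHigh, object@model))
})
setMethod("show", "TrialReport", function(object) {
  cat("TrialReport:", paste(colnames(object@relapseTable), collapse = ", "), "\n")
  print(object@relapseTable)
})
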