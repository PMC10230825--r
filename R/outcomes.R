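#' @describeIn GradeConfig-class constructor. Bands follow the clinical
#'   lymphocytopenia convention: grade 1 = 800-999, grade 2 = 500-799,
#'   grade 3 = 200-499, grade 4 < 200 cells/ul; grade 0 is >= 1000 so the
#'   bands partition `[0, Inf)`.
#' @param alcScale factor mapping simulated circulating lymphocyte counts to
#'   cells/ul; the default puts the homeostatic state near 1800/ul.
#' @export
gradeConfig <- function(alcScale = 1800 / 1620) {
  new("GradeConfig", cutoffs = c(1000, 800, 500, 200), alcScale = alcScale)
}

#' Segment an ODC trajectory into relapse events
#'
#' An episode opens when the oligodendrocyte count starts declining and
#' closes once net regeneration has persisted for the refractory window;
#' per-episode loss is the value at onset minus the episode minimum, and the
#' event is MRI-detectable when the loss reaches `mriThreshold` cells
#' (default 50e3 in the simulated 3 mm^3 volume). Events are non-overlapping
#' and time-ordered.
#'
#' @param odc numeric ODC counts per tick (or a trajectory data.frame with an
#'   `odc` column).
#' @param mriThreshold detectability threshold in cells.
#' @param refractoryTicks ticks of net regeneration that close an episode
#'   (default 42 ticks = 14 days at 8 h/tick).
#' @return data.frame(start_tick, end_tick, odc_loss, mri_detectable).
#' @export
segmentRelapses <- function(odc, mriThreshold = 50000, refractoryTicks = 42) {
  if (is.data.frame(odc)) odc <- odc$odc
  n <- length(odc)
  ev <- list()
  if (n >= 2) {
    open <- FALSE
    start_i <- 0L; start_v <- 0; min_v <- 0; min_i <- 0L
    for (i in 2:n) {
      if (!open) {
        if (odc[i] < odc[i - 1]) {
          open <- TRUE
          start_i <- i - 1L; start_v <- odc[i - 1]
          min_v <- odc[i]; min_i <- i
        }
      } else {
        if (odc[i] < min_v) { min_v <- odc[i]; min_i <- i }
        if (i - min_i >= refractoryTicks) {
          ev[[length(ev) + 1L]] <- c(start_i, min_i, start_v - min_v)
          open <- FALSE
        }
      }
    }
    if (open) ev[[length(ev) + 1L]] <- c(start_i, min_i, start_v - min_v)
  }
  if (!length(ev))
    return(data.frame(start_tick = integer(), end_tick = integer(),
                      odc_loss = numeric(), mri_detectable = logical()))
  m <- do.call(rbind, ev)
  data.frame(start_tick = as.integer(m[, 1]), end_tick = as.integer(m[, 2]),
             odc_loss = m[, 3], mri_detectable = m[, 3] >= mriThreshold)
}

#' Count MRI-detectable relapses
#'
#' Only episodes whose oligodendrocyte loss reaches the MRI-detectability
#' threshold count as relapses.
#'
#' @param events data.frame from [segmentRelapses()].
#' @return Integer count.
#' @export
countMriRelapses <- function(events) sum(events$mri_detectable)

#' Absolute lymphocyte count of a state
#'
#' `alcScale` times the summed blood-compartment T and B counts, in cells/ul.
#'
#' @param state an [ImmuneState-class], or a numeric raw circulating count.
#' @param config a [GradeConfig-class].
#' @return ALC in cells/ul.
#' @export
alcValue <- function(state, config = gradeConfig()) {
  raw <- if (is(state, "ImmuneState")) {
    ct <- state@counts
    ct[["CD4.resting.blood"]] + ct[["CD8.resting.blood"]] +
      ct[["B_naive.resting.blood"]]
  } else state
  config@alcScale * raw
}

#' Grade lymphocytopenia from an ALC value
#'
#' @param alc ALC in cells/ul (vectorized).
#' @param config a [GradeConfig-class].
#' @return Integer grade(s) in 0..4.
#' @export
gradeLymphocytopenia <- function(alc, config = gradeConfig()) {
  if (any(alc < 0)) stop("ALC must be >= 0")
  co <- config@cutoffs
  ifelse(alc >= co[1], 0L,
  ifelse(alc >= co[2], 1L,
  ifelse(alc >= co[3], 2L,
  ifelse(alc >= co[4], 3L, 4L))))
}

#' Worst lymphocytopenia grade over an ALC trajectory
#'
#' @param alcs numeric ALC trajectory in cells/ul.
#' @param config a [GradeConfig-class].
#' @return The maximum pointwise grade.
#' @export
worstGrade <- function(alcs, config = gradeConfig()) {
  if (!length(alcs)) stop("empty ALC trajectory")
  max(gradeLymphocytopenia(alcs, config))
}

#' Write relapse events to CSV
#'
#' @param events data.frame from [segmentRelapses()].
#' @param path output path.
#' @param patientId optional id column value.
#' @export
writeRelapseEvents <- function(events, path, patientId = NA_character_) {
  out <- cbind(patient_id = patientId, events)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
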