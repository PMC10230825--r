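#' @useDynLib rrmsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rpois rlnorm rgamma rnorm runif sd quantile median
NULL

TICKS_PER_DAY <- function(config) round(24 / config@tickHours)

default_engine_rates <- function() {
  c(
    # homeostasis / turnover (per tick)
    p_home_naive = 0.0008, p_home_innate = 0.05, p_home_treg = 0.004,
    rec_cd4 = 0.0002, rec_cd8 = 0.0002, rec_b = 0.0015, rec_neut = 0.1,
    # activated-pool death rates (per tick)
    d_th = 0.02, d_cd8a = 0.02, d_bact = 0.02, d_bmem = 0.002, d_bpla = 0.02,
    d_macact = 0.03, d_dcact = 0.05, d_cns = 0.03, d_neutcns = 0.08,
    d_ncns = 0.01, d_bactcns = 0.02, d_bplacns = 0.01, d_igg = 0.03,
    d_microact = 0.02, d_astroact = 0.02,
    # cytokine kinetics
    cyt_decay = 0.9, q_sec = 0.01, gate_K = 10, tgfb_source = 1
  )
}

default_set_points <- function() {
  c(
    "Th_naive.resting.lymphoid" = 1200, "CD8_naive.resting.lymphoid" = 600,
    "B_naive.resting.lymphoid" = 600, "DC.resting.lymphoid" = 500,
    "Macrophage.resting.lymphoid" = 400, "Microglia.resting.CNS" = 400,
    "Astrocyte.resting.CNS" = 400, "Treg.active.lymphoid" = 150,
    "CD4.resting.blood" = 900, "CD8.resting.blood" = 450,
    "B_naive.resting.blood" = 270, "Neutrophil.resting.blood" = 4000
  )
}

#' Create a simulation engine configuration
#'
#' @param tickHours hours per tick; default 8.
#' @param durationWeeks default horizon in weeks.
#' @param L receptor bit-string length; default 16.
#' @param nClones clone classes per adaptive lineage; default 12.
#' @param setPoints named homeostatic set-points; defaults cover all pools.
#' @param rates named per-tick rate constants; partial overrides are merged
#'   into the documented defaults.
#' @param odcCapacity oligodendrocytes in the simulated 3 mm^3 volume;
#'   default 150000.
#' @param seed integer seed recorded for provenance.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(tickHours = 8, durationWeeks = 96, L = 16L,
                      nClones = 12L, setPoints = NULL, rates = NULL,
                      odcCapacity = 150000, seed = 1L) {
  sp <- default_set_points()
  if (!is.null(setPoints)) sp[names(setPoints)] <- setPoints
  rt <- default_engine_rates()
  if (!is.null(rates)) {
    unknown <- setdiff(names(rates), names(rt))
    if (length(unknown))
      stop("unknown engine rate constant(s): ", paste(unknown, collapse = ", "))
    rt[names(rates)] <- rates
  }
  new("SimConfig", tickHours = tickHours, durationWeeks = durationWeeks,
      L = as.integer(L), nClones = as.integer(nClones), setPoints = sp,
      rates = rt, odcCapacity = odcCapacity, seed = as.integer(seed))
}

#' Draw a random receptor bit string
#'
#' @param L receptor length.
#' @return Character scalar over \{0,1\} of length `L`.
#' @export
randomReceptor <- function(L = 16L) {
  paste(sample(c("0", "1"), L, replace = TRUE), collapse = "")
}

#' Bit-string receptor affinity
#'
#' The affinity between two receptors is the number of bitwise-complementary
#' positions, an integer in `[0, L]`: identical strings score 0, exact
#' complements score `L`. Symmetric and deterministic.
#'
#' @param a,b receptor bit strings of equal length.
#' @return Integer complementarity count.
#' @export
affinity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || nchar(a) != nchar(b))
    stop("invalid receptor pair: lengths must match")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (!all(av %in% c("0", "1")) || !all(bv %in% c("0", "1")))
    stop("invalid receptor: only 0/1 symbols allowed")
  sum(av != bv)
}

# map clone affinities to activation weights: only near-complementary clones
# (affinity >= L-2, the activation threshold) react, with graded weight
affinity_weight <- function(aff, L) pmax(0, aff - (L - 3L)) / 3

# assemble the flat parameter vector the C++ kernel consumes
engine_params <- function(config, disease = NULL, course = NULL,
                          patient = NULL) {
  sp <- config@setPoints
  bscale <- if (!is.null(patient)) patient@traits$alcBase else 1
  p <- c(
    n_clones = as.numeric(config@nClones),
    sp_dc = sp[["DC.resting.lymphoid"]],
    sp_mac = sp[["Macrophage.resting.lymphoid"]],
    sp_micro = sp[["Microglia.resting.CNS"]],
    sp_astro = sp[["Astrocyte.resting.CNS"]],
    sp_treg = sp[["Treg.active.lymphoid"]],
    sp_thn = sp[["Th_naive.resting.lymphoid"]],
    sp_cd8n = sp[["CD8_naive.resting.lymphoid"]],
    sp_bn = sp[["B_naive.resting.lymphoid"]],
    sp_cd4_blood = sp[["CD4.resting.blood"]] * bscale,
    sp_cd8_blood = sp[["CD8.resting.blood"]] * bscale,
    sp_b_blood = sp[["B_naive.resting.blood"]] * bscale,
    sp_neut_blood = sp[["Neutrophil.resting.blood"]],
    config@rates,
    odc_cap = config@odcCapacity,
    disease_on = as.numeric(!is.null(disease)),
    hla = if (!is.null(patient)) patient@traits$hlaFactor else 1,
    sens = if (!is.null(patient)) patient@traits$sens else 1
  )
  dz <- if (is.null(disease)) default_disease_rates() * 0 else disease@rates
  # regulatory capacity varies across patients: scales the Treg expansion
  # feedback that sizes and spaces relapses
  if (!is.null(disease) && !is.null(patient) &&
      !is.null(patient@traits$tregScale))
    dz[["p_treg_exp"]] <- dz[["p_treg_exp"]] * patient@traits$tregScale
  p <- c(p, dz,
         il10_thr = if (is.null(disease)) 1e9 else disease@rates[["il10_thr"]],
         ebv_magnitude = if (is.null(disease)) 0 else disease@ebvMagnitude)
  p <- p[!duplicated(names(p))]
  if (is.null(course)) {
    p <- c(p, drug = 0, default_pd_params("placebo"))
  } else {
    p <- c(p, drug = switch(course@drug, placebo = 0, cladribine = 1,
                            ocrelizumab = 2, ifnb1a = 3),
           course@pdParams)
  }
  p[!duplicated(names(p))]
}

#' Build the initial immune state
#'
#' All populations start at their homeostatic set-points (scaled by the
#' patient's baseline lymphocyte factor for the circulating pools), clonal
#' naive pools are split evenly across clone classes, cytokines are zero, the
#' blood-brain barrier is at baseline permeability and the oligodendrocyte
#' pool is at capacity.
#'
#' @param config a [SimConfig-class].
#' @param disease optional [DiseaseConfig-class] (sets baseline permeability).
#' @param patient optional [DigitalPatient-class].
#' @return An [ImmuneState-class].
#' @export
initialState <- function(config, disease = NULL, patient = NULL) {
  K <- config@nClones
  nm <- cpp_state_names(K)
  s <- setNames(numeric(length(nm)), nm)
  sp <- config@setPoints
  bscale <- if (!is.null(patient)) patient@traits$alcBase else 1
  s["DC.resting.lymphoid"] <- sp[["DC.resting.lymphoid"]]
  s["Macrophage.resting.lymphoid"] <- sp[["Macrophage.resting.lymphoid"]]
  s["Microglia.resting.CNS"] <- sp[["Microglia.resting.CNS"]]
  s["Astrocyte.resting.CNS"] <- sp[["Astrocyte.resting.CNS"]]
  s["Treg.active.lymphoid"] <- sp[["Treg.active.lymphoid"]]
  s["CD4.resting.blood"] <- round(sp[["CD4.resting.blood"]] * bscale)
  s["CD8.resting.blood"] <- round(sp[["CD8.resting.blood"]] * bscale)
  s["B_naive.resting.blood"] <- round(sp[["B_naive.resting.blood"]] * bscale)
  s["Neutrophil.resting.blood"] <- sp[["Neutrophil.resting.blood"]]
  s[sprintf("Th_naive.clone%d.lymphoid", seq_len(K))] <-
    round(sp[["Th_naive.resting.lymphoid"]] / K)
  s[sprintf("CD8_naive.clone%d.lymphoid", seq_len(K))] <-
    round(sp[["CD8_naive.resting.lymphoid"]] / K)
  s[sprintf("B_naive.clone%d.lymphoid", seq_len(K))] <-
    round(sp[["B_naive.resting.lymphoid"]] / K)
  s["ODC.resting.CNS"] <- config@odcCapacity
  s["bbb_permeability"] <-
    if (is.null(disease)) 0.05 else disease@rates[["bbb_base"]]
  new("ImmuneState", counts = s, tick = 0L, nClones = K)
}

patient_weights <- function(config, patient) {
  if (is.null(patient)) {
    z <- numeric(config@nClones)
    list(w4 = z, w8 = z, wb = z)
  } else {
    patient@traits$affinities
  }
}

#' Advance the immune state one tick
#'
#' Applies the physiology layer (hematopoiesis, deaths, cytokine secretion and
#' decay), then the disease layer when a [DiseaseConfig-class] is given, then
#' the treatment layer when a [TreatmentCourse-class] is given — in that
#' order. Identical (state, seed) give identical output.
#'
#' @param state an [ImmuneState-class].
#' @param config a [SimConfig-class].
#' @param disease optional disease layer config.
#' @param course optional treatment course.
#' @param patient optional digital patient (supplies repertoire affinities).
#' @param ebvNow logical; fire the mimicry trigger on this tick.
#' @param doseNow logical; administer `doseAmount` (normalized units) now.
#' @param doseAmount normalized dose added to the drug effect level.
#' @return The advanced [ImmuneState-class].
#' @export
stepState <- function(state, config, disease = NULL, course = NULL,
                      patient = NULL, ebvNow = FALSE, doseNow = FALSE,
                      doseAmount = 0) {
  stopifnot(is(state, "ImmuneState"))
  par <- engine_params(config, disease, course, patient)
  w <- patient_weights(config, patient)
  out <- cpp_tick(state@counts, par, w$w4, w$w8, w$wb, ebvNow, doseNow,
                  doseAmount)
  names(out) <- names(state@counts)
  new("ImmuneState", counts = out, tick = state@tick + 1L,
      nClones = state@nClones)
}

#' Hematopoietic replenishment toward set-points
#'
#' Naive, circulating and resting pools receive a binomial influx with mean
#' `set_point * p` and lose a matched binomial efflux with mean `n * p`, so
#' each pool fluctuates around its set-point.
#'
#' @inheritParams stepState
#' @return The updated [ImmuneState-class] (tick unchanged).
#' @export
hematopoiesis <- function(state, config, patient = NULL) {
  par <- engine_params(config, patient = patient)
  out <- cpp_hematopoiesis(state@counts, par)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' Cytokine secretion and decay
#'
#' Each secreting population adds `q_sec * count` to its compartment milieu,
#' then all levels decay by the per-tick factor `cyt_decay`; levels stay
#' non-negative.
#'
#' @inheritParams stepState
#' @return The updated [ImmuneState-class].
#' @export
secreteAndDecay <- function(state, config, disease = NULL) {
  par <- engine_params(config, disease)
  out <- cpp_secrete_decay(state@counts, par)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' Run the engine for many ticks and record trajectories
#'
#' Low-level driver used by [simulatePatient()]; runs the C++ kernel for
#' `nTicks` and records tick-wise ODC count, per-tick ODC loss, and the
#' circulating CD4/CD8/B counts.
#'
#' @inheritParams stepState
#' @param nTicks number of ticks to advance.
#' @param ebvTicks integer ticks at which the mimicry trigger fires.
#' @param doseTicks,doseAmounts dosing schedule in ticks / normalized units.
#' @param snapshotEvery record a full state snapshot every so many ticks
#'   (0 = none).
#' @return list with `state` (final [ImmuneState-class]), `trajectory`
#'   (data.frame: tick, day, odc, loss, cd4_blood, cd8_blood, b_blood,
#'   alc_raw) and `snapshots` (matrix).
#' @export
runEngine <- function(state, config, disease = NULL, course = NULL,
                      patient = NULL, nTicks, ebvTicks = integer(),
                      doseTicks = integer(), doseAmounts = numeric(),
                      snapshotEvery = 0) {
  par <- engine_params(config, disease, course, patient)
  w <- patient_weights(config, patient)
  out <- cpp_run(state@counts, par, w$w4, w$w8, w$wb,
                 as.integer(ebvTicks), as.integer(doseTicks),
                 as.numeric(doseAmounts), as.integer(nTicks),
                 as.integer(snapshotEvery))
  cts <- out$state
  names(cts) <- names(state@counts)
  tpd <- TICKS_PER_DAY(config)
  traj <- data.frame(
    tick = state@tick + seq_len(nTicks),
    day = (state@tick + seq_len(nTicks)) / tpd,
    odc = out$odc, loss = out$loss,
    cd4_blood = out$cd4_blood, cd8_blood = out$cd8_blood,
    b_blood = out$b_blood, alc_raw = out$alc_raw
  )
  list(state = new("ImmuneState", counts = cts,
                   tick = state@tick + as.integer(nTicks),
                   nClones = state@nClones),
       trajectory = traj, snapshots = out$snapshots)
}

#' Write a tidy trajectory snapshot CSV
#'
#' @param trajectory data.frame from [runEngine()] or [simulatePatient()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

# ---- accessors ----

#' Accessors for ImmuneState
#'
#' @param state an [ImmuneState-class].
#' @return `odcCount`: the oligodendrocyte count; `bbbPermeability`: barrier
#'   permeability in [0,1]; `tickIndex`: tick; `cellCounts`: the named count
#'   vector of cell populations; `cytokineLevels`: a 16 x 3 matrix of
#'   mediator levels by compartment.
#' @export
odcCount <- function(state) state@counts[["ODC.resting.CNS"]]

#' @rdname odcCount
#' @export
bbbPermeability <- function(state) state@counts[["bbb_permeability"]]

#' @rdname odcCount
#' @export
tickIndex <- function(state) state@tick

#' @rdname odcCount
#' @export
cellCounts <- function(state) {
  ct <- state@counts
  ct[!grepl("^cyt\\.|^bbb_|^MBP\\.|^drug_", names(ct))]
}

#' @rdname odcCount
#' @export
cytokineLevels <- function(state) {
  ct <- state@counts[grepl("^cyt\\.", names(state@counts))]
  parts <- strsplit(sub("^cyt\\.", "", names(ct)), ".", fixed = TRUE)
  med <- vapply(parts, `[`, "", 1L)
  comp <- vapply(parts, `[`, "", 2L)
  m <- matrix(ct, nrow = 16, dimnames = list(unique(med), unique(comp)))
  m
}
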