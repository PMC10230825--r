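#' Myelin basic protein antigen
#'
#' @slot epitope receptor bit string presented by dendritic cells.
#' @slot abundance non-negative antigen level (arbitrary units).
#' @export
setClass("MbpAntigen", representation(epitope = "character",
                                      abundance = "numeric"),
  validity = function(object) {
    if (object@abundance < 0) return("abundance must be >= 0")
    TRUE
  })

#' @describeIn MbpAntigen-class constructor. The package default epitope is a
#'   fixed bit string against which patient repertoires are scored.
#' @param epitope receptor bit string.
#' @param abundance antigen level.
#' @export
mbpAntigen <- function(epitope = MBP_EPITOPE, abundance = 0) {
  new("MbpAntigen", epitope = epitope, abundance = abundance)
}

# fixed reference epitope (L = 16)
MBP_EPITOPE <- "1011001101001011"

#' @describeIn EbvTrigger-class constructor.
#' @param times integer ticks of scheduled mimicry events.
#' @param magnitude fraction in [0,1] of affine naive clones activated.
#' @export
ebvTrigger <- function(times = integer(), magnitude = 0.5) {
  new("EbvTrigger", times = as.integer(times), magnitude = magnitude)
}

default_disease_rates <- function() {
  c(
    k_dc = 0.5, K_mbp = 60, k_act = 0.007, k_act8 = 0.005, k_b = 0.012,
    p_pla = 0.03, p_mem = 0.005, q_igg = 0.05, p_prolif = 0.03,
    bbb_base = 0.05, K_bbb = 60, perm_damage_thr = 0.4, m0_mig = 0.55,
    p_naive_mig = 0.002, k_mic = 0.2, k_ast = 0.1, k_neut = 0.02,
    k_sec = 0.05, p_treg_exp = 0.012, il10_act_damp = 0, mbp_uptake = 5e-4,
    r_igg = 1.35e-3, r_cd8 = 6e-4, r_mac = 6e-4, r_neut = 1e-5,
    r_regen = 0.006, mbp_per_kill = 0.008, mbp_decay = 0.93, mbp_base = 0,
    il10_thr = 25
  )
}

#' Create the MS disease-layer configuration
#'
#' @param rates named overrides merged into the documented defaults (see
#'   [DiseaseConfig-class]).
#' @param ebvRatePerYear mean molecular-mimicry trigger rate per patient-year
#'   (per-patient rates are drawn around this when generating patients).
#' @param ebvMagnitude fraction of affine naive clones cross-activated per
#'   trigger.
#' @return A [DiseaseConfig-class].
#' @export
diseaseConfig <- function(rates = NULL, ebvRatePerYear = 2.2,
                          ebvMagnitude = 0.24) {
  rt <- default_disease_rates()
  if (!is.null(rates)) {
    unknown <- setdiff(names(rates), names(rt))
    if (length(unknown))
      stop("unknown disease rate constant(s): ", paste(unknown, collapse = ", "))
    rt[names(rates)] <- rates
  }
  new("DiseaseConfig", rates = rt, ebvRatePerYear = ebvRatePerYear,
      ebvMagnitude = ebvMagnitude)
}

# build a milieu-only state for ops that take a cytokine milieu directly
milieu_state <- function(config, milieu = NULL, tregCount = 0) {
  s <- initialState(config)
  ct <- s@counts
  ct[] <- 0
  if (!is.null(milieu)) {
    nm <- paste0("cyt.", names(milieu), ".lymphoid")
    bad <- !nm %in% names(ct)
    if (any(bad)) stop("unknown mediator(s): ",
                       paste(names(milieu)[bad], collapse = ", "))
    ct[nm] <- milieu
  }
  ct["Treg.active.lymphoid"] <- tregCount
  initialize(s, counts = ct)
}

#' Antigen presentation by dendritic cells
#'
#' Resting DCs are activated by MBP antigen; active DCs then prime naive CD4
#' clones (via MHC-II) and CD8 clones (via MHC-I) with probability increasing
#' in clone affinity to the epitope and the patient's HLA match factor. Newly
#' primed CD4 cells are partitioned by [differentiateHelper()] under the
#' current milieu.
#'
#' @param state an [ImmuneState-class].
#' @param config a [SimConfig-class].
#' @param disease a [DiseaseConfig-class].
#' @param patient a [DigitalPatient-class] supplying the repertoire.
#' @param mbp optional [MbpAntigen-class]; its abundance overrides the state's
#'   antigen level and clone weights are recomputed against its epitope.
#' @param actScale treatment-layer scaling of activation rates.
#' @return The updated [ImmuneState-class].
#' @export
presentAntigen <- function(state, config, disease, patient, mbp = NULL,
                           actScale = 1) {
  par <- engine_params(config, disease, patient = patient)
  w <- patient_weights(config, patient)
  ct <- state@counts
  if (!is.null(mbp)) {
    ct["MBP.level.lymphoid"] <- mbp@abundance
    par[["mbp_base"]] <- 0
    L <- config@L
    w <- lapply(patient@traits$receptors, function(r)
      affinity_weight(vapply(r, affinity, 0L, b = mbp@epitope), L))
    names(w) <- c("w4", "w8", "wb")
  }
  out <- cpp_present_antigen(ct, par, w$w4, w$w8, actScale)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' Cytokine-gated helper-T differentiation
#'
#' Partitions newly activated CD4 cells into Th1, Th17, Th2 and a
#' Treg-suppressed remainder. Th1 is favoured by IL-12 with IFN-gamma, Th17
#' by IL-6 with IL-23/TGF-beta — provided IL-10 is below the inhibition
#' threshold, which zeroes the Th17 output — and Th2 by IL-4. Treg counts
#' scale all subsets down.
#'
#' @param count number of newly activated naive CD4 cells.
#' @param milieu named cytokine levels (lymphoid compartment), e.g.
#'   `c("IL-12" = 50, "IFN-g" = 50)`.
#' @param config a [SimConfig-class].
#' @param disease a [DiseaseConfig-class].
#' @param tregCount regulatory T cells present.
#' @return Named numeric: Th1, Th17, Th2, suppressed.
#' @export
differentiateHelper <- function(count, milieu, config, disease,
                                tregCount = 0) {
  stopifnot(count >= 0)
  par <- engine_params(config, disease)
  st <- milieu_state(config, milieu, tregCount)
  cpp_differentiate(count, st@counts, par)
}

#' Th2-driven B-cell activation and antibody release
#'
#' Naive B clones are activated under Th2 help in the presence of IL-4, IL-5,
#' IL-6, IL-10 and IL-13; active B cells duplicate and differentiate into
#' plasma (and memory) cells, and plasma cells release anti-MBP IgG.
#'
#' @inheritParams presentAntigen
#' @return The updated [ImmuneState-class].
#' @export
activateBCells <- function(state, config, disease, patient, actScale = 1) {
  par <- engine_params(config, disease, patient = patient)
  w <- patient_weights(config, patient)
  out <- cpp_activate_b(state@counts, par, w$wb, actScale)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' EBV molecular-mimicry cross-activation
#'
#' At trigger ticks, a `magnitude` fraction of naive B and T cells in clones
#' affine to the MBP epitope is cross-activated; on other ticks the state is
#' returned unchanged.
#'
#' @inheritParams presentAntigen
#' @param trigger an [EbvTrigger-class].
#' @return The updated [ImmuneState-class].
#' @export
ebvMimicry <- function(state, config, disease, patient, trigger) {
  if (!(state@tick + 1L) %in% trigger@times || trigger@magnitude == 0)
    return(state)
  par <- engine_params(config, disease, patient = patient)
  w <- patient_weights(config, patient)
  out <- cpp_ebv(state@counts, par, w$w4, w$w8, w$wb, trigger@magnitude)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' Cytokine-driven blood-brain-barrier damage
#'
#' Permeability is a saturating increasing function of the weighted
#' pro-inflammatory cytokine load (IFN-gamma, TNF-alpha/beta, IL-17, IL-6,
#' IL-1, IL-22), with baseline `bbb_base` at zero load and limit 1.
#'
#' @param milieu named cytokine levels, or an [ImmuneState-class].
#' @param config a [SimConfig-class].
#' @param disease a [DiseaseConfig-class].
#' @return Permeability in [0,1].
#' @export
damageBbb <- function(milieu, config, disease) {
  st <- if (is(milieu, "ImmuneState")) milieu
        else milieu_state(config, milieu)
  par <- engine_params(config, disease)
  cpp_damage_bbb(st@counts, par)
}

#' Migration of effectors across the blood-brain barrier
#'
#' Activated Th1 (gated by IL-12), Th17 (IL-17/IL-6/IL-22/IL-23), macrophages
#' and IgG transfer from the lymphoid compartment to the CNS with probability
#' proportional to permeability; IL-10 above the inhibition threshold blocks
#' the Th1/Th17/macrophage/IgG routes (CD8 egress is unaffected). Resting
#' naive T/B cells cross only when permeability exceeds the damage threshold.
#'
#' @inheritParams presentAntigen
#' @param permeability optional override of the state's barrier permeability.
#' @return The updated [ImmuneState-class].
#' @export
migrateToCns <- function(state, config, disease, permeability = NULL) {
  ct <- state@counts
  if (!is.null(permeability)) {
    stopifnot(permeability >= 0, permeability <= 1)
    ct["bbb_permeability"] <- permeability
  }
  par <- engine_params(config, disease)
  out <- cpp_migrate(ct, par)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' CNS reactivation cascade
#'
#' Microglia switch to the active state on contact with CNS helper T cells
#' and secrete IL-1, IL-6, IL-12, TNF-alpha, IFN-gamma and IL-2; astrocytes
#' reactivate under IL-1/TNF-alpha; IL-17 recruits neutrophils from the blood
#' across the damaged barrier; and naive cells that crossed a damaged barrier
#' can be secondarily activated in the CNS.
#'
#' @inheritParams presentAntigen
#' @return The updated [ImmuneState-class].
#' @export
cnsReactivation <- function(state, config, disease) {
  par <- engine_params(config, disease)
  out <- cpp_cns_react(state@counts, par)
  names(out) <- names(state@counts)
  initialize(state, counts = out)
}

#' Oligodendrocyte destruction and regeneration
#'
#' CNS effectors (CD8, macrophages, IgG, neutrophils) kill oligodendrocytes
#' with per-cell hazard `1 - prod(1 - rate_e * effectors_e)` under the local
#' inflammatory milieu; the loss is binomial and bounded by the current count.
#' A slow regeneration term restores the pool toward capacity between
#' attacks, and myelin debris from killed cells feeds antigen presentation.
#'
#' @inheritParams presentAntigen
#' @return list(state = updated [ImmuneState-class], loss = cells lost).
#' @export
killOligodendrocytes <- function(state, config, disease) {
  par <- engine_params(config, disease)
  out <- cpp_kill_odc(state@counts, par)
  cts <- out$state
  names(cts) <- names(state@counts)
  list(state = initialize(state, counts = cts), loss = out$loss)
}
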