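KNOWN_ARMS <- c("placebo", "cladribine_3.5", "cladribine_5.25", "CP3.5",
                "CP5.25", "CC7", "CC8.75", "PC3.5", "ocrelizumab", "ifnb1a")

# pharmacodynamic defaults per drug; effect half-lives in ticks (8 h each).
# Cladribine kill-rate scales are calibrated so that median 12-month
# depletions land at 40-45% (CD4), 20-30% (CD8) and 80-85% (CD19 B);
# ocrelizumab holds the CD20+ pool at a deep nadir while dosing continues.
default_pd_params <- function(drug) {
  switch(drug,
    placebo = c(hl_drug = 1, k_clad_cd4 = 0, k_clad_cd8 = 0, k_clad_b = 0,
                k_ocr = 0, ocr_thr = 0, ocr_tmod = 0, ifn_act_red = 0,
                ifn_bbb_red = 0),
    cladribine = c(hl_drug = 500, k_clad_cd4 = 1.06e-4, k_clad_cd8 = 5.5e-5,
                   k_clad_b = 1.35e-3, k_ocr = 0, ocr_thr = 0, ocr_tmod = 0,
                   ifn_act_red = 0, ifn_bbb_red = 0),
    ocrelizumab = c(hl_drug = 189, k_clad_cd4 = 0, k_clad_cd8 = 0,
                    k_clad_b = 0, k_ocr = 0.15, ocr_thr = 0.1, ocr_tmod = 0.15,
                    ifn_act_red = 0, ifn_bbb_red = 0),
    ifnb1a = c(hl_drug = 9, k_clad_cd4 = 0, k_clad_cd8 = 0, k_clad_b = 0,
               k_ocr = 0, ocr_thr = 0, ocr_tmod = 0, ifn_act_red = 0.22,
               ifn_bbb_red = 0.2),
    stop("unknown drug: ", drug))
}

#' @describeIn TreatmentCourse-class constructor.
#' @param armName arm label.
#' @param drug drug identifier.
#' @param doses data.frame(day, drug, amount, route).
#' @param pdParams named pharmacodynamic overrides merged into drug defaults.
#' @export
treatmentCourse <- function(armName, drug, doses, pdParams = NULL) {
  pd <- default_pd_params(drug)
  if (!is.null(pdParams)) pd[names(pdParams)] <- pdParams
  new("TreatmentCourse", armName = armName, drug = drug, doses = doses,
      pdParams = pd)
}

cladribine_doses <- function(mgkg_per_year1, mgkg_per_year2, bodyWeight,
                             startWeek = 0, durationWeeks) {
  # label structure: each yearly course is two 5-day cycles four weeks apart
  cycles <- c(startWeek, startWeek + 4, startWeek + 48, startWeek + 52)
  mgkg_cycle <- c(rep(mgkg_per_year1 / 2, 2), rep(mgkg_per_year2 / 2, 2))
  days <- integer(); amts <- numeric()
  for (i in seq_along(cycles)) {
    if (mgkg_cycle[i] <= 0) next
    if (cycles[i] >= durationWeeks) next
    d <- cycles[i] * 7 + 1:5
    days <- c(days, d)
    amts <- c(amts, rep(mgkg_cycle[i] * bodyWeight / 5, 5))
  }
  data.frame(day = days, drug = "cladribine", amount = amts, route = "oral")
}

#' Build the dosing schedule for a trial arm
#'
#' Known arms: `placebo`; `cladribine_3.5` / `cladribine_5.25` (cumulative
#' mg/kg over two yearly courses of two 5-day cycles); the extension
#' sequences `CP3.5`, `CP5.25` (cladribine then placebo), `CC7`, `CC8.75`
#' (cladribine in both periods), `PC3.5` (placebo then cladribine from week
#' 96); `ocrelizumab` (300 mg IV on days 1 and 15, then 600 mg every 24
#' weeks); and `ifnb1a` (44 mcg SC three times per week).
#'
#' @param armName one of the known arms.
#' @param durationWeeks horizon the schedule must cover.
#' @param bodyWeight patient weight in kg (cladribine doses scale with it).
#' @return A [TreatmentCourse-class].
#' @export
buildSchedule <- function(armName, durationWeeks, bodyWeight = 70) {
  if (!armName %in% KNOWN_ARMS)
    stop("unknown arm: ", armName, " (known: ",
         paste(KNOWN_ARMS, collapse = ", "), ")")
  empty <- data.frame(day = integer(), drug = character(),
                      amount = numeric(), route = character())
  course <- switch(armName,
    placebo = treatmentCourse(armName, "placebo", empty),
    cladribine_3.5 = treatmentCourse(armName, "cladribine",
      cladribine_doses(1.75, 1.75, bodyWeight, 0, durationWeeks)),
    cladribine_5.25 = treatmentCourse(armName, "cladribine",
      cladribine_doses(2.625, 2.625, bodyWeight, 0, durationWeeks)),
    CP3.5 = treatmentCourse(armName, "cladribine",
      cladribine_doses(1.75, 1.75, bodyWeight, 0, durationWeeks)),
    CP5.25 = treatmentCourse(armName, "cladribine",
      cladribine_doses(2.625, 2.625, bodyWeight, 0, durationWeeks)),
    CC7 = treatmentCourse(armName, "cladribine", {
      d1 <- cladribine_doses(1.75, 1.75, bodyWeight, 0, durationWeeks)
      d2 <- cladribine_doses(1.75, 1.75, bodyWeight, 96, durationWeeks)
      rbind(d1, d2)
    }),
    CC8.75 = treatmentCourse(armName, "cladribine", {
      d1 <- cladribine_doses(2.625, 2.625, bodyWeight, 0, durationWeeks)
      d2 <- cladribine_doses(1.75, 1.75, bodyWeight, 96, durationWeeks)
      rbind(d1, d2)
    }),
    PC3.5 = treatmentCourse(armName, "cladribine",
      cladribine_doses(1.75, 1.75, bodyWeight, 96, durationWeeks)),
    ocrelizumab = {
      wk <- if (durationWeeks >= 24) seq(24, durationWeeks, by = 24)
            else numeric()
      doses <- data.frame(
        day = c(1, 15, wk * 7),
        drug = "ocrelizumab",
        amount = c(300, 300, rep(600, length(wk))),
        route = "IV")
      treatmentCourse(armName, "ocrelizumab", doses)
    },
    ifnb1a = {
      wk <- seq_len(durationWeeks) - 1
      days <- sort(as.vector(outer(c(1, 3, 5), wk * 7, `+`)))
      days <- days[days <= durationWeeks * 7]
      treatmentCourse(armName, "ifnb1a",
        data.frame(day = days, drug = "ifnb1a", amount = 44, route = "SC"))
    })
  course
}

# normalized effect units per dose: one cladribine cycle-day = 1, one full
# ocrelizumab infusion (600 mg) = 1, one 44 mcg IFN injection = 1
normalize_dose <- function(course, bodyWeight) {
  d <- course@doses
  if (!nrow(d)) return(numeric())
  switch(course@drug,
    cladribine = d$amount / (0.175 * bodyWeight),
    ocrelizumab = d$amount / 600,
    ifnb1a = d$amount / 44,
    placebo = rep(0, nrow(d)))
}

dose_ticks <- function(course, config) {
  tpd <- TICKS_PER_DAY(config)
  as.integer(course@doses$day * tpd - (tpd - 1L))
}

#' Apply one tick of a treatment course
#'
#' Dispatches to the drug-specific pharmacodynamic rule; placebo is an
#' identity. Depletion acts by binomial thinning, so counts never go
#' negative.
#'
#' @param state an [ImmuneState-class].
#' @param config a [SimConfig-class].
#' @param course a [TreatmentCourse-class].
#' @param tick 1-based tick at which the layer is applied (dose events whose
#'   tick matches are administered).
#' @param patient optional [DigitalPatient-class] (drug sensitivity).
#' @return list(state, actScale, bbbRed): the updated state plus the
#'   activation-rate and BBB-damage modulation factors the disease layer
#'   sees on this tick.
#' @export
applyTreatment <- function(state, config, course, tick, patient = NULL) {
  stopifnot(is(course, "TreatmentCourse"))
  par <- engine_params(config, course = course, patient = patient)
  dt <- dose_ticks(course, config)
  amt <- normalize_dose(course, if (is.null(patient)) 70 else patient@weight)
  hit <- which(dt == tick)
  out <- cpp_apply_treatment(state@counts, par, length(hit) > 0,
                             sum(amt[hit]))
  cts <- out$state
  names(cts) <- names(state@counts)
  list(state = initialize(state, counts = cts),
       actScale = out$act_scale, bbbRed = out$bbb_red)
}

#' @describeIn applyTreatment cladribine-specific effect (T- and B-lineage
#'   binomial kills scaled by the current drug effect level).
#' @export
cladribineEffect <- function(state, config, course, tick, patient = NULL) {
  stopifnot(course@drug == "cladribine")
  applyTreatment(state, config, course, tick, patient)
}

#' @describeIn applyTreatment ocrelizumab-specific effect (deep CD20+ B
#'   depletion while the drug level exceeds threshold; plasma cells spared;
#'   mild T-activation modulation).
#' @export
ocrelizumabEffect <- function(state, config, course, tick, patient = NULL) {
  stopifnot(course@drug == "ocrelizumab")
  applyTreatment(state, config, course, tick, patient)
}

#' @describeIn applyTreatment interferon beta-1a effect (reduces Th1/Th17
#'   activation rates and BBB damage while dosing is maintained).
#' @export
ifnb1aEffect <- function(state, config, course, tick, patient = NULL) {
  stopifnot(course@drug == "ifnb1a")
  applyTreatment(state, config, course, tick, patient)
}

#' Write a per-patient dose log CSV
#'
#' @param course a [TreatmentCourse-class].
#' @param path output path.
#' @export
writeDoseLog <- function(course, path) {
  utils::write.csv(course@doses, path, row.names = FALSE)
  invisible(path)
}
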