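# shared fixtures; heavyweight calibrations are computed once per session
fixture_env <- new.env(parent = emptyenv())

test_config <- function(...) simConfig(...)
test_disease <- function(...) diseaseConfig(...)

# a handmade patient whose repertoire is fully controlled: nAuto clones per
# lineage are exact complements of the epitope (activation weight 1)
make_test_patient <- function(nAuto = 3, config = simConfig(), seed = 5L,
                              sens = 1, alcBase = 1, ebvRate = 1.25) {
  p <- generatePatient(clarityDemographics(), seed = seed, config = config)
  L <- config@L
  K <- config@nClones
  epi <- strsplit(rrmsim:::MBP_EPITOPE, "")[[1]]
  comp <- paste(ifelse(epi == "0", "1", "0"), collapse = "")
  set.seed(seed + 1L)
  rec <- replicate(K, paste(sample(c("0", "1"), L, TRUE), collapse = ""))
  rec[seq_len(nAuto)] <- comp
  receptors <- list(w4 = rec, w8 = rec, wb = rec)
  affs <- lapply(receptors, function(r)
    rrmsim:::affinity_weight(vapply(r, affinity, 0L, b = rrmsim:::MBP_EPITOPE), L))
  p@traits$receptors <- receptors
  p@traits$affinities <- affs
  p@traits$sens <- sens
  p@traits$alcBase <- alcBase
  p@traits$ebvRatePerYear <- ebvRate
  p@traits$hlaFactor <- 1
  p@traits$tregScale <- 1
  p
}

# calibrated cohorts shared across acceptance tests (seeds fixed up front)
clarity_fixture <- function() {
  if (!is.null(fixture_env$clarity)) return(fixture_env$clarity)
  cal <- calibrateCohort(150, 900, clarityDemographics(), clarityTargets(),
                         seed = 42L)
  tr <- trialConfig("clarity",
                    list(list(arm = "placebo", n = 150),
                         list(arm = "cladribine_3.5", n = 150)),
                    durationWeeks = 96, shared = TRUE, seed = 42L)
  rep <- runTrial(tr, cal$patients)
  fixture_env$clarity <- list(cal = cal, trial = tr, report = rep)
  fixture_env$clarity
}

opera_fixture <- function() {
  if (!is.null(fixture_env$opera)) return(fixture_env$opera)
  cal <- calibrateCohort(200, 900, operaDemographics(), operaTargets("opera1"),
                         arm = "ifnb1a", durationWeeks = 100, readoutWeek = 96,
                         seed = 43L)
  tr <- trialConfig("opera1",
                    list(list(arm = "ifnb1a", n = 200),
                         list(arm = "ocrelizumab", n = 200)),
                    durationWeeks = 100, readoutWeek = 96, shared = TRUE,
                    seed = 43L)
  rep <- runTrial(tr, cal$patients)
  fixture_env$opera <- list(cal = cal, trial = tr, report = rep)
  fixture_env$opera
}
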