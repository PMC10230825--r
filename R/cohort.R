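#' Demographic distribution presets
#'
#' Editable YAML files under `inst/extdata` carry the baseline demographic
#' distributions (age, sex, weight, race) and the calibration-target tables
#' for the cladribine-trial-like and ocrelizumab-trial-like cohorts,
#' transcribed from the published baseline/outcome tables. These loaders
#' parse them into the list/target structures the generators consume.
#'
#' @param name file stem under `extdata` (without `.yaml`).
#' @return `loadDemographics`: a list(age, sexFemale, weight, race);
#'   the target loaders: a [CalibrationTarget-class].
#' @export
loadDemographics <- function(name = "clarity_demographics") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "rrmsim")
  if (path == "") stop("no such demographics preset: ", name)
  yaml::read_yaml(path)
}

#' @rdname loadDemographics
#' @export
clarityDemographics <- function() loadDemographics("clarity_demographics")

#' @rdname loadDemographics
#' @export
operaDemographics <- function() loadDemographics("opera_demographics")

#' @rdname loadDemographics
#' @export
clarityTargets <- function() {
  y <- yaml::read_yaml(system.file("extdata", "clarity_targets.yaml",
                                   package = "rrmsim"))
  calibrationTarget(
    relapseDist = unlist(y$relapse_distribution),
    gradeDist = unlist(y$grade_distribution),
    tolerance = y$tolerance)
}

#' @rdname loadDemographics
#' @param trial "opera1" or "opera2".
#' @param exposureYears readout exposure the selection distribution is built
#'   for (default 96 weeks).
#' @export
operaTargets <- function(trial = c("opera1", "opera2"),
                         exposureYears = 96 * 7 / 365.25) {
  trial <- match.arg(trial)
  y <- yaml::read_yaml(system.file("extdata", "opera_targets.yaml",
                                   package = "rrmsim"))
  t <- y[[trial]]
  # selection distribution: negative-binomial law at the comparator-arm rate
  mu <- t$arr_ifnb1a * exposureYears
  p <- stats::dnbinom(0:3, size = y$nb_size, mu = mu)
  rd <- c(p, 1 - sum(p))
  names(rd) <- c("0", "1", "2", "3", "4+")
  calibrationTarget(relapseDist = rd, arrTarget = t$arr_ifnb1a,
                    arrTol = t$arr_tol, tolerance = y$tolerance)
}

#' @describeIn CalibrationTarget-class constructor.
#' @param relapseDist named proportions over "0","1","2","3","4+".
#' @param gradeDist optional named proportions over grades "0".."4".
#' @param arrTarget,arrTol optional annualized-relapse-rate target.
#' @param tolerance total-variation tolerance for matching.
#' @export
calibrationTarget <- function(relapseDist, gradeDist = numeric(),
                              arrTarget = NA_real_, arrTol = 0.05,
                              tolerance = 0.05) {
  new("CalibrationTarget", relapseDist = relapseDist,
      gradeDist = gradeDist, arrTarget = arrTarget, arrTol = arrTol,
      tolerance = tolerance)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

#' Generate one digital patient
#'
#' Demographics are drawn from the configured distributions; all eight
#' HLA/MHC loci (A, B, C and DM, DO, DP, DQ, DR) receive allele codes drawn
#' uniformly over receptor space. Simulation traits are derived from the
#' same seeded stream: the HLA match factor (how strongly the DR alleles
#' present the myelin epitope), the autoreactive clone repertoire per
#' lineage, a lognormal drug-sensitivity multiplier, a lognormal baseline
#' lymphocyte scale, and the patient's mimicry-trigger rate.
#'
#' @param demographics list as returned by [clarityDemographics()].
#' @param seed integer; the patient is a deterministic function of it.
#' @param id patient identifier.
#' @param config a [SimConfig-class] (receptor length and clone count).
#' @param disease a [DiseaseConfig-class]; its baseline mimicry rate, scaled
#'   by the preset's disease-activity factor, parameterizes the patient's
#'   trigger rate.
#' @return A [DigitalPatient-class].
#' @export
generatePatient <- function(demographics = clarityDemographics(), seed = 1L,
                            id = sprintf("DP%06d", seed %% 1000000L),
                            config = simConfig(), disease = diseaseConfig()) {
  set.seed(seed)
  d <- demographics
  age <- rtrunc_norm(1, d$age$mean, d$age$sd, d$age$min, d$age$max)
  sex <- if (runif(1) < d$sexFemale) "F" else "M"
  weight <- rtrunc_norm(1, d$weight$mean, d$weight$sd, d$weight$min,
                        d$weight$max)
  race <- sample(names(d$race), 1, prob = unlist(d$race))
  L <- config@L
  loci1 <- c("A", "B", "C"); loci2 <- c("DM", "DO", "DP", "DQ", "DR")
  mhc1 <- setNames(lapply(loci1, function(l) c(randomReceptor(L),
                                               randomReceptor(L))), loci1)
  mhc2 <- setNames(lapply(loci2, function(l) c(randomReceptor(L),
                                               randomReceptor(L))), loci2)
  hla <- new("HlaProfile", mhc1 = mhc1, mhc2 = mhc2)
  # presentation strength scored by how close the DR alleles come to the
  # epitope's complement
  drAff <- max(vapply(mhc2$DR, affinity, 0L, b = MBP_EPITOPE))
  hlaFactor <- 0.6 + 0.8 * drAff / L
  # per-patient autoreactive load: the fraction of thymic-escape clones
  # varies across patients, widening the relapse-count tail
  pAuto <- rbeta(1, 2, 4.5)
  receptors <- lapply(1:3, function(l) {
    vapply(seq_len(config@nClones), function(i) {
      if (runif(1) < pAuto) {
        # thymic-escape clone: near-complement of the epitope
        flips <- sample(0:3, 1, prob = c(0.15, 0.35, 0.3, 0.2))
        bits <- as.integer(strsplit(MBP_EPITOPE, "")[[1]] == "0")  # complement
        if (flips > 0) {
          ix <- sample(L, flips)
          bits[ix] <- 1L - bits[ix]
        }
        paste(bits, collapse = "")
      } else randomReceptor(L)
    }, "")
  })
  names(receptors) <- c("w4", "w8", "wb")
  affs <- lapply(receptors, function(r)
    affinity_weight(vapply(r, affinity, 0L, b = MBP_EPITOPE), L))
  traits <- list(
    hlaFactor = hlaFactor,
    sens = rlnorm(1, 0, 0.34),
    alcBase = rlnorm(1, 0, 0.48),
    ebvRatePerYear = rgamma(1, shape = 1,
                            rate = 1 / (disease@ebvRatePerYear *
                                        (d$ebvRateScale %||% 1))),
    tregScale = rlnorm(1, 0, 0.5),
    receptors = receptors,
    affinities = affs
  )
  new("DigitalPatient", id = id, age = age, sex = sex, weight = weight,
      race = race, hla = hla, repertoireSeed = as.integer(seed),
      traits = traits)
}

#' Generate a cohort of digital patients
#'
#' @inheritParams generatePatient
#' @param n cohort size.
#' @param seed root seed; per-patient seeds are spawned from it so each
#'   patient is reproducible independently of cohort size.
#' @param idPrefix prefix for patient ids.
#' @return list of [DigitalPatient-class].
#' @export
generateCohort <- function(n, demographics = clarityDemographics(), seed = 1L,
                           idPrefix = "DP", config = simConfig(),
                           disease = diseaseConfig()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i)
    generatePatient(demographics, seeds[i], sprintf("%s%05d", idPrefix, i),
                    config, disease))
}

#' Simulate one patient on one arm
#'
#' Draws the patient's mimicry-trigger schedule (a Poisson process at the
#' patient's rate), builds the arm's dosing schedule against the patient's
#' body weight, runs the engine over the horizon and extracts the outcome
#' trajectory.
#'
#' @param patient a [DigitalPatient-class].
#' @param arm arm name understood by [buildSchedule()], or a
#'   [TreatmentCourse-class].
#' @param config a [SimConfig-class].
#' @param disease a [DiseaseConfig-class].
#' @param grade a [GradeConfig-class].
#' @param durationWeeks horizon (defaults to the config's).
#' @param seed run seed (combined with the patient's own stream).
#' @return list(trajectory, events, state): tick-wise trajectory data.frame
#'   (with `alc` in cells/ul), the relapse-event table and the final state.
#' @export
simulatePatient <- function(patient, arm, config = simConfig(),
                            disease = diseaseConfig(), grade = gradeConfig(),
                            durationWeeks = config@durationWeeks, seed = 1L) {
  course <- if (is(arm, "TreatmentCourse")) arm
            else buildSchedule(arm, durationWeeks, patient@weight)
  tpd <- TICKS_PER_DAY(config)
  nTicks <- as.integer(durationWeeks * 7 * tpd)
  # the mimicry-trigger schedule is intrinsic to the patient (a deterministic
  # function of the repertoire seed), so the same digital patient relapses at
  # the same times across arms and replications
  set.seed(patient@repertoireSeed %% 1000003L)
  years <- durationWeeks * 7 / 365.25
  nEbv <- rpois(1, patient@traits$ebvRatePerYear * years)
  ebvTicks <- sort(sample.int(nTicks, min(nEbv, nTicks)))
  set.seed((patient@repertoireSeed %% 1000003L) * 2027L + (seed %% 2027L))
  st <- initialState(config, disease, patient)
  out <- runEngine(st, config, disease, course, patient, nTicks,
                   ebvTicks = ebvTicks,
                   doseTicks = dose_ticks(course, config),
                   doseAmounts = normalize_dose(course, patient@weight))
  traj <- out$trajectory
  traj$alc <- alcValue(traj$alc_raw, grade)
  events <- segmentRelapses(traj$odc)
  list(trajectory = traj, events = events, state = out$state,
       ebvTicks = ebvTicks)
}

#' Simulate outcome profiles for a cohort
#'
#' Runs every patient (times `replicates`, each with its own seed) on the
#' given arm and collects per-profile outcome records: MRI relapse count in
#' the readout window, episode count, worst lymphocytopenia grade, total ODC
#' loss and exposure.
#'
#' @inheritParams simulatePatient
#' @param patients list of [DigitalPatient-class].
#' @param replicates repertoire replicates per patient.
#' @param readoutStartWeek,readoutWeek window over which relapses and grades
#'   are counted (defaults to the whole horizon).
#' @param seed root seed for the replicate streams.
#' @return data.frame(id, replicate, seed, relapses, episodes, worst_grade,
#'   total_loss, exposure_years, arm).
#' @export
simulateProfiles <- function(patients, arm, config = simConfig(),
                             disease = diseaseConfig(), grade = gradeConfig(),
                             durationWeeks = config@durationWeeks,
                             readoutStartWeek = 0,
                             readoutWeek = durationWeeks,
                             replicates = 1L, seed = 1L) {
  if (!length(patients))
    return(data.frame(id = character(), replicate = integer(),
                      seed = integer(), relapses = integer(),
                      episodes = integer(), worst_grade = integer(),
                      total_loss = numeric(), exposure_years = numeric(),
                      arm = character()))
  tpd <- TICKS_PER_DAY(config)
  t0 <- readoutStartWeek * 7 * tpd
  t1 <- readoutWeek * 7 * tpd
  rows <- vector("list", length(patients) * replicates)
  k <- 0L
  for (p in patients) for (r in seq_len(replicates)) {
    k <- k + 1L
    rseed <- (seed + 7919L * (r - 1L)) %% 2048L
    sim <- simulatePatient(p, arm, config, disease, grade, durationWeeks,
                           seed = rseed)
    ev <- sim$events
    win <- ev[ev$start_tick >= t0 & ev$start_tick <= t1, , drop = FALSE]
    alcs <- sim$trajectory$alc[sim$trajectory$tick > t0 &
                               sim$trajectory$tick <= t1]
    rows[[k]] <- data.frame(
      id = p@id, replicate = r, seed = rseed,
      relapses = countMriRelapses(win),
      episodes = nrow(win),
      worst_grade = worstGrade(alcs, grade),
      total_loss = sum(win$odc_loss),
      exposure_years = (readoutWeek - readoutStartWeek) * 7 / 365.25,
      arm = if (is(arm, "TreatmentCourse")) arm@armName else arm)
  }
  do.call(rbind, rows)
}

relapse_category <- function(x) {
  f <- ifelse(x >= 4, "4+", as.character(x))
  factor(f, levels = c("0", "1", "2", "3", "4+"))
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

#' Select profiles matching a calibration target
#'
#' Greedy stratified selection: candidate profiles are binned by relapse
#' category (and worst grade when the target carries a grade distribution)
#' and drawn, in seeded random order, to fill per-stratum quotas derived
#' from the target proportions. Selection fails — naming the worst stratum —
#' when the pool cannot bring the selected empirical distribution within the
#' target's total-variation tolerance.
#'
#' @param records data.frame from [simulateProfiles()].
#' @param target a [CalibrationTarget-class].
#' @param nSelect profiles to select.
#' @param seed selection seed.
#' @return The selected subset of `records` (with attribute "tv" holding the
#'   achieved total-variation distances).
#' @export
selectMatching <- function(records, target, nSelect, seed = 1L) {
  stopifnot(nrow(records) >= nSelect)
  set.seed(seed)
  ord <- sample.int(nrow(records))
  rec <- records[ord, , drop = FALSE]
  rcat <- relapse_category(rec$relapses)
  want_r <- round(target@relapseDist * nSelect)
  useGrade <- length(target@gradeDist) > 0
  if (useGrade) {
    gcat <- factor(rec$worst_grade, levels = 0:4)
    want_g <- round(target@gradeDist * nSelect)
  }
  take <- logical(nrow(rec))
  got_r <- setNames(numeric(5), levels(rcat))
  got_g <- setNames(numeric(5), as.character(0:4))
  n_taken <- 0L
  for (i in seq_len(nrow(rec))) {
    rc <- as.character(rcat[i])
    if (got_r[rc] >= want_r[rc]) next
    if (useGrade) {
      gc <- as.character(gcat[i])
      if (got_g[gc] >= want_g[gc] + ceiling(0.02 * nSelect)) next
      got_g[gc] <- got_g[gc] + 1
    }
    got_r[rc] <- got_r[rc] + 1
    take[i] <- TRUE
    n_taken <- n_taken + 1L
    if (n_taken >= nSelect) break
  }
  # back-fill any shortfall, preferring relapse categories still in deficit
  if (n_taken < nSelect) {
    for (pass in 1:2) {
      for (i in seq_len(nrow(rec))) {
        if (n_taken >= nSelect) break
        if (take[i]) next
        rc <- as.character(rcat[i])
        if (pass == 1 && got_r[rc] >= want_r[rc]) next
        take[i] <- TRUE
        n_taken <- n_taken + 1L
        got_r[rc] <- got_r[rc] + 1
        if (useGrade)
          got_g[as.character(gcat[i])] <- got_g[as.character(gcat[i])] + 1
      }
    }
  }
  sel <- rec[take, , drop = FALSE]
  emp_r <- as.numeric(table(relapse_category(sel$relapses))) / nrow(sel)
  tv_r <- tv_distance(emp_r, target@relapseDist)
  tv_g <- NA_real_
  if (useGrade) {
    emp_g <- as.numeric(table(factor(sel$worst_grade, levels = 0:4))) /
      nrow(sel)
    tv_g <- tv_distance(emp_g, target@gradeDist)
  }
  ok <- tv_r <= target@tolerance && (!useGrade || tv_g <= target@tolerance)
  if (!is.na(target@arrTarget)) {
    arr <- sum(sel$relapses) / sum(sel$exposure_years)
    if (abs(arr - target@arrTarget) > target@arrTol) {
      diff_r <- abs(emp_r - target@relapseDist)
      stop(sprintf(
        "calibration failure: selected ARR %.3f outside %.3f +/- %.3f",
        arr, target@arrTarget, target@arrTol))
    }
  }
  if (!ok) {
    diffs <- abs(emp_r - target@relapseDist)
    worst <- levels(rcat)[which.max(diffs)]
    stop(sprintf(
      "calibration failure: relapse/grade distribution outside tolerance %.3f (worst stratum: %s relapses, deviation %.3f)",
      target@tolerance, worst, max(diffs)))
  }
  sel <- sel[order(match(sel$id, records$id), sel$replicate), , drop = FALSE]
  attr(sel, "tv") <- c(relapse = tv_r, grade = tv_g)
  sel
}

#' Augment a calibrated cohort by stratified bootstrap
#'
#' Resamples selected patients with replacement within their outcome strata,
#' jittering the demographics within stratum bounds and re-seeding the
#' repertoire, until the target size is reached. Stratum proportions are
#' preserved up to rounding and no stratum absent from the source appears.
#'
#' @param cohort list of [DigitalPatient-class] (the selected patients).
#' @param nTarget target cohort size (>= current size).
#' @param seed integer.
#' @param strata optional per-patient stratum labels (e.g. relapse
#'   categories from the calibration records); defaults to one stratum.
#' @param demographics distribution list (for jitter bounds).
#' @param config a [SimConfig-class].
#' @return list of [DigitalPatient-class] of length `nTarget`.
#' @export
augmentCohort <- function(cohort, nTarget, seed = 1L, strata = NULL,
                          demographics = clarityDemographics(),
                          config = simConfig()) {
  stopifnot(length(cohort) > 0, nTarget >= length(cohort))
  if (nTarget == length(cohort)) return(cohort)
  if (is.null(strata)) strata <- rep("all", length(cohort))
  strata <- as.character(strata)
  set.seed(seed)
  n_extra <- nTarget - length(cohort)
  prop <- table(strata) / length(strata)
  extra_per <- round(prop * n_extra)
  # fix rounding drift
  while (sum(extra_per) < n_extra) {
    i <- which.max(prop); extra_per[i] <- extra_per[i] + 1
  }
  while (sum(extra_per) > n_extra) {
    i <- which.max(extra_per); extra_per[i] <- extra_per[i] - 1
  }
  out <- cohort
  idx <- length(cohort)
  for (s in names(extra_per)) {
    pool <- which(strata == s)
    if (!length(pool) || extra_per[[s]] == 0) next
    picks <- sample(pool, extra_per[[s]], replace = TRUE)
    for (p in picks) {
      idx <- idx + 1
      src <- cohort[[p]]
      newSeed <- sample.int(.Machine$integer.max - 1L, 1)
      child <- generatePatient(demographics, newSeed,
                               sprintf("%s.a%05d", src@id, idx), config)
      # keep the parent's demographic neighborhood
      child@age <- min(demographics$age$max,
                       max(demographics$age$min, src@age + rnorm(1, 0, 2)))
      child@weight <- min(demographics$weight$max,
                          max(demographics$weight$min,
                              src@weight + rnorm(1, 0, 3)))
      child@sex <- src@sex
      child@race <- src@race
      out[[idx]] <- child
    }
  }
  attr(out, "strata") <- c(strata, rep(names(extra_per),
                                       times = as.numeric(extra_per)))
  out
}

#' Calibrate a digital cohort against trial targets
#'
#' The full digital-patient calibration loop: generate a candidate pool,
#' simulate every candidate on the calibration arm, and select the profiles
#' whose outcome distribution matches the target (relapse-count
#' distribution, optionally the worst-grade distribution and an annualized
#' relapse rate). The selected patients are the calibrated cohort used for
#' the in silico trial arms.
#'
#' @param nSelect cohort size to select.
#' @param poolSize candidate pool size (several times `nSelect`).
#' @param demographics distribution list (see [clarityDemographics()]).
#' @param target a [CalibrationTarget-class].
#' @param arm calibration arm (the arm the target describes).
#' @param config,disease,grade configurations.
#' @param durationWeeks,readoutWeek simulation horizon and endpoint window.
#' @param seed root seed.
#' @return list(patients, records, pool): the selected patients (in
#'   selection order), their outcome records, and the full candidate pool.
#' @export
calibrateCohort <- function(nSelect, poolSize = 4 * nSelect,
                            demographics = clarityDemographics(),
                            target = clarityTargets(), arm = "placebo",
                            config = simConfig(), disease = diseaseConfig(),
                            grade = gradeConfig(), durationWeeks = 96,
                            readoutWeek = durationWeeks, seed = 1L) {
  pool <- generateCohort(poolSize, demographics, seed = seed,
                         config = config, disease = disease)
  records <- simulateProfiles(pool, arm, config, disease, grade,
                              durationWeeks = durationWeeks,
                              readoutWeek = readoutWeek, seed = seed)
  sel <- selectMatching(records, target, nSelect, seed = seed)
  ids <- match(sel$id, vapply(pool, function(p) p@id, ""))
  list(patients = pool[ids], records = sel, pool = pool)
}
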