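cfg <- simConfig()
dz <- diseaseConfig()

test_that("dose schedules follow the trial regimens", {
  # ocrelizumab over 100 weeks: 300 mg on days 1 and 15, then 600 mg q24w
  ocr <- buildSchedule("ocrelizumab", 100)
  expect_equal(ocr@doses$day, c(1, 15, 24 * 7, 48 * 7, 72 * 7, 96 * 7))
  expect_equal(ocr@doses$amount, c(300, 300, 600, 600, 600, 600))
  expect_true(all(ocr@doses$route == "IV"))
  # placebo: empty dose list
  expect_equal(nrow(buildSchedule("placebo", 96)@doses), 0L)
  # cladribine 3.5 mg/kg at 70 kg dispenses 245 mg in total
  cl <- buildSchedule("cladribine_3.5", 96, bodyWeight = 70)
  expect_equal(sum(cl@doses$amount), 3.5 * 70)
  expect_equal(sum(buildSchedule("cladribine_5.25", 96, 70)@doses$amount),
               5.25 * 70)
  # interferon beta-1a: 44 mcg three times weekly
  ifn <- buildSchedule("ifnb1a", 4)
  expect_equal(nrow(ifn@doses), 12L)
  expect_true(all(ifn@doses$amount == 44))
  # extension sequences dose only in their assigned period
  pc <- buildSchedule("PC3.5", 182)
  expect_true(all(pc@doses$day > 96 * 7))
  cp <- buildSchedule("CP3.5", 182)
  expect_true(all(cp@doses$day <= 96 * 7))
  expect_error(buildSchedule("mystery_arm", 96), "unknown arm")
})

test_that("no depletion occurs before the first dose", {
  p <- make_test_patient()
  set.seed(1)
  sim <- simulatePatient(p, "cladribine_3.5", cfg, disease = NULL,
                         grade = gradeConfig(), durationWeeks = 4, seed = 1)
  # dosing starts day 1; compare against a placebo run pre-dose is trivial,
  # so check the treatment layer alone before any dose tick
  course <- buildSchedule("ocrelizumab", 96, p@weight)
  st <- initialState(cfg, NULL, p)
  set.seed(2)
  out <- applyTreatment(st, cfg, course, tick = 1L, patient = p)  # day 1 dose
  pre <- applyTreatment(st, cfg, course, tick = 2L, patient = p)
  # tick 2 has no dose and drug level is still 0 in `st`
  expect_identical(unname(pre$state@counts[["B_naive.resting.blood"]]),
                   unname(st@counts[["B_naive.resting.blood"]]))
})

test_that("cladribine depletion ordering holds: B > CD4 > CD8", {
  dep <- local({
    pats <- generateCohort(60, seed = 31, disease = dz)
    t(vapply(pats, function(p) {
      sim <- simulatePatient(p, "cladribine_3.5", cfg, dz,
                             durationWeeks = 53, seed = 2)
      tr <- sim$trajectory
      base <- tr[1, c("cd4_blood", "cd8_blood", "b_blood")]
      m12 <- tr[round(365.25 * 3), c("cd4_blood", "cd8_blood", "b_blood")]
      c(cd4 = 100 * (1 - m12$cd4_blood / base$cd4_blood),
        cd8 = 100 * (1 - m12$cd8_blood / base$cd8_blood),
        b = 100 * (1 - m12$b_blood / base$b_blood))
    }, numeric(3)))
  })
  meds <- apply(dep, 2, median)
  expect_gt(meds[["b"]], meds[["cd4"]])
  expect_gt(meds[["cd4"]], meds[["cd8"]])
})

test_that("cladribine action is non-increasing on its target pools", {
  p <- make_test_patient()
  course <- buildSchedule("cladribine_3.5", 96, p@weight)
  st <- initialState(cfg, NULL, p)
  ct <- st@counts; ct["drug_level"] <- 5
  st <- methods::initialize(st, counts = ct)
  set.seed(4)
  for (i in 1:10) {
    out <- applyTreatment(st, cfg, course, tick = 10000L, patient = p)
    for (pool in c("CD4.resting.blood", "CD8.resting.blood",
                   "B_naive.resting.blood"))
      expect_lte(out$state@counts[[pool]], st@counts[[pool]])
    expect_true(all(out$state@counts >= 0))
    st <- out$state
  }
})

test_that("ocrelizumab spares plasma cells and repletes after stopping", {
  p <- make_test_patient()
  course <- buildSchedule("ocrelizumab", 96, p@weight)
  st <- initialState(cfg, NULL, p)
  ct <- st@counts
  ct["B_plasma.active.lymphoid"] <- 500
  ct["drug_level"] <- 1
  st <- methods::initialize(st, counts = ct)
  set.seed(5)
  out <- applyTreatment(st, cfg, course, tick = 10000L, patient = p)
  expect_equal(out$state@counts[["B_plasma.active.lymphoid"]], 500)
  expect_lt(out$state@counts[["B_naive.resting.blood"]],
            st@counts[["B_naive.resting.blood"]])
  expect_lt(out$actScale, 1)   # T-cell modulation while above threshold

  # after the drug washes out the CD20+ pool recovers toward its set-point
  # with the configured lineage half-time
  sp <- cfg@setPoints[["B_naive.resting.blood"]]
  depleted <- initialState(cfg, NULL, p)
  ct2 <- depleted@counts
  ct2["B_naive.resting.blood"] <- round(0.05 * sp)
  depleted <- methods::initialize(depleted, counts = ct2)
  set.seed(6)
  rec <- runEngine(depleted, cfg, nTicks = 1000)$trajectory$b_blood
  halfTicks <- log(2) / cfg@rates[["rec_b"]]
  deficit0 <- sp - 0.05 * sp
  at_half <- rec[round(halfTicks)]
  expect_lt(abs((sp - at_half) / deficit0 - 0.5), 0.15)
  expect_gt(rec[1000], rec[1])
})

test_that("interferon beta-1a modulates activation only while dosed", {
  p <- make_test_patient()
  course <- buildSchedule("ifnb1a", 96, p@weight)
  st <- initialState(cfg, NULL, p)
  # no dose administered and zero level: identity modulation
  out0 <- applyTreatment(st, cfg, course, tick = 10000L, patient = p)
  expect_equal(out0$actScale, 1)
  expect_equal(out0$bbbRed, 0)
  # with drug on board the activation scale and BBB damage drop
  ct <- st@counts; ct["drug_level"] <- 1
  out1 <- applyTreatment(methods::initialize(st, counts = ct), cfg, course,
                         tick = 10000L, patient = p)
  expect_lt(out1$actScale, 1)
  expect_gt(out1$bbbRed, 0)
  # a zero-effect calibration is indistinguishable from placebo
  null_course <- treatmentCourse("ifn_null", "ifnb1a", course@doses,
                                 pdParams = c(ifn_act_red = 0, ifn_bbb_red = 0))
  out2 <- applyTreatment(methods::initialize(st, counts = ct), cfg,
                         null_course, tick = 10000L, patient = p)
  expect_equal(out2$actScale, 1)
  expect_equal(out2$bbbRed, 0)
})

test_that("placebo is an identity and treated arms never exceed placebo loss", {
  p <- make_test_patient()
  st <- initialState(cfg, NULL, p)
  set.seed(7)
  out <- applyTreatment(st, cfg, buildSchedule("placebo", 96), tick = 1L,
                        patient = p)
  expect_identical(unname(out$state@counts), unname(st@counts))

  pats <- generateCohort(40, seed = 17, disease = dz)
  loss_for <- function(arm) {
    rec <- simulateProfiles(pats, arm, cfg, dz, durationWeeks = 96, seed = 3)
    mean(rec$total_loss)
  }
  placebo <- loss_for("placebo")
  for (arm in c("cladribine_3.5", "ocrelizumab", "ifnb1a"))
    expect_lte(loss_for(arm), placebo * 1.02)
})
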