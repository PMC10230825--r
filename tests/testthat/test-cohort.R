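cfg <- simConfig()
dz <- diseaseConfig()

test_that("patient generation is reproducible and demographically bounded", {
  p1 <- generatePatient(seed = 123)
  p2 <- generatePatient(seed = 123)
  expect_identical(p1@traits, p2@traits)
  expect_identical(p1@hla@mhc2$DR, p2@hla@mhc2$DR)
  d <- clarityDemographics()
  pats <- generateCohort(50, seed = 9, disease = dz)
  ages <- vapply(pats, function(p) p@age, 1)
  expect_true(all(ages >= d$age$min & ages <= d$age$max))
  expect_true(all(vapply(pats, function(p) p@weight, 1) > 0))
  # all eight loci carry allele pairs
  expect_identical(sort(names(p1@hla@mhc2)), c("DM", "DO", "DP", "DQ", "DR"))
  expect_true(all(vapply(c(p1@hla@mhc1, p1@hla@mhc2), length, 1L) == 2L))
})

test_that("HLA allele codes are drawn uniformly over receptor space", {
  pats <- generateCohort(300, seed = 14, disease = dz)
  # pool every allele bit across loci; each position should be fair
  alleles <- unlist(lapply(pats, function(p)
    c(unlist(p@hla@mhc1), unlist(p@hla@mhc2))))
  bits <- do.call(rbind, lapply(strsplit(alleles, ""), as.integer))
  n <- nrow(bits)
  freq <- colMeans(bits)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / n)))
  # chi-square against uniformity across positions
  chi <- sum((colSums(bits) - n / 2)^2 / (n / 4))
  expect_lt(chi, qchisq(0.999, df = ncol(bits)))
})

test_that("profile simulation yields one record per patient-replicate", {
  expect_equal(nrow(simulateProfiles(list(), "placebo", cfg, dz)), 0L)
  pats <- generateCohort(4, seed = 3, disease = dz)
  rec <- simulateProfiles(pats, "placebo", cfg, dz, durationWeeks = 12,
                          replicates = 3L, seed = 1)
  expect_equal(nrow(rec), 12L)
  expect_equal(unname(table(rec$id)), rep(3L, 4), ignore_attr = TRUE)
  # replicates with distinct seeds differ somewhere in their outcomes
  expect_gt(length(unique(interaction(rec$seed, rec$replicate))), 1L)
  expect_true(all(rec$exposure_years > 0))
})

test_that("selection matches a feasible target and fails an infeasible one", {
  set.seed(8)
  mk_rec <- function(relapses) data.frame(
    id = sprintf("P%04d", seq_along(relapses)), replicate = 1L,
    seed = 1L, relapses = relapses, episodes = relapses,
    worst_grade = 0L, total_loss = relapses * 6e4,
    exposure_years = 1.846, arm = "placebo")
  # target equal to the pool's own empirical distribution succeeds
  pool <- mk_rec(rep(c(0, 1, 2, 3, 4), times = c(240, 100, 40, 16, 4)))
  emp <- as.numeric(table(factor(pmin(pool$relapses, 4), levels = 0:4))) / 400
  tgt <- calibrationTarget(setNames(emp, c("0", "1", "2", "3", "4+")),
                           tolerance = 0.05)
  sel <- selectMatching(pool, tgt, 200, seed = 1)
  expect_equal(nrow(sel), 200L)
  expect_lte(attr(sel, "tv")[["relapse"]], 0.05)
  # known stratum counts are matched within tolerance
  cnt <- table(factor(pmin(sel$relapses, 4), levels = 0:4))
  expect_true(all(abs(as.numeric(cnt) / 200 - emp) <= 0.05))
  # all-zero pool cannot satisfy a 30%-relapser target
  zeros <- mk_rec(rep(0, 300))
  bad <- calibrationTarget(c("0" = 0.7, "1" = 0.3, "2" = 0, "3" = 0,
                             "4+" = 0), tolerance = 0.05)
  expect_error(selectMatching(zeros, bad, 100, seed = 1),
               "calibration failure")
  # reproducible given the seed
  expect_identical(selectMatching(pool, tgt, 200, seed = 7)$id,
                   selectMatching(pool, tgt, 200, seed = 7)$id)
})

test_that("augmentation preserves strata and is seed-reproducible", {
  pats <- generateCohort(30, seed = 5, disease = dz)
  strata <- rep(c("0", "1", "2"), times = c(18, 9, 3))
  expect_identical(augmentCohort(pats, 30, seed = 1, strata = strata), pats)
  aug <- augmentCohort(pats, 60, seed = 1, strata = strata)
  expect_length(aug, 60L)
  s2 <- attr(aug, "strata")
  p0 <- table(strata) / 30
  p1 <- table(s2) / 60
  expect_true(all(abs(p1[names(p0)] - p0) <= 0.02 + 1e-9))
  # no stratum absent from the source appears
  expect_true(all(names(p1) %in% names(p0)))
  # deterministic given seed
  ids_a <- vapply(augmentCohort(pats, 60, seed = 9, strata = strata),
                  function(p) p@id, "")
  ids_b <- vapply(augmentCohort(pats, 60, seed = 9, strata = strata),
                  function(p) p@id, "")
  expect_identical(ids_a, ids_b)
})

test_that("identical (records, target, seed) give identical cohorts", {
  pats <- generateCohort(20, seed = 77, disease = dz)
  r1 <- simulateProfiles(pats, "placebo", cfg, dz, durationWeeks = 24,
                         seed = 5)
  r2 <- simulateProfiles(pats, "placebo", cfg, dz, durationWeeks = 24,
                         seed = 5)
  expect_identical(r1, r2)
  emp <- as.numeric(table(factor(pmin(r1$relapses, 4), levels = 0:4))) / 20
  tgt <- calibrationTarget(setNames(emp, c("0", "1", "2", "3", "4+")),
                           tolerance = 0.2)
  expect_identical(selectMatching(r1, tgt, 10, seed = 3),
                   selectMatching(r2, tgt, 10, seed = 3))
})
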