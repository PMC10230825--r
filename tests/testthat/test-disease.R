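cfg <- simConfig()
dz <- diseaseConfig()

test_that("helper differentiation follows the cytokine gates", {
  hi <- 200
  # IL-12 + IFN-gamma dominated milieu: essentially all Th1
  out <- differentiateHelper(1000, c("IL-12" = hi, "IFN-g" = hi), cfg, dz)
  expect_gt(out[["Th1"]], out[["Th17"]] + out[["Th2"]])
  # Th17 milieu without IL-10
  set.seed(2)
  out17 <- differentiateHelper(1000, c("IL-6" = hi, "IL-21" = hi,
                                       "IL-23" = hi, "TGF-b" = hi), cfg, dz)
  expect_gt(out17[["Th17"]], out17[["Th1"]])
  expect_gt(out17[["Th17"]], out17[["Th2"]])
  # IL-10 above the inhibition threshold zeroes the Th17 output
  outBlock <- differentiateHelper(1000, c("IL-6" = hi, "IL-23" = hi,
                                          "TGF-b" = hi, "IL-4" = hi,
                                          "IL-10" = hi), cfg, dz)
  expect_identical(outBlock[["Th17"]], 0)
  expect_gt(outBlock[["Th2"]], 0)
  # zero input, zero output; partition is conserved
  expect_true(all(differentiateHelper(0, c("IL-4" = 5), cfg, dz) == 0))
  expect_equal(sum(out17), 1000)
})

test_that("Treg counts scale all helper subsets down", {
  set.seed(4)
  free <- differentiateHelper(2000, c("IL-12" = 50, "IFN-g" = 50), cfg, dz,
                              tregCount = 0)
  reg <- differentiateHelper(2000, c("IL-12" = 50, "IFN-g" = 50), cfg, dz,
                             tregCount = 2000)
  expect_gt(sum(free[c("Th1", "Th17", "Th2")]),
            sum(reg[c("Th1", "Th17", "Th2")]))
  expect_gt(reg[["suppressed"]], free[["suppressed"]])
})

test_that("antigen presentation requires antigen, DCs and affine clones", {
  p <- make_test_patient(nAuto = 3)
  st <- initialState(cfg, dz, p)
  # zero abundance: no activation events
  set.seed(1)
  s0 <- presentAntigen(st, cfg, dz, p, mbp = mbpAntigen(abundance = 0))
  expect_equal(s0@counts[["DC.active.lymphoid"]], 0)
  expect_equal(s0@counts[["Th1.active.lymphoid"]], 0)
  # no DCs: no activation
  ct <- st@counts; ct["DC.resting.lymphoid"] <- 0
  s1 <- presentAntigen(methods::initialize(st, counts = ct), cfg, dz, p,
                       mbp = mbpAntigen(abundance = 500))
  expect_equal(s1@counts[["CD8.active.lymphoid"]], 0)
  # activation probability strictly increasing in abundance (Monte Carlo)
  act_at <- function(ab, n = 200) {
    set.seed(10)
    mean(replicate(n, {
      s <- presentAntigen(st, cfg, dz, p, mbp = mbpAntigen(abundance = ab))
      s@counts[["CD8.active.lymphoid"]] +
        sum(s@counts[grep("^Th1|^Th2|^Th17", names(s@counts))])
    }))
  }
  a1 <- act_at(20); a2 <- act_at(100); a3 <- act_at(400)
  expect_lt(a1, a2)
  expect_lt(a2, a3)
})

test_that("B-cell activation needs Th2 help and accumulates IgG", {
  p <- make_test_patient(nAuto = 3)
  st <- initialState(cfg, dz, p)
  ct <- st@counts
  for (c in c("IL-4", "IL-5", "IL-6", "IL-13"))
    ct[paste0("cyt.", c, ".lymphoid")] <- 100
  ct["cyt.IL-10.lymphoid"] <- 20   # supportive but below the veto threshold
  # zero Th2: no activation
  set.seed(3)
  s0 <- activateBCells(methods::initialize(st, counts = ct), cfg, dz, p)
  expect_equal(s0@counts[["B_active.active.lymphoid"]], 0)
  # Th2 present: naive B clones activate; binomial oracle on the rate
  ct["Th2.active.lymphoid"] <- 1e6   # saturates the Th2 gate
  st2 <- methods::initialize(st, counts = ct)
  k_b <- dz@rates[["k_b"]]
  K <- cfg@rates[["gate_K"]]
  g <- 0.2 * (4 * 100 / (100 + K) + 20 / (20 + K))
  pr <- 1 - exp(-k_b * g)            # saturated Th2 help, weight-1 clones
  nB <- sum(st2@counts[grep("^B_naive.clone", names(st2@counts))][1:3])
  set.seed(3)
  acts <- replicate(300, {
    s <- activateBCells(st2, cfg, dz, p)
    nB - sum(s@counts[grep("^B_naive.clone", names(s@counts))][1:3])
  })
  expect_lt(abs(mean(acts) - nB * pr), 4 * sqrt(nB * pr * (1 - pr) / 300))
  # IgG is non-decreasing while plasma cells persist
  ct2 <- st2@counts
  ct2["B_plasma.active.lymphoid"] <- 50
  s3 <- activateBCells(methods::initialize(st2, counts = ct2), cfg, dz, p)
  expect_gte(s3@counts[["IgG.level.lymphoid"]],
             ct2[["IgG.level.lymphoid"]])
})

test_that("EBV mimicry activates affine clones only at trigger ticks", {
  p <- make_test_patient(nAuto = 2)
  st <- initialState(cfg, dz, p)
  trig <- ebvTrigger(times = 5L, magnitude = 1)
  # off-trigger tick and zero magnitude are identities
  expect_identical(ebvMimicry(st, cfg, dz, p, trig)@counts, st@counts)
  expect_identical(
    ebvMimicry(st, cfg, dz, p, ebvTrigger(times = 1L, magnitude = 0))@counts,
    st@counts)
  # magnitude 1: every cell of the weight-1 affine clones is activated
  st4 <- methods::initialize(st, tick = 4L)
  set.seed(8)
  s <- ebvMimicry(st4, cfg, dz, p, trig)
  expect_equal(sum(s@counts[grep("^CD8_naive.clone", names(s@counts))][1:2]), 0)
  expect_equal(sum(s@counts[grep("^B_naive.clone", names(s@counts))][1:2]), 0)
  nOn <- sum(st@counts[grep("^CD8_naive.clone", names(st@counts))][1:2])
  expect_equal(s@counts[["CD8.active.lymphoid"]], nOn)
})

test_that("BBB permeability saturates in the weighted cytokine load", {
  expect_equal(damageBbb(c("IL-6" = 0), cfg, dz), dz@rates[["bbb_base"]])
  expect_gt(damageBbb(c("TNF-a" = 1e9), cfg, dz), 0.999)
  # monotone non-decreasing grid scan per mediator
  for (med in c("IFN-g", "TNF-a", "IL-17", "IL-6", "IL-1")) {
    perms <- vapply(c(0, 5, 20, 80, 320), function(v) {
      m <- setNames(v, med)
      damageBbb(m, cfg, dz)
    }, 1)
    expect_true(all(diff(perms) >= 0))
  }
})

test_that("migration obeys the IL-10 veto and conserves cells", {
  p <- make_test_patient()
  st <- initialState(cfg, dz, p)
  ct <- st@counts
  ct["Th1.active.lymphoid"] <- 500; ct["Th17.active.lymphoid"] <- 500
  ct["Macrophage.active.lymphoid"] <- 200; ct["CD8.active.lymphoid"] <- 300
  ct["IgG.level.lymphoid"] <- 100
  for (c in c("IL-12", "IL-17", "IL-6", "IL-22", "IL-23", "TNF-a"))
    ct[paste0("cyt.", c, ".lymphoid")] <- 100
  base <- methods::initialize(st, counts = ct)
  set.seed(5)
  mig <- migrateToCns(base, cfg, dz, permeability = 0.9)
  expect_gt(mig@counts[["Th1.active.CNS"]], 0)
  # conservation per population
  for (pop in c("Th1", "Th17")) {
    tot0 <- ct[[paste0(pop, ".active.lymphoid")]]
    expect_equal(mig@counts[[paste0(pop, ".active.lymphoid")]] +
                 mig@counts[[paste0(pop, ".active.CNS")]], tot0)
  }
  # IL-10 above threshold blocks Th1/Th17/macrophage/IgG but not CD8
  ct10 <- ct
  ct10["cyt.IL-10.lymphoid"] <- 10 * dz@rates[["il10_thr"]]
  set.seed(5)
  blocked <- migrateToCns(methods::initialize(st, counts = ct10), cfg, dz,
                          permeability = 0.9)
  expect_equal(blocked@counts[["Th1.active.CNS"]], 0)
  expect_equal(blocked@counts[["Th17.active.CNS"]], 0)
  expect_equal(blocked@counts[["Macrophage.active.CNS"]], 0)
  expect_equal(blocked@counts[["IgG.level.CNS"]], 0)
  expect_gt(blocked@counts[["CD8.active.CNS"]], 0)
  # resting cells cross only a damaged barrier
  set.seed(6)
  intact <- migrateToCns(base, cfg, dz,
                         permeability = dz@rates[["perm_damage_thr"]] - 0.01)
  expect_equal(intact@counts[["Th_naive.resting.CNS"]], 0)
})

test_that("CNS reactivation needs helper T cells and recruits neutrophils", {
  p <- make_test_patient()
  st <- initialState(cfg, dz, p)
  set.seed(2)
  quiet <- cnsReactivation(st, cfg, dz)
  expect_equal(quiet@counts[["Microglia.active.CNS"]], 0)
  ct <- st@counts
  ct["Th17.active.CNS"] <- 400
  ct["cyt.IL-17.CNS"] <- 100
  ct["bbb_permeability"] <- 0.8
  hot <- methods::initialize(st, counts = ct)
  set.seed(2)
  draws <- replicate(100, {
    s <- cnsReactivation(hot, cfg, dz)
    c(mic = s@counts[["Microglia.active.CNS"]],
      neu = s@counts[["Neutrophil.active.CNS"]])
  })
  expect_gt(mean(draws["mic", ]), 0)
  expect_gt(mean(draws["neu", ]), 0)  # IL-17-driven recruitment
})

test_that("ODC killing matches the analytic binomial mean", {
  p <- make_test_patient()
  st <- initialState(cfg, dz, p)
  # zero effectors: no loss
  set.seed(1)
  expect_equal(killOligodendrocytes(st, cfg, dz)$loss, 0)
  # zero ODC: no loss
  ct0 <- st@counts; ct0["ODC.resting.CNS"] <- 0
  ct0["CD8.active.CNS"] <- 1000
  expect_equal(
    killOligodendrocytes(methods::initialize(st, counts = ct0), cfg, dz)$loss,
    0)
  # one effector type at saturated inflammation: expected loss n*(1-(1-r)^E)
  # approximated by the per-cell hazard r*E (small r), binomial mean oracle
  E <- 50
  ct <- st@counts
  ct["CD8.active.CNS"] <- E
  ct["cyt.TNF-a.CNS"] <- 1e6; ct["cyt.IFN-g.CNS"] <- 1e6  # cg saturates at 1
  hot <- methods::initialize(st, counts = ct)
  r <- dz@rates[["r_cd8"]]
  hazard <- r * E
  n <- cfg@odcCapacity
  set.seed(9)
  losses <- replicate(400, killOligodendrocytes(hot, cfg, dz)$loss)
  expect_lt(abs(mean(losses) - n * hazard),
            4 * sqrt(n * hazard * (1 - hazard) / 400) + n * 1e-5)
})

test_that("ODC bookkeeping: decline never exceeds recorded loss", {
  p <- make_test_patient(nAuto = 4)
  set.seed(21)
  sim <- simulatePatient(p, "placebo", cfg, dz, durationWeeks = 30, seed = 3)
  tr <- sim$trajectory
  decline <- pmax(0, -diff(c(cfg@odcCapacity, tr$odc)))
  expect_true(all(decline <= tr$loss + 1e-9))
  expect_true(all(tr$odc >= 0 & tr$odc <= cfg@odcCapacity))
})

test_that("raising only IL-10 never increases Th17 output or ODC loss", {
  p <- make_test_patient(nAuto = 4)
  st <- initialState(cfg, dz, p)
  ct <- st@counts
  for (c in c("IL-6", "IL-23", "TGF-b")) ct[paste0("cyt.", c, ".lymphoid")] <- 80
  lvls <- c(0, 10, 30, 100, 300)
  th17 <- vapply(lvls, function(v) {
    m <- c("IL-6" = 80, "IL-23" = 80, "TGF-b" = 80, "IL-10" = v)
    set.seed(31)
    differentiateHelper(2000, m, cfg, dz)[["Th17"]]
  }, 1)
  expect_true(all(diff(th17) <= 0))
  # expected cumulative ODC loss under an inflamed start, IL-10 low vs high
  loss_at <- function(il10) {
    ct2 <- ct
    ct2["cyt.IL-10.lymphoid"] <- il10
    ct2["Th1.active.lymphoid"] <- 400; ct2["Th17.active.lymphoid"] <- 400
    ct2["IgG.level.lymphoid"] <- 200
    s <- methods::initialize(st, counts = ct2)
    set.seed(17)
    sum(runEngine(s, cfg, dz, patient = p, nTicks = 150)$trajectory$loss)
  }
  expect_lte(loss_at(300), loss_at(0))
})
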