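test_that("affinity counts complementary positions and is symmetric", {
  expect_identical(affinity("0101", "0101"), 0L)
  expect_identical(affinity(paste(rep("0", 16), collapse = ""),
                            paste(rep("1", 16), collapse = "")), 16L)
  # brute-force oracle at L = 8: position-by-position comparison
  set.seed(1)
  oracle <- function(a, b)
    sum(substring(a, 1:8, 1:8) != substring(b, 1:8, 1:8))
  all8 <- vapply(0:255, function(i)
    paste(rev(as.integer(intToBits(i))[1:8]), collapse = ""), "")
  pairs <- cbind(sample(256, 400, TRUE), sample(256, 400, TRUE))
  for (k in seq_len(nrow(pairs))) {
    a <- all8[pairs[k, 1]]; b <- all8[pairs[k, 2]]
    expect_identical(affinity(a, b), as.integer(oracle(a, b)))
    expect_identical(affinity(a, b), affinity(b, a))
  }
  expect_error(affinity("0101", "01"), "length")
  expect_error(affinity("01a1", "0101"), "0/1")
})

test_that("step is deterministic and inert when all rates are zero", {
  cfg <- simConfig()
  p <- make_test_patient()
  dz <- diseaseConfig()
  st <- initialState(cfg, dz, p)
  run2 <- function() {
    set.seed(99)
    runEngine(st, cfg, dz, patient = p, nTicks = 200,
              ebvTicks = c(10, 50))$trajectory
  }
  expect_identical(run2(), run2())

  zr <- rrmsim:::default_engine_rates() * 0
  zr[["gate_K"]] <- 10          # a saturation constant, not a rate
  zero <- simConfig(rates = zr)
  s0 <- initialState(zero)
  set.seed(1)
  s1 <- stepState(s0, zero)
  expect_identical(s1@tick, 1L)
  expect_identical(unname(s1@counts), unname(s0@counts))
})

test_that("homeostasis holds populations near set-points without disease", {
  cfg <- simConfig()
  st <- initialState(cfg)
  set.seed(7)
  out <- runEngine(st, cfg, nTicks = 1000)
  tr <- out$trajectory
  sp <- cfg@setPoints
  rate <- c(cd4_blood = "rec_cd4", cd8_blood = "rec_cd8", b_blood = "rec_b")
  for (col in names(rate)) {
    key <- c(cd4_blood = "CD4.resting.blood", cd8_blood = "CD8.resting.blood",
             b_blood = "B_naive.resting.blood")[[col]]
    s0 <- sp[[key]]; pr <- cfg@rates[[rate[[col]]]]
    # oracle: replicate binomial birth/death chains give the SE of the
    # 1000-tick time average
    chains <- matrix(s0, nrow = 200, ncol = 1)
    sums <- numeric(200)
    for (t in 1:1000) {
      chains <- chains + rbinom(200, s0, pr) - rbinom(200, chains, pr)
      sums <- sums + chains
    }
    se <- sd(sums / 1000)
    expect_lt(abs(mean(tr[[col]]) - s0), 3 * se)
  }
  expect_true(all(out$state@counts >= 0))
})

test_that("hematopoiesis influx matches the binomial birth oracle", {
  cfg <- simConfig()
  st <- initialState(cfg)
  ct <- st@counts
  ct["Neutrophil.resting.blood"] <- 0  # empty pool: influx only
  st <- methods::initialize(st, counts = ct)
  p <- cfg@rates[["rec_neut"]]
  sp <- cfg@setPoints[["Neutrophil.resting.blood"]]
  set.seed(3)
  draws <- replicate(2000, {
    s2 <- hematopoiesis(st, cfg)
    s2@counts[["Neutrophil.resting.blood"]]
  })
  # influx ~ Binomial(sp, p) minus death Binomial(0, p) = pure influx
  expect_lt(abs(mean(draws) - sp * p), 4 * sqrt(sp * p * (1 - p) / 2000))
  # empty pool with positive set-point has strictly positive expected influx
  expect_gt(mean(draws), 0)
})

test_that("cytokine secretion converges to the closed-form steady state", {
  cfg <- simConfig()
  st <- initialState(cfg)
  ct <- st@counts
  ct[] <- 0
  n_th17 <- 300
  ct["Th17.active.lymphoid"] <- n_th17
  st <- methods::initialize(st, counts = ct)
  for (i in 1:300) st <- secreteAndDecay(st, cfg)
  q <- cfg@rates[["q_sec"]]; d <- cfg@rates[["cyt_decay"]]
  steady <- q * n_th17 * d / (1 - d)   # geometric series limit
  lvl <- cytokineLevels(st)
  expect_equal(lvl["IL-17", "lymphoid"], steady, tolerance = 1e-6)
  # no secretors: decay is geometric toward zero
  st0 <- methods::initialize(st, counts = {
    z <- st@counts; z[grep("^Th17", names(z))] <- 0; z
  })
  st1 <- secreteAndDecay(st0, cfg)
  expect_equal(cytokineLevels(st1)["IL-17", "lymphoid"], lvl["IL-17", "lymphoid"] * d,
               tolerance = 1e-8)
  expect_true(all(st1@counts >= 0))
})

test_that("no operation produces negative counts on randomized states", {
  cfg <- simConfig(); dz <- diseaseConfig()
  p <- make_test_patient()
  set.seed(11)
  for (rep in 1:20) {
    st <- initialState(cfg, dz, p)
    ct <- st@counts
    ct[] <- ct * runif(length(ct), 0, 3)
    idx <- grep("^cyt\\.", names(ct))
    ct[idx] <- runif(length(idx), 0, 100)
    ct["bbb_permeability"] <- runif(1)
    ct["ODC.resting.CNS"] <- round(runif(1, 0, cfg@odcCapacity))
    st <- methods::initialize(st, counts = round(ct, 3))
    s2 <- stepState(st, cfg, dz, patient = p, ebvNow = rep %% 2 == 0)
    expect_true(all(s2@counts >= 0))
    expect_lte(s2@counts[["bbb_permeability"]], 1)
  }
})

test_that("state accessors expose the population structure", {
  cfg <- simConfig()
  st <- initialState(cfg)
  expect_equal(odcCount(st), 150000)
  expect_equal(tickIndex(st), 0L)
  expect_true(bbbPermeability(st) >= 0 && bbbPermeability(st) <= 1)
  cc <- cellCounts(st)
  expect_true("CD4.resting.blood" %in% names(cc))
  expect_false(any(grepl("^cyt\\.", names(cc))))
  lv <- cytokineLevels(st)
  expect_equal(dim(lv), c(16L, 3L))
  expect_true(all(c("IL-10", "TGF-b") %in% rownames(lv)))
})

test_that("invalid states are rejected by the class validity", {
  cfg <- simConfig()
  st <- initialState(cfg)
  ct <- st@counts
  ct["CD4.resting.blood"] <- -5
  expect_error(methods::validObject(methods::initialize(st, counts = ct)),
               "non-negative")
  expect_error(simConfig(durationWeeks = -1), "durationWeeks")
  expect_error(simConfig(rates = c(nonsense_rate = 1)), "unknown")
})
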