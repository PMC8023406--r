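ctrHNA <- c(`FSC-A` = 4.3, `SSC-A` = 3.8, `FL1-A` = 4.8, `FL3-A` = 2.0)

test_that("growth curves honour lag, rate zero and the doubling closed form", {
  sp <- populationSpec("p", ctrHNA, n0 = 100, lagH = 10, mu = 0.1,
                       capacity = 1e6)
  expect_equal(simulateGrowth(sp, c(0, 5, 9.99)), rep(100, 3))

  flat <- populationSpec("p", ctrHNA, n0 = 42, mu = 0)
  expect_equal(simulateGrowth(flat, c(0, 50, 100)), rep(42, 3))

  dbl <- populationSpec("p", ctrHNA, n0 = 100, mu = log(2), capacity = 1e9)
  expect_equal(simulateGrowth(dbl, 3), 800, tolerance = 1e-3)

  expect_error(simulateGrowth(sp, -1), ">= 0")
  expect_error(populationSpec("p", ctrHNA, n0 = 100, mu = 0.1, capacity = 50),
               "capacity")
})

test_that("growth is continuous at the lag and monotone up to capacity", {
  sp <- populationSpec("p", ctrHNA, n0 = 10, lagH = 20, mu = 0.15,
                       capacity = 500)
  eps <- 1e-9
  expect_equal(simulateGrowth(sp, 20 - eps), simulateGrowth(sp, 20 + eps),
               tolerance = 1e-6)
  tt <- seq(0, 200, by = 0.5)
  n <- simulateGrowth(sp, tt)
  expect_true(all(diff(n) >= -1e-9))
  expect_true(all(n <= 500 + 1e-9))
  # decline branch is continuous at its onset too
  dc <- populationSpec("p", ctrHNA, n0 = 100, mu = 0.1, lagH = 0,
                       declineRate = 0.02, declineStartH = 30)
  expect_equal(simulateGrowth(dc, 30 - eps), simulateGrowth(dc, 30 + eps),
               tolerance = 1e-6)
  expect_lt(simulateGrowth(dc, 50), simulateGrowth(dc, 30))
})

test_that("sampling is Poisson-consistent and seeded", {
  pop <- populationSpec("p", ctrHNA, n0 = 100, gateName = "HNA_p")
  cfg <- cocultureConfig(list(pop), seed = 7, backgroundRate = 0)
  counts <- vapply(1:200, function(i)
    nEvents(simulateSample(cfg, 0, seed = 3000 + i)), numeric(1))
  lambda <- 100 * 61 / 100
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # variance/mean ~ 1 for a Poisson count
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.3)

  a <- simulateSample(cfg, 1, seed = 5)
  b <- simulateSample(cfg, 1, seed = 5)
  expect_identical(eventMatrix(a), eventMatrix(b))

  zero <- populationSpec("z", ctrHNA, n0 = 0)
  cfg0 <- cocultureConfig(list(zero), seed = 7, backgroundRate = 0)
  expect_equal(nEvents(simulateSample(cfg0, 0, seed = 1)), 0)
})

test_that("a 3-day run at 25-minute cadence yields 173 samples", {
  pop <- populationSpec("p", ctrHNA, n0 = 5)
  cfg <- cocultureConfig(list(pop), seed = 3, durationH = 72)
  run <- simulateCocultureSeries(cfg)
  # 72*60/25 = 172.8 -> 172 whole intervals, plus the t = 0 sample
  expect_length(run$series@samples, 173)
  expect_equal(elapsedHours(run$series)[1:3], c(0, 25, 50) / 60,
               tolerance = 1e-9)
  tr0 <- run$truth[run$truth$time_h == 0, ]
  expect_equal(tr0$concentration[tr0$population == "p"], 5)
})

test_that("ground truth at t = 0 equals every population's N0", {
  cfg <- cocultureScenario(4, seed = 1)
  run0 <- simulateCocultureSeries({ cfg@durationH <- 1; cfg })
  tr0 <- run0$truth[run0$truth$time_h == 0, ]
  n0s <- vapply(cfg@populations, function(p) p@n0, numeric(1))
  names(n0s) <- vapply(cfg@populations, function(p) p@name, character(1))
  expect_equal(setNames(tr0$concentration, tr0$population), n0s[tr0$population])
  expect_equal(sum(n0s[c("Sphingopyxis", "Tistrella", "Pseudomonas")]), 126.6)
})

test_that("generated events land in their population's gate", {
  gs <- defaultGateSet()
  cfg <- cocultureScenario(3, seed = 17)
  r <- simulateSample(cfg, 60, seed = 44, labels = TRUE)
  tab <- transformEvents(r$table)
  gmap <- setNames(vapply(cfg@populations, function(p) p@gateName, character(1)),
                   vapply(cfg@populations, function(p) p@name, character(1)))
  own <- r$labels != "background"
  hit <- logical(sum(own))
  k <- 0
  for (g in unique(gmap)) {
    mask <- applyGate(tab, gs@gates[[g]])
    sel <- which(own & gmap[r$labels] == g)
    hit[match(sel, which(own))] <- mask[sel]
  }
  expect_gte(mean(hit), 0.99)
})

test_that("preset scenarios anchor their endpoints to the measured values", {
  # coculture 4: prokaryotes 126.6 -> peak 1305.7 at 37.5 h -> 1002.4 at 72 h
  cfg <- cocultureScenario(4)
  prok <- Filter(function(p) p@gateName == "HNA_p", cfg@populations)
  tot <- function(t) sum(vapply(prok, simulateGrowth, numeric(1), t = t))
  expect_equal(tot(0), 126.6, tolerance = 1e-9)
  expect_equal(tot(37.5), 1305.7, tolerance = 1e-6)
  expect_equal(tot(72), 1002.4, tolerance = 1e-6)
  # coculture 1: 2.4 -> 37.0 after a 72.5 h lag, within a 96 h run
  cfg1 <- cocultureScenario(1)
  sph <- Filter(function(p) p@name == "Sphingopyxis", cfg1@populations)[[1]]
  expect_equal(simulateGrowth(sph, 72.5), 2.4, tolerance = 1e-9)
  expect_equal(simulateGrowth(sph, 96), 37.0, tolerance = 1e-6)
  expect_equal(cfg1@durationH, 96)
})
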