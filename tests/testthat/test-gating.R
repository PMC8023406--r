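test_that("log transform maps known values and clips at one unit", {
  m <- cbind(`FL1-A` = c(1.5e4, 0, -5, 1), `FL3-A` = c(10, 10, 10, 10))
  tab <- transformEvents(EventTable(m))
  x <- eventMatrix(tab)[, "FL1-A"]
  expect_equal(x[1], log10(1.5e4), tolerance = 1e-12)
  expect_equal(x[2], 0)  # clipped to 1 before log
  expect_equal(x[3], 0)
  expect_equal(x[4], 0)
  expect_equal(unname(eventMatrix(tab)[1, "FL3-A"]), 1)
})

test_that("the transform is monotone and refuses to run twice", {
  set.seed(7)
  m <- cbind(`FL1-A` = 10^runif(1000, 0, 6), `FL3-A` = 10^runif(1000, 0, 6))
  tab <- EventTable(m)
  tt <- transformEvents(tab)
  for (ch in c("FL1-A", "FL3-A"))
    expect_identical(order(eventMatrix(tt)[, ch]), order(m[, ch]))
  expect_error(transformEvents(tt), "already")
})

test_that("default gates carry the adapted HNA/LNA boundary and threshold", {
  gs <- defaultGateSet()
  fl1 <- log10(1.5e4)
  expect_equal(min(gs@gates$HNA_p@vertices[, 1]), fl1, tolerance = 1e-12)
  expect_equal(max(gs@gates$LNA_p@vertices[, 1]), fl1, tolerance = 1e-12)
  expect_equal(gs@acquisitionThreshold, 800)
  expect_identical(gs@thresholdChannel, "FL1-H")
  expect_true(gatesDisjoint(gs))
  expect_identical(gs@priority, c("microalgal", "HFL3_p", "HNA_p", "LNA_p"))
})

test_that("gate membership uses a closed boundary and matches ray casting", {
  sq <- Gate("sq", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  mkTab <- function(x, y)
    EventTable(cbind(`FL1-A` = x, `FL3-A` = y), transformed = TRUE)
  expect_true(applyGate(mkTab(0.5, 0.5), sq))
  expect_true(applyGate(mkTab(0, 0), sq))      # vertex counts as inside
  expect_true(applyGate(mkTab(0.5, 1), sq))    # edge counts as inside
  expect_false(applyGate(mkTab(1.2, 0.5), sq))

  set.seed(11)
  x <- runif(1e4, 0, 2); y <- runif(1e4, 0, 2)
  got <- applyGate(mkTab(x, y), sq)
  want <- vapply(seq_along(x), function(i) rayCastPoint(x[i], y[i], sq@vertices),
                 logical(1))
  expect_identical(got, want)
  # expected hit count 2500 of 1e4; 3 sigma of a binomial(1e4, 1/4)
  expect_lt(abs(sum(got) - 2500), 3 * sqrt(1e4 * 0.25 * 0.75))
})

test_that("counts convert to concentrations via dilution over volume", {
  gs <- defaultGateSet()
  m <- cbind(`FSC-A` = rep(1e4, 61), `SSC-A` = rep(1e4, 61),
             `FL1-A` = rep(1e5, 61), `FL3-A` = rep(10, 61),
             `FL1-H` = rep(9e4, 61))
  tab <- transformEvents(EventTable(m))  # all events inside HNA_p
  cr <- countPopulations(tab, gs)
  expect_equal(unname(gateCounts(cr)[["HNA_p"]]), 61)
  expect_equal(unname(gateConcentrations(cr)[["HNA_p"]]), 100)
  expect_equal(unname(gateConcentrations(cr)[["LNA_p"]]), 0)  # empty gate

  # doubling the dilution doubles concentrations, counts unchanged
  tab2 <- tab; tab2@dilutionFactor <- 200
  cr2 <- countPopulations(tab2, gs)
  expect_identical(gateCounts(cr2), gateCounts(cr))
  expect_equal(gateConcentrations(cr2), 2 * gateConcentrations(cr))

  # concentrations scale as 1/volume
  tab3 <- tab; tab3@acquiredVolumeuL <- 30.5
  expect_equal(gateConcentrations(countPopulations(tab3, gs)),
               2 * gateConcentrations(cr))
})

test_that("every above-threshold event lands in exactly one bucket", {
  gs <- defaultGateSet()
  tab <- transformEvents(makeLinearTable(5000, seed = 3))
  cr <- countPopulations(tab, gs)
  expect_equal(sum(gateCounts(cr)) + cr@ungated + cr@subThreshold,
               cr@totalEvents)
  expect_equal(cr@totalEvents, 5000)
})

test_that("sub-threshold events are excluded from population counts", {
  gs <- defaultGateSet()
  m <- cbind(`FL1-A` = rep(1e5, 10), `FL3-A` = rep(10, 10),
             `FL1-H` = c(rep(900, 6), rep(100, 4)))
  cr <- countPopulations(transformEvents(EventTable(m)), gs)
  expect_equal(unname(gateCounts(cr)[["HNA_p"]]), 6)
  expect_equal(cr@subThreshold, 4)
})

test_that("a seeded dilute community is recovered without bias", {
  # 100 replicate samples of a 37.0 cells/uL population; the mean recovered
  # concentration must sit within 3 Poisson standard errors of truth
  gs <- defaultGateSet()
  ctr <- c(`FSC-A` = 4.3, `SSC-A` = 3.8, `FL1-A` = 4.8, `FL3-A` = 2.0)
  pop <- populationSpec("sphingo", ctr, n0 = 37.0, gateName = "HNA_p")
  cfg <- cocultureConfig(list(pop), seed = 99, backgroundRate = 0)
  conc <- vapply(1:100, function(i) {
    tab <- transformEvents(simulateSample(cfg, 0, seed = 5000 + i))
    gateConcentrations(countPopulations(tab, gs))[["HNA_p"]]
  }, numeric(1))
  lambda <- 37.0 * 61 / 100
  sePoisson <- sqrt(lambda / 100) * 100 / 61
  expect_lt(abs(mean(conc) - 37.0), 3 * sePoisson)
})

test_that("gate sets round-trip through YAML", {
  gs <- defaultGateSet()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeGateSet(gs, f)
  back <- readGateSet(f)
  expect_identical(back@priority, gs@priority)
  expect_equal(back@acquisitionThreshold, gs@acquisitionThreshold)
  for (g in names(gs@gates))
    expect_equal(back@gates[[g]]@vertices, gs@gates[[g]]@vertices,
                 tolerance = 1e-12)
})

test_that("gates reject degenerate polygons and out-of-range vertices", {
  expect_error(Gate("bad", cbind(c(0, 1), c(0, 1))), "3 vertices")
  expect_error(Gate("bad", cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))), "simple")
  expect_error(Gate("bad", cbind(c(0, 9, 9), c(0, 0, 9))), "range")
})
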