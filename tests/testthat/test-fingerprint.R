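test_that("unit rescaling hits the endpoints and inverts cleanly", {
  full <- log10(2^24)
  m <- cbind(`FL1-A` = c(full, 0, 3.2), `FL3-A` = c(1, 2, 3))
  tab <- EventTable(m, transformed = TRUE)
  u <- rescaleChannels(tab, c("FL1-A", "FL3-A"))
  expect_equal(unname(u[1, "FL1-A"]), 1.0)
  expect_equal(unname(u[2, "FL1-A"]), 0.0)
  set.seed(3)
  r <- matrix(runif(400, 0, full), 100, 4,
              dimnames = list(NULL, c("FSC-A", "SSC-A", "FL1-A", "FL3-A")))
  tab2 <- EventTable(r, transformed = TRUE)
  expect_lt(max(abs(rescaleChannels(tab2) * full - r)), 1e-12)
  expect_warning(
    rescaleChannels(EventTable(cbind(`FL1-A` = c(8, 1), `FL3-A` = c(1, 1)),
                               transformed = TRUE)),
    "clipped")
})

test_that("fingerprints are normalized, sized 6*nbin^2 and deterministic", {
  tab <- makeCommunityTable(300, 200, seed = 9)
  for (nbin in c(32, 64)) {
    fp <- computeFingerprint(tab, nbin = nbin, bandwidth = 0.01)
    v <- fingerprintValues(fp)
    expect_length(v, 6 * nbin^2)
    expect_true(all(v >= 0))
    expect_lt(abs(sum(v) - 1), 1e-9)
  }
  f1 <- computeFingerprint(tab, nbin = 32, subsampleN = 100, seed = 4)
  f2 <- computeFingerprint(tab, nbin = 32, subsampleN = 100, seed = 4)
  expect_identical(fingerprintValues(f1), fingerprintValues(f2))
})

test_that("a point community concentrates each pair grid at one cell", {
  one <- matrix(rep(c(3.1, 2.9, 4.4, 1.7), each = 50), 50, 4,
                dimnames = list(NULL, c("FSC-A", "SSC-A", "FL1-A", "FL3-A")))
  tab <- EventTable(one, transformed = TRUE)
  nbin <- 64
  fp <- computeFingerprint(tab, nbin = nbin, bandwidth = 0.01)
  v <- matrix(fingerprintValues(fp), ncol = 6)
  # each of the 6 pair grids carries exactly 1/6 of the mass
  expect_equal(colSums(v), rep(1 / 6, 6), tolerance = 1e-12)
  # and within each grid, the cell containing the point is the mode
  u <- one[1, c("FL1-A", "FL3-A", "FSC-A", "SSC-A")] / log10(2^24)
  pairs <- combn(4, 2)
  bin <- function(x) pmin(nbin, floor(x * nbin) + 1)
  for (k in 1:6) {
    idx <- bin(u[pairs[1, k]]) + (bin(u[pairs[2, k]]) - 1) * nbin
    expect_equal(which.max(v[, k]), idx)
  }
  expect_error(computeFingerprint(EventTable(one[1, , drop = FALSE],
                                             transformed = TRUE)),
               "insufficient")
})

test_that("Hill diversity matches closed forms and its q -> 1 limit", {
  expect_equal(hillDiversity(c(1, rep(0, 9))), 1)               # point mass
  n <- 128^2
  expect_equal(hillDiversity(rep(1 / n, n)), n)                 # uniform
  expect_equal(hillDiversity(c(0.5, 0.25, 0.25)), 1 / 0.375)

  set.seed(12)
  for (i in 1:25) {
    p <- randProb(sample(3:2000, 1))
    expect_equal(hillDiversity(p, 2), bruteD2(p), tolerance = 1e-9)
    expect_equal(hillDiversity(p, 1), exp(bruteShannon(p)), tolerance = 1e-9)
    # permutation invariance
    expect_equal(hillDiversity(sample(p), 2), hillDiversity(p, 2),
                 tolerance = 1e-12)
  }
  expect_error(hillDiversity(c(0.7, 0.7)), "normalization")
})

test_that("independent ecology oracles agree with the Hill computation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:10) {
    p <- randProb(500)
    expect_equal(hillDiversity(p, 2), unname(vegan::diversity(p, "invsimpson")),
                 tolerance = 1e-9)
    expect_equal(log(hillDiversity(p, 1)), unname(vegan::diversity(p, "shannon")),
                 tolerance = 1e-9)
  }
})

test_that("moving mass towards dominance lowers D2 (Schur concavity)", {
  set.seed(31)
  for (i in 1:20) {
    p <- sort(randProb(sample(3:10, 1)), decreasing = TRUE)
    eps <- p[length(p)] / 2
    q <- p; q[1] <- q[1] + eps; q[length(q)] <- q[length(q)] - eps
    expect_lt(hillDiversity(q, 2), hillDiversity(p, 2))
    expect_gte(hillDiversity(p, 2), 1)
    expect_lte(hillDiversity(p, 2), sum(p > 0) + 1e-12)
  }
})

test_that("bootstrap diversity is seeded and degenerate cases behave", {
  tab <- makeCommunityTable(150, 150, seed = 2)
  one <- diversityBootstrap(tab, nBoot = 1, seed = 7, nbin = 32)
  expect_equal(d2Sd(one), 0)

  a <- diversityBootstrap(tab, nBoot = 3, seed = 7, nbin = 32)
  b <- diversityBootstrap(tab, nBoot = 3, seed = 7, nbin = 32)
  expect_identical(a@d2Boot, b@d2Boot)
  c <- diversityBootstrap(tab, nBoot = 3, seed = 8, nbin = 32)
  expect_false(identical(a@d2Boot, c@d2Boot))
  # different seeds still estimate the same community
  expect_lt(abs(d2Mean(a) - d2Mean(c)), 6 * (d2Sd(a) + d2Sd(c) + 1))
})

test_that("an even community scores higher D2 than a skewed one", {
  wins <- 0
  for (i in 1:6) {
    even <- diversityBootstrap(makeCommunityTable(250, 250, seed = 40 + i),
                               nBoot = 3, seed = 40 + i, nbin = 32)
    skew <- diversityBootstrap(makeCommunityTable(475, 25, seed = 140 + i),
                               nBoot = 3, seed = 140 + i, nbin = 32)
    wins <- wins + (d2Mean(even) > d2Mean(skew))
  }
  expect_gte(wins, 5)
})

test_that("a stationary community yields a flat D2 trajectory", {
  gs <- defaultGateSet()
  ctr <- c(`FSC-A` = 4.3, `SSC-A` = 3.8, `FL1-A` = 4.8, `FL3-A` = 2.0)
  pop <- populationSpec("stable", ctr, n0 = 300, gateName = "HNA_p")
  cfg <- cocultureConfig(list(pop), seed = 50, durationH = 3.8,
                         backgroundRate = 0)
  run <- simulateCocultureSeries(cfg)
  res <- diversityTimeseries(run$series, gates = gs, nbin = 32, nBoot = 3,
                             seed = 99)
  expect_length(res, 10)
  d2 <- vapply(res, d2Mean, numeric(1))
  expect_lt(diff(range(d2)) / mean(d2), 0.5)  # no trend beyond bootstrap noise
  expect_true(all(diff(vapply(res, function(r) r@timeH, numeric(1))) > 0))
})

test_that("samples with too few gated events are skipped with a warning", {
  gs <- defaultGateSet()
  empty <- EventTable(matrix(numeric(0), 0, 4,
                             dimnames = list(NULL, c("FSC-A", "SSC-A",
                                                     "FL1-A", "FL3-A"))),
                      transformed = TRUE, sampleId = "void",
                      timestamp = as.POSIXct("2026-01-01", tz = "UTC"))
  full <- makeCommunityTable(200, 100, seed = 3)
  full@timestamp <- as.POSIXct("2026-01-01 01:00:00", tz = "UTC")
  ser <- makeSeries(list(empty, full))
  expect_warning(res <- diversityTimeseries(ser, gates = gs, nbin = 32,
                                            seed = 1),
                 "skipped")
  expect_length(res, 1)
})
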