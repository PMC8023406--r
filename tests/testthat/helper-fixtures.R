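# Fixtures are built in code; nothing binary ships with the package.

# linear-scale event table with the standard channel set
makeLinearTable <- function(n = 100, seed = 1, sampleId = "fix",
                            timestamp = as.POSIXct("2026-01-01 12:00:00",
                                                   tz = "UTC")) {
  set.seed(seed)
  m <- cbind(
    `FSC-A` = 10^runif(n, 3, 6), `SSC-A` = 10^runif(n, 3, 6),
    `FL1-A` = 10^runif(n, 3, 6), `FL3-A` = 10^runif(n, 0.5, 4),
    `FL1-H` = 10^runif(n, 3, 6), Time = seq_len(n)
  )
  EventTable(m, sampleId = sampleId, timestamp = timestamp)
}

# a transformed table whose events sit in a 2-cluster prokaryote community
makeCommunityTable <- function(n1, n2, seed = 1) {
  set.seed(seed)
  c1 <- c(4.3, 3.8, 4.8, 2.0)  # FSC, SSC, FL1, FL3 (log10)
  c2 <- c(4.5, 4.0, 5.1, 1.6)
  draw <- function(n, ctr) {
    m <- sapply(seq_along(ctr), function(j) rnorm(n, ctr[j], 0.12))
    if (n == 1) m <- matrix(m, 1)
    m
  }
  logm <- rbind(draw(n1, c1), draw(n2, c2))
  colnames(logm) <- c("FSC-A", "SSC-A", "FL1-A", "FL3-A")
  EventTable(logm, transformed = TRUE, sampleId = "community")
}

makeSeries <- function(tsList, t0 = as.POSIXct("2026-01-01", tz = "UTC")) {
  MeasurementSeries(tsList, t0 = t0)
}

mkCTS <- function(t, conc) {
  new("CultureTimeSeries", population = "x", timeH = t, concentration = conc,
      sampleIds = sprintf("s%d", seq_along(t)))
}
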