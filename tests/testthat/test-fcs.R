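test_that("FCS write/read round-trips event matrices and metadata", {
  for (n in c(0L, 1L, 10000L)) {
    tab <- makeLinearTable(n, seed = n + 1)
    f <- withr::local_tempfile(fileext = ".fcs")
    writeFCS(tab, f)
    back <- readFCS(f)
    expect_identical(nEvents(back), n)
    expect_identical(channelNames(back), channelNames(tab))
    if (n > 0)
      expect_lt(max(abs(eventMatrix(back) - eventMatrix(tab)) /
                      pmax(abs(eventMatrix(tab)), 1)), 1e-6)
    expect_equal(acquiredVolume(back), 61)
    expect_equal(dilutionFactor(back), 100)
    expect_equal(as.numeric(sampleTimestamp(back)),
                 as.numeric(sampleTimestamp(tab)))
    expect_identical(sampleId(back), sampleId(tab))
  }
})

test_that("volume and dilution keywords survive non-default values", {
  tab <- makeLinearTable(5)
  tab@acquiredVolumeuL <- 99.5
  tab@dilutionFactor <- 10
  f <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(tab, f)
  back <- readFCS(f)
  expect_equal(acquiredVolume(back), 99.5)
  expect_equal(dilutionFactor(back), 10)
})

test_that("the log-transform flag round-trips through a file", {
  tab <- transformEvents(makeLinearTable(10))
  f <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(tab, f)
  expect_true(isTransformed(readFCS(f)))
})

test_that("a generated sample survives a file round trip exactly in count", {
  cfg <- cocultureScenario(1, seed = 42)
  tab <- simulateSample(cfg, 0)
  f <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(tab, f)
  back <- readFCS(f)
  expect_identical(nEvents(back), nEvents(tab))
  expect_identical(back@keywords[["#SIMULATED"]], "TRUE")
})

test_that("malformed files raise errors naming the offending segment", {
  f <- withr::local_tempfile(fileext = ".fcs")
  writeLines("this is not a flow cytometry file, it is a text file", f)
  expect_error(readFCS(f), "header")

  tab <- makeLinearTable(50)
  f2 <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(tab, f2)
  raw <- readBin(f2, "raw", file.size(f2))
  writeBin(raw[1:(length(raw) - 400)], f2)  # truncate the DATA segment
  expect_error(readFCS(f2), "DATA")
})

test_that("missing required channels are reported with what was found", {
  tab <- makeLinearTable(5)
  f <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(tab, f)
  err <- expect_error(readFCS(f, require = c("FL1-A", "FL9-A")), "FL9-A")
  expect_match(conditionMessage(err), "FL1-A")  # lists channels found
})

test_that("sidecar metadata fills in missing keywords, defaults warn", {
  # hand-written minimal file without $VOL / #DILUTION keywords
  writeBare <- function(path) {
    d <- "\x0c"
    kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0", "$BEGINSTEXT", "0",
            "$ENDSTEXT", "0", "$BEGINDATA", "0", "$ENDDATA", "0",
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0", "$PAR", "1", "$TOT", "0", "$P1N", "FL1-A",
            "$P1B", "32", "$P1E", "0,0", "$P1R", "16777216")
    txt <- paste0(d, paste(kw, collapse = d), d)
    hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", 58L,
                   58L + nchar(txt) - 1L, 0L, 0L, 0L, 0L)
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(paste0(hdr, txt), con, eos = NULL)
  }
  f <- withr::local_tempfile(fileext = ".fcs")
  writeBare(f)
  expect_warning(tab <- readFCS(f), "defaults")
  expect_equal(acquiredVolume(tab), 61)
  expect_equal(dilutionFactor(tab), 100)
  expect_identical(nEvents(tab), 0L)

  writeLines(c("volume_uL: 50", "dilution: 20", "sample_id: side",
               "timestamp: 2026-02-01T08:00:00"), paste0(f, ".yaml"))
  tab2 <- readFCS(f)
  expect_equal(acquiredVolume(tab2), 50)
  expect_equal(dilutionFactor(tab2), 20)
  expect_identical(sampleId(tab2), "side")
})

test_that("loadSeries orders samples and reports elapsed hours", {
  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  paths <- vapply(0:2, function(i) {
    tab <- makeLinearTable(10, seed = i + 1, sampleId = sprintf("s%d", i),
                           timestamp = t0 + i * 25 * 60)
    f <- tempfile(fileext = ".fcs"); writeFCS(tab, f); f
  }, character(1))
  on.exit(unlink(paths))
  ser <- loadSeries(paths, t0 = t0)
  expect_length(ser@samples, 3)
  expect_equal(elapsedHours(ser), c(0, 25 / 60, 50 / 60), tolerance = 1e-10)
})

test_that("files without timestamps fall back to the nominal cadence", {
  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  paths <- vapply(1:3, function(i) {
    tab <- makeLinearTable(5, seed = i)
    tab@timestamp <- flowCulture:::.naTime()
    f <- tempfile(fileext = ".fcs"); writeFCS(tab, f); f
  }, character(1))
  on.exit(unlink(paths))
  expect_warning(ser <- loadSeries(paths, t0 = t0, intervalMin = 25),
                 "assigning")
  expect_equal(elapsedHours(ser), c(0, 25, 50) / 60, tolerance = 1e-10)
})

test_that("duplicate or unordered timestamps are a series error", {
  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  mk <- function(ts, seed) {
    tab <- makeLinearTable(5, seed = seed, timestamp = ts)
    f <- tempfile(fileext = ".fcs"); writeFCS(tab, f); f
  }
  dup <- c(mk(t0, 1), mk(t0, 2))
  on.exit(unlink(dup))
  expect_error(loadSeries(dup, t0 = t0), "duplicate")
  rev2 <- c(mk(t0 + 3600, 3), mk(t0 + 60, 4))
  on.exit(unlink(rev2), add = TRUE)
  expect_error(loadSeries(rev2, t0 = t0), "order")
})
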