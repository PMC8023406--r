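#' Construct an EventTable
#'
#' @param exprs events x channels numeric matrix with channel names as
#'   column names (e.g. `"FSC-A"`, `"SSC-A"`, `"FL1-A"`, `"FL3-A"`).
#' @param acquiredVolumeuL analyzed volume in microlitres (default 61, the
#'   volume corresponding to a 90 s acquisition on the reference instrument).
#' @param dilutionFactor pre-measurement dilution (default 100, i.e. 1:100).
#' @param timestamp acquisition time (`POSIXct`); `NA` if unknown.
#' @param sampleId sample identifier.
#' @param transformed whether analysis channels are already log10-scaled.
#' @param keywords named list of auxiliary keywords.
#' @return an [EventTable-class] object.
#' @examples
#' m <- cbind(`FL1-A` = c(100, 2e4), `FL3-A` = c(50, 80))
#' tab <- EventTable(m, sampleId = "demo")
#' nEvents(tab)
#' @export
EventTable <- function(exprs, acquiredVolumeuL = 61, dilutionFactor = 100,
                       timestamp = .naTime(), sampleId = "sample",
                       transformed = FALSE, keywords = list()) {
  if (is.data.frame(exprs)) exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (!inherits(timestamp, "POSIXct")) timestamp <- as.POSIXct(timestamp, tz = "UTC")
  new("EventTable", exprs = exprs, acquiredVolumeuL = acquiredVolumeuL,
      dilutionFactor = dilutionFactor, timestamp = timestamp,
      sampleId = sampleId, transformed = transformed, keywords = keywords)
}

.naTime <- function() as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")

#' @rdname flowCulture-generics
setMethod("eventMatrix", "EventTable", function(object) object@exprs)

#' @rdname flowCulture-generics
setMethod("channelNames", "EventTable", function(object) colnames(object@exprs))

#' @rdname flowCulture-generics
setMethod("nEvents", "EventTable", function(object) nrow(object@exprs))

#' @rdname flowCulture-generics
setMethod("acquiredVolume", "EventTable", function(object) object@acquiredVolumeuL)

#' @rdname flowCulture-generics
setMethod("dilutionFactor", "EventTable", function(object) object@dilutionFactor)

#' @rdname flowCulture-generics
setMethod("sampleId", "EventTable", function(object) object@sampleId)

#' @rdname flowCulture-generics
setMethod("sampleTimestamp", "EventTable", function(object) object@timestamp)

#' @rdname flowCulture-generics
setMethod("isTransformed", "EventTable", function(object) object@transformed)

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable '%s': %d events x %d channels (%s scale)\n",
              object@sampleId, nrow(object@exprs), ncol(object@exprs),
              if (object@transformed) "log10" else "linear"))
  cat("  channels:", paste(channelNames(object), collapse = ", "), "\n")
  cat(sprintf("  volume %.1f uL, dilution 1:%g, timestamp %s\n",
              object@acquiredVolumeuL, object@dilutionFactor,
              format(object@timestamp)))
})

#' Construct a MeasurementSeries
#'
#' @param samples list of [EventTable-class] objects, time-ordered.
#' @param t0 inoculation time (`POSIXct`).
#' @param samplingIntervalMin nominal cadence in minutes (default 25).
#' @return a [MeasurementSeries-class] object.
#' @export
MeasurementSeries <- function(samples, t0, samplingIntervalMin = 25) {
  if (!inherits(t0, "POSIXct")) t0 <- as.POSIXct(t0, tz = "UTC")
  new("MeasurementSeries", samples = samples, t0 = t0,
      samplingIntervalMin = samplingIntervalMin)
}

setMethod("length", "MeasurementSeries", function(x) length(x@samples))

setMethod("[[", "MeasurementSeries", function(x, i) x@samples[[i]])

#' @rdname flowCulture-generics
setMethod("elapsedHours", "MeasurementSeries", function(object) {
  as.numeric(difftime(.seriesTimestamps(object), object@t0, units = "hours"))
})

setMethod("show", "MeasurementSeries", function(object) {
  eh <- elapsedHours(object)
  cat(sprintf("MeasurementSeries: %d samples, %.2f-%.2f h, cadence %g min\n",
              length(object), if (length(eh)) min(eh) else NA,
              if (length(eh)) max(eh) else NA, object@samplingIntervalMin))
})

#' @rdname flowCulture-generics
setMethod("gateCounts", "CountResult", function(object) object@counts)

#' @rdname flowCulture-generics
setMethod("gateConcentrations", "CountResult", function(object) object@concentrations)

#' @rdname flowCulture-generics
setMethod("sampleId", "CountResult", function(object) object@sampleId)

setMethod("show", "CountResult", function(object) {
  cat(sprintf("CountResult '%s' (t = %.2f h): %d events total\n",
              object@sampleId, object@timeH, object@totalEvents))
  df <- data.frame(count = object@counts,
                   cells_per_uL = round(object@concentrations, 2))
  print(df)
  cat(sprintf("  ungated %d, below threshold %d\n",
              as.integer(object@ungated), as.integer(object@subThreshold)))
})

setMethod("show", "Gate", function(object) {
  cat(sprintf("Gate '%s' on %s x %s, %d vertices\n", object@name,
              object@channelX, object@channelY, nrow(object@vertices)))
})

setMethod("show", "GateSet", function(object) {
  cat(sprintf("GateSet: %d gates (priority: %s)\n", length(object@gates),
              paste(object@priority, collapse = " > ")))
  cat(sprintf("  acquisition threshold %g on %s\n",
              object@acquisitionThreshold, object@thresholdChannel))
})

setMethod("show", "CultureTimeSeries", function(object) {
  cat(sprintf("CultureTimeSeries '%s': %d points, %.2f-%.2f h, %.2f-%.2f cells/uL\n",
              object@population, length(object@timeH),
              min(object@timeH), max(object@timeH),
              min(object@concentration), max(object@concentration)))
})

setMethod("show", "GrowthPhaseAnnotation", function(object) {
  cat("GrowthPhaseAnnotation:\n")
  print(transform(object@segments, mu = signif(mu, 3)))
})

#' @rdname flowCulture-generics
setMethod("fingerprintValues", "Fingerprint", function(object) object@values)

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d channels, nbin %d, bandwidth %g -> length %d (sum %.6f)\n",
              length(object@channels), object@nbin, object@bandwidth,
              length(object@values), sum(object@values)))
})

#' @rdname flowCulture-generics
setMethod("d2Mean", "DiversityResult", function(object) object@d2Mean)

#' @rdname flowCulture-generics
setMethod("d2Sd", "DiversityResult", function(object) object@d2Sd)

setMethod("show", "DiversityResult", function(object) {
  cat(sprintf("DiversityResult: D2 = %.1f +/- %.1f a.u. (n_boot = %d, %d gated events)\n",
              object@d2Mean, object@d2Sd, object@nBoot, object@nEventsGated))
})

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf("PopulationSpec '%s': N0 %.1f cells/uL, lag %.1f h, mu %.3f 1/h, K %g\n",
              object@name, object@n0, object@lagH, object@mu, object@capacity))
})

setMethod("show", "SyntheticCultureConfig", function(object) {
  cat(sprintf("SyntheticCultureConfig: %d populations, %g h at %g-min cadence (seed %d)\n",
              length(object@populations), object@durationH,
              object@samplingIntervalMin, object@seed))
})

#' Tabulate a list of per-sample count results
#'
#' @param counts list of [CountResult-class] objects.
#' @return long-format `data.frame` with columns `sample_id`, `time_h`,
#'   `gate`, `count`, `concentration_cells_per_uL`.
#' @export
countsAsDataFrame <- function(counts) {
  do.call(rbind, lapply(counts, function(cr) {
    gates <- c(names(cr@counts), "ungated", "sub_threshold")
    data.frame(
      sample_id = cr@sampleId,
      time_h = cr@timeH,
      gate = gates,
      count = c(cr@counts, cr@ungated, cr@subThreshold),
      concentration_cells_per_uL = c(cr@concentrations, NA_real_, NA_real_),
      row.names = NULL
    )
  }))
}
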