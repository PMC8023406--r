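#' @import methods
NULL

setOldClass(c("POSIXct", "POSIXt"))

## Instrument dynamic range: 24-bit ADC, so log10 intensities live in
## [0, log10(2^24)] ~ [0, 7.22]; gate coordinates are allowed up to 7.3.
.LOG10_FULL_SCALE <- log10(2^24)
.LOG10_GATE_MAX <- 7.3
.ANALYSIS_CHANNELS <- c("FSC-A", "SSC-A", "FL1-A", "FL3-A")

#' EventTable: per-sample flow-cytometry events with acquisition metadata
#'
#' Container for one measurement point: an events x channels matrix of
#' scatter/fluorescence intensities plus the acquisition metadata needed to
#' turn event counts into concentrations of the original, undiluted culture
#' (analyzed volume in microlitres and pre-measurement dilution factor).
#'
#' @slot exprs numeric matrix, events x channels; column names are channel
#'   labels such as `"FL1-A"`. Intensities are linear instrument units unless
#'   `transformed` is `TRUE`, in which case the analysis channels carry
#'   log10 intensities.
#' @slot acquiredVolumeuL analyzed volume in microlitres (> 0).
#' @slot dilutionFactor pre-measurement dilution (>= 1; 100 means 1:100).
#' @slot timestamp acquisition time (`POSIXct`, may be `NA`).
#' @slot sampleId sample identifier.
#' @slot transformed whether the log10 transform has been applied to the
#'   analysis channels (applied at most once).
#' @slot keywords named list of auxiliary FCS keywords carried through I/O.
#'
#' @seealso [readFCS()], [writeFCS()], [transformEvents()]
#' @exportClass EventTable
setClass("EventTable",
  representation(
    exprs = "matrix",
    acquiredVolumeuL = "numeric",
    dilutionFactor = "numeric",
    timestamp = "POSIXct",
    sampleId = "character",
    transformed = "logical",
    keywords = "list"
  )
)

setValidity("EventTable", function(object) {
  msg <- character(0)
  m <- object@exprs
  if (!is.numeric(m)) msg <- c(msg, "'exprs' must be a numeric matrix")
  if (is.null(colnames(m)) && ncol(m) > 0)
    msg <- c(msg, "'exprs' must have channel names as column names")
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    msg <- c(msg, "channel names must be unique")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "all event intensities must be finite")
  if (length(object@acquiredVolumeuL) != 1 ||
      !is.finite(object@acquiredVolumeuL) || object@acquiredVolumeuL <= 0)
    msg <- c(msg, "'acquiredVolumeuL' must be a single positive number")
  if (length(object@dilutionFactor) != 1 ||
      !is.finite(object@dilutionFactor) || object@dilutionFactor < 1)
    msg <- c(msg, "'dilutionFactor' must be a single number >= 1")
  if (length(object@sampleId) != 1) msg <- c(msg, "'sampleId' must be length 1")
  if (length(object@transformed) != 1 || is.na(object@transformed))
    msg <- c(msg, "'transformed' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' MeasurementSeries: a time-ordered set of flow-cytometry samples
#'
#' @slot samples list of [EventTable-class] objects with strictly increasing
#'   timestamps.
#' @slot t0 inoculation time; elapsed time of sample i is
#'   `timestamp_i - t0` in hours.
#' @slot samplingIntervalMin nominal sampling cadence in minutes.
#'
#' @seealso [loadSeries()], [elapsedHours()]
#' @exportClass MeasurementSeries
setClass("MeasurementSeries",
  representation(
    samples = "list",
    t0 = "POSIXct",
    samplingIntervalMin = "numeric"
  )
)

setValidity("MeasurementSeries", function(object) {
  msg <- character(0)
  if (!all(vapply(object@samples, is, logical(1), "EventTable")))
    msg <- c(msg, "'samples' must all be EventTable objects")
  ts <- .seriesTimestamps(object)
  if (anyNA(ts)) msg <- c(msg, "all samples must carry a timestamp")
  else {
    if (length(ts) > 1 && any(diff(as.numeric(ts)) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
    if (length(ts) && as.numeric(ts[1]) < as.numeric(object@t0))
      msg <- c(msg, "first timestamp precedes t0 (elapsed time would be negative)")
  }
  if (length(object@samplingIntervalMin) != 1 || object@samplingIntervalMin <= 0)
    msg <- c(msg, "'samplingIntervalMin' must be a single positive number")
  if (length(msg)) msg else TRUE
})

.seriesTimestamps <- function(series) {
  do.call(c, lapply(series@samples, function(s) s@timestamp))
}

#' Gate: a 2-D polygon gate in log10 intensity space
#'
#' @slot name gate name, e.g. `"microalgal"`, `"HNA_p"`, `"LNA_p"`, `"HFL3_p"`.
#' @slot channelX,channelY channel names of the gating plane (canonically
#'   `"FL1-A"` x `"FL3-A"`).
#' @slot vertices n x 2 matrix of polygon vertices in log10 intensity units.
#'   Membership uses a closed boundary: points on an edge or vertex are inside.
#'
#' @seealso [applyGate()], [defaultGateSet()]
#' @exportClass Gate
setClass("Gate",
  representation(
    name = "character",
    channelX = "character",
    channelY = "character",
    vertices = "matrix"
  )
)

setValidity("Gate", function(object) {
  msg <- character(0)
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2) msg <- c(msg, "'vertices' must be an n x 2 numeric matrix")
  else {
    if (nrow(v) < 3) msg <- c(msg, "a gate needs at least 3 vertices")
    if (!all(is.finite(v))) msg <- c(msg, "vertices must be finite")
    else if (any(v < 0) || any(v > .LOG10_GATE_MAX))
      msg <- c(msg, sprintf("vertices must lie within the instrument log10 range [0, %.1f]",
                            .LOG10_GATE_MAX))
    if (nrow(v) >= 3 && all(is.finite(v)) && !.polygonIsSimple(v))
      msg <- c(msg, "polygon must be simple (no self-intersection)")
  }
  if (length(object@name) != 1 || !nzchar(object@name)) msg <- c(msg, "'name' required")
  if (length(msg)) msg else TRUE
})

#' GateSet: named gates with an evaluation priority and acquisition threshold
#'
#' Events are assigned to the first gate in `priority` that contains them
#' (first match wins); events matching no gate are labelled "ungated" and kept
#' in totals. Events whose `thresholdChannel` intensity (linear units) falls
#' below `acquisitionThreshold` are discarded before gating, emulating the
#' instrument's acquisition trigger.
#'
#' @slot gates named list of [Gate-class] objects.
#' @slot priority character vector naming every gate exactly once, in
#'   evaluation order.
#' @slot acquisitionThreshold minimum intensity (instrument units) on
#'   `thresholdChannel` for an event to be counted at all.
#' @slot thresholdChannel channel the threshold applies to (default
#'   `"FL1-H"`).
#'
#' @exportClass GateSet
setClass("GateSet",
  representation(
    gates = "list",
    priority = "character",
    acquisitionThreshold = "numeric",
    thresholdChannel = "character"
  )
)

setValidity("GateSet", function(object) {
  msg <- character(0)
  nm <- names(object@gates)
  if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "gates must be uniquely named")
  if (!all(vapply(object@gates, is, logical(1), "Gate")))
    msg <- c(msg, "'gates' must all be Gate objects")
  if (!setequal(object@priority, nm) || length(object@priority) != length(nm))
    msg <- c(msg, "'priority' must cover every gate exactly once")
  if (length(object@acquisitionThreshold) != 1 || object@acquisitionThreshold < 0)
    msg <- c(msg, "'acquisitionThreshold' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' CountResult: per-gate event counts and concentrations for one sample
#'
#' Concentrations refer to the original, undiluted culture:
#' `concentration = count * dilutionFactor / acquiredVolumeuL` (cells/uL).
#' The partition invariant holds: per-gate counts + ungated + sub-threshold
#' events equal the total event count.
#'
#' @slot sampleId sample identifier.
#' @slot timeH elapsed time since inoculation (hours; may be `NA`).
#' @slot counts named numeric, events per gate.
#' @slot concentrations named numeric, cells/uL per gate.
#' @slot ungated above-threshold events contained in no gate.
#' @slot subThreshold events discarded by the acquisition threshold.
#' @slot totalEvents all events in the sample.
#'
#' @seealso [countPopulations()]
#' @exportClass CountResult
setClass("CountResult",
  representation(
    sampleId = "character",
    timeH = "numeric",
    counts = "numeric",
    concentrations = "numeric",
    ungated = "numeric",
    subThreshold = "numeric",
    totalEvents = "numeric"
  )
)

setValidity("CountResult", function(object) {
  msg <- character(0)
  if (!identical(names(object@counts), names(object@concentrations)))
    msg <- c(msg, "'counts' and 'concentrations' must share gate names")
  if (any(object@counts < 0) || any(object@concentrations < 0))
    msg <- c(msg, "counts and concentrations must be non-negative")
  tot <- sum(object@counts) + object@ungated + object@subThreshold
  if (!isTRUE(all.equal(tot, object@totalEvents)))
    msg <- c(msg, "counts + ungated + subThreshold must equal totalEvents")
  if (length(msg)) msg else TRUE
})

#' CultureTimeSeries: concentration trajectory of one gated population
#'
#' @slot population gate name the series was assembled for.
#' @slot timeH hours since inoculation, strictly increasing.
#' @slot concentration cells/uL, non-negative.
#' @slot sampleIds source sample identifiers.
#'
#' @seealso [assembleTimeseries()], [detectGrowthPhases()], [foldChange()]
#' @exportClass CultureTimeSeries
setClass("CultureTimeSeries",
  representation(
    population = "character",
    timeH = "numeric",
    concentration = "numeric",
    sampleIds = "character"
  )
)

setValidity("CultureTimeSeries", function(object) {
  msg <- character(0)
  n <- length(object@timeH)
  if (length(object@concentration) != n || length(object@sampleIds) != n)
    msg <- c(msg, "'timeH', 'concentration' and 'sampleIds' must have equal length")
  if (n > 1 && any(diff(object@timeH) <= 0))
    msg <- c(msg, "'timeH' must be strictly increasing")
  if (any(object@concentration < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GrowthPhaseAnnotation: segmentation of a trajectory into growth phases
#'
#' Phases are inferred from sliding-window log-linear regressions of
#' ln(concentration) on time; each segment carries its specific growth rate
#' estimate (per hour). Segments are contiguous, non-overlapping, and cover
#' the observed time span.
#'
#' @slot segments data.frame with columns `tStart`, `tEnd`, `label`
#'   (lag/exponential/stationary/decline) and `mu` (1/h).
#' @slot times observation times (h).
#' @slot pointMu per-point windowed growth-rate estimates (1/h).
#' @slot pointLabel per-point phase labels after merging.
#'
#' @seealso [detectGrowthPhases()], [lagExponentialBoundary()]
#' @exportClass GrowthPhaseAnnotation
setClass("GrowthPhaseAnnotation",
  representation(
    segments = "data.frame",
    times = "numeric",
    pointMu = "numeric",
    pointLabel = "character"
  )
)

#' Fingerprint: the phenotypic fingerprint of a gated community
#'
#' A probability vector obtained by binning events on an `nbin` x `nbin` grid
#' over the unit square for every unordered pair of the selected channels,
#' Gaussian-smoothing each grid, flattening, concatenating, and globally
#' normalizing to sum one.
#'
#' @slot values non-negative vector of length `n_pairs * nbin^2`, sums to 1.
#' @slot channels channels used (default FL1-A, FL3-A, FSC-A, SSC-A).
#' @slot nbin grid size per axis.
#' @slot bandwidth Gaussian kernel width on the unit scale.
#' @slot gateName gate applied before estimation ("" if none).
#' @slot subsampleN events drawn (NA if all events used).
#' @slot nEvents events that entered the estimate.
#'
#' @seealso [computeFingerprint()], [hillDiversity()]
#' @exportClass Fingerprint
setClass("Fingerprint",
  representation(
    values = "numeric",
    channels = "character",
    nbin = "integer",
    bandwidth = "numeric",
    gateName = "character",
    subsampleN = "numeric",
    nEvents = "integer"
  )
)

setValidity("Fingerprint", function(object) {
  msg <- character(0)
  np <- choose(length(object@channels), 2)
  if (length(object@values) != np * object@nbin^2)
    msg <- c(msg, "length(values) must equal n_pairs * nbin^2")
  if (any(object@values < 0)) msg <- c(msg, "fingerprint entries must be >= 0")
  if (length(object@values) && abs(sum(object@values) - 1) > 1e-9)
    msg <- c(msg, "fingerprint must sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' DiversityResult: bootstrap Hill diversity of order two
#'
#' @slot d2Mean mean phenotypic diversity index over bootstraps (a.u.).
#' @slot d2Sd bootstrap standard deviation (a.u.).
#' @slot d2Boot per-bootstrap D2 values.
#' @slot nBoot number of bootstraps.
#' @slot timeH elapsed time of the sample (h, may be NA).
#' @slot nEventsGated gated events resampled.
#' @slot settings fingerprint settings (nbin, bandwidth, channels, gate);
#'   D2 values are comparable only across identical settings.
#'
#' @seealso [diversityBootstrap()], [diversityTimeseries()]
#' @exportClass DiversityResult
setClass("DiversityResult",
  representation(
    d2Mean = "numeric",
    d2Sd = "numeric",
    d2Boot = "numeric",
    nBoot = "integer",
    timeH = "numeric",
    nEventsGated = "integer",
    settings = "list"
  )
)

setValidity("DiversityResult", function(object) {
  msg <- character(0)
  if (object@nBoot < 1) msg <- c(msg, "'nBoot' must be >= 1")
  if (length(object@d2Boot) != object@nBoot)
    msg <- c(msg, "'d2Boot' must have nBoot entries")
  if (any(object@d2Boot < 1)) msg <- c(msg, "D2 cannot be below 1")
  if (object@d2Sd < 0) msg <- c(msg, "'d2Sd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PopulationSpec: one synthetic population's cluster shape and growth curve
#'
#' Events are log-normal: Gaussian in log10 intensity space around `center`
#' with covariance `covariance`. Concentration follows a lag phase at `n0`,
#' then logistic growth at rate `mu` towards carrying capacity `capacity`,
#' optionally switching to exponential decline after `declineStartH`.
#'
#' @slot name population name.
#' @slot center named numeric, cluster mean per channel (log10 units) over
#'   FSC-A, SSC-A, FL1-A, FL3-A.
#' @slot covariance 4 x 4 symmetric positive-definite matrix (log10 units^2).
#' @slot n0 initial concentration (cells/uL, >= 0).
#' @slot lagH lag duration (h).
#' @slot mu specific growth rate (1/h, >= 0).
#' @slot capacity carrying capacity K (cells/uL; `Inf` for pure exponential).
#' @slot declineRate exponential decline rate after the peak (1/h; `NA` = none).
#' @slot declineStartH time the decline starts (h; `NA` = none).
#' @slot gateName the gate this cluster is designed to fall into (used by
#'   recovery tests; `""` if unspecified).
#'
#' @seealso [populationSpec()], [simulateGrowth()]
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  representation(
    name = "character",
    center = "numeric",
    covariance = "matrix",
    n0 = "numeric",
    lagH = "numeric",
    mu = "numeric",
    capacity = "numeric",
    declineRate = "numeric",
    declineStartH = "numeric",
    gateName = "character"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character(0)
  ch <- .ANALYSIS_CHANNELS
  if (!all(ch %in% names(object@center)))
    msg <- c(msg, sprintf("'center' must name %s", paste(ch, collapse = ", ")))
  cv <- object@covariance
  if (!is.matrix(cv) || nrow(cv) != 4 || ncol(cv) != 4)
    msg <- c(msg, "'covariance' must be 4 x 4")
  else {
    if (max(abs(cv - t(cv))) > 1e-12) msg <- c(msg, "'covariance' must be symmetric")
    else if (any(eigen(cv, symmetric = TRUE, only.values = TRUE)$values <= 0))
      msg <- c(msg, "'covariance' must be positive-definite")
  }
  if (object@n0 < 0) msg <- c(msg, "'n0' must be >= 0")
  if (object@mu < 0) msg <- c(msg, "'mu' must be >= 0")
  if (object@lagH < 0) msg <- c(msg, "'lagH' must be >= 0")
  if (object@mu > 0 && is.finite(object@capacity) && object@capacity < object@n0)
    msg <- c(msg, "'capacity' must be >= n0 when mu > 0")
  if (!is.na(object@declineStartH) && is.na(object@declineRate))
    msg <- c(msg, "'declineRate' required when 'declineStartH' is set")
  if (length(msg)) msg else TRUE
})

#' SyntheticCultureConfig: a full synthetic coculture experiment
#'
#' @slot populations list of [PopulationSpec-class] objects.
#' @slot backgroundRate expected background events per sample (uniform
#'   low-intensity cloud).
#' @slot backgroundBox named list of c(lo, hi) log10 ranges per channel for
#'   background events.
#' @slot durationH experiment duration (h).
#' @slot samplingIntervalMin sampling cadence (min, default 25).
#' @slot acquiredVolumeuL analyzed volume per sample (uL, default 61).
#' @slot dilutionFactor pre-measurement dilution (default 100).
#' @slot seed mandatory base seed; per-sample substreams are derived from it.
#' @slot t0 inoculation time.
#'
#' @seealso [cocultureConfig()], [simulateCocultureSeries()]
#' @exportClass SyntheticCultureConfig
setClass("SyntheticCultureConfig",
  representation(
    populations = "list",
    backgroundRate = "numeric",
    backgroundBox = "list",
    durationH = "numeric",
    samplingIntervalMin = "numeric",
    acquiredVolumeuL = "numeric",
    dilutionFactor = "numeric",
    seed = "integer",
    t0 = "POSIXct"
  )
)

setValidity("SyntheticCultureConfig", function(object) {
  msg <- character(0)
  if (!all(vapply(object@populations, is, logical(1), "PopulationSpec")))
    msg <- c(msg, "'populations' must be PopulationSpec objects")
  nm <- vapply(object@populations, function(p) p@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "population names must be unique")
  if (object@durationH <= 0) msg <- c(msg, "'durationH' must be > 0")
  if (object@samplingIntervalMin <= 0) msg <- c(msg, "'samplingIntervalMin' must be > 0")
  if (object@acquiredVolumeuL <= 0) msg <- c(msg, "'acquiredVolumeuL' must be > 0")
  if (object@dilutionFactor < 1) msg <- c(msg, "'dilutionFactor' must be >= 1")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "'seed' is mandatory")
  if (object@backgroundRate < 0) msg <- c(msg, "'backgroundRate' must be >= 0")
  if (length(msg)) msg else TRUE
})
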