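## Growth dynamics: trajectory assembly, sliding-window phase detection,
## fold-change and percent-change summaries.

#' Assemble a concentration time series for one gated population
#'
#' @param counts list of [CountResult-class] objects with `timeH` set.
#' @param population gate name to extract. A sample lacking that gate is an
#'   error naming the sample (never a silent zero).
#' @return a [CultureTimeSeries-class], ordered in time.
#' @export
assembleTimeseries <- function(counts, population) {
  if (length(counts) < 2)
    stop("at least two count results are required", call. = FALSE)
  conc <- vapply(counts, function(cr) {
    if (!population %in% names(cr@concentrations))
      stop("population '", population, "' absent from sample '",
           cr@sampleId, "'", call. = FALSE)
    cr@concentrations[[population]]
  }, numeric(1))
  times <- vapply(counts, function(cr) cr@timeH, numeric(1))
  ids <- vapply(counts, function(cr) cr@sampleId, character(1))
  if (anyNA(times)) stop("count results must carry elapsed times", call. = FALSE)
  if (anyDuplicated(times)) stop("duplicate times in count results", call. = FALSE)
  o <- order(times)
  new("CultureTimeSeries", population = population, timeH = times[o],
      concentration = conc[o], sampleIds = ids[o])
}

#' Detect lag / exponential / stationary / decline growth phases
#'
#' The specific growth rate at each observation is estimated by log-linear
#' regression of ln(concentration) on time over a sliding window centred on
#' the observation (zeros are replaced by half the smallest positive
#' concentration before taking logs). Points are labelled by comparing the
#' windowed rate to `muThreshold`: above it, exponential; below its negative,
#' decline; otherwise lag (before any exponential phase) or stationary
#' (after). Adjacent same-label points are merged into contiguous segments
#' covering the observed span; segments shorter than `minSegmentH` are
#' absorbed into their longer neighbour, which suppresses label flicker from
#' counting noise.
#'
#' @param series a [CultureTimeSeries-class] with at least 5 points.
#' @param windowH sliding-window width in hours (default 10; must span at
#'   least 3 observations).
#' @param muThreshold growth-rate threshold in 1/h (default 0.02).
#' @param minSegmentH minimum segment duration in hours (default 5).
#' @return a [GrowthPhaseAnnotation-class].
#' @seealso [lagExponentialBoundary()]
#' @export
detectGrowthPhases <- function(series, windowH = 10, muThreshold = 0.02,
                               minSegmentH = 5) {
  stopifnot(is(series, "CultureTimeSeries"))
  t <- series@timeH
  conc <- series@concentration
  n <- length(t)
  if (n < 5) stop("at least 5 points are required", call. = FALSE)
  if (all(conc == 0))
    stop("degenerate series: all concentrations are zero", call. = FALSE)
  pos <- conc[conc > 0]
  pseudo <- min(pos) / 2
  lc <- log(ifelse(conc <= 0, pseudo, conc))

  mu <- numeric(n)
  half <- windowH / 2
  for (i in seq_len(n)) {
    idx <- which(t >= t[i] - half & t <= t[i] + half)
    if (length(idx) < 3) idx <- order(abs(t - t[i]))[1:3]
    tw <- t[idx]; lw <- lc[idx]
    mu[i] <- sum((tw - mean(tw)) * (lw - mean(lw))) / sum((tw - mean(tw))^2)
  }
  if (max(t) - min(t) < windowH && n < 3)
    stop("window must span at least 3 points", call. = FALSE)

  lab <- ifelse(mu > muThreshold, "exponential",
                ifelse(mu < -muThreshold, "decline", "flat"))
  # resolve 'flat' to lag before the first exponential point, stationary after
  firstExp <- match("exponential", lab)
  lab[lab == "flat"] <- ifelse(
    seq_len(n)[lab == "flat"] < ifelse(is.na(firstExp), n + 1L, firstExp),
    "lag", "stationary")

  # absorb short runs into the longer neighbour
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) break
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    durs <- t[ends] - t[starts]
    short <- which(durs < minSegmentH)
    if (!length(short)) break
    k <- short[which.min(durs[short])]
    nb <- if (k == 1) 2L else if (k == length(r$lengths)) k - 1L else {
      if (durs[k - 1] >= durs[k + 1]) k - 1L else k + 1L
    }
    lab[starts[k]:ends[k]] <- r$values[nb]
  }

  # relabel each merged segment from its own regression slope (so labels and
  # segment-level rates are mutually consistent), iterating until stable
  segMuOf <- function(idx) {
    if (length(idx) >= 2) {
      tw <- t[idx]; lw <- lc[idx]
      sum((tw - mean(tw)) * (lw - mean(lw))) / sum((tw - mean(tw))^2)
    } else mu[idx]
  }
  for (pass in 1:5) {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    segMu <- vapply(seq_along(starts), function(k) segMuOf(starts[k]:ends[k]),
                    numeric(1))
    segLab <- ifelse(segMu > muThreshold, "exponential",
                     ifelse(segMu < -muThreshold, "decline", "flat"))
    firstExpSeg <- match("exponential", segLab)
    segLab[segLab == "flat"] <- ifelse(
      seq_along(segLab)[segLab == "flat"] <
        ifelse(is.na(firstExpSeg), length(segLab) + 1L, firstExpSeg),
      "lag", "stationary")
    newLab <- rep(segLab, r$lengths)
    if (identical(newLab, lab)) break
    lab <- newLab
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  segMu <- vapply(seq_along(starts), function(k) segMuOf(starts[k]:ends[k]),
                  numeric(1))
  bounds <- if (length(starts) > 1)
    (t[ends[-length(ends)]] + t[starts[-1]]) / 2 else numeric(0)
  segs <- data.frame(
    tStart = c(t[1], bounds),
    tEnd = c(bounds, t[n]),
    label = r$values,
    mu = segMu,
    stringsAsFactors = FALSE
  )
  new("GrowthPhaseAnnotation", segments = segs, times = t, pointMu = mu,
      pointLabel = lab)
}

#' Time of the lag-to-exponential transition
#'
#' Without `series`, returns the start time of the longest exponential
#' segment. With the underlying trajectory supplied, the estimate is refined
#' by a two-phase least-squares fit in log space — a constant (lag) segment
#' followed by a free straight line (exponential growth), with the
#' breakpoint chosen to minimise the total squared error. The refinement is
#' much less sensitive to counting noise at low concentrations than the
#' windowed labels; it assumes a single lag-to-growth transition, so apply
#' it to the pre-peak part of a trajectory that later declines.
#'
#' @param annotation a [GrowthPhaseAnnotation-class].
#' @param series optionally, the [CultureTimeSeries-class] the annotation was
#'   computed from, enabling the changepoint refinement.
#' @return time in hours, or `NA` if no exponential phase was found.
#' @export
lagExponentialBoundary <- function(annotation, series = NULL) {
  segs <- annotation@segments
  ex <- segs[segs$label == "exponential", , drop = FALSE]
  if (!nrow(ex)) return(NA_real_)
  coarse <- ex$tStart[which.max(ex$tEnd - ex$tStart)]
  if (is.null(series)) return(coarse)
  stopifnot(is(series, "CultureTimeSeries"))
  t <- series@timeH
  conc <- series@concentration
  pos <- conc[conc > 0]
  lc <- log(ifelse(conc <= 0, min(pos) / 2, conc))
  n <- length(t)
  if (n < 5) return(coarse)
  sseLin <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) return(sum((y - mean(y))^2))
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    sum((y - mean(y) - b * (x - mean(x)))^2)
  }
  best <- coarse; bestSse <- Inf
  for (i in 2:(n - 2)) {
    sse <- sum((lc[1:i] - mean(lc[1:i]))^2) +
      sseLin(t[(i + 1):n], lc[(i + 1):n])
    if (sse < bestSse) {
      bestSse <- sse
      best <- (t[i] + t[i + 1]) / 2
    }
  }
  best
}

#' Fold change of a concentration trajectory
#'
#' `final` mode is last/first; `max` mode is max/first (the paper-style
#' "peak" fold). The first concentration must be positive.
#'
#' @param series a [CultureTimeSeries-class] or a numeric concentration
#'   vector in time order.
#' @param mode `"final"` (default) or `"max"`.
#' @return the dimensionless ratio.
#' @examples
#' foldChange(c(126.6, 1002.4))           # 7.92, i.e. 8-fold to nearest integer
#' foldChange(c(2.4, 40, 37), mode = "max")
#' @export
foldChange <- function(series, mode = c("final", "max")) {
  mode <- match.arg(mode)
  x <- if (is(series, "CultureTimeSeries")) series@concentration else series
  if (length(x) < 2) stop("need at least two concentrations", call. = FALSE)
  if (x[1] <= 0)
    stop("undefined ratio: first concentration must be > 0", call. = FALSE)
  if (mode == "final") x[length(x)] / x[1] else max(x) / x[1]
}

#' Percent change between two values
#'
#' `increase`: `(target - reference) / reference * 100`;
#' `decline`: `(reference - target) / reference * 100`. Values are returned
#' unrounded; round to one decimal for reporting, as is conventional.
#'
#' @param reference baseline value (> 0).
#' @param target value compared against the baseline.
#' @param direction `"increase"` or `"decline"`.
#' @param digits optional rounding for reporting (e.g. 1); `NULL` = exact.
#' @return the percent change.
#' @examples
#' percentChange(1465.5, 2341.1, "increase", digits = 1)  # 59.7
#' percentChange(2341.1, 1680.5, "decline", digits = 1)   # 28.2
#' @export
percentChange <- function(reference, target,
                          direction = c("increase", "decline"),
                          digits = NULL) {
  direction <- match.arg(direction)
  if (reference <= 0)
    stop("undefined: reference must be > 0", call. = FALSE)
  pct <- switch(direction,
                increase = (target - reference) / reference * 100,
                decline = (reference - target) / reference * 100)
  if (!is.null(digits)) round(pct, digits) else pct
}

#' Tabulate a trajectory with its phase annotation
#'
#' @param series a [CultureTimeSeries-class].
#' @param annotation the matching [GrowthPhaseAnnotation-class] (optional).
#' @return `data.frame` with columns `time_h`, `population`,
#'   `concentration_cells_per_uL`, `phase_label`, `mu_per_h`.
#' @export
dynamicsAsDataFrame <- function(series, annotation = NULL) {
  df <- data.frame(
    time_h = series@timeH,
    population = series@population,
    concentration_cells_per_uL = series@concentration,
    phase_label = NA_character_,
    mu_per_h = NA_real_,
    row.names = NULL
  )
  if (!is.null(annotation)) {
    df$phase_label <- annotation@pointLabel
    df$mu_per_h <- annotation@pointMu
  }
  df
}
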