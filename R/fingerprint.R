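## Phenotypic fingerprinting: binned bivariate kernel density grids over
## every pair of the selected channels, concatenated into one probability
## vector, summarised by the Hill diversity of order two with bootstrap
## errors ("effective number of phenotypic states").

#' Rescale log-transformed channels to the unit interval
#'
#' Divides each log10 intensity by log10(2^24), the instrument's 24-bit full
#' scale, mapping the dynamic range onto [0, 1] so kernel-density grids are
#' comparable across samples. Values above 1 are clipped with a warning.
#'
#' @param table a log-transformed [EventTable-class].
#' @param channels channels to rescale (default: the analysis channels).
#' @return numeric matrix of unit-scaled values, events x channels.
#' @export
rescaleChannels <- function(table, channels = NULL) {
  stopifnot(is(table, "EventTable"))
  if (!isTransformed(table))
    stop("events must be log-transformed first; see transformEvents()",
         call. = FALSE)
  if (is.null(channels))
    channels <- intersect(.ANALYSIS_CHANNELS, channelNames(table))
  missing <- setdiff(channels, channelNames(table))
  if (length(missing))
    stop("channel error: ", paste(missing, collapse = ", "),
         " not present", call. = FALSE)
  m <- eventMatrix(table)[, channels, drop = FALSE] / .LOG10_FULL_SCALE
  if (length(m) && any(m > 1)) {
    warning("values above full scale clipped to 1", call. = FALSE)
    m[m > 1] <- 1
  }
  m
}

## Column-normalized Gaussian band matrix: entry [i, j] is the share of mass
## moving from source bin j to target bin i. Truncated at 4 sigma; columns
## sum to 1 (edge bins renormalized), so smoothing conserves total mass.
.blurMatrix <- function(nbin, sigmaBins) {
  if (sigmaBins <= 0) return(diag(nbin))
  r <- max(1L, ceiling(4 * sigmaBins))
  K <- matrix(0, nbin, nbin)
  for (j in seq_len(nbin)) {
    lo <- max(1L, j - r); hi <- min(nbin, j + r)
    w <- stats::dnorm(lo:hi, mean = j, sd = sigmaBins)
    K[lo:hi, j] <- w / sum(w)
  }
  K
}

## Fingerprint of a unit-scaled event matrix: per channel pair, 2-D histogram
## on an nbin x nbin grid over [0,1]^2, Gaussian-smoothed, flattened; grids
## are concatenated and globally normalized to sum 1.
.fingerprintFromUnit <- function(m, nbin, bandwidth) {
  ch <- colnames(m)
  pairs <- utils::combn(length(ch), 2)
  K <- .blurMatrix(nbin, bandwidth * nbin)
  bin <- function(x) pmin(nbin, floor(x * nbin) + 1L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ix <- bin(m[, pairs[1, k]])
    iy <- bin(m[, pairs[2, k]])
    H <- matrix(tabulate(ix + (iy - 1L) * nbin, nbins = nbin * nbin),
                nbin, nbin)
    out[[k]] <- as.vector(K %*% H %*% t(K))
  }
  v <- unlist(out)
  v / sum(v)
}

#' Compute the phenotypic fingerprint of a (gated) sample
#'
#' For each of the unordered pairs of the selected channels (6 pairs for the
#' default 4 channels) the gated events are binned on an `nbin` x `nbin`
#' grid over the unit square, smoothed with a Gaussian kernel of width
#' `bandwidth` (unit scale, truncated at 4 sigma), flattened, concatenated,
#' and globally normalized to sum one. The result is a probability vector of
#' length `choose(n_channels, 2) * nbin^2` describing the community's
#' single-cell phenotype distribution.
#'
#' @param table an [EventTable-class]; transformed to log scale internally
#'   if still linear.
#' @param gate optional [Gate-class] restricting the events used.
#' @param channels phenotypic traits (default FL1-A, FL3-A, FSC-A, SSC-A).
#' @param nbin grid size per axis (default 128).
#' @param bandwidth kernel width on the unit scale (default 0.01).
#' @param subsampleN if smaller than the available events, that many events
#'   are drawn with replacement under `seed`.
#' @param seed RNG seed for the subsample draw (required for reproducibility
#'   when `subsampleN` is used).
#' @return a [Fingerprint-class].
#' @seealso [hillDiversity()], [diversityBootstrap()]
#' @export
computeFingerprint <- function(table, gate = NULL,
                               channels = c("FL1-A", "FL3-A", "FSC-A", "SSC-A"),
                               nbin = 128, bandwidth = 0.01,
                               subsampleN = NULL, seed = NULL) {
  stopifnot(is(table, "EventTable"))
  if (!isTransformed(table)) table <- transformEvents(table)
  keep <- if (is.null(gate)) rep(TRUE, nEvents(table)) else applyGate(table, gate)
  m <- rescaleChannels(table, channels)[keep, , drop = FALSE]
  if (nrow(m) < 2)
    stop("insufficient data: need at least 2 gated events", call. = FALSE)
  drawn <- NA_real_
  if (!is.null(subsampleN) && subsampleN < nrow(m)) {
    m <- .withSeed(seed, m[sample.int(nrow(m), subsampleN, replace = TRUE), ,
                           drop = FALSE])
    drawn <- subsampleN
  }
  v <- .fingerprintFromUnit(m, nbin, bandwidth)
  new("Fingerprint", values = v, channels = channels, nbin = as.integer(nbin),
      bandwidth = bandwidth,
      gateName = if (is.null(gate)) "" else gate@name,
      subsampleN = drawn, nEvents = nrow(m))
}

#' Hill diversity of order q
#'
#' `D_q = (sum(p_i^q))^(1/(1-q))` for `q != 1`; at `q = 1` the limit,
#' `exp` of the Shannon entropy. Order two gives the inverse Simpson index
#' `1 / sum(p_i^2)`, weighing richness and evenness equally — the phenotypic
#' diversity index when applied to a fingerprint. `D_q` ranges from 1 (a
#' point mass) to the number of non-zero entries (uniform distribution).
#'
#' @param x a [Fingerprint-class] or a probability vector summing to 1.
#' @param q Hill order (>= 0; default 2).
#' @return the diversity (a.u. for fingerprints).
#' @examples
#' hillDiversity(c(0.5, 0.25, 0.25))        # 1 / 0.375 = 2.667
#' hillDiversity(rep(1 / 16384, 16384))     # uniform: support size
#' @export
hillDiversity <- function(x, q = 2) {
  p <- if (is(x, "Fingerprint")) fingerprintValues(x) else x
  if (q < 0) stop("'q' must be >= 0", call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("normalization error: input must be a probability vector summing to 1",
         call. = FALSE)
  p <- p[p > 0]
  p <- p / sum(p)  # remove the residual <= 1e-6 imbalance
  if (q == 1) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Bootstrap phenotypic diversity of a gated community
#'
#' Draws `nBoot` independent resamples of the gated events (with
#' replacement, at the full gated size), computes the fingerprint and its
#' order-two Hill diversity for each, and reports the mean and standard
#' deviation across bootstraps.
#'
#' @inheritParams computeFingerprint
#' @param nBoot number of bootstraps (default 3).
#' @param timeH elapsed time annotation carried into the result.
#' @return a [DiversityResult-class].
#' @export
diversityBootstrap <- function(table, gate = NULL,
                               channels = c("FL1-A", "FL3-A", "FSC-A", "SSC-A"),
                               nbin = 128, bandwidth = 0.01, nBoot = 3,
                               seed = NULL, timeH = NA_real_) {
  stopifnot(is(table, "EventTable"), nBoot >= 1)
  if (!isTransformed(table)) table <- transformEvents(table)
  keep <- if (is.null(gate)) rep(TRUE, nEvents(table)) else applyGate(table, gate)
  m <- rescaleChannels(table, channels)[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 2)
    stop("insufficient data: need at least 2 gated events", call. = FALSE)
  d2 <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
    mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
    hillDiversity(.fingerprintFromUnit(mb, nbin, bandwidth), q = 2)
  }, numeric(1)))
  new("DiversityResult",
      d2Mean = mean(d2), d2Sd = if (nBoot > 1) stats::sd(d2) else 0,
      d2Boot = d2, nBoot = as.integer(nBoot), timeH = timeH,
      nEventsGated = as.integer(n),
      settings = list(nbin = as.integer(nbin), bandwidth = bandwidth,
                      channels = channels,
                      gate = if (is.null(gate)) "" else gate@name))
}

#' Diversity trajectory of a measurement series
#'
#' Applies [diversityBootstrap()] to every sample, by default on the HNA_p
#' gate (the low-nucleic-acid and elevated-red-fluorescence fractions are
#' excluded from diversity analysis, being prone to background
#' contamination). Samples with fewer than 2 gated events are skipped with a
#' warning. Per-sample seeds are derived from `seed` so each sample is
#' independently reproducible.
#'
#' @param series a [MeasurementSeries-class].
#' @param gates a [GateSet-class] (default [defaultGateSet()]).
#' @param gateName gate defining the community (default `"HNA_p"`).
#' @inheritParams diversityBootstrap
#' @return list of [DiversityResult-class], time-ordered (skipped samples
#'   omitted).
#' @export
diversityTimeseries <- function(series, gates = defaultGateSet(),
                                gateName = "HNA_p",
                                channels = c("FL1-A", "FL3-A", "FSC-A", "SSC-A"),
                                nbin = 128, bandwidth = 0.01, nBoot = 3,
                                seed = NULL) {
  stopifnot(is(series, "MeasurementSeries"))
  if (length(series) == 0) stop("empty series", call. = FALSE)
  if (!gateName %in% names(gates@gates))
    stop("gate '", gateName, "' not in gate set", call. = FALSE)
  gate <- gates@gates[[gateName]]
  eh <- elapsedHours(series)
  out <- vector("list", length(series))
  for (i in seq_len(length(series))) {
    tab <- series[[i]]
    if (!isTransformed(tab)) tab <- transformEvents(tab)
    nGated <- sum(applyGate(tab, gate))
    if (nGated < 2) {
      warning("sample '", sampleId(tab), "' has ", nGated,
              " gated events; skipped", call. = FALSE)
      next
    }
    out[[i]] <- diversityBootstrap(
      tab, gate, channels = channels, nbin = nbin, bandwidth = bandwidth,
      nBoot = nBoot,
      seed = if (is.null(seed)) NULL else .substream(seed, i),
      timeH = eh[i])
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Tabulate a diversity trajectory
#'
#' @param results list of [DiversityResult-class] (from
#'   [diversityTimeseries()]).
#' @return `data.frame` with columns `time_h`, `D2_mean`, `D2_sd`,
#'   `n_events_gated`, `settings`.
#' @export
diversityAsDataFrame <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    time_h = r@timeH,
    D2_mean = r@d2Mean,
    D2_sd = r@d2Sd,
    n_events_gated = r@nEventsGated,
    settings = sprintf("nbin=%d;bw=%g;gate=%s", r@settings$nbin,
                       r@settings$bandwidth, r@settings$gate),
    row.names = NULL
  )))
}
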