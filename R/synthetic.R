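## Synthetic coculture experiments: log-normal event clusters per population,
## lag -> logistic growth -> optional decline, Poisson sampling of measured
## events, uniform low-intensity background, seeded throughout.

.defaultCovariance <- function(sdFSC = 0.15, sdSSC = 0.15, sdFL1 = 0.12,
                               sdFL3 = 0.12, rhoScatter = 0.3) {
  s <- c(sdFSC, sdSSC, sdFL1, sdFL3)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- rhoScatter  # size and granularity co-vary
  cv <- diag(s) %*% R %*% diag(s)
  dimnames(cv) <- list(.ANALYSIS_CHANNELS, .ANALYSIS_CHANNELS)
  cv
}

#' Define a synthetic population
#'
#' @param name population name.
#' @param center named numeric of cluster means in log10 intensity units for
#'   `FSC-A`, `SSC-A`, `FL1-A`, `FL3-A`.
#' @param covariance 4 x 4 covariance in log10 units^2 (default: modest
#'   spreads of 0.12-0.15 log decades with mild scatter correlation,
#'   matching the compact clusters seen on cytometry density plots).
#' @param n0 initial concentration (cells/uL).
#' @param lagH lag-phase duration in hours (default 0).
#' @param mu specific growth rate in 1/h (default 0).
#' @param capacity carrying capacity K in cells/uL (default `Inf`:
#'   pure exponential growth after the lag).
#' @param declineRate,declineStartH optional exponential decline of rate
#'   `declineRate` (1/h) starting at `declineStartH` hours (post-peak decay).
#' @param gateName gate the cluster is designed to fall into (metadata for
#'   recovery checks).
#' @return a [PopulationSpec-class].
#' @export
populationSpec <- function(name, center, covariance = .defaultCovariance(),
                           n0, lagH = 0, mu = 0, capacity = Inf,
                           declineRate = NA_real_, declineStartH = NA_real_,
                           gateName = "") {
  new("PopulationSpec", name = name,
      center = center[.ANALYSIS_CHANNELS], covariance = covariance,
      n0 = n0, lagH = lagH, mu = mu, capacity = capacity,
      declineRate = declineRate, declineStartH = declineStartH,
      gateName = gateName)
}

#' Assemble a synthetic coculture configuration
#'
#' Defaults mirror the online-monitoring setup: 25-min sampling cadence,
#' 61 uL analyzed per sample, 1:100 dilution.
#'
#' @param populations list of [PopulationSpec-class] objects.
#' @param seed mandatory base seed; each sampling time gets a derived
#'   substream so samples are independently reproducible.
#' @param durationH experiment duration in hours (default 72, a 3-day run).
#' @param samplingIntervalMin cadence in minutes (default 25).
#' @param acquiredVolumeuL analyzed volume in uL (default 61).
#' @param dilutionFactor dilution (default 100).
#' @param backgroundRate expected background events per sample (default 50).
#' @param backgroundBox named list of `c(lo, hi)` log10 ranges per channel
#'   for the uniform background cloud (default: low FL1/FL3 region).
#' @param t0 inoculation time.
#' @return a [SyntheticCultureConfig-class].
#' @export
cocultureConfig <- function(populations, seed, durationH = 72,
                            samplingIntervalMin = 25, acquiredVolumeuL = 61,
                            dilutionFactor = 100, backgroundRate = 50,
                            backgroundBox = list(
                              `FSC-A` = c(2.0, 3.5), `SSC-A` = c(2.0, 3.5),
                              `FL1-A` = c(2.0, 3.1), `FL3-A` = c(0.0, 3.0)),
                            t0 = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  new("SyntheticCultureConfig", populations = populations,
      backgroundRate = backgroundRate, backgroundBox = backgroundBox,
      durationH = durationH, samplingIntervalMin = samplingIntervalMin,
      acquiredVolumeuL = acquiredVolumeuL, dilutionFactor = dilutionFactor,
      seed = as.integer(seed), t0 = t0)
}

#' True concentration of a synthetic population at time t
#'
#' `N(t) = N0` during the lag; from the end of the lag, logistic growth
#' `N(t) = K N0 e^{mu tau} / (K + N0 (e^{mu tau} - 1))` with `tau = t - lag`
#' (reducing to pure exponential when `K = Inf`); if a decline is specified,
#' exponential decay at `declineRate` from `declineStartH` onwards. The
#' curve is continuous at the lag and at the decline onset, and monotone
#' non-decreasing up to the capacity.
#'
#' @param spec a [PopulationSpec-class].
#' @param t time(s) in hours (>= 0); vectorized.
#' @return concentration(s) in cells/uL.
#' @examples
#' sp <- populationSpec("demo", c(`FSC-A` = 4, `SSC-A` = 4, `FL1-A` = 5,
#'                                `FL3-A` = 2), n0 = 100, mu = log(2),
#'                      capacity = 1e9)
#' simulateGrowth(sp, 3)  # three doublings: ~800
#' @export
simulateGrowth <- function(spec, t) {
  stopifnot(is(spec, "PopulationSpec"))
  validObject(spec)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  grow <- function(tt) {
    tau <- pmax(0, tt - spec@lagH)
    if (spec@mu == 0 || spec@n0 == 0) return(rep(spec@n0, length(tt)))
    if (is.infinite(spec@capacity)) return(spec@n0 * exp(spec@mu * tau))
    K <- spec@capacity; N0 <- spec@n0
    e <- exp(spec@mu * tau)
    K * N0 * e / (K + N0 * (e - 1))
  }
  n <- grow(t)
  if (!is.na(spec@declineStartH)) {
    post <- t > spec@declineStartH
    if (any(post)) {
      peak <- grow(spec@declineStartH)
      n[post] <- peak * exp(-spec@declineRate * (t[post] - spec@declineStartH))
    }
  }
  n
}

## Draw events for one population: multivariate normal in log10 space,
## exponentiated to linear instrument units; FL1-H is derived from FL1-A
## (pulse height a bit below area).
.drawClusterEvents <- function(spec, count) {
  if (count == 0)
    return(matrix(numeric(0), 0, 6,
                  dimnames = list(NULL, c(.ANALYSIS_CHANNELS, "FL1-H", "Time"))))
  L <- chol(spec@covariance)
  z <- matrix(stats::rnorm(count * 4), count, 4) %*% L
  logm <- sweep(z, 2, spec@center[.ANALYSIS_CHANNELS], "+")
  lin <- 10^logm
  colnames(lin) <- .ANALYSIS_CHANNELS
  fl1h <- lin[, "FL1-A"] * 10^stats::runif(count, -0.15, 0)
  cbind(lin, `FL1-H` = fl1h, Time = rep(NA_real_, count))
}

#' Simulate one measurement point
#'
#' For each population the expected number of measured events is
#' `lambda = N(t) * volume / dilution`; the realized count is Poisson.
#' Events are drawn from the population's log-normal cluster; background
#' events are uniform over a low-intensity log10 box. The returned table is
#' on the linear scale with channels FSC-A, SSC-A, FL1-A, FL3-A, FL1-H and
#' Time, and carries a `#SIMULATED` provenance keyword.
#'
#' @param config a [SyntheticCultureConfig-class].
#' @param t time in hours.
#' @param seed seed for this draw (default: substream of the config seed at
#'   index 0).
#' @param sampleId sample identifier.
#' @param labels if `TRUE`, return `list(table, labels)` with the per-event
#'   generating population (`"background"` for background events).
#' @return an [EventTable-class], or a list when `labels = TRUE`.
#' @export
simulateSample <- function(config, t, seed = NULL, sampleId = NULL,
                           labels = FALSE) {
  stopifnot(is(config, "SyntheticCultureConfig"))
  validObject(config)
  if (is.null(seed)) seed <- .substream(config@seed, 0L)
  if (is.null(sampleId)) sampleId <- sprintf("sim_t%07.2fh", t)
  res <- .withSeed(seed, {
    blocks <- list(); labs <- character(0)
    for (p in config@populations) {
      lam <- simulateGrowth(p, t) * config@acquiredVolumeuL / config@dilutionFactor
      cnt <- stats::rpois(1, lam)
      blocks[[length(blocks) + 1]] <- .drawClusterEvents(p, cnt)
      labs <- c(labs, rep(p@name, cnt))
    }
    nb <- stats::rpois(1, config@backgroundRate)
    if (nb > 0) {
      box <- config@backgroundBox
      logm <- vapply(.ANALYSIS_CHANNELS, function(ch)
        stats::runif(nb, box[[ch]][1], box[[ch]][2]), numeric(nb))
      if (nb == 1) logm <- matrix(logm, 1, 4,
                                  dimnames = list(NULL, .ANALYSIS_CHANNELS))
      lin <- 10^logm
      fl1h <- lin[, "FL1-A"] * 10^stats::runif(nb, -0.15, 0)
      blocks[[length(blocks) + 1]] <- cbind(lin, `FL1-H` = fl1h,
                                            Time = rep(NA_real_, nb))
      labs <- c(labs, rep("background", nb))
    }
    m <- do.call(rbind, blocks)
    m[, "Time"] <- seq_len(nrow(m)) * (90 / max(1, nrow(m)))  # within 90 s
    list(m = m, labs = labs)
  })
  tab <- EventTable(res$m,
                    acquiredVolumeuL = config@acquiredVolumeuL,
                    dilutionFactor = config@dilutionFactor,
                    timestamp = config@t0 + t * 3600,
                    sampleId = sampleId,
                    keywords = list(`#SIMULATED` = "TRUE"))
  if (labels) list(table = tab, labels = res$labs) else tab
}

#' Simulate a full coculture measurement series
#'
#' One sample per sampling time from t = 0 to the duration (inclusive) at
#' the configured cadence, each drawn under its own derived seed. Ground
#' truth is returned alongside for recovery tests: the schedule of true
#' per-population concentrations and the per-event generating labels.
#'
#' @param config a [SyntheticCultureConfig-class].
#' @return a list with elements `series` ([MeasurementSeries-class]),
#'   `truth` (`data.frame` with `time_h`, `population`, `concentration`) and
#'   `labels` (list of per-event label vectors, one per sample).
#' @examples
#' cfg <- cocultureScenario(1, seed = 42)
#' cfg@durationH <- 4  # tiny run for illustration
#' run <- simulateCocultureSeries(cfg)
#' length(run$series)
#' @export
simulateCocultureSeries <- function(config) {
  stopifnot(is(config, "SyntheticCultureConfig"))
  validObject(config)
  timesH <- seq(0, config@durationH * 60, by = config@samplingIntervalMin) / 60
  samples <- vector("list", length(timesH))
  labels <- vector("list", length(timesH))
  for (i in seq_along(timesH)) {
    r <- simulateSample(config, timesH[i],
                        seed = .substream(config@seed, i),
                        sampleId = sprintf("T%04d", i - 1L), labels = TRUE)
    samples[[i]] <- r$table
    labels[[i]] <- r$labels
  }
  truth <- do.call(rbind, lapply(config@populations, function(p) data.frame(
    time_h = timesH, population = p@name,
    concentration = simulateGrowth(p, timesH), row.names = NULL)))
  list(series = MeasurementSeries(samples, t0 = config@t0,
                                  samplingIntervalMin = config@samplingIntervalMin),
       truth = truth, labels = labels)
}

## Growth rate that makes a logistic curve starting at n0 pass through
## `target` after `tauH` hours with capacity K (exact inverse of the
## logistic form; K = Inf gives the exponential rate).
.muForTarget <- function(n0, target, tauH, K = Inf) {
  if (tauH <= 0 || target <= n0) return(0)
  if (is.infinite(K)) return(log(target / n0) / tauH)
  log(target * (K - n0) / (n0 * (K - target))) / tauH
}

## Reference cluster positions (log10 units) for the organisms used in the
## coculture scenarios; approximate readings of typical density-plot
## positions, placed well inside their gates.
.clusterCenters <- list(
  chlorella = c(`FSC-A` = 5.8, `SSC-A` = 5.2, `FL1-A` = 5.5, `FL3-A` = 5.5),
  sphingopyxis = c(`FSC-A` = 4.3, `SSC-A` = 3.8, `FL1-A` = 4.8, `FL3-A` = 2.0),
  tistrella = c(`FSC-A` = 4.5, `SSC-A` = 4.0, `FL1-A` = 5.1, `FL3-A` = 1.6),
  pseudomonas = c(`FSC-A` = 4.2, `SSC-A` = 3.7, `FL1-A` = 4.6, `FL3-A` = 2.4),
  hfl3 = c(`FSC-A` = 4.0, `SSC-A` = 3.6, `FL1-A` = 3.3, `FL3-A` = 3.6)
)

#' Preset coculture scenarios
#'
#' Seeded emulations of the five monitored cocultures of *Chlorella
#' vulgaris* with *Sphingopyxis* sp., *Tistrella* sp. and *Pseudomonas* sp.:
#' initial and final concentrations follow the measured values (coculture 1:
#' prokaryote 2.4 -> 37.0 cells/uL with a 72.5-h lag; 2: 2.2 -> 28.4, ~50-h
#' lag; 3: three strains totalling 2.6 -> 47.6, ~50-h lag, plus a constant
#' 12.8 cells/uL elevated-red-fluorescence cluster; 4: 126.6 -> peak 1305.7
#' at 37.5 h -> 1002.4 with immediate exponential growth and a constant
#' 47.6 cells/uL HFL3 cluster; 5: an undefined contaminant 2.2 -> 39.9).
#' Growth rates are solved so the curves pass through those anchors.
#' Scenario 1 runs 96 h so its 72.5-h lag is followed by an observable
#' exponential phase; the others run 72 h (3 days).
#'
#' @param scenario integer 1-5.
#' @param seed base seed (default `1000 + scenario`).
#' @return a [SyntheticCultureConfig-class].
#' @export
cocultureScenario <- function(scenario, seed = 1000L + scenario) {
  cc <- .clusterCenters
  mkChlorella <- function(n0, nf, durationH) {
    if (nf >= n0)
      populationSpec("C_vulgaris", cc$chlorella, n0 = n0,
                     mu = .muForTarget(n0, nf, durationH),
                     gateName = "microalgal")
    else  # slight net decline over the run
      populationSpec("C_vulgaris", cc$chlorella, n0 = n0,
                     declineRate = log(n0 / nf) / durationH,
                     declineStartH = 0, gateName = "microalgal")
  }
  mkHfl3 <- function(n0)
    populationSpec("HFL3_cluster", cc$hfl3, n0 = n0, gateName = "HFL3_p")
  strains <- function(n0tot, nftot, lagH, durationH, peakH = NA, declTo = NA) {
    nm <- c("Sphingopyxis", "Tistrella", "Pseudomonas")
    ctr <- cc[c("sphingopyxis", "tistrella", "pseudomonas")]
    lapply(seq_along(nm), function(i) {
      n0 <- n0tot / 3
      if (is.na(peakH)) {
        populationSpec(nm[i], ctr[[i]], n0 = n0, lagH = lagH,
                       mu = .muForTarget(n0, nftot / 3, durationH - lagH),
                       gateName = "HNA_p")
      } else {
        populationSpec(nm[i], ctr[[i]], n0 = n0, lagH = lagH,
                       mu = .muForTarget(n0, nftot / 3, peakH - lagH),
                       declineRate = log(nftot / declTo) / (durationH - peakH),
                       declineStartH = peakH, gateName = "HNA_p")
      }
    })
  }
  pops <- switch(scenario,
    # 1: C. vulgaris - Sphingopyxis; long lag then exponential growth
    list(mkChlorella(46.5, 49.0, 96),
         populationSpec("Sphingopyxis", cc$sphingopyxis, n0 = 2.4,
                        lagH = 72.5, mu = .muForTarget(2.4, 37.0, 96 - 72.5),
                        gateName = "HNA_p")),
    # 2: C. vulgaris - Tistrella
    list(mkChlorella(27.2, 48.0, 72),
         populationSpec("Tistrella", cc$tistrella, n0 = 2.2,
                        lagH = 50, mu = .muForTarget(2.2, 28.4, 22),
                        gateName = "HNA_p")),
    # 3: three strains inoculated below C. vulgaris
    c(list(mkChlorella(43.6, 39.1, 72)),
      strains(2.6, 47.6, lagH = 50, durationH = 72),
      list(mkHfl3(12.8))),
    # 4: three strains inoculated above C. vulgaris; peak then decline
    c(list(mkChlorella(66.4, 66.7, 72)),
      strains(126.6, 1305.7, lagH = 0, durationH = 72, peakH = 37.5,
              declTo = 1002.4),
      list(mkHfl3(47.6))),
    # 5: spontaneous, undefined contamination
    list(mkChlorella(45.6, 49.2, 72),
         populationSpec("contaminant", cc$sphingopyxis, n0 = 2.2,
                        lagH = 55, mu = .muForTarget(2.2, 39.9, 17),
                        gateName = "HNA_p")),
    stop("scenario must be 1..5", call. = FALSE)
  )
  cocultureConfig(pops, seed = seed,
                  durationH = if (scenario == 1) 96 else 72)
}
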