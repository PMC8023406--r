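# flowCulture

Automated online flow cytometry is an attractive monitoring tool for
non-axenic microalgal cultures: a sampling robot stains a culture aliquot
with SYBR Green I every 25 minutes and pushes it through a flow cytometer,
yielding one FCS event file per time point. Because *Chlorella vulgaris*
carries chlorophyll autofluorescence (red, FL3) on top of the nucleic-acid
stain signal (green, FL1), microalgae and prokaryotes can be separated on
the FL1/FL3 plane and tracked simultaneously — counts, growth phases, and
community structure — over a concentration range of roughly 2 to 1,000
cells·µL⁻¹.

`flowCulture` implements that analysis end to end for R users working with
such time series (bioprocess engineers, microbial ecologists):

* **FCS I/O** — reads FCS 3.0/3.1 event files and writes FCS 3.1, carrying
  acquisition volume, dilution and timestamps as keywords or sidecar
  metadata (`readFCS()`, `writeFCS()`, `loadSeries()`).
* **Gating** — log₁₀ transform, polygon gates on FL1-A × FL3-A with a
  closed boundary, first-match-wins priority, and an FL1-H acquisition
  threshold of 800. The default gate set separates `microalgal`, `HNA_p`,
  `LNA_p` and `HFL3_p` populations, with the high/low nucleic-acid boundary
  at FL1-A = 1.5 × 10⁴; concentrations follow
  `count × dilution / volume` (`defaultGateSet()`, `countPopulations()`).
* **Dynamics** — per-population concentration trajectories, sliding-window
  log-linear growth-rate estimation with lag/exponential/stationary/decline
  segmentation, fold and percent changes (`assembleTimeseries()`,
  `detectGrowthPhases()`, `foldChange()`, `percentChange()`).
* **Phenotypic fingerprinting** — for the gated prokaryotic community
  (HNA_p by default), bivariate kernel densities on every pair of FL1-A,
  FL3-A, FSC-A and SSC-A are estimated on a 128 × 128 grid over the unit
  square, concatenated and normalized into one probability vector `p`,
  summarised by the Hill diversity of order two

  D₂ = (Σᵢ pᵢ²)⁻¹,

  the "effective number of phenotypic states", with bootstrap errors over
  n = 3 resamples (`computeFingerprint()`, `hillDiversity()`,
  `diversityBootstrap()`, `diversityTimeseries()`).
* **Synthetic cocultures** — a seeded generator of full experiments
  (log-normal event clusters per population, lag → logistic → optional
  decline growth, Poisson event sampling, uniform background) including
  presets for five monitored coculture scenarios, so every pipeline stage
  is testable without instrument data (`cocultureScenario()`,
  `simulateCocultureSeries()`).
* **Pipeline** — `runMonitor()` runs everything and writes `counts.csv`,
  `dynamics.csv`, `diversity.csv`, plots and a reproducibility manifest;
  `inst/scripts/monitor.R` is a shell wrapper.

## Worked example

Emulate the coculture in which three prokaryotic strains are inoculated
above the *C. vulgaris* concentration (126.6 vs 66.4 cells·µL⁻¹), then gate,
track and summarise it:

```r
library(flowCulture)

gs  <- defaultGateSet()
cfg <- cocultureScenario(4, seed = 11)     # 72 h at 25-min cadence
run <- simulateCocultureSeries(cfg)        # 173 samples + ground truth

counts <- countSeries(run$series, gs)
counts[[1]]
#> CountResult 'T0000' (t = 0.00 h): 207 events total
#>            count cells_per_uL
#> microalgal    53        86.89
#> HFL3_p        24        39.34
#> HNA_p         92       150.82
#> LNA_p          4         6.56
#>   ungated 2, below threshold 32

ts <- assembleTimeseries(counts, "HNA_p")
detectGrowthPhases(ts)@segments
#>   tStart     tEnd       label           mu
#> 1  0.000 38.12500 exponential  0.061908049
#> 2 38.125 71.66667  stationary -0.006875713

round(foldChange(ts, mode = "max"), 2)     # peak/initial prokaryote fold
#> [1] 9
```

The first sample's 92 HNA_p events in 61 µL at 1:100 dilution give
150.8 cells·µL⁻¹ (single Poisson draw around the true 126.6); the
segmentation finds immediate exponential growth at µ̂ ≈ 0.062 h⁻¹ turning
over near 38 h, matching the generating curve (µ = 0.062 h⁻¹, peak at
37.5 h). The diversity trajectory of the same run:

```r
d2 <- diversityTimeseries(run$series, gates = gs, nbin = 64, nBoot = 3, seed = 1)
head(diversityAsDataFrame(d2), 1)
#>   time_h  D2_mean    D2_sd n_events_gated                   settings
#> 1      0 253.4273 2.929825             92 nbin=64;bw=0.01;gate=HNA_p
```

D₂ values are arbitrary units comparable only across identical
(nbin, bandwidth, channels, gate) settings, which every result embeds.

## Vignette

`vignettes/coculture-monitoring.Rmd` describes the model and its
assumptions, the default parameters (gates, threshold, fingerprint grid,
growth-phase windows) and why they were chosen, what the synthetic
generator does and does not emulate, and known limitations.
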