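---
title: "Monitoring microalgal-bacterial cocultures by online flow cytometry"
author: "flowCulture authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring microalgal-bacterial cocultures by online flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowCulture)
```

## The measurement and its model

An automated sampling robot draws a culture aliquot every 25 minutes,
dilutes it 1:100, stains nucleic acids with SYBR Green I, and runs it for
90 s (about 61 µL analyzed) on a flow cytometer with a 488-nm laser. Each
particle yields forward and sideward scatter (FSC, SSC: size and
granularity) plus green (FL1, 533 ± 30 nm: stain, i.e. nucleic-acid
content) and red fluorescence (FL3, > 670 nm: chlorophyll
autofluorescence). Events below an FL1-H pulse-height of 800 are not
recorded — that acquisition trigger suppresses unstained debris.

Two facts make mixed microalga–prokaryote cultures separable on the
FL1 × FL3 plane alone. *Chlorella vulgaris* is strongly red-fluorescent
(chlorophyll) *and* strongly stained, so it sits high on both axes.
Prokaryotes lack chlorophyll and split, after staining, into high (HNA) and
low (LNA) nucleic-acid-content fractions along FL1; a further cluster with
elevated FL3 at prokaryotic FL1 (here called HFL3_p) appears in some
cocultures and may reflect pigment-forming strains or background. Counts in
a gate convert to concentrations of the undiluted culture as

$$c = n \cdot \frac{\text{dilution}}{\text{volume}_{\mu L}} \quad
  [\text{cells}\,\mu L^{-1}].$$

`flowCulture` treats the analyzed volume and dilution as per-sample *data*
(FCS keywords or sidecar metadata, defaulting to 61 µL and 1:100 with a
warning) rather than deriving volume from flow rate × time; the analyzed
volume is what the formula needs, and instruments report it directly.

## Gates are data

All gating happens after `x -> log10(max(x, 1))` on the analysis channels
(area channels only; pulse-height channels are carried through untouched
and used solely for the acquisition threshold). Clipping at one instrument
unit keeps the transform total on the instrument's non-negative 24-bit
scale. Gate membership uses a closed boundary (edge and vertex points are
inside) — deterministic and in line with common cytometry practice.

Only one gate coordinate is a quantitatively established constant: the
HNA_p/LNA_p boundary at FL1-A $= 1.5\times 10^4$ ($\log_{10} = 4.176$), the
adaptation required because prokaryotes emit lower on FL1 in coculture with
*C. vulgaris* than in the aquatic ecosystems the HNA/LNA scheme was
developed for. Every other default vertex is a qualitative reading of
density-plot positions and is expected to be adjusted per experiment: gates
are serialisable data (`readGateSet()`/`writeGateSet()` YAML), not code.
Defaults are disjoint rectangles; evaluation priority (microalgal >
HFL3_p > HNA_p > LNA_p, first match wins) only matters for user-edited,
overlapping gates and for points exactly on the shared HNA/LNA boundary
line. Events in no gate are "ungated" and stay in the totals — background
is excluded from population counts, never silently dropped.

## Growth phases

Each gated population's trajectory is segmented by estimating the specific
growth rate $\hat\mu$ at every observation from a log-linear regression of
$\ln c$ on $t$ over a sliding window (default 10 h, i.e. 24 points at
25-min cadence). Zeros are replaced by half the smallest positive
concentration — the standard pseudo-count, which keeps lag phases at a few
cells per µL analysable. Points are labelled exponential
($\hat\mu > \mu_{thr}$), decline ($\hat\mu < -\mu_{thr}$), or lag/stationary
(before/after the first exponential phase); the default
$\mu_{thr} = 0.02\,h^{-1}$ resolves lags of 50–72.5 h against growth rates
of 0.06–0.17 h⁻¹ without chasing noise. Runs shorter than 5 h are absorbed
into their longer neighbour, and segment labels are re-derived from each
merged segment's own regression slope until stable, so the reported
per-segment $\hat\mu$ always agrees with its label.

At concentrations of a few cells per µL the windowed $\hat\mu$ has a
standard error comparable to $\mu_{thr}$, so the *position* of a
lag-to-exponential boundary read off the labels alone is noisy.
`lagExponentialBoundary(annotation, series)` therefore refines it by a
two-phase least-squares fit in log space (constant lag level, then a free
straight line) over all candidate breakpoints. On seeded emulations of a
72.5-h lag followed by $\mu = 0.08\,h^{-1}$ growth observed through the full
simulate–gate–count pipeline, the refined estimate falls within a few hours
of the truth; the label-based estimate is good to roughly one window. The
refinement assumes a single lag-to-growth transition and should be applied
to the pre-peak part of trajectories that later decline.

Fold changes are computed from the data as final/first (`final` mode) or
max/first (`max` mode) — peak-based values and endpoint-based values can
legitimately differ, so both are exposed and none is hard-coded.

## The phenotypic fingerprint and D2

Community structure is summarised without taxonomy: for every unordered
pair of the four phenotypic traits (FL1-A, FL3-A, FSC-A, SSC-A — six
pairs), the gated events are binned on an `nbin` × `nbin` grid over the
unit square (log intensities divided by $\log_{10} 2^{24}$, the full ADC
scale, so grids align across samples), smoothed with a Gaussian kernel, and
the six grids are flattened, concatenated, and globally normalized to sum
one. The Hill diversity of order two of that probability vector,

$$D_2 = \Big(\sum_i p_i^2\Big)^{-1},$$

weighs richness and evenness equally and reads as the effective number of
occupied phenotypic states. Bootstrap errors come from `nBoot = 3`
resamples of the gated events, with replacement at full gated size.

Numerical choices:

* `nbin = 128`, `bandwidth = 0.01` (unit scale) are the documented defaults
  of the reference fingerprinting approach for aquatic prokaryotes; both
  are parameters because no universally correct value exists. The kernel is
  realized as a binned histogram convolved with a discrete Gaussian
  truncated at 4σ whose edge columns are renormalized — deterministic,
  grid-aligned, and mass-conserving, so the normalization contract
  (sum = 1 within 10⁻⁹) holds for any gate, subsample or bandwidth.
* Normalization is global across the concatenated vector rather than
  per-pair, making $D_2$ a single effective-state count for the whole
  fingerprint.
* Diversity is computed on HNA_p-gated events only: the LNA_p and HFL3_p
  fractions are low-count and plausibly background-contaminated, which
  would bias an evenness-sensitive index. The gate is a parameter.
* $D_2$ is in arbitrary units comparable only across identical
  (nbin, bandwidth, channels, gate) settings; every result embeds them.
  Absolute a.u. values from other software are not comparable targets —
  only ratio arithmetic on a given trajectory is.

## The synthetic generator

Real instrument runs are not redistributable, so the generator *is* the
test bed, and its defaults are the study conditions: 25-min cadence, 61 µL,
1:100 dilution, 3-day duration (at that cadence, 172 whole intervals fit in
72 h, giving 173 samples including $t = 0$). Populations are log-normal
clusters (Gaussian in log₁₀ with spreads of 0.12–0.15 decades and mild
scatter correlation — plausible, not fitted, since within-population
covariances cannot be recovered from published density plots). Expected
measured events are $\lambda = N(t)\,V/d$ with Poisson-distributed actual
counts; concentration follows lag → logistic → optional exponential
decline,

$$N(t) = \frac{K N_0 e^{\mu (t - t_{lag})}}{K + N_0 (e^{\mu (t-t_{lag})}-1)},
\qquad t \ge t_{lag},$$

one parametric family that reproduces the observed lag, exponential, and
peak-then-decline patterns. Background is a uniform low-FL1/low-FL3 cloud
(50 events/sample by default), consistent with indistinct low-intensity
scattering; a fraction of it survives the FL1-H threshold and lands in the
LNA_p gate or ungated, as in real data.

`cocultureScenario(1..5)` anchors the five monitored experiments to their
measured endpoints (e.g. scenario 1: prokaryote 2.4 → 37.0 cells·µL⁻¹
after a 72.5-h lag; scenario 4: 126.6 → peak 1305.7 at 37.5 h → 1002.4,
with constant 47.6 cells·µL⁻¹ in HFL3_p), solving $\mu$ so the curves pass
exactly through those anchors. Three-strain scenarios split the inoculum
into equal shares with a common rate, so totals stay anchored. Scenario 1
runs 96 h: a 72.5-h lag followed by an observable exponential phase cannot
fit into 72 h, and the reported final concentration requires ~23 h of
growth past the lag — the one place where the published numbers are
internally inconsistent and a choice had to be made. Seeds are mandatory;
each sample draws from a substream derived from the base seed, so any
single time point is reproducible in isolation.

What passing the recovery tests shows — and what it does not: the pipeline
is unbiased and Poisson-limited on well-separated log-normal clusters with
stationary cluster positions. Real data add drift of cluster positions
(staining kinetics, metabolic state), overlapping populations at the gate
fringes, doublets, and instrument noise; none of these is emulated, so
gate-fit on real runs must still be validated per experiment.

## Scale of the shipped checks

The packaged tests and the acceptance script run the five scenario
emulations at their native ~10²–10³ events per sample (about 950 samples
total), a 265-sample lag-recovery run, and 20 replicate pairs for the
evenness comparison at `nbin = 64` — sizes chosen so a full desk-side rerun
of everything finishes in well under a minute while keeping Poisson errors
small relative to the tolerances tested.

## Known limitations

* FCS support targets list-mode float/double data as produced by modern
  instruments and this package's writer; integer-mode FCS 2.0 dialects and
  compensation matrices are out of scope (no compensation is applied).
* Gate geometry beyond the printed HNA/LNA boundary is approximate by
  construction and must be validated against each instrument's density
  plots.
* The growth-phase segmentation is descriptive (windowed regression), not
  a mechanistic fit; no Monod/Baranyi parameters are inferred, and no
  interaction between populations is modelled.
* Phenotypic fingerprints cannot attribute diversity shifts to taxa;
  discriminating strains with similar phenotypes requires sorting plus
  sequencing, outside this package's scope.
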