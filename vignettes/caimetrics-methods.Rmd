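---
title: "Methods: quantifying neuronal-ensemble calcium-imaging recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neuronal-ensemble calcium-imaging recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caimetrics)
```

## Scope and data model

`caimetrics` starts where source extraction ends: a frames × neurons
fluorescence matrix (arbitrary units, 15 frames/s by default) and a table of
neuron centroids in pixels, per recording session. Sessions are organized in
a manifest keyed by mouse and state label (five baseline days, a stress
session, and 3-h and 10-day follow-ups, or any custom vocabulary). Frames
are 0-based; times are reported in seconds. Recordings are conventionally 7
minutes long and trimmed to the middle 5 minutes (`trim_recording`, default
60 s off each end) before analysis, so the standard analysis window is
4500 frames.

## Binarization

Calcium transients are a low-pass proxy of spiking: the informative part is
the fast rise. Four rule-based binarizers are provided, deliberately simple
and deterministic (no deconvolution model):

- **spike** — the normative method for all activity metrics. The trace is
  smoothed by a centered moving average over `window` frames (default 10;
  edges use a truncated window, keeping the filter shift-free). Candidate
  active frames are frames of positive first difference of the smoothed
  trace. Runs shorter than `cold` frames (default 0, the minimum active
  duration) are deleted; passive gaps shorter than `warm` frames (default
  50, the minimum passive duration) merge flanking runs, acting as a
  refractory gap so a multi-peak transient counts once.
- **full** — frames above `median + k_mad·MAD` (default `k_mad = 3`). When
  the MAD degenerates to zero the threshold falls back to `mean + k_mad·SD`;
  a constant trace yields all zeros. This marks the whole supra-threshold
  plateau, hence longer runs than *spike*.
- **signal** — frames whose intensity z-score exceeds `z` (default 2); the
  least strict method, intensity only.
- **diff** — frames whose first-difference z-score exceeds `z` (default 2);
  rise frames only, like *spike* but without run filtering.

A numerical point on the *spike* candidate rule: a strict sign test on the
derivative is only meaningful on noiseless data — with any additive noise
the sign of the smoothed derivative is random on about half of the baseline
frames, and after `warm`-gap merging the raster would collapse into one
giant run. The candidate criterion therefore requires the smoothed first
difference to exceed `z_slope` times a robust noise scale (the MAD of the
differenced smoothed trace), `z_slope = 4` by default. The MAD is taken over
all frames; because events are sparse, it estimates the noise floor of the
derivative. On noiseless traces this scale is numerically zero and the rule
reduces exactly to the strict positive-derivative criterion. `z_slope = 4`
puts the per-frame false-candidate probability near `3e-5` (sub-one false
event per 4500-frame trace) while rise slopes of unit-amplitude transients
exceed the bound by a factor of roughly two at the default noise level; the
parameter is exposed for unusually clean or dirty data.

The `cold`/`warm` glosses (minimum active / minimum passive duration) are
adopted literally; an *activation* is one contiguous active run, counted by
0→1 transitions.

## Activity and network metrics

- **Burst rate**: activations per minute per neuron.
- **Network spike rate (NSR)**: the recording is split into 1-s intervals; a
  neuron is active in an interval if it has ≥ 1 active frame there
  (chosen over frame-wise averaging because the metric is defined on counts
  of active neurons per interval); NSR is the percent of active neurons. A
  trailing partial interval is dropped (irrelevant at 300 s × 1 s, needed
  for general inputs).
- **Network spike peak**: max NSR.
- **Network spike duration**: seconds with NSR strictly above each threshold
  in {2.5, 5, 10, 15, 20, 25} %. Seconds are normative; percent of the
  recording is available via `as_percent`.
- Histograms use left-closed right-open bins anchored at 0 (burst rate:
  width 1/3 events/min; NSR: width 2.5 points over [0, 100], with an NSR of
  exactly 100 kept in the last bin), reported as percent of neurons or
  intervals.

## Correlation networks

Pearson correlation is computed between binarized frame vectors of every
neuron pair, per binarization method. Constant columns make the coefficient
undefined; such entries are stored as `NA` and *excluded* from every derived
statistic rather than zero-filled — zero-filling would bias the percentile
threshold procedure — with the count kept for provenance.

The **strong-correlation threshold** is derived from baseline recordings:
the 95th percentile (linear interpolation between order statistics, the
default quantile convention) of each recording's off-diagonal coefficients,
averaged over recordings, then rounded to the nearest multiple of the
threshold-grid step (0.05; half-way cases round up). The percentile is taken
over all off-diagonal values, not only positive ones. **Network degree** is
the fraction of unordered pairs above each grid threshold;
**connectivity** the per-neuron percent of partners above a threshold.

**Clusters**: a pair is linked when its coefficient strictly exceeds the
80th percentile of all off-diagonal coefficients ("stronger than 80 % of the
connections"); clusters are connected components (the minimal relational
closure of the pairwise rule) with ≥ 2 members. Intracluster correlation is
the mean over within-cluster pairs, intercluster the mean over
member/non-member pairs. With all coefficients equal nothing strictly
exceeds the percentile and nothing is clustered.

## Spatial statistics

Euclidean distance is the straight centroid-to-centroid distance; radial
distance is `| ‖p_i − c‖ − ‖p_j − c‖ |` with `c` the unweighted centroid of
all neurons (ROI areas are unavailable after extraction, so every neuron
gets equal mass). Radial distance is never larger than Euclidean (triangle
inequality through the center). Pairs are stratified into a strong band
(`r` above the strong threshold, strict) and a weak band (`(0, threshold]`
by default). The lower edge of the weak band is a genuine free choice — the
convention here is "any positive correlation up to the strong threshold",
exposed as `weak_band` — and empty bands report `NA`, never 0.

## Cross-session tracking and stress-response classification

Neurons are matched across sessions by greedy globally-nearest centroid
matching with a 7-pixel acceptance radius: repeatedly match the closest
unmatched cross-session pair while its distance is ≤ 7 px, with exact ties
broken by id order, so the matching is one-to-one and deterministic. This is
a documented, parameter-compatible stand-in for probabilistic
footprint-model registration, which needs the spatial footprints themselves.
Multi-session experiments are matched pairwise against the reference session
(baseline day 5), not transitively.

Per-neuron rates are normalized to the reference session; baseline-zero
neurons are excluded (with a logged count) rather than producing infinities,
and neurons absent from a later session simply drop out of that session's
classification. Classification thresholds are 1.75 (activated, strict) and
0.5 (inhibited, strict); the closed interval between is non-responsive, so
boundary values are conservatively non-responsive and the partition is
exhaustive and exclusive.

## Ensemble-state PCA

Each recording becomes a fixed 100-feature vector: for each of the four
binarization methods, mean burst rate, mean NSR, network spike peak, the six
network-spike-duration values, mean pairwise correlation, degree at the
seven grid thresholds, mean connectivity, intra/intercluster means, mean
pairwise active accuracy, and the four band-distance means
(`metric_schema()` is the canonical ordering). Distributional metrics enter
as means — scalar summaries keep the feature count fixed across recordings.

Features are standardized to zero mean and unit variance before PCA: the
features mix units (events/min, percent, pixels, correlations), so
unstandardized PCA would be dominated by the pixel-scale distances.
Zero-variance features are dropped (logged); undefined entries are imputed
with the feature's cross-recording mean, i.e. zero after standardization,
which is variance-neutral. Component signs are fixed by making each
component's largest-magnitude loading positive, so projections are
bit-reproducible. Group comparison of the projected coordinates is left to
`compare_groups`.

## Group-comparison reporting

`compare_groups` is declared plumbing: it calls standard test routines and
only automates the branch choice. Normality uses Shapiro-Wilk below n = 50
and a fitted-normal Kolmogorov-Smirnov otherwise (the usual split given both
tests are in common use without a stated rule), homogeneity uses Bartlett;
pass both in every group and the parametric branch runs (t-test, or ANOVA
with Tukey or Dunnett), otherwise the nonparametric branch (Mann-Whitney, or
Kruskal-Wallis with Dunn's rank test, Holm-adjusted). The choice between
Tukey, Dunnett or Dunn is per call rather than global. The branch is a
deterministic function of the data and alpha.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
the optics: it starts at extracted traces.

- **Events**: homogeneous Poisson per neuron, default 1.27 events/min (a
  typical baseline mean for CA1 under these conditions), thinned to unique
  frames at 15 fps.
- **Transients**: difference of exponentials
  `A·(e^(−t/τ_d) − e^(−t/τ_r))` normalized to unit peak, `τ_r = 0.1 s`,
  `τ_d = 0.6 s` — fast-indicator kinetics of GCaMP6f scale; per-event
  amplitudes LogNormal(0, 0.25) to avoid degenerate identical transients
  (set `amp_sdlog = 0` to disable); additive Gaussian noise, default SD 0.1
  of the unit peak.
- **Coupling**: for a pair `(i, j, f)`, neuron `j` keeps each own onset with
  probability `1 − f` and copies each of `i`'s onsets with probability `f`.
  Copying at the same frame (rather than jittered) keeps the binarized
  Pearson correlation analytically tractable; at `f = 1` the onset lists are
  identical, and at equal rates the expected shared fraction equals `f`.
- **Positions**: uniform over a 600 × 600 px field with a 10-px exclusion
  radius. Somata are extended objects and source extraction cannot return
  two cells essentially on top of each other; without the exclusion the
  generator plants centroid pairs a few pixels apart whose identity is
  unrecoverable by *any* centroid matcher under session jitter.
- **Sessions**: one recording per (mouse, state); state multipliers scale
  rates (defaults 1 for baseline days, 1.95 stress, 1.83 at 3 h, 1.07 at 10
  days — the relative shifts the generator is meant to emulate), centroids
  get Gaussian jitter (default SD 2 px) and a dropout fraction (default 0.1)
  of neurons is absent per session. Ground-truth identity is kept so
  registration can be scored.
- **Determinism**: every draw flows from the config seed; identical configs
  give bit-identical traces, onsets and positions.

What the generator does *not* emulate: neuropil contamination, motion
artifacts, indicator saturation, bursty (non-Poisson) firing, distance-
dependent correlation structure, or slow drift. Passing tests therefore
demonstrate correctness of the analysis rules and recoverability under the
stated statistical assumptions — not robustness to every artifact of real
recordings.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical checks have comfortable power:
50–100 neurons and 300-s sessions for recovery checks, ≤ 10 neurons and
≤ 200 frames for the brute-force oracle suite (100 random instances), 8
recordings per group for the PCA separation check, and a three-mouse
eight-session series (60 neurons each) in `scripts/acceptance.R`.

Other conventions: quantiles use linear interpolation (type 7); grid
rounding of the strong threshold rounds half-way cases up; thresholds are
strict (`>`) throughout; empty selections yield `NA` markers, never silent
zeros; 0/0 active-accuracy is defined as 0; all binarizers are deterministic
and shape-preserving.

## Known limitations

- The centroid matcher ignores spatial footprints; with jitter approaching
  half the typical nearest-neighbour distance its accuracy degrades, and it
  offers no confidence model.
- The spike method's `warm = 50` merge window makes events closer than
  ~3.3 s at 15 fps count once, biasing burst rates downward by the Poisson
  coincidence fraction (≈ 7 % at 1.27 events/min). This is inherent to the
  rule, not to its implementation.
- Dunn's test is implemented in-package (rank z-statistics with tie
  correction and Holm adjustment) because no installed package provides it;
  all other tests delegate to standard routines.
- Correlation analysis is zero-lag Pearson only; no lagged, partial or
  model-based connectivity.
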