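# caimetrics

Quantitative analysis of neuronal-ensemble calcium-imaging recordings in R.

One-photon miniscope imaging of genetically encoded calcium indicators
(GCaMP6f and relatives) yields, after source extraction (CNMF/Minian), a
fluorescence trace per neuron and a centroid per neuron. `caimetrics` covers
the downstream quantitative analysis of such data for experiments that
compare ensemble activity across states — e.g. baseline days versus an acute
stressor and its follow-ups:

- **Binarization** of traces into active/inactive frames by four rule-based
  methods: *spike* (the rapid-rise phase only, with smoothing `window`,
  minimum active duration `cold`, minimum passive duration `warm`), *full*
  (above `median + k·MAD`), *signal* (intensity z-score) and *diff*
  (derivative z-score), plus the *active accuracy* overlap
  `|A ∩ B| / |A ∪ B|` between neurons.
- **Activity metrics**: per-neuron burst rate (activations/min), network
  spike rate (percent of neurons active per 1-s interval), network spike
  peak, network spike duration above thresholds of 2.5–25 %, and their
  standard histograms.
- **Correlation networks**: pairwise Pearson correlation of binarized
  activity; mean correlation and network degree over a threshold sweep
  (0–0.3); a data-derived strong-correlation threshold (mean 95th percentile
  of baseline coefficients, rounded to the 0.05 grid); per-neuron
  connectivity; clustering by the stronger-than-80 %-of-connections rule
  with intra/intercluster correlation.
- **Spatial statistics**: Euclidean and radial (distance-from-ensemble-
  centroid difference) distances for weakly vs strongly correlated pairs.
- **Cross-session tracking**: greedy nearest-centroid matching under the
  7-pixel same-cell criterion, baseline normalization of rates, and
  classification of neurons as stress-activated (> 1.75× baseline),
  inhibited (< 0.5×) or non-responsive.
- **Ensemble state**: a fixed 100-feature metric vector per recording (all
  metrics × all four binarization methods) projected by standardized PCA,
  with explained variance and ranked loadings.
- **Group comparison**: a thin reporting wrapper (normality check, then
  t/ANOVA+Tukey/Dunnett or Mann-Whitney/Kruskal-Wallis+Dunn).
- **A ground-truthed synthetic generator** — Poisson activation events,
  GCaMP6f-like difference-of-exponentials transients, controllable pairwise
  event coupling, 2-D soma positions with an exclusion radius, and
  multi-session series with per-state rate multipliers, centroid jitter and
  dropout — so the whole pipeline is testable without raw recordings.

## Worked example

```r
library(caimetrics)

cfg <- sim_config(n_neurons = 40, duration_s = 300, rate_per_min = 1.27,
                  noise_sd = 0.1, seed = 42)
rec <- simulate_recording(cfg)
rec$traces
#> Trace matrix: 4500 frames x 40 neurons at 15 fps (300.0 s)

raster <- binarize(rec$traces, "spike")
raster
#> Binary raster: 4500 frames x 40 neurons (spike method), 1.5% frames active

mean(burst_rate(raster))
#> 1.21            # events/min; the simulation planted 1.27/min
network_spike_peak(raster)
#> 17.5            # at most 17.5% of neurons co-active in any 1-s interval

graph <- pairwise_pearson(raster)
graph
#> Correlation graph: 40 neurons (spike method), mean r = -0.001, 0 undefined pair(s)
strong_threshold(graph)
#> 0.1             # mean 95th percentile, rounded to the 0.05 grid

band_distance_summary(graph, rec$positions, strong_threshold = 0.1)
#>     band n_pairs mean_euclidean_px mean_radial_px
#> 1   weak      79          319.4149      107.12086
#> 2 strong      34          328.6598       95.96831
```

The detected mean burst rate (1.21/min) sits within Poisson sampling error
of the planted 1.27/min; the strong/weak distance summary shows the two
correlation bands occupy similar spatial scales here, as expected for
uncoupled neurons placed uniformly at random.

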