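# tonomap

Receptive-field complexity and tonotopic organization in primary auditory
cortex (A1), analysed from two-photon calcium imaging trial data or
synthetic equivalents.

## The problem

A1 carries a tonotopic map — best frequency (BF) drifts log-linearly along
one cortical axis — yet single-cell imaging shows neighbouring neurons can
prefer frequencies octaves apart. This package implements the analysis
showing that much of that local scatter is carried by neurons with
*multi-peaked* frequency response areas (FRAs): it classifies each
frequency-sensitive neuron's FRA as single-peaked, double-peaked or
complex, and quantifies how tonotopic order degrades with FRA complexity,
locally and along the whole map, in species-comparable units.

For whom: anyone analysing tone-evoked population recordings on a
frequency × level × trial grid (two-photon, or unit recordings exported in
the same layout), or needing a ground-truth synthetic cortex to validate
such analyses.

## The core quantities

* **Sensitivity** — two-way ANOVA per neuron, `response ~ freq * level`;
  sensitive iff p(freq) < α or p(freq:level) < α.
* **Classification** — on the level-averaged profile, count maximal runs
  above `0.75 · max`: 1 run = single, 2 = double (weaker run's argmax =
  peak 2), ≥3 = complex. BF = global argmax; bandwidth = contiguous range
  above `0.5 · response(BF)`, in octaves; Fano factor = var/mean across
  trials at the best cell.
* **Local deviation** — per neuron, `|log2 BF_i − median(log2 BF_others)|`
  over same-class neurons of the field (≥3 per class), in oct and oct/mm.
* **Species normalization** — map slope = `log2(hi/lo) / axis length`:
  4.91 oct/mm (mouse, 2–60 kHz over 1 mm), 2.93 oct/mm (ferret,
  36 Hz–44 kHz over 3.5 mm); the expected-BF-range fraction is the share
  of neurons within `slope × field size / 2` octaves of the field median.
* **Global gradient** — linear fit of log2(BF) vs axis position
  (equivalently `BF = a·e^{bx}`), Pearson r, residuals in octaves.
* **Pair correlations** — noise: correlation of residual trial series
  after per-stimulus mean subtraction; signal: correlation of
  trial-averaged FRAs minus the pair's noise correlation.

A seeded synthetic-cortex generator (`generateField()`) produces imaging
fields with known class labels, BFs, gradient, shared trial noise and
optional neuropil mixing, so the whole chain is testable offline; see the
methods vignette (`vignettes/tonotopy-methods.Rmd`) for the generative
model and its limits.

## Worked example

```r
library(tonomap)
res <- runPipeline(list(species = "ferret", n_fields = 6, n_neurons = 60,
                        class_mix = c(single = 0.43, double = 0.32,
                                      complex = 0.25, nonsensitive = 0),
                        seed = 11))
res$summary$sensitive_line
#> [1] "360 of 360 (100.00%)"
unlist(res$summary$mean_deviation_oct)
#>    single    double   complex
#> 0.2857143 0.4964953 0.6778846
unlist(res$summary$expected_range_pct)
#>   single   double  complex      all
#> 70.92377 52.82405 43.85684 55.27778
res$gradient$single$slope_oct_per_mm   # generative gradient is 2.93 oct/mm
#> [1] 2.822648
unlist(res$summary$noise_correlation_means)
#>     single     double    complex
#> 0.11670413 0.11452851 0.04799254
```

Reading it: every neuron of this all-sensitive mixture passes the ANOVA;
local BF deviation grows with FRA complexity (0.29 → 0.50 → 0.68 oct), so
complex neurons sit least predictably on the map; correspondingly ~71 % of
single-peaked but only ~44 % of complex neurons fall inside the
species-expected BF range of their field; the fitted global slope
(2.82 oct/mm, r = 0.98 on single-peaked neurons) recovers the generative
ferret gradient; and noise correlations are weaker among complex pairs
(0.048) than among single/double pairs (~0.12), reflecting their weaker
shared-noise coupling.

`out_dir` in the config additionally writes `classifications.csv`,
`field_metrics.csv`, `pairs.csv` and `summary.json`.

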