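---
title: "Receptive-field complexity and tonotopic organization: models and methods"
author: "tonomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptive-field complexity and tonotopic organization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonomap)
```

## The scientific problem

Primary auditory cortex (A1) carries a tonotopic map: preferred sound
frequency changes systematically along one cortical axis, roughly linearly
in log-frequency. Two-photon calcium imaging, which resolves every neuron
in a ~250 µm field, shows that this map is locally messy — neighbouring
neurons can prefer frequencies octaves apart. A key observation is that
much of the local scatter is carried by neurons whose frequency receptive
fields (FRAs) are not single-peaked: neurons with two response peaks, or
with complex multi-peaked FRAs, sit much less predictably on the map than
classical V-shaped single-peaked neurons, in both ferrets and mice.

`tonomap` implements that analysis chain end to end:

1. **Frequency sensitivity.** Per neuron, a balanced two-way ANOVA of
   trial-wise evoked responses with tone frequency and sound level as
   categorical predictors. A neuron is *frequency-sensitive* when the
   frequency main effect or the frequency × level interaction is
   significant at `alpha = 0.05`. Only sensitive neurons are analysed
   further.
2. **FRA shape.** The level-averaged tuning profile is thresholded at 75 %
   of its maximum; maximal runs of consecutive grid frequencies strictly
   above threshold are counted. One run → *single-peaked*, two →
   *double-peaked* (the weaker run's argmax is *peak 2*), three or more →
   *complex*. Best frequency (BF) is the global argmax of the profile; the
   bandwidth is the contiguous range around BF above 50 % of the BF
   response, in octaves. The Fano factor (across-trial variance over mean
   at the best frequency/level cell) quantifies trial reliability.
3. **Local tonotopy.** Within an imaging field, each neuron's deviation is
   `|log2(BF_i) - center(log2 BF_others)|`, a leave-one-out centre over the
   neurons of the same class (fields contribute only if they hold at least
   three neurons of the class). Deviations are reported in octaves and in
   octaves per mm of cortex.
4. **Species normalization.** Dividing hearing range by axis length gives
   the expected map slope — `speciesSlope(2e3, 60e3, 1.0)` = 4.91 oct/mm
   for mouse, `speciesSlope(36, 44e3, 3.5)` = 2.93 oct/mm for ferret. A
   perfect gradient could span `slope × field diameter` octaves across one
   field; the percentage of neurons within half that span of the field's
   median BF is a scatter measure comparable across species.
5. **Global gradient.** Least-squares fit of log2(BF) against position on
   the tonotopic axis (the linearization of a single-term exponential
   `BF = a·exp(b·x)`), with Pearson's r and per-neuron residuals in
   octaves; Welch t-tests compare residual magnitudes between classes.
6. **Pairwise correlations.** Noise correlation: Pearson correlation of
   the two neurons' residual trial series after subtracting each
   stimulus's mean response. Signal correlation: correlation of the two
   trial-averaged FRAs *minus* the pair's noise correlation (so shared
   trial-by-trial fluctuation does not masquerade as shared tuning; the
   difference can exceed 1 in magnitude). Both are summarized per class
   pair and against inter-neuron distance.

## The synthetic cortex

Real two-photon datasets are large and external, so the package carries a
generator (`generateField()`, `generateCohort()`) that emulates the
*statistical structure* the analyses rely on, with known ground truth.

**Templates.** Each peak of an FRA template is a Gaussian bump in
log2-frequency whose full width at half maximum equals the neuron's
bandwidth at the lowest sound level and widens by 1 %/dB with level — the
V-shape — while amplitude grows with level, so the FRA maximum sits at
(BF, highest level). Double-peaked neurons carry a second bump scaled by a
gain ratio drawn in (0.84, 0.895); complex neurons carry two further bumps.
Secondary gains sit deliberately above the 0.75 classifier threshold —
a generative "double" whose second peak cannot be detected by the 75 %
rule would be a single-peaked neuron by definition.

**Peak placement.** True BFs follow the species gradient at each neuron's
projected axis coordinate, jittered in log2-frequency by a class-dependent
SD (defaults 0.3 / 0.7 / 1.2 octaves for single / double / complex — the
generative scatter whose recovery the acceptance tests check). Peak
frequencies are snapped to the probed stimulus grid: the grid defines the
resolution at which a peak is identifiable, and on-grid ground truth is
exactly recoverable in the noiseless limit. Secondary peaks are drawn
uniformly over the grid range. For double-peaked neurons the *second peak
is drawn first* and the BF jitter is conditioned on it (re-drawn, or the
bumps narrowed, until the peaks are at least 1.7 bandwidths apart): the
conditioning always flows from peak 2 to BF, never the reverse, so
generative peak-2 frequencies carry no tonotopic structure — the property
reported for second peaks in vivo, and the null the neuropil-contamination
analysis needs.

**Separability geometry.** Two Gaussian bumps merge into one
suprathreshold run when the dip between them stays above 75 % of the
maximum. With the level-averaged width about 1.3 × the base bandwidth,
separation of 1.7 bandwidths keeps the dip below ~0.6 of the maximum, with
margin for trial noise; a 0.3-octave allowance covers the displacement
introduced by snapping peaks to the grid. Multi-peaked bandwidths are kept
in [0.4, 0.9] octaves so that these constraints are always satisfiable
within the probed ranges.

**Noise.** Trial responses are template value + *loading* × field-common
fluctuation + independent noise, rectified at zero (deconvolved event
rates are nonnegative). Defaults: independent SD 0.15, shared SD 0.1, and
loadings 0.6 / 0.6 / 0.35 / 0.45 for single / double / complex /
nonsensitive — chosen once so that same-class noise correlations land near
values typical of A1 population imaging (~0.14 for simple cells, ~0.05 for
complex cells, via the mixture identity ρ = L²σ_c² / (L²σ_c² + σ²)) and so
the weaker coupling of complex neurons is part of the generated
conditions. A Poisson family (`noise = list(family = "poisson")`) replaces
the additive model for Fano-factor calibration. A `baseline` offset lifts
responses clear of the rectifier when linear-noise identities are being
verified.

**Amplitudes.** Peak gains are log-normal with medians 1 / 0.8 / 0.7 for
single / double / complex, reproducing the qualitative ordering of
response strength at BF (single-peaked strongest) without claiming
quantitative means — the source material reports no amplitude
distributions.

**Neuropil.** Contamination is modelled at the response level: stored
responses are `(1-c)·own + c·field-average`, with the field-average signal
kept in the field metadata. `neuropilCorrect()` applies the standard
first-order correction `mixed - r·neuropil` (rectified); with `r = c` it
recovers the neuron's own responses up to scale, which the scale-invariant
classifier does not see. The default `r = 0.7` is the common practical
choice; it is a configuration value, not an estimate.

**Class mixture.** The default mixture is the ferret-wide condition:
19.23 % frequency-sensitive neurons split 42.71 / 31.75 / 24.96 across
single / double / complex. Note that a *measured* sensitive fraction will
exceed the generative 19.23 %, because nonsensitive neurons trip the
two-test union at its ~9.75 % false-positive rate; analyses that need many
neurons per class instead pass a sensitive-only mixture explicitly — this
is conditioning the experiment on sensitivity, not a change of the
underlying conditions.

**Seeding.** One master seed drives everything; per-neuron substreams are
derived from it, and the caller's RNG state is restored afterwards. Equal
seeds give byte-identical fields.

## What the generator does and does not emulate

It reproduces: class-dependent local BF scatter around a global log-linear
gradient, detectable multi-peaked FRA geometry, shared-trial-noise
structure with class-dependent loadings, response-amplitude ordering,
neuropil mixing, and the two species' grids, hearing ranges and axis
lengths. It does not emulate: calcium indicator dynamics beyond the
optional exponential-kernel `convolveCalcium()`, deconvolution artifacts,
non-Gaussian FRA shapes (I/O-shapes, inhibitory sidebands), realistic
signal-correlation magnitudes (template families are too regular, so
same-class signal correlations run high), Fano factors of spiking scale
under the Gaussian noise family, or spatial clustering of cell bodies.
Passing tests therefore validate the *analysis machinery* — recovery of
known structure, invariances, calibration against analytic values — not
any claim about real cortical data.

## Numerical choices and degenerate inputs

* Argmax ties break toward the lowest frequency (deterministic,
  storage-order independent).
* Thresholds are strict (`> 0.75·max`, `> 0.5·BF response`), so a value
  exactly at threshold is outside the peak.
* The ANOVA uses the balanced Type-I decomposition (the design is balanced
  by construction; sum-of-squares types coincide there). Zero total
  variance → not sensitive, p-values NA, flagged. Zero within-cell
  variance with between-cell structure → the infinite-F convention
  (p = 0), flagged, so noiseless fields classify cleanly. Grids with one
  sound level fall back to a one-way ANOVA on frequency.
* Fano factor uses the unbiased (n−1) variance; undefined (NA) when the
  trial mean is zero.
* A pair with zero residual variance has noise correlation defined as 0
  (flagged); a constant FRA makes the signal correlation NA (flagged).
* The local-deviation centre is the median (config: mean). The source
  material's prose supports both; the median is the default because the
  analysis leans on robustness to the very outliers it measures.
* Per-mm normalization divides by the field extent `max(width, height)`;
  the expected-range half-width is `slope × extent / 2`.
* Distance for correlation-vs-distance trends defaults to separation along
  the tonotopic axis (config: Euclidean in the field plane).

## Problem sizes

The shipped tests and the acceptance script use: 20 fields × 60 neurons
for scatter-recovery and correlation summaries; 60 fields × 60 neurons
(single-peak-dominated mixture, c = 0.5) for the neuropil-artifact
analysis, where the contamination effect on second peaks is modest
(r ≈ 0.15) and needs several hundred double-peaked survivors for a stable
verdict; 1 000 Monte-Carlo neurons for the type-I check; 10 000 trials for
noise-correlation and Fano calibrations; n = 500 for gradient recovery.
These sizes were chosen as the smallest at which the checked effects are
statistically stable across seeds.

## Known limitations

* The classifier operates on the raw (unsmoothed) level-averaged profile;
  `smoothFRA()` exists for display only. Manual reclassification of
  ambiguous FRAs — part of the original workflow — is out of scope, so
  borderline profiles near the 75 % threshold are decided mechanically.
* The expected-range measure assumes a constant log-frequency gradient
  across the whole axis.
* Unbalanced designs (unequal trials per cell) are not supported by the
  sensitivity ANOVA; the serialization enforces a full grid.
* The G-test for class proportions treats neurons as independent;
  within-field dependence is not modelled.

## A worked run

```{r, eval = FALSE}
res <- runPipeline(list(species = "ferret", n_fields = 12, n_neurons = 60,
                        class_mix = c(single = 0.43, double = 0.32,
                                      complex = 0.25, nonsensitive = 0),
                        seed = 11, out_dir = "results"))
res$summary$sensitive_line
res$summary$mean_deviation_oct
res$gradient$single$slope_oct_per_mm
```
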