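---
title: "Methods: nested bootstrap inference and synapse image quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested bootstrap inference and synapse image quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

# The problem

Culture electrophysiology experiments are nested: sweeps are recorded within
cells, cells within culture batches, and batches within genotype groups.
Measurements from the same cell are correlated, and cells from the same
culture may be too. Treating sweeps (or even cells) as independent
observations understates uncertainty. `synquant` implements an inference
pipeline built for a four-group design — two knockout lines, each with a
genetically matched control — where the scientific question is whether the
second manipulation changes transmission *beyond* the first, after
normalizing each knockout to its own control. It also implements the
measurement side: per-sweep electrophysiology metrics, side-view synapse
line-profile quantification for STED/confocal images, and automatic 2D
puncta segmentation.

# The ratio statistic and the hierarchical bootstrap

For groups `control_A`, `ko_A`, `control_B`, `ko_B`, the test statistic is

$$T \;=\; \frac{\overline{ko_A}/\overline{control_A}}
               {\overline{ko_B}/\overline{control_B}},$$

the ratio of control-normalized group means. Its null value is 1 (equal
normalized knockout effects in the two lines). With amplitude-like
measurements the alternative is $T > 1$ (line B more impaired); for
paired-pulse ratios, which move inversely to release probability, the
alternative is $T < 1$.

Each group mean is by default the *pooled* grand mean over all sweep values
in the group. The mean-of-cell-means alternative is exposed
(`group_mean = "cell"` in `statistic_T()` / `run_bootstrap()`) because both
conventions are defensible when designs are unbalanced; the pooled form is
the package default because the statistic is defined directly on group
means.

The sampling distribution of $T$ is estimated by a three-level hierarchical
bootstrap (`run_bootstrap()`). Within each group independently — group
identity is never resampled — batches are drawn with replacement (as many as
the group has); within each drawn batch, its cells are drawn with
replacement (that batch's own cell count); within each drawn cell, its
sweeps are drawn with replacement (that cell's own sweep count). Unbalanced
trees therefore keep the drawn unit's own size. Designs with one measurement
per cell (sucrose-evoked charge) set `single_sweep = TRUE`, which skips the
sweep level. From the replicates $T^*$:

* the 95% confidence interval is the percentile interval, with type-7
  (linear-interpolation) empirical quantiles — the interpolation rule is
  recorded in the result;
* the directional null probability is
  $P_{H_0} = \#\{T^* \le 1\}/n_{\mathrm{iter}}$ for the alternative $T > 1$
  and $\#\{T^* \ge 1\}/n_{\mathrm{iter}}$ for $T < 1$. Ties at exactly 1
  count toward the null in both directions, following the defining
  inequalities literally. This is a plausibility measure of the null given
  the data, not a frequentist p-value.

Headline analyses use 100,000 iterations. The resampling inner loop is
implemented in C++ but consumes R's RNG stream, so results are bit-identical
for identical `(dataset, n_iter, seed)` and independent of any
parallelization. Degenerate resamples with a zero control mean (possible
only when a group contains zeros) are re-drawn rather than propagated as
infinities, and the re-draw count is reported.

```{r}
d <- simulate_ephys_dataset(seed = 7)
run_bootstrap(d, n_iter = 10000, direction = "greater", seed = 7)
```

## What the bootstrap can and cannot do at small batch counts

With three cultures per group the bootstrap resamples three batch labels,
so the batch-level spread of $T^*$ is slightly narrower than the true
sampling spread (the classic $(n-1)/n$ bootstrap shrinkage, at $n = 3$ a
factor of $2/3$ on the batch variance component). Two consequences, both
measured by the test suite on the package's own generator (500 replicate
experiments, between-culture and between-cell SD 0.3 log units, sweep CV
0.3, 3 batches x 6 cells x 3 sweeps):

* the null false-positive fraction at $P_{H_0} < 0.05$ is about 0.06–0.08 —
  approximately, not exactly, calibrated, inside the sanity envelope
  [0.01, 0.10], and the 95% percentile interval covers the true ratio about
  92% of the time;
* one-sided power to detect a true 2-fold ratio is about 0.6. Three
  cultures per group with realistic between-culture variability is simply
  not a high-powered design for a ratio-of-ratios; the package reports this
  honestly rather than tuning the generator toward optimism.

# Synthetic nested data

`simulate_ephys_dataset()` generates the statistical structure the inference
assumes, nothing more (no membrane biophysics, no vesicle-pool kinetics).
Values are log-normal — positive and right-skewed, like PSC amplitudes.
Group effects are multiplicative. Batch and cell random effects are
mean-one log-normals with SDs `batch_sd` and `cell_sd` (log units); sweep
noise is a mean-one log-normal with coefficient of variation `sweep_cv`.
Control and knockout groups of the same line draw independent batches,
mirroring independent per-group resampling in the inference. Defaults:

* `baseline_mean = 500` pA, a typical evoked PSC scale in these cultures
  (the statistic is scale-invariant, so this choice is cosmetic);
* `group_effects = (1, 0.15, 1, 0.075)`: line A retains ~15% of control
  transmission (a strong active-zone disruption phenotype), line B a further
  ~50% less, so the true ratio is $T_{\mathrm{true}} = 2$;
* `batch_sd = cell_sd = 0.3`, `sweep_cv = 0.3`: culture-to-culture and
  cell-to-cell variability of ~30%, realistic for primary cultures;
* 3 batches x 6 cells x 3 sweeps per group; sweep counts follow the
  convention of averaging three to four sweeps per cell for paired-pulse
  measurements, since per-cell sweep counts are rarely reported.

A note on validating the generator: the plug-in ratio of means is biased
upward by $O(1/n_{\mathrm{batches}})$ (about 6% at the defaults), so the
Monte-Carlo check of generator calibration is performed on
$\log \hat{T}$, where the equal coefficients of variation of knockout and
control means cancel the bias to second order.

# Electrophysiology metrics

All metrics share two windowing conventions that the underlying recordings
force but rarely state precisely: a stimulus-artifact blanking window
(default 2 ms) after each stimulus time, excluded from both baseline and
peak search, and a baseline window (default 1 ms) starting when blanking
ends — i.e. the baseline is taken immediately after the stimulus artifact.
This local baselining is what makes amplitudes meaningful when responses
ride on the decay of earlier ones (paired pulses, 10 Hz trains).

* `psc_amplitude()`: |peak − baseline| with the polarity-signed extremum in
  a search window defaulting to the inter-stimulus interval (50 ms for a
  single stimulus). Invariant to constant offsets.
* `rise_time_20_80()`: first crossings of 20% and 80% of peak on the rising
  phase, linearly interpolated between samples.
* `paired_pulse_ratio()`: sweeps are averaged sample-wise first, then the
  ratio of second to first amplitude is taken on the mean trace — the usual
  reading of computing the ratio from an average of a few sweeps per cell;
  the per-sweep-ratio average is available as `method = "per_sweep"` since
  the two conventions differ on noisy data.
* `sucrose_charge()`: trapezoidal integral of |baseline-subtracted current|
  over the first 10 s from response onset. Onset is the first crossing of
  3x the pre-application baseline SD sustained for 50 ms, because a
  definition of onset is needed and none is conventional; an explicit
  `onset` overrides detection. A flat trace yields 0 pC rather than an
  error.
* `train_amplitudes()`: one amplitude per stimulus, each with its own
  post-artifact baseline.
* `detect_minis()`: sliding scaled-template detection with an idealized
  biexponential template (rise 0.3 ms, decay 4 ms by default) and the
  fitted-scale/standard-error criterion with threshold 4; the criterion
  threshold is in noise-SD units, so detection is invariant to intensity
  scaling. Frequency is events per 100 s analysis window. Event decay time
  is the time from peak to $1/e$ of peak, a $\tau$-equivalent, chosen
  because the decay metric is otherwise undefined.

# Side-view line profiles

`fit_psd_ellipse()` reduces a (manually drawn or ground-truth) PSD mask to a
center and orientation via intensity-weighted second moments; masks without
clear elongation (axis ratio < 1.3) are rejected because their orientation
is meaningless. `extract_profile()` samples a ~1200 nm x 200 nm rectangle
perpendicular to the band through its center, averaging across the width,
with bilinear interpolation at pixel-pitch steps; the presynaptic (negative)
direction is assigned toward the vesicle-channel centroid. `align_profiles()`
smooths the PSD channel only with a centered 5-sample moving average
(shrinking at the edges), defines position 0 at the smoothed peak (ties
broken toward the position nearest 0, for alignment stability; peaks at the
window edge are flagged), shifts all channels accordingly, and reports the
axis cropped to [−400, +200] nm. Reporting crops a wider extraction so that
shifted profiles still cover the reported axis. Peak values per profile are
position-independent maxima; non-PSD channels are left unsmoothed for peak
extraction since only the PSD channel's smoothing is conventional. All
intensities are raw — no background subtraction anywhere in the imaging
pipeline.

`simulate_sideview_image()` renders this geometry (PSD ridge, vesicle cloud,
offset test-protein ridge, Gaussian noise) at 11.4 nm/pixel with a default
test-protein offset of −45 nm, the midpoint of the typical active-zone peak
region (−70 to −20 nm). What it does *not* emulate: the STED point-spread
function, labeling stochasticity, background structure from neighboring
synapses, or chromatic offsets between channels. Recovery tests on these
images therefore validate the geometry and bookkeeping of the pipeline —
axis signs, alignment, interpolation — not its robustness to real optical
artifacts.

`factorial_profile_test()` compares aligned profiles between two conditions
with a two-way (condition x position) ANOVA restricted to a 200-nm window
centered on the active-zone peak, plus Bonferroni-adjusted per-position
comparisons (adjustment over the in-window positions).

# Puncta segmentation

The segmentation criterion is `median + k x MAD` (scaled to the normal,
`k = 4` by default) on raw intensities — robust to the punctum pixels
themselves and invariant to intensity rescaling. Components use
8-connectivity by default (4-connectivity available) with a minimum area of
4 pixels. Every parameter is recorded in the result. Density is reported
per image, matching per-image quantification conventions, with per-µm² as
auxiliary. The colocalization filter retains an object when its fractional
pixel overlap with the union of the reference channel's objects strictly
exceeds the threshold; at the conventional threshold of 0%, a single shared
pixel suffices (a zero threshold with a strict inequality). The original
analysis code this emulates is not described algorithmically anywhere we
could follow, so these defaults are declared choices, not inferences.

# Numerical and design notes

* Windows on traces are closed sample-index intervals; a 10-s plateau
  integrates to its nominal charge to <0.01%.
* The exact paired-pulse identity (1.500 on a noise-free 100/150 pA pair)
  holds to <1e−6 because the first response's biexponential tail under the
  second peak is ~1e−5 pA at a 50 ms interval.
* Quantile rule, tie policy at $T^* = 1$, and the re-draw rule for
  zero-mean resamples are all recorded in `bootstrap_result`.
* Problem sizes in the test suite (500 replicate experiments at 2,000
  bootstrap iterations; 100 synthetic synapses; 50-punctum fields) were
  chosen so Monte-Carlo error is small relative to the tolerances being
  asserted while a full run stays comfortably interactive.

# Known limitations

* The bootstrap is approximate at very small batch counts (see above); it
  does not implement BCa or studentized intervals by design.
* Mini detection assumes a roughly correct template shape; grossly wrong
  time constants degrade the detection criterion.
* Profile extraction requires the full rectangle inside the image and
  errors otherwise rather than padding.
* The image generators are geometric, not optical, models.
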