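---
title: "Models and methods behind visrecov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind visrecov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`visrecov` implements the analysis pipeline used to quantify
stimulus-specific recovery of mouse V1 responses after long-term monocular
deprivation (LTMD): stimulus synthesis, per-neuron response metrics from
extracellular recordings, Fourier analysis of intrinsic-signal imaging, an
earth-mover's-distance (EMD) "fictive longitudinal" population analysis, and
the group-level statistics that tie them together. Because the original raw
data are in-lab animal recordings, the package ships a synthetic-data
generator whose forward models invert each analysis; every estimator is
validated by parameter recovery against that generator, by closed-form
oracles, or by exhaustive enumeration. This vignette documents the models,
the defaults and why they were chosen, the numerical decisions, and what the
synthetic validation does and does not establish.

# Stimulus synthesis

**Noise movie.** The visual stimulus is band-limited contrast-modulated
Gaussian noise. We draw spatiotemporal white Gaussian noise on a
`grid_px × grid_px × n_frames` lattice, take its 3-D FFT, zero every
coefficient whose radial spatial frequency exceeds `sf_cutoff_cpd` or whose
temporal frequency exceeds `tf_cutoff_hz`, and invert. Masking by frequency
*magnitude* preserves Hermitian symmetry, so the inverse transform is real
to machine precision; the test suite verifies that out-of-band power is
below 10⁻⁶ of the total for several seeds. Defaults: 60 × 60 pixels over
30°, 30 frames/s, 5 min, cutoffs 0.05 cycles/° and 4 Hz — the published
stimulus calibration. The pass-band is flat; the original stimulus was
described as matched to the mouse's spatiotemporal sensitivity, which may
imply a shaped spectrum, but only the cutoffs are documented, so
flat-within-band is implemented (a shaped-spectrum hook would slot in at the
masking step).

**Normalization.** Frames are rescaled so the 99.9th percentile of
`|value|` equals 1 and then clipped to `[-1, 1]`. A max-based rescale lets a
single extreme pixel set the contrast of the whole movie; percentile scaling
plus clipping distorts only ~0.1% of samples. The clipping introduces tiny
out-of-band harmonics, so the strict spectral-support invariant is stated on
the unclipped stack (`frames_raw`, available via `keep_raw = TRUE`), while
the practical 1%-of-peak band-edge criterion holds for the final frames.

**Contrast envelope.** The movie runs gray → full contrast → gray once per
`contrast_period_s` (default 10 s). A plain sinusoid would go negative, so
the envelope is the raised cosine `e(t) = (1 − cos(2πt/P))/2`; the rectified
sine `|sin(πt/P)|` is available via `form = "abs_sine"` for comparison. Both
satisfy `e(0) = e(P) = 0`, `e(P/2) = 1`.

**Grating protocol.** One block holds 12 equally spaced drift directions ×
6 spatial frequencies (0.01–0.32 cpd, doubling) plus one blank (full-field
flicker, coded `sf_cpd = 0`) per direction slot; blocks are shuffled
independently per eye and repeat (default 6 repeats/eye), so blanks are
interspersed and every condition appears exactly `repeats` times per eye.
Trials last 1.5 s at 2 Hz temporal frequency.

**Axes.** Pixel `[1, 1]` is top-left; x increases rightward (azimuth), y
downward (elevation). The image format itself does not define this, so it
is fixed here by convention.

# Synthetic populations

Each unit is a parameter vector: per-eye grating gains and preferred
orientations, shared tuning width `σ` (degrees), direction ratio
`A2/A1 ∈ [0, 1]`, log-Gaussian spatial-frequency tuning (peak `sf_pref_cpd`,
width in octaves), Naka–Rushton contrast parameters (`c50`, exponent `n`),
spontaneous rate, and per-eye noise gains. Cell class is broad-spiking with
probability 0.8, matching the ~80/20 broad/narrow split of unbiased
silicon-probe sampling.

**Forward models.**

- Grating trial rate: `spont + gain_eye · G(θ) · S(sf)`, with `G` the sum of
  two circularly wrapped Gaussians (amplitudes 1 and `dir_ratio`, peaks at
  θ_pref and θ_pref + 180°, shared width σ) and `S` the log-Gaussian SF
  profile; blanks fire at `spont`. Counts are Poisson over the 1.5-s trial.
  An over-dispersed count model is deliberately *not* the default: no count
  noise model beyond trial-to-trial variability is documented for the
  original recordings, and Poisson keeps recovery tests interpretable.
- Noise response rate: `spont + gain · c(t)ⁿ/(c(t)ⁿ + c50ⁿ)` with `c(t)`
  the movie's contrast envelope, discretized at the frame rate
  (inhomogeneous Poisson). Note the generator drives rate through the
  *envelope* — the analysis stage must rediscover the 0.1-Hz modulation
  from counts alone.
- Imaging: each pixel oscillates as `A(x,y)·sin(2πft + φ(x,y))` plus slow
  drift (per-pixel linear ramp and one-cycle cosine, scaled by
  `drift_scale`) and white noise.

The SF tuning generated (log-Gaussian) deliberately differs from the model
fitted downstream (difference of Gaussians) so SF-preference recovery tests
are honest about model mismatch.

**Group effects.** Treatment groups act as multipliers on contra-eye
(deprived-eye) grating gain, contra-eye noise gain, spontaneous rate (broad
and narrow separately), binocular mismatch spread, and orientation
selectivity. The published results are group contrasts, not per-neuron
effect sizes, so these multipliers are *documented package defaults chosen
once*, sized to reproduce the qualitative pattern — deprived-eye suppression
after LTMD, slow home-cage recovery, stimulus-specific restoration under
noise+run vs grating+run, elevated broad-spiking and suppressed
narrow-spiking spontaneous activity after deprivation:

| group        | grating gain | noise gain | spont (broad/narrow) | mismatch SD | OSI scale |
|--------------|-------------:|-----------:|---------------------:|------------:|----------:|
| non-deprived | 1.00 | 1.00 | 1.0 / 1.0  | 15° | 1.00 |
| LTMD         | 0.25 | 0.25 | 1.5 / 0.4  | 40° | 0.60 |
| home-cage    | 0.35 | 0.35 | 1.3 / 0.45 | 35° | 0.65 |
| noise+run    | 0.50 | 0.90 | 1.1 / 0.45 | 35° | 0.70 |
| grating+run  | 0.90 | 0.50 | 1.1 / 0.5  | 18° | 0.90 |

Because the spec of the direction profile fixes its shape, the OSI scale is
implemented as a widening of the tuning width (`σ / osi_scale`, capped at
80°) rather than as a separate untuned component.

**Waveform features.** Broad and narrow classes draw
(trough-to-peak, slope at 0.5 ms) from bivariate normals
(broad: 0.75 ± 0.12 ms, +0.06 ± 0.03; narrow: 0.33 ± 0.07 ms,
−0.05 ± 0.025). These are calibrated so the two-criterion classifier
(narrow iff trough-to-peak < 0.5 ms *and* slope ≤ 0) misclassifies under 5%
per class — verified by 10⁴-draw Monte Carlo in the tests. Only the feature
rule is documented for the original classification; the numeric thresholds
here are configurable package defaults.

# Per-unit metrics

- **Spontaneous rate**: mean of `count/duration` over blank trials; its
  absence is an error, not a silent zero.
- **Evoked response**: condition mean rate minus spontaneous; negative
  (suppressed) values are preserved in tables but clipped to zero inside
  ODI/OSI ratios, where signed numerators make the ratio unstable.
- **Preferred orientation**: `θ_pref = ½ · arg Σ F(θ)e^{2iθ}` over
  directions, with `F` the baseline-subtracted response averaged across
  spatial frequencies (a flag for raw `F` is the only plausible
  alternative; baseline-subtracted is the default because blanks are
  abundant in the protocol). A zero resultant (perfect symmetry) raises an
  undefined-preference error and excludes the unit from orientation
  analyses. The estimator is rotation-equivariant, which the tests check as
  a property.
- **Tuning fit**: with θ_pref held fixed, bounded nonlinear least squares
  (Levenberg–Marquardt, `minpack.lm`) of
  `B + A1·g(θ; θ_pref, σ) + A2·g(θ; θ_pref+180°, σ)`, wrapped Gaussians
  summed over ±360° images (adequate for σ ≤ 90°), bounds `A1, A2 ≥ 0`,
  `σ ∈ [5°, 90°]`. Multi-start over σ ∈ {10°, 20°, 40°} with the
  lowest-residual fit retained guards against local minima. `R_pref` and
  `R_ortho` are evaluated *from the fitted curve* at θ_pref and
  θ_pref ± 90° — fitted rather than raw values because single-condition
  means at 6 repeats are noisy.
- **OSI** `(R_pref − R_ortho)/(R_pref + R_ortho)`; **tuning width** is the
  half-width at half-maximum above baseline found by root-finding on the
  fitted curve (for an isolated Gaussian this equals `σ√(2 ln 2)`, the
  closed form used as the test oracle).
- **Binocular mismatch**: contra minus ipsi preference wrapped into
  `(−90°, 90°]`; `|dO|` is the matching statistic.
- **SF fit**: difference of two zero-centred Gaussians on the *linear* SF
  axis (the axis is not documented; linear is the common convention for
  DoG receptive-field models), amplitudes non-negative; `sf_pref` is the
  argmax of the fitted curve on a fine grid over `[0, 2·max SF]`, falling
  back to the raw argmax (flagged) on non-convergence.
- **F1 response**: counts are folded into one 10-s cycle, the rate is
  averaged per phase bin, and the first-harmonic amplitude
  `2|Σ r_k e^{−2πik/m}|/m` is returned in spikes/s. Folding requires an
  integer number of bins per period; resampling is deliberately the
  caller's job. Responsiveness thresholds: ≥ 2.0 spikes/s evoked through
  either eye for gratings, F1 > 0.2 for noise.
- **C½**: rates are binned by instantaneous contrast (20 equal-width bins),
  and C½ is the lowest contrast where the piecewise-linear curve crosses
  `(max + baseline)/2`, baseline being the lowest-contrast bin. The
  estimator is scale-invariant in gain; a contrast-independent cell has
  undefined C½ (`NA`).

# Imaging analysis

Recordings are trimmed to a whole number of stimulus cycles (avoiding
leakage), each pixel is mean-removed and, by default, linearly detrended
(intrinsic signals drift; the closed-form projection on the shared time
axis keeps this cheap), and the complex component at the stimulus frequency
is extracted. Amplitude uses the single-sided convention `2|X_f|/N` — this
affects the absolute reflectance scale but cancels in ODI and group
contrasts. Phase is reported in the `A·sin(2πft + φ)` convention. Detrending
a pure sinusoid removes a small in-band component (relative error ~10⁻³ at
our test sizes), so `detrend = FALSE` exists for exactness checks; with
drift and noise the detrended estimator is the accurate one, which is what
the SNR-10 recovery criterion exercises. ROI quantification is a mask
average with at least four repeat measurements enforced, and
`odi_imaging(R, L) = (R − L)/(R + L)`.

# Fictive-longitudinal EMD analysis

Without chronic tracking, "before" and "after" populations are different
neurons. The fictive-longitudinal analysis asks whether a minimal-total-
movement correspondence between the two cross-sections behaves like a
plausible longitudinal dataset: each unit is a point in the
(grating response, noise F1) plane, the 500 most responsive units per
condition are kept, and the uniform-mass optimal-transport plan under
Euclidean ground distance is computed.

Numerical decisions:

- **Axis scaling.** The two axes are in the same nominal units but span
  very different ranges (grating peaks reach several-fold higher rates than
  noise F1), and the published flow fields use unequal axis scales. Each
  axis is therefore divided by its pooled 95th percentile
  (`axis_scales()`), computed once across all conditions being compared and
  passed to both the selection and the transport steps; the factors are
  recorded in the result.
- **Solver.** The transport problem is solved *exactly* by successive
  shortest augmenting paths with node potentials, implemented in C++
  (`src/transport.cpp`). At n = 500 × 500 the exact solution takes seconds,
  so no sliced/entropic approximation is used. Equal-size uniform-mass
  problems return a one-to-one assignment; unequal sizes split mass with
  marginals `1/|A|` and `1/|B|`. The solver is checked against an
  exhaustive-permutation oracle (all n! assignments, n ≤ 8, 100 random
  instances) and for metric properties (symmetry, identity, triangle
  inequality).
- **Flow heat maps.** Each flow is binned at its source on a 25 × 25 grid
  over the scaled unit square, accumulating
  `mass × (target − source)` along the chosen axis in original spikes/s;
  sources beyond the 95th-percentile edge are clamped to edge bins and
  counted. The sum over bins equals the population's mean displacement
  along that axis (a conservation identity tested directly).
- **Diagonal contrast.** The published comparison of flow maps reports a
  chi-square but not its table; the construction here — declared, not
  asserted as the original — is a 2 × 2 table of positive-flow magnitude
  {above, below the scaled-space diagonal} × {map 1, map 2}, compared with
  Pearson's chi-square without continuity correction. Because transport
  masses sum to 1, the mass-weighted table totals are of order of the mean
  displacement and a chi-square on them is uninformative at any effect
  size; the contrast therefore multiplies each map's magnitudes by its
  source-neuron count, putting the table in population-summed spikes/s —
  the scale at which the flow fields are drawn.

# Group statistics

Median ± SE summaries use a with-replacement bootstrap (default 1000
resamples) for the SE of the median; distributions are compared with the
two-sample Kolmogorov–Smirnov test and Bonferroni correction
(`min(1, p·m)`). The family size defaults to the number of group pairs per
metric — whether the original correction family was per-metric or global
over the whole table is not documented, so per-metric is the default and
`m` is an argument. Adjusted p-values are bucketed into the levels used in
the published comparison table (`<0.00001` … `n.s.`). Repeated-measures
ANOVA and Kruskal–Wallis are standard `stats` routines and are used
directly rather than wrapped.

# Validation sizes and determinism

Every stochastic function takes an explicit seed and is bit-reproducible
under it. The test suite exercises, among others: tuning-parameter recovery
on 200 simulated units (gain 10 spikes/s, σ = 25°, 6 repeats × 12
directions; median errors required < 10° in θ_pref, < 5° in σ, < 0.1 in
ODI); imaging amplitude recovery at SNR 10 with drift over 4 averaged
measurements (median relative error < 5%); a 100-instance EMD oracle sweep;
and an end-to-end run with population sizes mirroring the published samples
(900 LTMD, 660 noise+run, 720 grating+run broad-spiking units, top 500
selected) checking the stimulus-specific ordering of group medians and the
diagonal-flow contrast. These sizes were chosen as the smallest that make
the stochastic criteria statistically comfortable, and the movie specs used
in tests are scaled-down variants of the default calibration (same cutoffs,
smaller grids/durations).

# Limitations

The generator emulates tuning, gains, Poisson spiking, and group-level
multipliers — it does not emulate locomotion-gain dynamics within a
session, eye movements, spike-sorting contamination, electrode drift,
correlated (shared) trial-to-trial variability, hemodynamic nonlinearity in
imaging, or per-animal clustering of effects. Passing recovery tests on
this synthetic data therefore establishes that the estimators are correct
and well-calibrated for their stated models, not that real recordings meet
those models. Group-effect multipliers are placeholders for qualitative
contrasts; absolute synthetic effect sizes should not be read as
predictions. The EMD correspondence is a descriptive device: optimal
transport between cross-sections is a lower bound on plausible change, not
evidence that any particular neuron changed.
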