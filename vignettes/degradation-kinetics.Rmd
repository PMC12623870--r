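---
title: "Quantifying acute protein degradation in fluorescence time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute protein degradation in fluorescence time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degtrace)
```

## The measurement problem

Auxin-inducible degron (AID2) experiments make a tagged protein of interest
degradable on demand: adding the inducer 5-Ph-IAA triggers ubiquitination of
the mAID-tagged fusion protein and its proteasomal destruction. Imaging such
experiments produces two kinds of raw data that this package quantifies:

* **Culture movies** — multi-channel confocal time-lapse stacks of neurons in
  which the tagged scaffold protein (PSD-95, GKAP, gephyrin) appears as
  bright synaptic puncta on a dim dendritic background. The quantity of
  interest is the fluorescence of each punctum over time, from which
  degradation kinetics and per-synapse co-loss relationships are derived.
* **Longitudinal in-vivo sessions** — z-stacks of the same cortical volume
  recorded over hours to days, with a stable nuclear reference channel
  (H2B-tagged) and a cytosolic signal channel whose loss is to be measured
  per cell across sessions.

Neither kind of raw data is bundled here; the synthetic-data module renders
seeded scenes with known ground truth so every stage of the pipeline can be
validated end to end.

## The kinetic model

After inducer addition at time $t_0$, a trace is modelled as a sum of two
exponentials with a mixing fraction:

$$F(t) = A\left[f\,e^{-(t-t_0)/\tau_1} + (1-f)\,e^{-(t-t_0)/\tau_2}\right],
\qquad t \ge t_0,$$

with $F(t) = A$ before $t_0$. The *major pool* is the component carrying a
fraction $\ge 0.5$ (ties go to the faster component); the headline time
constant of a construct is $\tau_\mathrm{major}$. In practice major pools
comprise most of the signal and the minor pool is roughly an order of
magnitude slower, plausibly reflecting secondary processes such as slow
photobleaching rather than degradation proper.

`fit_biexponential()` minimizes the sum of squared residuals by exhaustive
grid search: $\tau$ on a logarithmic grid of 40 steps per decade over
$[0.1, 1000]$ h for both components (with $\tau_1 \le \tau_2$ to halve the
space), $f$ on $\{0, 0.01, \ldots, 1\}$, and $A$ fixed to the normalized
reference value of 1 so the search has exactly three free parameters. The
SSR over $f$ at fixed $(\tau_1,\tau_2)$ is a quadratic whose coefficients
come from the Gram matrix of the exponential basis, so the whole grid is
evaluated in vectorized form; the values are algebraically identical to the
naive triple loop (the test suite spot-checks this). Fits carry two flags:
`boundary_hit` when a reported component sits on a grid edge and
`non_decaying` when the fitted curve declines by less than 1% over the
observation window.

```{r fit-demo}
tt <- c(-2, -1, 0:24)
y <- kinetics_value(kinetics_spec(1, 0.9, 3.7, 37, 0), tt)
fit_biexponential(tt, y, t_inducer = 0)
```

### Identifiability of the minor pool

On noiseless data the fitted SSR surface has a quasi-flat ridge in
$(\tau_2, f)$: a minor pool that decays by only a few percent inside the
observation window is nearly indistinguishable from a constant offset, so
adjacent grid nodes differ in SSR by $\sim 10^{-8}$ and the discrete argmin
can sit several nodes away from the generating parameters without any error
in the fitter. The parameter-recovery acceptance check therefore draws its
ground-truth parameters from the search grid itself (where the unique
zero-SSR node must be found exactly — a sharp test of exhaustiveness and of
the major/minor reporting convention), while robustness of
$\tau_\mathrm{major}$ for off-grid truths is covered separately. Headline
constants quoted from fits should always be the major-pool constant;
minor-pool values are reported but should not be over-interpreted.

## Culture quantification

The measurement chain mirrors standard synapse-imaging practice:

1. **Maximum-intensity projection** over z per time point and channel.
2. **Detection**: multi-scale Laplacian-of-Gaussian blob detection
   (`detect_puncta()`), local maxima above `mean + 4·sd` of the LoG
   response, with a minimum pairwise separation enforced greedily by
   descending score. The detection operator and its thresholds are
   deliberately exposed parameters: published analyses of this kind used
   interactive software whose operator is not specified, so a reproducible,
   parameterized stand-in is used.
3. **Tracking**: greedy nearest-neighbour linking from the first time point
   (`track_puncta()`), with formed / disappeared / merged / split
   classification. Merged means two track heads contesting one detection,
   split the converse; morphological "morphing" is not separately
   detectable and surfaces as one of those two.
4. **ROI quantification**: mean of the 9×9-pixel square centred on the
   tracked position, measured on the projection (`measure_roi()`).
5. **Background correction**: one scalar per (image, channel, time),
   subtracted from every ROI mean. The default estimator averages a
   *cell-free mask* — pixels below the Otsu threshold of a blurred copy,
   dilated so punctum skirts are excluded — computed once at the reference
   frame and re-measured on every frame. A fixed region matches how
   cell-free regions are chosen in practice and avoids a subtle artefact:
   re-running Otsu per frame lets the threshold chase the fading foreground,
   which bends the floor of every normalized trace.
6. **Normalization**: each trace divided by its value at the last time point
   before inducer addition (`normalize_to_reference()`), so the reference
   point is exactly 1.

### Exclusion policy for vanished puncta

Tracks flagged formed, merged or split are always excluded, as are traces
with a non-positive reference value. Disappearance needs care: once
degradation is under way every punctum eventually falls below the detection
limit — that near-zero measurement *is* the signal, not a tracking failure.
`quantify_culture()` therefore distinguishes (default
`disappear_policy = "pre_inducer"`) tracks undetected *before* inducer
addition (excluded: unstable or misdetected synapses) from tracks lost
*after* it (kept; the ROI holds its last tracked position and keeps
measuring). The strict rule — any missed detection excludes the track — is
available as `disappear_policy = "any"` and remains the definition of the
`persistent` flag in `track_puncta()`.

### Population averaging and downstream statistics

`population_average()` averages in two levels — synapses within a neuron,
then neurons — matching how population curves are normally presented.
Headline constants are fitted on the population-average trace; per-neuron
fits are available by fitting each neuron's average separately (both modes
exist because published reports rarely state which was used).
`fit_initial_rate()` regresses absolute (non-normalized) fluorescence on
time over exactly the first five post-inducer points, the convention for
initial-rate analyses of degradation. `per_synapse_correlation()` returns
the pooled Pearson r and p alongside per-neuron coefficients summarized as
mean ± sd; `loss_delta_analysis()` computes per-synapse absolute losses in
two channels (on non-normalized values, which scale with protein quantity),
their ratio and their correlation. `group_compare()` wraps the two
group-level tests used in this field: Welch's unequal-variance two-tailed
t-test and the two-sided Wilcoxon rank-sum test. p-values are reported
unadjusted.

## In-vivo quantification

The longitudinal pipeline follows five steps per session:

1. **FOV selection** (`select_fovs()`): by default 13 planes starting 60 µm
   below the reference surface in 10 µm steps, converted to plane indices
   from the stack's z-spacing.
2. **FOV matching** (`match_fov()`): keypoints are LoG maxima with
   mean/sd-normalized 9×9 patch descriptors, matched by mutual nearest
   neighbour and validated either by Lowe's distance-ratio test or by
   consensus with the dominant displacement (fields of near-identical
   nuclei defeat a ratio test alone). When keypoints are scarce the method
   falls back to a translation-invariant normalized cross-correlation (the
   peak of the FFT cross-correlation over all shifts), flagged in the
   result.
3. **Nucleus detection** (`detect_nuclei()`): Gaussian blur (σ = 2 px),
   global Otsu binarization, LoG blob detection with maxima restricted to
   the foreground. LoG scales probe the configured nuclear radius ± 40%.
4. **Registration and tracking** (`register_and_track()`): a global
   xy-translation (phase correlation on images, or a Hough-style
   displacement-consensus vote on centroids) followed by an iteratively
   refined least-squares local affine on matched centroid pairs. Fewer than
   three usable pairs degrades to a translation-only map, flagged.
5. **Ring quantification and normalization**: the cytosolic signal is the
   mean over the half-open annulus $4 \le d < 8$ px around each centroid
   (`ring_quantify()`; half-open so nucleus disk and ring partition the
   neighbourhood), divided by the *session-level* mean nuclear-reference
   fluorescence (`normalize_nuclear()`). Session-level normalization is the
   default because its purpose is correcting session-to-session recording
   gain; per-cell normalization is provided as an option. Nuclear means are
   measured on an interior disk (radius − 1 px) so a ~1 px registration
   error cannot bleed background into the reference.

Inclusion filters (`apply_inclusion_filters()`) then drop cells whose
nearest-neighbour distance is below 3 px — interpreted as centroid-to-
centroid distance, the only per-cell distance defined in this pipeline —
and cells whose initial normalized signal is below 0.3.
`neuropil_background_ratio()` implements the histology read-out: mean
neuropil fluorescence across ROIs divided by mean background (vessel)
fluorescence.

## The synthetic-data generator

`simulate_culture_movie()` renders puncta as isotropic 2-D Gaussians
(σ = 1.5 px by default, matching the 9×9 ROI scale) at their brightest
z-plane with Gaussian axial falloff, on a uniform background, with optional
correlated-lognormal per-punctum amplitudes across channels (`reporter_rho`
controls the Pearson correlation of channel amplitudes), scheduled punctum
appearance/disappearance, Poisson shot noise and additive Gaussian read
noise (both optional), and per-frame exponential photobleaching (off by
default, since sparse sampling rather than bleaching correction is the
usual mitigation). `simulate_invivo_sessions()` renders nuclei as constant
disks in the reference channel and cytosolic disks following per-cell
kinetics in the signal channel, with later sessions displaced by a random
translation (≤ 10 px per axis by default) plus mild rotation/scale jitter;
ground truth stores exact centroids and transforms.
`simulate_histology_fov()` renders neuropil/vessel regions with specified
means and labelled masks. All generators are bit-reproducible for a given
seed.

Default study conditions were chosen once to mirror the biology being
emulated: culture kinetics of 90% pools with 1.6–8.5 h major constants and
~10× slower minor pools; in-vivo sessions at −2, 1, 2, 3, 4, 5, 6, 8 h
around the inducer with cytosolic kinetics (τ = 1.6 h, 90% pool) that floor
near 10% of baseline, matching the ~90% maximal in-vivo reduction such
experiments report; acquisition noise set to SNR ≈ 10 at baseline, a
deliberately conservative figure since published acquisition noise is not
stated (the level is config-exposed).

### What the generator does not emulate

Optical realism is out of scope: no empirical PSF beyond the Gaussian, no
sCMOS fixed-pattern noise, no axial drift, no dendrite morphology — the
background is uniform rather than structured. One consequence worth knowing
about real multi-plane data: a maximum projection over independently noisy
z-planes is a biased order statistic — the background floor rises by the
expected maximum of $n_z$ noise draws, and mid-intensity pixels are
attenuated roughly $n_z$-fold relative to it — which at low SNR steepens
apparent decay curves. Acquisition protocols mitigate this by frame
averaging before projection; the end-to-end validation scenes here use one
noisy plane per time point at the stated SNR instead, and passing them
demonstrates correct trace recovery at that SNR, not robustness to heavy
multi-plane projection noise.

## Numerical choices

* Coordinates are 0-based (row, col); a 9×9 ROI spans centre ± 4 px.
* ROI means accumulate as a plain sum over the footprint divided by the
  pixel count, so they equal brute-force enumeration bit for bit.
* Ring membership uses pixel-centre distances with a half-open interval.
* TIFF round trips store 32-bit samples scaled into [0, 1] by a power of
  two kept in the JSON sidecar; pixel values return exact to $2^{-32}$ of
  full scale, far below detector quantization.
* Missing time points within a trace are dropped pairwise, never
  interpolated.
* Near-zero SSR values in the grid search (below $10^{-12}\,\Sigma y^2$)
  are snapped to exactly zero so tie-breaking across $f$ is deterministic.
* Problem sizes in the validation suite (30 puncta on 160×160 px movies,
  40 nuclei on 256×256 px sessions, 100-trace fitter sweeps) were chosen as
  the smallest scenes that exercise every code path at realistic densities.

## Known limitations

* Tracking is greedy nearest-neighbour; it is validated for the slow,
  quasi-stationary motion of synaptic puncta and nuclear centroids, not for
  fast or crowded motion.
* The keypoint matcher is intensity-based and translation/gain invariant
  only; large rotations between sessions would require a rotation-invariant
  descriptor.
* `match_fov` scores are relative; absolute score thresholds should be
  calibrated per dataset.
* The fitter's minor-pool parameters are reported as found on the grid and
  inherit the identifiability caveat above.
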