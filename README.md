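# degtrace

Quantification and kinetics of acute, induced protein degradation in
fluorescence imaging. `degtrace` is built for auxin-inducible degron (AID2)
experiments on synaptic scaffold proteins: a mAID-tagged protein of interest
is degraded on addition of the inducer 5-Ph-IAA, and the evidence is a
fluorescence time course — synaptic puncta fading in culture movies, or
cytosolic signal fading across longitudinal in-vivo imaging sessions. The
package takes such data from pixels to time constants, and ships a seeded
synthetic-microscopy generator with ground truth so the whole chain is
testable without any raw data.

## What it computes

**Trace model.** After inducer addition at `t0`, fluorescence is modelled as
a two-pool exponential decay

    F(t) = A * [ f * exp(-(t - t0)/tau1) + (1 - f) * exp(-(t - t0)/tau2) ]

fitted by exhaustive grid search (tau on a log grid, 40 steps/decade over
0.1–1000 h; f in steps of 0.01; A fixed at the normalized reference value 1)
minimizing the sum of squared residuals. Results are reported under the
major/minor pool convention: the headline constant `tau_major` belongs to
the component holding the majority fraction.

**Culture pipeline** (`quantify_culture`): max projection over z →
multi-scale LoG punctum detection → greedy nearest-neighbour tracking with
formed/disappeared/merged/split classification → 9×9-pixel ROI means at
tracked positions → background subtraction from a fixed cell-free region →
normalization to the last pre-inducer time point → biexponential fit of the
population average. Also: initial rates (OLS over the first 5 post-inducer
points on absolute fluorescence), per-synapse Pearson correlations (pooled
and per neuron), per-synapse loss deltas and ratios across channels,
spectral unmixing, per-time-point punctum counts, Welch t and Wilcoxon
rank-sum group comparisons.

**In-vivo pipeline** (`quantify_invivo`): FOV selection by depth, keypoint
z-plane matching, nucleus detection (blur → Otsu → LoG), translation +
iterated local-affine registration and tracking, cytosolic quantification on
the 4–8 px ring around each nucleus normalized to the session-level nuclear
reference, inclusion filters (min 3 px pair distance, initial normalized
signal ≥ 0.3), and neuropil/background ratios for histology fields.

**Synthetic data** (`simulate_culture_movie`, `simulate_invivo_sessions`,
`simulate_decay_traces`, `simulate_histology_fov`): seeded, bit-reproducible
scenes with exact ground truth (positions, kinetics, transforms, masks).

## Worked example

Simulate a movie of 30 synapses whose tagged protein degrades with a 3.7 h
major time constant (90% pool) at baseline SNR 10, then recover the kinetics
from pixels alone:

```r
library(degtrace)

kin   <- kinetics_spec(amplitude = 100, f_major = 0.9, tau_major = 3.7,
                       tau_minor = 37, t_inducer = 0)
pos   <- random_positions(30, c(160, 160), min_sep = 12, seed = 11)
scene <- scene_spec(shape = c(160, 160), n_z = 1, positions = pos,
                    kinetics = kin, background = 10, gaussian_sd = 10,
                    seed = 11)
movie <- simulate_culture_movie(scene, times = c(-2, -1, 0:16))

q   <- quantify_culture(movie, min_separation_px = 6)
rec <- q$records; rec$id <- rec$punctum
nn  <- normalize_to_reference(rec, t_inducer = 0); nn$neuron <- 1L
pop <- population_average(nn)
fit_biexponential(pop$time, pop$mean, t_inducer = 0)
#> biexp_fit: tau_major = 3.98 h (94% pool), tau_minor = 125 h, SSR = 0.00522
```

The recovered `tau_major` of 3.98 h sits within 8% of the simulated 3.7 h;
the 94% pool estimate brackets the simulated 90%; the minor-pool constant is
reported but weakly identified (see the vignette). The same fitter applied
to a noiseless trace returns 3.76 h — the grid node nearest the truth.

A ready-made end-to-end run with output files (trace CSV, track CSV, counts
CSV, fit JSON, run manifest):

```r
res <- run_pipeline(list(mode = "simulate", seed = 11, out_dir = "out"))
res$fit$tau_major
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/degtrace.R` with subcommands `simulate`, `quantify-culture`,
`fit-kinetics`, `quantify-invivo` and `run`.

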