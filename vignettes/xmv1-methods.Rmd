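---
title: "xmv1 methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{xmv1 methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmv1)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter (with units and defaults),
what the synthetic-data generator emulates and what it does not, the
numerical choices, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The scientific setting

Mouse auditory cortex projects directly to primary visual cortex (V1). The
projection population is biased toward neurons that signal **loud sound
onsets** (as opposed to quiet onsets, offsets, or sustained "tonic"
responses). In V1 this input acts in a context-dependent way: sound alone
*suppresses* the population in darkness but *excites* it under dim
illumination, and when a sound coincides with a visual stimulus the visual
response can be boosted *supra-linearly*, most strongly for loud onsets. The
package implements the full measurement chain for these phenomena on
two-photon calcium imaging data, plus a minimal circuit model that
reproduces the qualitative signatures.

## 2. Calcium forward model and deconvolution

### Forward model (generator)

Firing rates are converted to fluorescence with a difference-of-exponentials
kernel

$$k(t) = e^{-t/\tau_d} - e^{-t/\tau_r},
\qquad \tau_d = 2\ \mathrm{s},\ \tau_r = 0.18\ \mathrm{s},$$

as `F = baseline · (1 + amp · (r ⊛ k)·dt) + noise`. The decay constant 2 s is
the GCaMP6s value used throughout; the rise constant is an implementation
choice (the indicator is only known to have a "relatively slow" rise): 0.18 s
gives the deconvolved-peak delay of roughly 70–150 ms that slow indicators
exhibit, and it is the single knob controlling that delay. With
$\tau_r = 0$ the kernel degenerates to a pure exponential and the
deconvolution below inverts the forward model exactly, which is the basis of
the round-trip acceptance test.

A shared slow contaminant (low-passed random walk, one per field of view) is
mixed in as `F ← F + 0.7·F_np`, with `F_np` returned alongside. Using the
*exact* coefficient 0.7 makes neuropil subtraction testable as an identity
rather than only in expectation.

### Preprocessing (analysis)

* `subtract_neuropil()`: $F_c = F - 0.7\,F_{np}$ (0.7 from the standard
  GCaMP6s calibration in mouse cortex; config-exposed).
* `estimate_baseline()`: per 5 s imaging block, $F_{c0}$ is the minimum of a
  Gaussian-filtered trace (σ = 1 s) over the 5 neighbouring blocks. The σ is
  not specified by the source protocol; 1 s is long enough to ignore single
  transients and short against the 25 s neighbourhood. Edge blocks use
  truncated neighbourhoods (an open question in the protocol; truncation is
  the least-surprising choice). Non-positive baselines flag the ROI for
  exclusion rather than producing infinities downstream.
* `dff()`: $f = (F_c - F_{c0})/F_{c0}$.
* `deconvolve()`: $r(t) = f'(t) + f(t)/\tau$ with τ = 2 s and the derivative
  as a **forward difference at one-frame lag** (~32 ms at 31.5 Hz, matching
  the stated ~30 ms derivative spacing). A centered difference would change
  the delay properties. Consequence: for an exponential-kernel signal,
  $\hat r(t) = r(t+1) + O(dt)$ — the estimate *leads* by exactly one frame.
  Tests and the acceptance round trip therefore compare at that matched lag.
  Negative values are retained by default (they carry genuine
  below-baseline suppression); clipping is an option, off by default.
* `smooth_traces()`: centered boxcar, 190 ms (6 frames at 31.5 Hz); the
  source protocol says only "sliding window filter", and a boxcar is the
  minimal reading. Edges use truncated windows.
* `epoch_and_average()`: per-trial pre-onset baseline (0 to 0.5 s before
  onset) and the blank-trial average profile are subtracted; stimuli with no
  valid trials are flagged missing, never zero-filled.

**Timebase.** Frames are acquired only during the 5 s stimulation blocks
(3 s inter-block gaps are not imaged), so traces are stored as contiguous
concatenated blocks, and block *k* starts at sample
$(k-1)\cdot\mathrm{round}(5\,f_s)+1$. The synthetic pupil track shares this
contiguous timebase so trial windows align across modalities.

## 3. The synthetic world

`make_synthetic_dataset()` draws a population over eight functional
archetypes (loud/quiet ON, mixed ON, loud OFF, quiet/loud tonic,
tonic + loud-OFF, non-responsive), with rate templates built from
alpha-function transients (peak 150 ms after their trigger) and
raised-cosine plateaus:

* the **down-ramp** starts loud: loud-ON cells respond at its onset;
* the **up-ramp** reaches its maximum at 2 s: loud-ON cells respond weakly
  near 2 s, quiet-ON cells at its onset;
* OFF cells respond after the 2 s stimulus ends; tonic cells hold a plateau
  during the half of the ramp in their preferred intensity range.

Defaults the source material does not state, chosen once as a realistic
regime and not revisited:

| parameter | default | units | rationale |
|---|---|---|---|
| `trial_gain_cv` | 0.3 | — | per-trial multiplicative gain variability typical of cortical sensory responses |
| `noise_sd` | 0.02 | ΔF/F per frame | shot noise of good somatic GCaMP6s recordings; the deconvolution derivative amplifies per-frame noise by ~frame rate, so this is the binding constraint |
| `drift_sd` | 0.01 | ΔF/F | slow multiplicative baseline drift |
| `amp` | 0.05 | ΔF/F per spike | peak single-trial responses of tens of percent ΔF/F |
| `stim_onset` | 0.5 | s into block | leaves exactly the 0.5 s pre-onset baseline window the averaging uses |
| `context_mod_hz` | 0 | Hz | the emulated projection neurons are context-independent; V1-like context modulation is available as an additive term |

With these defaults, trial-averaged profiles of same-type cells correlate at
roughly 0.7–0.8 while iid-noise cells sit near 0 — the regime in which the
0.4 homogeneity threshold separates signal from noise, as it must for the
thresholds to be meaningful at all. The generator does **not** emulate:
imaging motion, ROI segmentation errors, spike-to-calcium nonlinearity
(saturation), correlated (shared) noise between neighbouring cells, eyelid
occlusion, or sound-evoked pupil dilation. A green clustering test therefore
establishes correctness of the pipeline under its stated assumptions, not
robustness to those artefacts.

## 4. Eye tracking and trial filtering

The pupil is an axis-aligned ellipse with four parameters (center x/y,
radius, eccentricity) — the parameter count rules out an orientation angle.
The fit maximises (mean luminance outside − mean luminance inside) + λ ×
(mean outward normal gradient along the boundary), λ = 1 in normalised
luminance units, by Nelder–Mead from the supplied initialisation. The
inside/outside term is piecewise constant in the parameters (pixel
memberships change discretely), so the optimiser tolerance is kept at 1e-8 —
far below a pixel — rather than machine precision. Flat images return the
initialisation with a failure flag.

The saccade statistic is the maximal pairwise distance between pupil centers
during the 2 s of stimulation, computed literally (O(n²) over ~100 samples).
Conversion to visual angle uses arc length: 57.6 µm on a 1.65 mm-radius eye
is 2.0°, reproducing the published threshold exactly (at 2° the chord/arc
distinction is below 0.01 %). Dark-context trials are never filtered —
saccade-triggered V1 responses are a lit-context phenomenon — and trials
without tracking coverage in lit contexts are invalidated with reason
`"no_tracking"`.

## 5. Clustering

Ward linkage on Euclidean distances (`hclust(method = "ward.D2")`, the
correct Ward implementation for raw distances), cut at `n_over` clusters
(default 25 for V1-like data, 100 for auditory-cortex-like data — the
published procedure lowered the threshold "until clusters became redundant"
by eye; fixed defaults make the pipeline deterministic). Homogeneity is the
mean pairwise Pearson correlation of member profiles; the published wording
is ambiguous between pairwise correlations and correlations against the
cluster mean — pairwise is adopted; singletons are defined homogeneous (1)
and zero-variance profiles contribute 0 with a warning. Pruning pools
clusters at or below 0.4; re-aggregation rescues pooled cells correlating
above 0.4 with a kept centroid, *without* recomputing centroids — centroid
stability under re-aggregation is asserted as a test property (< 5 % RMS
movement on default synthetic data) instead of being assumed.

Cluster→archetype labelling: the published clusters were labelled by visual
inspection. Here each kept centroid is assigned the archetype whose
generator template (passed through the same smoothing) it correlates with
best. Since the templates are themselves defined purely by peak-timing and
stimulus-preference rules, this is a reproducible restatement of
"label by peak timing and stimulus preference".

Explained variance is `100·(1 − SS_res/SS_tot)` over clustered neurons, with
SS_tot about the grand mean profile; it is invariant to global rescaling and
equals 100 % for singleton clusters.

## 6. Statistics

* **Responder detection**: two-sided Wilcoxon rank-sum on per-trial windowed
  response scalars vs blank trials, α = 0.01. Tie-free data use an exact
  Mann–Whitney fast path (vectorised via `pwilcox`, verified against
  `stats::wilcox.test` in the tests); ties fall back to the normal
  approximation. The exact test is slightly conservative at n = 20 + 20
  (achievable level just under 1 %), which is inherent to rank tests, not a
  calibration error. Displayed responder fractions mask the first 1
  percentage point as potential false positives.
* **Partition bootstrap**: the observed per-cluster statistic is
  `fraction_A − fraction_B`; the null pools all labels and re-partitions them
  into groups of the original sizes (default 10,000 partitions).
* **Supra-linearity bootstrap**: pseudo-trials of the linear prediction are
  built by randomly pairing one visual and one auditory presentation
  (without replacement, up to the smaller trial count) and summing
  samplewise — this preserves the group mean exactly. The null shuffles the
  bimodal/prediction labels (the published count is 10⁶; tests use reduced
  counts, available via a parameter).
* **Sidedness**: the published description says only "percentile". Both
  bootstraps use two-sided doubled-tail p-values with add-one correction,
  `p = min(1, 2·min(#{null ≤ obs}+1, #{null ≥ obs}+1)/(B+1))`, which is
  valid (never anti-conservative) under exchangeability and is what the
  calibration acceptance tests verify.
* **Response windows**: defaults follow the published windows (0.2–0.5 s
  after onset for dark negative responses, 0.2–1.0 s for light positive
  responses); both are configuration values.

## 7. Fourier retinotopy

"Band-passing around 0.1 Hz" is realised as single-bin extraction at the
stimulus frequency: each pixel is least-squares fitted with
`a + b·t + A·sin(ωt) + B·cos(ωt)` jointly, so linear detrending cannot leak
into the stimulus bin (a sequential detrend-then-DFT introduces O(1/N) phase
bias, which would break the 1e-6 identity tests). Amplitude is
`sqrt(A²+B²)`; phase is reported in the sin convention. Sweep-direction
reversal flips the retinotopic phase but not the hemodynamic lag, so for
forward/reverse phases `φ±` the half-difference recovers the retinotopic
phase and the half-sum the delay. The half-angle ambiguity (φ vs φ+π) is
inherent; generator defaults keep |φ|, |δ| < π/2 where the combination is
unique. The V1 mask thresholds amplitude at a quantile (default 0.75) and
requires local phase smoothness (circular gradient < 0.5 rad/pixel against
above-threshold neighbours only, so the region boundary is not eroded); the
largest 4-connected component is returned, mirroring "the largest
retinotopic field". The published criterion was visual; both cutoffs are
config values.

## 8. The rate model

Two populations (I = putative L1 interneurons, E = L2/3 pyramidal cells),
synchronous update with one-step recurrence,

$$r_i(t) = f_i\!\big(b^i_{ctx} + g^i_{aud}\,s_{aud}(t) + g^i_{vis}\,s_{vis}(t)
+ \textstyle\sum_j g_{ji}\, r_j(t-1)\big),$$

with two-segment nonlinearities `f(x) = max(0, offset + k_lo·x)` below the
threshold θ, continuing with slope `k_hi` above it. The sub-threshold segment
is not constant zero: background inputs are stochastic, so the mean transfer
function rises below threshold. Inputs: the auditory drive is an
exponentially decaying transient (τ_a = 0.3 s, an implementation choice; the
source states the shapes only qualitatively) and the visual drive a plateau.
Simulations start at the no-stimulus fixed point, found by damped iteration
(η = 0.5, tolerance 1e-12, max 10⁴ iterations; non-convergence is an error).

All gains and thresholds are shipped in
`inst/extdata/rate_model_default.yaml` and are **chosen to reproduce the
qualitative signatures, not fitted** (the source gives no numeric values).
The mechanism requires an open parameter region, not a point: in the dark, I
sits at its threshold (`b_dark(I) = θ_I`), so sound recruits it at the high
gain and feed-forward inhibition dominates the direct drive to E
(`|g_IE|·k_hi,I·g_aud,I > g_aud,E` in the linearised sense); in the light, I
is pushed well below threshold (`b_light(I) = θ_I − 2`), its response stays
in the low-gain regime, and direct excitation wins. Boosting requires only
that the preferred visual drive put E at or above θ_E while the
non-preferred one keeps it below; then the same auditory input sums with
`k_hi` vs `k_lo`. Making every `f` affine (equal gains, offset large enough
that nothing clips) linearises the network and abolishes boosting exactly —
a structural, not numeric, property that the tests assert at 1e-10.

## 9. Known limitations

* The eyelid two-arc model, manual correction GUIs, motion registration,
  ROI segmentation, and spike sorting are out of scope by design.
* The rate model is a two-population caricature: no dynamics within the
  stimulus beyond the input shapes, no synaptic time constants, no
  dendritic biophysics (the plausible cellular substrate of the high-gain
  segment).
* The generator's archetype templates are noiseless idealisations; real
  response types overlap continuously. Recovery rates on synthetic data are
  upper bounds for real data.
* The per-neuron GLM-based boosting test from the original analysis is not
  implemented (its specification is incomplete); the shuffle bootstrap is
  the supported supra-linearity test.

## 10. Reproducibility

Every stochastic function takes a `seed`; a fixed seed reproduces datasets
bit-exactly. The pipeline writes a JSON manifest with config hash, per-file
md5 checksums, timings and captured warnings; deterministic stages reproduce
identical checksums for the same config and seed. The acceptance criteria
live in `tests/testthat/test-acceptance.R`; the acceptance report is
`scripts/acceptance.R`.
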