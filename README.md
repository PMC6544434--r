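# xmv1 — cross-modal auditory–visual analysis toolkit for mouse V1 imaging

`xmv1` is an R package for studying how sounds shape activity in mouse primary
visual cortex (V1). Auditory cortex sends direct axonal projections to V1 that
preferentially carry **loud sound onsets**; in V1 this input **suppresses**
activity in darkness, **excites** it under dim illumination, and
**supra-linearly boosts** responses to coincident visual stimuli. The package
re-implements the complete computational chain needed to quantify these
effects from two-photon calcium imaging — and ships a synthetic-data
generator with known ground truth so every stage is testable without any
experimental data.

It is aimed at systems neuroscientists analysing block-structured two-photon
recordings (ROI fluorescence + neuropil traces, trial tables, pupil videos,
intrinsic-imaging movies) and at methodologists who want a self-contained,
seeded reference implementation of the statistics involved.

## What it computes

**Preprocessing & deconvolution.** Neuropil correction
`F_c(t) = F(t) − 0.7 F_np(t)`; per-block baseline `F_c0` as the minimum of a
Gaussian-filtered trace over the 5 neighbouring 5 s imaging blocks;
`f(t) = (F_c − F_c0)/F_c0`; temporal deconvolution of the GCaMP6s decay

    r(t) = f′(t) + f(t)/τ,   τ = 2 s,

with the derivative at one-frame lag (~32 ms at 31.5 Hz), then a 190 ms
sliding-window average. Trial epochs are baseline- and blank-subtracted and
averaged over valid trials.

**Eye tracking & trial filtering.** Axis-aligned ellipse fit of the pupil
(4 parameters, luminance-contrast + boundary-gradient objective); the
per-trial saccade statistic max over instants t, t′ of
`‖(x_c, y_c)(t) − (x_c, y_c)(t′)‖` during the 2 s of stimulation; trials above
the mouse visual acuity of 2° (57.6 µm on a 1.65 mm-radius eye, arc length)
are discarded in lit contexts.

**Functional clustering.** Ward-linkage hierarchical clustering (Euclidean
metric) of concatenated response profiles, deliberately over-clustered (25
cuts for V1-like, 100 for auditory-cortex-like data); clusters with
homogeneity (mean pairwise Pearson correlation) ≤ 0.4 become a non-responsive
pool; pooled cells correlating > 0.4 with a kept centroid are re-aggregated.

**Statistics.** Wilcoxon rank-sum responder detection against blank trials at
α = 0.01 with the first 1 % of displayed fractions masked as chance; a
10,000-partition bootstrap for cluster-distribution differences between
populations; trial-resolved linear predictions (one visual + one auditory
presentation per pseudo-trial) and a label-shuffle bootstrap for
supra-linear bimodal responses.

**Fourier retinotopy.** Per-pixel phase/amplitude at the 0.1 Hz drifting-bar
frequency; opposite sweep directions combined so the retinotopic phase
(half-difference) separates from the hemodynamic delay (half-sum); V1 is the
largest connected region of amplitude-thresholded, phase-smooth pixels.

**Rate model.** A minimal threshold-linear network

    r_i(t) = f( b_context,i + g_aud,i s_aud(t) + g_vis,i s_vis(t) + Σ_j g_ji r_j(t−1) )

with two-segment nonlinearities `f`. An inhibitory population near threshold
in the dark (and pushed below it by light) reproduces the context-dependent
sign switch; a low/high-gain threshold in the excitatory population
reproduces preferred-stimulus bimodal boosting.

## Worked example

```r
library(xmv1)
ds     <- make_synthetic_dataset(n_neurons = 300, n_reps = 20, seed = 1)
pp     <- preprocess_traces(ds$traces)
trials <- filter_trials(ds$trials, ds$pupil)          # 2 degree acuity filter
rp     <- epoch_and_average(pp$r, trials, frame_rate = pp$frame_rate)
X      <- profiles_matrix(rp)
model  <- cluster_pipeline(X, n_over = 25)
model
#> ClusterModel: 16 clusters, 195/300 neurons clustered, total EV 67.6%
match_to_truth(model$labels, ds$truth_labels[pp$kept])$accuracy
#> [1] 1
types <- label_clusters(model, ds$templates, attr(X, "stimuli"))
round(type_fractions(model$labels, types), 3)
#>            loud_ON tonic_plus_loudOFF         loud_tonic           quiet_ON
#>              0.385              0.108              0.077              0.123
#>           ON_mixed           loud_OFF        quiet_tonic
#>              0.108              0.123              0.077
```

All 195 truly responsive cells are clustered (the 105 non-responsive cells
fall into the pool), every injected archetype is recovered, and the centroid
assignment explains 67.6 % of the profile variance. The loud-onset class
dominates the clustered population, as configured in the generator.

The rate model with its shipped default parameters:

```r
spec <- default_rate_model_spec()
round(c(context_experiment(spec)), 4)
#>    dark   light
#> -0.0744  0.0136
bimodal_experiment(spec)[, c("level", "boost")]
#>          level        boost
#> 1         none 5.587936e-11
#> 2 nonpreferred 5.587940e-11
#> 3    preferred 1.227720e-01
```

Sound alone suppresses the excitatory population in the dark and excites it
in the light; bimodal boosting is confined to the preferred visual stimulus
and exceeds the sound-alone response (0.123 vs 0.014).

## Command line

```sh
exec/xmv1 run --out runs/demo --seed 1     # synth → … → model, writes report.md
exec/xmv1 retinotopy --out runs/ret        # synthetic phase-mapping demo
exec/xmv1 help
```

Exit codes: 0 ok, 2 configuration error, 3 stage failure.

## Documentation

`vignettes/xmv1-methods.Rmd` describes the models and assumptions, every
tunable parameter with units and defaults, what the synthetic generator does
and does not emulate, numerical choices, and known limitations.
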