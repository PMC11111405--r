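# facegeom

Population-geometry analysis of how familiar faces are encoded by
face-selective neural populations, together with a synthetic spiking
generator that makes every estimator testable by parameter recovery.

## The problem

Neurons in anterior IT and perirhinal face patches encode unfamiliar faces
with a linear **axis code**: a cell's rate is a projection of the
stimulus' face-space coordinates onto a preferred direction,

    r = c · f + c0

where `f` holds shape/appearance features, `c` is the cell's preferred axis
and `c0` an offset. The scientific question is how *familiarity* modifies
this code. Two signatures are analysed:

* an **early orthogonal subspace shift** — shortly after stimulus onset the
  familiar-face response manifold is translated by a population vector
  orthogonal to the feature-coding subspace, making familiarity linearly
  decodable (and d′ along the centroid axis significant) without degrading
  feature decoding;
* a **long-latency axis rotation** — later in the response, familiar faces
  drive cells through rotated axes, so axes fit on familiar faces
  decorrelate from the unfamiliar reference (the UU-vs-UF comparison), a
  feature decoder trained on unfamiliar faces fails on familiar faces in
  that epoch, and the effect survives controls for gain changes, monotone
  output nonlinearities, feature-subset sensitivity changes, feature-matched
  stimulus subsets, and temporal-context reversals of mean rate.

The package is for computational/systems neuroscientists who want these
analyses as tested, reusable, pipeable R functions: everything takes a data
frame (or a light `response_tensor` container for cells × faces × trials ×
bins spike counts) and returns tibbles, with `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` displays.

## What's inside

| Stage | Functions |
|---|---|
| Synthetic experiments | `sim_config()`, `sample_face_space()`, `make_population()`, `simulate_responses()`, `make_context_experiment()`, `simulate_experiment()` |
| Spike handling | `bin_spikes()`, `window_response()`, `normalize_per_cell()`, text I/O (`write_simulation()`, `read_face_set()`, ...) |
| Axis model | `fit_axes()`, `fit_axis()`, `split_half_axis_consistency()`, `tuning_curve()` |
| Axis dynamics | `uu_uf_comparison()`, `time_resolved_axis_similarity()`, `contrast_control()`, `cross_context_axis_stability()`, `model_comparison()` |
| Population geometry | `decode_features()`, `reconstruct_features()`, `decode_familiarity()`, `centroid_distance_trace()`, `dprime_along_centroid()`, `dprime_trace()`, `rate_shift_distribution()`, `familiarity_axis_orthogonality()`, `rsa_matrix()`, `condition_contrast()` |
| Latencies | `response_latency()`, `divergence_latency()`, `latency_ms()` |
| Stimulus matching | `match_subsets()`, `matching_report()` |

## Worked example

Simulate the full phenomenon at the study scale (150 cells, 36 familiar +
1,000 unfamiliar faces, shift from 100 ms, 60° rotation from 200 ms) and
run the two headline analyses:

```r
library(facegeom)

cfg <- sim_config(seed = 1)
sim <- simulate_experiment(cfg)

uu_uf_comparison(sim$tensor, sim$faces, window = c(220, 300))
#> <axis_comparison> 148 cells, window [220, 300) ms: mean UU = 0.751,
#>   mean UF = 0.361, t = 28.57, p = 9.52e-17

tr <- time_resolved_axis_similarity(sim$tensor, sim$faces)
tr$latency_ms
#> [1] 220

dec <- decode_familiarity(sim$tensor, sim$faces)
latency_ms(dec); mean(dec$value[dec$time_ms >= 200])
#> [1] 110
#> [1] 1
```

Reading the numbers: in the long-latency window, axes fit on held-out
unfamiliar faces agree with the unfamiliar reference at the noise ceiling
(mean cosine 0.75) while axes fit on familiar faces are attenuated to 0.36
≈ 0.75 × cos 60° — recovering the generated rotation angle. The axis
divergence is first detected in the window ending at 220 ms (onset 200 ms),
while familiarity itself is decodable from 110 ms (shift onset 100 ms) with
perfect plateau accuracy — the two codes are temporally multiplexed.
`ggplot2::autoplot(tr$uf)` plots the similarity time course with its
latency marker.

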