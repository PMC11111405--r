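---
title: "Population geometry of familiar-face coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population geometry of familiar-face coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(facegeom)
```

## The scientific question

Face-selective neurons in anterior inferotemporal and perirhinal face
patches encode unfamiliar faces with a linear *axis code*: a cell's firing
rate is a projection of the stimulus' face-space coordinates onto a
preferred direction,

$$ r = \mathbf{c} \cdot \mathbf{f} + c_0, $$

where $\mathbf{f}$ collects shape and appearance features of the face,
$\mathbf{c}$ is the cell's preferred axis and $c_0$ an offset. `facegeom`
implements the population-geometry analyses that ask how *familiarity*
modifies this code, together with a synthetic spiking-population generator
that makes every estimator verifiable by parameter recovery. The analyses
target two signatures:

* an **early subspace shift** — from a short latency after stimulus onset,
  responses to familiar faces are translated by a population vector
  orthogonal to the feature-coding subspace, which makes familiarity
  linearly decodable without disturbing feature decoding;
* a **long-latency axis rotation** — from a later latency, familiar faces
  drive each cell through a rotated preferred axis, so axes estimated from
  familiar faces decorrelate from the unfamiliar reference axis, and a
  feature decoder trained on unfamiliar faces fails on familiar faces in
  that epoch only.

## The generative model

`sim_config()` + `make_population()` + `simulate_responses()` realize the
following model. Each of $n$ cells has a unit preferred axis $\mathbf{c}_i$
uniform on the sphere in $d$ dimensions ($d = 20$ by default: the top ten
shape plus top ten appearance coordinates of a 120-dimensional face space;
features are i.i.d. standard normal, i.e. treated as whitened coordinates —
the analyses depend only on second-order structure and the matching module
makes empirical distributions comparable anyway). Expected rates, in Hz:

* before `visual_onset_ms` (90 ms): `baseline_hz` (10 Hz);
* after onset: $c_0 + g_i (\mathbf{a}_i(t) \cdot \mathbf{f})$ with
  $c_0$ = `peak_hz` (50 Hz) and per-cell gain $g_i$ of
  `(peak_hz - baseline_hz)/3` Hz per feature-s.d., jittered ±20% across
  cells — this puts single-trial signal-to-noise in a regime where
  split-half axis reliability is ≈0.7–0.9, the regime the analyses are
  designed for;
* $\mathbf{a}_i(t)$ is $\mathbf{c}_i$ for unfamiliar faces always, and for
  familiar faces until `rotation_onset_ms` (200 ms); afterwards it is the
  rotated axis $\mathbf{c}_i'$, obtained by rotating $\mathbf{c}_i$ by
  `rotation_angle_deg` in the 2-plane spanned by $\mathbf{c}_i$ and a
  per-cell random orthogonal direction (one controllable angle per cell);
  simultaneously `familiar_gain` (< 1 models familiarity suppression)
  multiplies the whole evoked component of familiar responses — the gain
  must act on the offset as well as the axis drive, because the empirical
  phenomenon it models is a change in *mean* rate;
* from `shift_onset_ms` (100 ms) familiar faces additionally receive the
  population shift $s_i$. The stored shift vector is a unit direction times
  `shift_magnitude`; its physical scale is `shift_magnitude` times the
  population signal s.d. $\sigma_{pop} = \sqrt{\sum_i g_i^2}$ (both sides
  of the ratio are population-vector norms), so per-cell shift loadings are
  comparable to per-cell tuning range — individual cells then show
  significant positive and negative familiar-minus-unfamiliar rate
  differences, as the rate-shift analysis expects. The shift direction is
  orthogonalized (QR projection removal) against both the raw and the
  gain-weighted encoding columns, because linear decoders read the
  population through $\mathrm{diag}(g)\,C$; orthogonality to both spans is
  what guarantees zero leakage into feature decoding.
* expectation effects: `make_context_experiment()` composes a stimulus set
  at a stated familiar:unfamiliar ratio and multiplies the evoked response
  of the *minority* class by `context_gain_rare` (1.3), emulating stronger
  responses to unexpected stimuli.

Rates are rectified at 0 (physical rates are nonnegative; the mild
nonlinearity this induces is a useful stress test for axis recovery) and
spike counts per 10-ms bin are Poisson(rate × bin/1000); a Gaussian noise
model with matched (or fixed, including zero) variance supports exactness
tests. Epoch boundaries are sharp rather than ramped so that latency
recovery has an unambiguous ground truth. Time bins are half-open
$[t, t+\mathrm{bin})$ ms relative to stimulus onset. Everything is
deterministic given the config seed.

What the generator does *not* emulate: correlated trial-to-trial noise,
rate adaptation within a trial, non-Poisson dispersion, eye-movement
artefacts, and the true (non-whitened) covariance of empirical face
features. Passing parameter-recovery tests therefore demonstrates that the
estimators are correct under the stated model, not that real recordings
satisfy that model.

## Estimators and their numerical choices

**Axis fits** (`fit_axes()`, `fit_axis()`). Trial-averaged window rates are
regressed on features standardized *on the fitting set only* (stored and
re-applied to evaluation sets; no leakage). The solver is a closed-form
(optionally ridge-penalized) normal-equations solve, batched across cells;
the default relative ridge `1e-6` (scaled by `trace(X'X)/d`) only guards
conditioning — `ridge = 0` recovers OLS exactly and errors informatively on
rank-deficient designs. Axes are fit on raw windowed rates; baseline
subtraction only changes the intercept of a linear model, not the axis.

**Rolling windows and latencies.** All time-resolved statistics use
half-open windows labeled by their *trailing edge*: evidence reported at
time $t$ can only reflect divergence that had occurred by $t$. Center
labeling would date evidence up to half a window before the onset that
produced it, with the bias growing with statistical power. Mean-rate
latencies (`response_latency()`, `divergence_latency()`) use contiguous
10-ms windows and paired t-tests across cells (cells are the experimental
unit); axis and decoding traces use 50-ms windows stepped by 10 ms, wide
enough to fit 20-coefficient axes per window. A latency requires two
consecutive windows below the detection level (the run-length rule is a
declared choice; one window is fragile to single-window flukes and longer
runs delay detection).

**UU/UF comparison** (`uu_uf_comparison()`). Per cell, a reference axis is
fit on the unfamiliar pool minus a held-out subset, and compared against an
axis fit on (a) the held-out unfamiliar faces — the matched-$n$ noise
ceiling — and (b) an equal number of familiar faces. Held-out draws are
repeated (default 20) and averaged per cell. Two p-values are reported. The
across-cell paired t-test is the classical choice but is anticonservative
here: the familiar axis is fit on *one* fixed stimulus set, whose design
conditioning moves every cell's UF cosine coherently, and an across-cell
test counts that shared fluctuation as evidence (measured: ~15–20%
rejections at nominal 5% under a no-rotation generator). The headline
p-value is therefore a *set-level exchangeability test*: under the null the
familiar set is exchangeable with any same-size unfamiliar set, so its
population-mean cosine is referred to the distribution of held-out set
means. Because most of that distribution's spread is predictable from each
set's design conditioning $\tau = \mathrm{tr}((X'X)^{-1})$ (ill-conditioned
draws attenuate cosines; $R^2 \approx 0.65$), $\tau$ is regressed out and
the familiar set is evaluated at its own $\tau$ — a noise-ceiling
adjustment that roughly doubles power (measured null rejection ~5%;
rotation onsets recovered within 10–30 ms at 150 cells).

**Contrast and monotone-transform controls** (`contrast_control()`). A pure
gain change (e.g. low-contrast stimuli) or any monotone output transform
preserves the preferred axis but lowers the effective SNR of axes fit on
the affected set, attenuating cosines; a raw UU-vs-control comparison would
flag that attenuation as axis change at any realistic power. The control
therefore compares each cell's observed cosine against an SNR-matched
parametric null: control responses re-simulated under the no-rotation
hypothesis at the control set's fitted gain and residual noise, axes refit.
A monotone nonlinearity's lack-of-fit variance enters the fitted residual
and is absorbed by the null (the rank order of preferred stimuli is
preserved), while a true rotation drops the observed cosine below it.

**Alternative response models** (`model_comparison()`). Gain
($r = \alpha(\mathbf{c}\cdot\mathbf{f}) + \beta$), feature-subset
sensitivity decrease ($\mathbf{m} \in [0,1]^d$, bounded nonnegative lasso
via glmnet; the upper bound is what makes it a sensitivity *decrease* and
prevents the model from imitating rotations), monotone nonlinearity
(isotonic regression, the weakest monotone assumption), and a full axis
refit, each scored by 5-fold cross-validated variance explained on familiar
faces, selected by the one-standard-error rule in complexity order (guards
against overfitting the refit model).

**Decoders** (`fit_feature_decoder()`, `fit_familiarity_classifier()`,
`decode_familiarity()`, `decode_features()`). Feature decoding is ridge
regression from population activity to each feature. The familiarity
classifier is ridge regression onto ±1 labels in per-cell z-scored
population space with repeated majority-class subsampling (keeps chance at
0.5 for the 36 vs 1,000 imbalance); its default regularization is strong
(`ridge_rel = 1`), which keeps the weight vector close to the class
centroid axis — the interpretable object for the orthogonality analysis —
rather than the whitened discriminant. Cross-validation folds split by face
identity (no identity in both train and test), so above-chance accuracy
demonstrates identity-general familiarity decoding. The accuracy null band
comes from identity-level label permutations (99th percentile).

**Geometry** (`centroid_distance_trace()`, `dprime_along_centroid()`).
Population distances use per-cell z-scored trial-averaged rates by default
(prevents high-rate cells dominating; distances grow ~√n with population
size). The familiar-vs-unfamiliar centroid distance is accompanied by a
matched-size unfamiliar-subset control, and by the quadrature-debiased
excess $\sqrt{\max(d_{fam}^2 - d_{ctl}^2, 0)}$ — distances add in
quadrature with the centroid-estimation noise floor, so the plain
difference of the two curves underestimates an injected shift while the
excess recovers it. d′ uses a centroid axis estimated on a random half of
each class's faces and projections of the held-out half (an uncrossed axis
is optimistically biased), with label-shuffle nulls (seed-controlled).

**Stimulus matching** (`match_subsets()`). The objective is the sum over
features of the two-sample Kolmogorov–Smirnov statistic between the two
subsets plus an equal-weight KS term on their pairwise-distance
distributions ("matched in the distribution of each feature as well as in
the distribution of pairwise face distances"; the KS statistic and λ = 1
are declared choices — no statistic is prescribed by the phenomenon). The
discrete optimizer does greedy single-member swaps, accepted only when the
objective decreases (ties broken toward a smaller worst-feature KS, which
walks the plateaus created by the 1/k grid of the statistic), initialized
by greedy nearest-neighbour matching and helped by proposals that move pool
mass across the worst feature's largest ECDF gap. For reference, two
same-distribution samples of size 30 have an expected per-feature KS of
about 0.21, so the achieved worst-feature values of 0.17–0.20 are below
what genuinely identically distributed draws would show.

## Degenerate inputs and edge rules

Zero-variance cells are excluded per analysis (flagged, never silently
NaN-propagated); empty or out-of-span windows, rank-deficient designs with
`ridge = 0`, single-trial split-half requests, and undefined similarities
of zero vectors raise classed errors. Missing trials are carried as an
explicit mask and respected by every mean. When the feature-encoding span
exhausts the population space, the orthogonal shift is set to zero with a
warning rather than silently leaking into the feature subspace.

## Problem sizes used by the tests

Module tests run on 30–60 cell populations with 140–340 faces. The
acceptance suite uses the study conditions — 150 cells (200 for the
orthogonality analysis), 36 familiar + 1,000 unfamiliar faces, 6 trials per
stimulus — with rotation-sweep and contrast checks simulating only the
long-latency epoch they analyse, and the null-calibration study running 100
seeds at 30 cells. These sizes were chosen as the smallest at which the
estimators operate in the same SNR regime as the full design.

## Worked example

```{r example}
library(facegeom)

cfg <- sim_config(seed = 1)        # full phenomenon: shift + rotation + gain
sim <- simulate_experiment(cfg)

# axis rotation: UU vs UF in the long-latency epoch
cmp <- uu_uf_comparison(sim$tensor, sim$faces, window = c(220, 300))
glance(cmp)

# time course and latency of the axis divergence
tr <- time_resolved_axis_similarity(sim$tensor, sim$faces)
tr$latency_ms
ggplot2::autoplot(tr$uf)

# early familiarity decoding from the orthogonal shift
dec <- decode_familiarity(sim$tensor, sim$faces)
latency_ms(dec)
```

## Known limitations

The set-level UU/UF test needs a handful of held-out resamples for its
reference distribution (at least 4; defaults use 8–20) and its power at
small populations (<60 cells) delays latency detection by one to two
windows past the onset. The SNR-matched contrast null assumes additive
response noise around the axis prediction within the analysis window.
Euclidean centroid distances are population-size dependent and should only
be compared within a fixed cell set. The generator's sharp epoch boundaries
make recovered latencies cleaner than the ramped transitions real neurons
likely show.
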