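---
title: "Rating and predicting perceived visual complexity from 2AFC comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating and predicting perceived visual complexity from 2AFC comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Perceived visual complexity is a promising proxy for the perceptual load a
real-world image places on an observer. Direct Likert-style complexity
ratings are vulnerable to response bias and criterion drift, so a more
robust protocol asks observers a long series of two-alternative
forced-choice (2AFC) questions — "which of these two images is more
complex?" — and converts the pairwise outcomes into a one-dimensional
score per image. `complexr` implements that conversion, the balanced
comparison designs that feed it, predictors of the resulting scores from
image statistics, image parts and object annotations, and a synthetic
observer/image world so the whole chain can be validated with known
ground truth.

```{r, message = FALSE}
library(complexr)
```

## The rating model

Each item (image or image part) carries a Gaussian belief over its latent
complexity: a mean `mu` — the reported complexity score — and a standard
deviation `sigma` expressing the engine's remaining uncertainty. Every
judged comparison is treated as a two-player game won by the chosen item.
Performances are modelled as the latent scores plus Gaussian performance
noise of standard deviation `beta`, so the probability that the winner's
performance exceeded the loser's is `Phi((s_w - s_l) / (sqrt(2) beta))`.
Multiplying the prior by that win likelihood and moment-matching the
result gives the classical skill update: with
`c^2 = 2 beta^2 + sigma_w^2 + sigma_l^2` and standardized margin
`t = (mu_w - mu_l) / c`,

* `mu_w <- mu_w + (sigma_w^2 / c) v(t)` and
  `mu_l <- mu_l - (sigma_l^2 / c) v(t)`,
* each variance is multiplied by `1 - (sigma^2 / c^2) w(t)`,

where `v(t) = phi(t) / Phi(t)` and `w(t) = v(t)(v(t) + t)` are the mean
and variance corrections of a zero-truncated Gaussian. These are exact
posterior moments, which is what the test suite verifies against a dense
two-dimensional Gauss–Legendre quadrature of the unnormalized posterior.
Both moments are evaluated in log space (`dnorm(log = TRUE)`,
`pnorm(log.p = TRUE)`) so updates remain stable for margins as extreme as
`t = -30`, where the naive ratio underflows.

```{r}
update_pair(winner = c(25, 25 / 3), loser = c(25, 25 / 3),
            rating_config(tau = 0))
```

### Parameters

All defaults follow the standard parameterization of skill-rating
systems; the units are arbitrary "complexity units" fixed by the prior:

| parameter | default | meaning |
|---|---|---|
| `mu0` | 25 | prior mean; anchors the score scale |
| `sigma0` | 25/3 | prior sd; initial uncertainty per item |
| `beta` | `sigma0/2` | performance noise sd; smaller values make single upsets more informative |
| `tau` | `sigma0/100` | dynamics sd added (in variance) before each update; keeps beliefs from freezing |
| `epochs_max` | 10 | full passes over the comparison list |
| `epsilon_converge` | 0.01 | stop when the mean absolute per-item change of `mu` in an epoch falls below this |

The task forces a choice on every trial, so the draw probability is zero
and no draw branch exists.

### The epoch schedule

A pure online rating system consumes each comparison once. Because a
fixed dataset is being scored rather than a live tournament, the engine
replays the shuffled comparison list for several epochs until the mean
absolute `mu` change per item drops below `epsilon_converge`. Replaying
improves rank recovery (early comparisons are re-evaluated against
matured beliefs) at a known cost: repeated use of the same evidence
spreads the `mu` distribution beyond the spread a single pass would
give, so the score *scale* after convergence is wider than the latent
scale. Rank-based quantities (Spearman recovery, consistency) are
unaffected; anyone needing a single-pass scale can set `epochs_max = 1`.
The per-epoch trace is kept in the `epoch_trace` attribute of the
returned table so convergence can be inspected.

### Consistency

`consistency_score()` reports the fraction of judged comparisons whose
chosen item ended with the strictly higher `mu`; exact ties count 0.5,
which is the unbiased convention under exchangeability. Two cautions
apply. First, the statistic is computed in-sample: with few comparisons
per item the engine partially fits lucky streaks, so even coin-flipping
observers score above 0.5 at, say, 40 comparisons per item; the chance
level is approached as per-item counts grow, which is how the test suite
pins it. Second, its ceiling is set by observer noise, so it decreases
monotonically as the simulated observer gets noisier.

## The comparison design

`generate_design()` schedules trials with a randomized round-robin
(circle-method) tournament: one cycle visits every unordered pair exactly
once, organized into rounds that are near-perfect matchings. Item labels
and round order are freshly randomized each cycle. Consequences, by
construction rather than by chance: item participation counts never
differ by more than 2, observer loads never differ by more than 1, and a
pair can repeat only after all `C(n, 2)` pairs have been used. At the
scale of a large rating study (4000 items, 75,020 trials) each item takes
part in 37–38 comparisons.

## The synthetic world

The simulator exists so that every downstream stage has ground truth:

* **Latent scores** are drawn from a normal distribution with mean 25 and
  standard deviation 5.5, matching the empirical score distribution of
  large natural-scene rating studies.
* **Observers** are Thurstonian: each presented item evokes its latent
  score plus independent Gaussian noise (`noise_sd`), and the larger
  internal value is chosen, giving
  `P(choose A) = Phi((s_A - s_B) / (sqrt(2) noise_sd))`; the `sqrt(2)`
  reflects independent noise on each of the two representations. A
  `lapse_rate` mixes in uniformly random responses. The default
  `noise_sd = 2` against a latent spread of 5.5 was chosen once as a
  realistic perceptual noise level: it produces clearly imperfect but
  well-above-chance consistency, qualitatively matching human 2AFC
  complexity data. The noise level implied by any particular human
  consistency value cannot be separated from the latent spread, so both
  knobs stay exposed rather than being collapsed into one
  "human-equivalent" setting.
* **Procedural images** are textured mid-gray canvases with `n_shapes`
  random ellipses, rectangles and triangles coloured from a
  `palette_size`-colour palette, each tagged with a bounding box and a
  class label from the 20-name VOC vocabulary. Complexity drivers (shape
  count, palette size, texture noise) are therefore known exactly, and
  the feature battery responds to them in the expected directions (edge
  density and region counts grow with shape count, colour count with
  palette size, sub-band entropy with texture noise).

What the simulator does *not* emulate: natural image statistics (1/f
spectra, occlusion, lighting), semantic content, and inter-observer
differences (all simulated observers share one noise model, mirroring
the practice of not modelling individual observers). Passing tests on
this world therefore demonstrate that the machinery is correct and
well-calibrated, not that any particular feature predicts *human*
complexity judgements of photographs.

## The feature battery

`extract_features()` computes the classical scalar complexity/clutter
statistics per image; conventions that needed fixing are:

* **Grey-level co-occurrence** (contrast, correlation, energy,
  homogeneity): luminance `0.299 R + 0.587 G + 0.114 B` quantized to 8
  equal-width levels, offset (0, 1), symmetric and normalized. A constant
  image has undefined correlation; it is returned as 0 with a warning and
  flag.
* **Colour features** in CIELAB (sRGB, D65):
  `colourfulness = sqrt(sd_a^2 + sd_b^2) + 0.3 sqrt(mean_a^2 + mean_b^2)`;
  colour count = occupied 10-unit CIELAB cubes holding at least 0.01% of
  pixels; colour harmony scores hue concentration against rotated
  one/two-arc templates — a stand-in for proprietary harmony software,
  comparable only within this package.
* **Entropies**: Shannon entropy (base 2) of 256-bin histograms over
  `[0, 1]` for R, G, B, H, S, V and luminance, with `0 log 0 = 0`.
* **Clutter** (feature-congestion style): local CIELAB a/b covariance
  volume and band-pass luminance contrast pooled over a 3-level Gaussian
  pyramid; sub-band entropy from a 3-level Haar decomposition (the exact
  pooling of the original clutter model is not published, so this is a
  faithful-in-spirit reimplementation, not a numerical replica).
* **Edge density**: Canny with sigma 1 and hysteresis thresholds
  0.11/0.27 on the max-normalized gradient magnitude; the normalizer is
  floored at 0.25 so a near-flat image does not have its noise amplified
  into edges.
* **JPEG ratio**: 3 bytes/pixel divided by the JPEG size at quality 75.
* **Frequency factor**: radial frequency below which 99% of FFT power
  (DC included) lies, over the Nyquist frequency (0.5 cycles/pixel along
  the shorter axis). Broadband images only reach 99% beyond the Nyquist
  circle (the spectrum support is square), so the value is capped at 1.
* **Counts**: the reference backend provides difference-of-Gaussians
  scale-space extrema (SIFT-like), determinant-of-Hessian blobs
  (SURF-like), stable-threshold connected regions (MSER-like) and
  mean-shift modes on a downscaled CIELAB raster. These are deliberately
  simple, deterministic counters; counts from dedicated detector
  software can be substituted through the external backend, and features
  that require trained deep models or human data (detector object
  counts, salience statistics, search reaction times) enter only as
  external CSV columns, never silently as zeros.

## Prediction models

`fit_feature_models()` runs linear, lasso, ridge, SVR or a small ReLU
network under leave-one-out, 10-fold, or image-grouped cross-validation.
Inputs are standardized to zero mean and unit variance with training-fold
statistics only; ratings are never rescaled. Reported correlations are
computed on pooled out-of-fold predictions, and a shuffled-ratings check
in the test suite confirms the pipeline cannot leak validation
information. Choices the literature leaves open, fixed here once:

* lasso/ridge strength is picked by inner 5-fold CV over 10 log-spaced
  values from 1e-15 to 20;
* SVR uses an RBF kernel with `C = 1`, `epsilon = 0.1`;
* the network is `{128, 64, 32, 1}` with ReLU hidden units, linear
  output, Adam, up to 200 epochs with early stopping on an inner 10%
  split (no installed package provides a multi-layer perceptron, so a
  minimal one is implemented in-package);
* pixel-level regression resizes images to a common 64 x 64 raster by
  default and ridge-stabilizes the fit, since the pixel dimension
  usually exceeds the sample size. In that overparameterized regime a
  linear-functional target is recovered only approximately; with more
  images than raster pixels recovery is essentially exact, which is the
  regime the test uses.

`descriptor_vectors()` controls for keypoint count by resampling exactly
500 keypoints per image with replacement, giving fixed-length vectors
(500 x 128 = 64,000 or 500 x 64 = 32,000).

## Image parts

`decompose_discs()` covers an image with overlapping discs of radius 50
px whose centers form a square grid from `r` to `dim - r` at stride
`round(1.2 r) = 60` (overlap is guaranteed since the stride is below the
diameter). The grid pitch was chosen so photo-typical frames (shorter
side 350–500 px, longer side 500 px) break into 30–50 discs — a 375 x 500
frame gives exactly 5 x 7 = 35. Pixels outside a disc are set to
mid-gray 0.5 so feature extraction on disc rasters is well-defined;
whether the original study masked, cropped or blended disc borders is
not recorded, and mid-gray masking is this package's choice.

Disc ratings come from the same engine as whole images. `complexity_map()`
interpolates the rating means from the center grid to a per-pixel surface
with Catmull–Rom bicubic interpolation (which passes through the node
values exactly); with fewer than 4 centers per axis it falls back to
bilinear with a warning, and pixels beyond the outermost centers take the
boundary value. `part_whole_predictors()` aggregates member-disc means
into the mean-rating and summed-rating predictors of whole-image
complexity; sums confound disc count, so they are flagged as
non-comparable unless all images share one disc count (the reason the
original analysis restricted sums to same-size images).
`grouped_split()` holds out a fraction of *images*, not discs, so a model
can never exploit same-image disc similarity across the split.

## Object tags

Bounding-box annotations (VOC XML or JSON; converted to 0-based,
half-open coordinates) drive the tag-only predictors. The image's
*central object* is the tag with the largest box area (ties to file
order). For each class, `class_complexity_table()` reports the mean
rating of images containing it anywhere, as central object, and in the
background — with "background" defined as *present but not central*, so
the two cells partition the anywhere set and the anywhere mean is exactly
their image-weighted mean. `predict_from_tags()` exposes the biggest-
object, summed/mean class-complexity, background-only and tag-count
predictors; classes unseen in training fall back to the global mean
rating so predictions stay total. The summed/mean predictors use the
anywhere means by default (`use_central_means = TRUE` switches), since
the class table's first-computed cell is the natural choice and the
alternative is a flag away.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to what
the method needs rather than to any hardware: the rating engine is
exercised at the full study scale (4000 items, 75,020 comparisons, 62
observers), parameter recovery at 200 items x 40 comparisons/item over 5
seeds, the disc study at 100 photo-typical frames (~3,700 discs, ~26
simulated comparisons each), and feature/model checks on procedural
images of 32–96 px where the relevant identities are exact. Convergence
and tie-break rules worth knowing: per-epoch shuffling is seeded
(`shuffle_seed`), `w(t)` is clamped to `[0, 1]` against rounding at
extreme margins, central-object ties break by file order, and equal-`mu`
consistency contributions are 0.5.

## Known limitations

* Scores are relative to the comparison set; `mu` values from different
  runs or datasets are not on a common scale (and the epoch replay
  widens the scale relative to a single pass).
* The feature battery aims at the classical definitions, not bit-exact
  parity with the original MATLAB/EDISON implementations; colour
  harmony, the clutter pooling and the reference counters are documented
  stand-ins.
* Correlations between features and *human* complexity ratings cannot be
  reproduced without the original behavioural data; the synthetic world
  validates machinery and directions of effect only.
* Per-observer skill or bias is not modelled, matching the original
  protocol.
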