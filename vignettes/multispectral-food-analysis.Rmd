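---
title: "Multispectral food analysis with calospec: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral food analysis with calospec: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ordinary RGB food photography fails on foods that look alike but differ in
composition: sugared versus sugar-free drinks, tofu versus milk pudding,
coffee with and without sugar. Water, sugar and fat absorb near-infrared
(NIR) light very differently from visible light, so images captured under
narrow-band NIR (and UV) LEDs carry composition information that the
visible bands do not. `calospec` implements a complete analysis pipeline
for such multispectral food images: feasibility statistics that quantify
how much the non-visible bands add, a compact convolutional network that
classifies food items and regresses their caloric content, and a
wrapper-style search for the most informative subset of wavelengths.

The channel set is 19 narrow-band center wavelengths — 385, 405 (UV); 430,
470, 490, 510, 560, 590, 625, 645, 660 (VIS); 810, 850, 870, 890, 910,
950, 970, 1020 nm (NIR) — plus one white shot from which the three RGB
planes are split. A white LED spans roughly 430–640 nm; we nevertheless
count 645 and 660 nm as visible, because the analysis of selection rates
is defined over a 9-wavelength VIS band and an 8-wavelength NIR band, and
that counting must be consistent across modules. An RGB shot is one
captured image but three input channels; all reporting curves index by
captured images.

## Feasibility statistics

Let $p(y \mid I, \lambda)$ be the distribution of brightness values $y$
inside the food mask of image $I$ captured at wavelength $\lambda$
(histograms use $B = 256$ equal-width bins over the 16-bit range by
default; both images of a pair always share a binning). Differences
between two items $m, n$ at one wavelength are measured by the
Bhattacharyya distance

$$D_B(I_n, I_m \mid \lambda) = -\log \sum_y \sqrt{p(y \mid I_n, \lambda)\, p(y \mid I_m, \lambda)}.$$

We use the natural logarithm, the common convention; the distance is 0
exactly for bin-wise identical histograms and unbounded as supports
separate, with `Inf` returned for disjoint supports. A bounded variant,
one minus the Bhattacharyya coefficient (in $[0,1]$), is available via
`clamp = TRUE` for users who want a normalized score.

Each band's representative distance for a pair is the maximum over the
band's wavelengths: $D_B^{(V)}$ over the nine VIS channels and
$D_B^{(NV)}$ over the UV and NIR channels together. The headline
feasibility statistic is the fraction of visually similar pairs that the
non-visible bands separate,

$$F_C(T_V, T_{NV}) = \frac{\bigl|\{(m,n): D_B^{(V)} < T_V \text{ and } D_B^{(NV)} > T_{NV}\}\bigr|}{\bigl|\{(m,n): D_B^{(V)} < T_V\}\bigr|},$$

reported over grids of both thresholds. An empty denominator (no pair is
visually similar at $T_V$) makes the ratio undefined; grid cells report
`NA` and the scalar function raises an error rather than returning zero.

For caloric feasibility, the absolute relative caloric difference
$D_C(n,m) = |c_n - c_m| / (c_n + c_m)$ is correlated (Pearson) with
$D_B(\cdot \mid \lambda)$ across item pairs, one correlation per
wavelength. Items with missing calorie values, and pairs where both
calories are zero, are excluded. Visible and non-visible band means of
these correlations are compared by a two-sample t-test on Fisher-z
transformed values — the classical comparison for correlation
coefficients; the test choice is recorded in the output metadata, and the
degenerate constant-sample limit returns p = 1 (equal means) or 0.

Two conventions are deliberate choices where the procedure could be read
several ways. First, an item's representative histogram pools the in-mask
pixels of all its views at one wavelength, which makes the statistic a
property of the item rather than of a single view. Second, pairs range
over unordered distinct items.

## The network

Both tasks share one architecture: conv 11×11 → ReLU → maxpool 4×4 →
conv 7×7 → ReLU → maxpool 4×4 → flatten → FC(112) → ReLU → FC(128) → ReLU
→ output. Inputs are 64×64, the size that performed best in the study
this pipeline operationalizes; the full frame is resized by bilinear
interpolation with no cropping (a 640×480 frame maps to 64×64 without
preserving aspect ratio). The spatial trace is 64 → 54 → 13 → 7 → 1; any
configuration that collapses a dimension below 1 fails at build time. The
output is a soft-max over the food classes (cross-entropy loss) or a
single linear unit (mean absolute percentage error, MAPE). Zero calorie
labels are replaced by 5 kcal before training: a printed zero in a
nutrition table means "below the labelling minimum", and the percentage
error is undefined at zero truth.

Several training details are not dictated by the architecture and were
fixed as follows:

* **Filter counts** (never part of the published architecture) default to
  16 and 32 and scale down to 8/16 in the desk-scale configurations used
  by the tests; they are plain configuration fields.
* **Optimizer**: Adam, learning rate $10^{-3}$, mini-batches of 32,
  He-style initialisation, all seeded; the same seed, data and
  configuration reproduce a loss trace bit for bit.
* **Epochs** default to 1000. The package's own tests and scripts use
  30 (classification) to 100 (regression) epochs on small synthetic sets;
  these are the points where the validation loss stops moving on those
  sets, and they are stated wherever used.
* **Target standardization (regression)**: Adam's parameter steps are of
  order the learning rate, so a linear output cannot traverse a label
  scale of hundreds of kcal in a short run. The network therefore
  regresses the standardized label internally and maps predictions back
  through the training mean and standard deviation; the loss is always
  computed in kcal. This changes no reported quantity, only conditioning.
* The published node count "18" for the output layer conflicts with the
  101-class / single-output heads; it is treated as a typo and the output
  size always equals the number of targets.

## Piecewise wavelength selection

The wrapper search scores a candidate wavelength set by assembling inputs
restricted to that set, training the task's CNN, and taking its final
validation loss (cross-entropy or MAPE). "Final loss" could mean training
loss, but selecting on training loss rewards overfitting, so validation
loss is used; both are logged. Each iteration performs forward selection
(add the argmin-loss wavelength), backward elimination (remove the member
whose removal minimizes loss), and a final forward selection in which the
just-removed wavelength may return. Iterations continue until the working
set is the full set; the best set at each cardinality is recorded and the
global optimum is the minimum-loss end-of-iteration set (intermediate
forward/backward sets do not compete).

Determinism and comparability required three choices the procedure leaves
open. Ties break to RGB first, then the smallest center wavelength.
Every candidate set trains with a seed derived from the global seed and
the set's canonical key, so a set's loss is a pure function of the set
and is memoized; the trace records every evaluation, cached or not, for
audit. In RGB mode the working set is seeded with RGB, which is never
removable — consistent with per-cardinality result tables in which every
row contains RGB. When the forward step leaves only one removable member
(the first iteration), backward elimination would have to score an empty,
untrainable set; steps two and three are skipped for that iteration.

## The synthetic data generator

The authors' acquisition dataset is available only on request, so the
generator produces datasets with the statistical structure the analysis
relies on, and every stage is validated against that planted structure:

* one item per class, rendered as an analytic silhouette (disk, square,
  annulus or blob) whose texture is a band-limited sum of oriented
  sinusoids in object coordinates — rotating the view rotates the content
  exactly, emulating acquisition from many angles;
* per-shot multiplicative illumination jitter (log-normal, σ = 0.05) and
  additive Gaussian sensor noise (σ = 1% of full scale), clipped to the
  16-bit range; in-mask intensity is reflectance × jitter × 60 000 ×
  texture, leaving headroom below 65 535 so clipping is rare;
* confusable class pairs that are *exact copies* in UV, VIS and RGB and
  differ only at one designated NIR channel by exactly `nir_delta`
  (default 0.3 at 890 nm). Pair members share silhouette, texture and
  weight (visually identical items served as the same amount in the same
  container) and differ in sugar fraction by 0.10 — the scale of a
  sugared versus plain drink — so their calories differ while nothing
  visible does;
* calorie labels via an Atwater-style rule,
  kcal = weight × (4·sugar + 9·fat). Serving weights are drawn
  anti-correlated with caloric density — dense snacks are served light,
  watery foods heavy — matching the structure of the packaged food table,
  where weight and kcal/g correlate at −0.76;
* NIR reflectance encoding caloric density (watery foods absorb NIR,
  dry/dense foods reflect it, plus small per-wavelength noise), so
  caloric differences correlate with NIR image differences; the coupling
  can be disabled for null simulations;
* a view-based train/validation split (every fourth view held out),
  mirroring a 75/25 proportion of views of *seen* classes — validation
  images are unseen views, not unseen foods, as in the original
  evaluation protocol.

Defaults are desk-scale: 6 classes, 8 views, 96×96 frames, two confusable
pairs. Images default to 96×96 rather than the rig's 640×480 because the
network input is 64×64 and the masked-histogram statistics are resolution
independent; nothing in the pipeline assumes a particular frame size.

What the generator does **not** emulate: photorealistic food appearance,
real reflectance spectra, specular highlights, shadows, camera vignetting
or inter-camera variation (a single synthetic camera; the view axis
stands in for the four-camera rig). Passing the planted-recovery tests
therefore shows that the pipeline extracts NIR contrast that visible
channels lack; it does not certify accuracy numbers on real acquisitions.

## Intensity normalization

Shot-to-shot LED intensity drift is compensated by scaling a shot so its
mean matches a per-wavelength reference, $\alpha = \mu_{\text{shot}} /
\mu_{\text{ref}}$, pixels divided by $\alpha$ (the only direction under
which the shot mean approximates the reference). The operation is exactly
idempotent away from clipping. The reference is the mean of per-shot
means over many shots.

One consequence deserves emphasis: applied per *food* shot, this
normalization forces every shot's mean to the wavelength reference and
thereby erases the between-class mean-reflectance contrast — exactly the
signal a planted NIR channel carries (two pixel-identical silhouettes
that differ only in mean brightness become identical after both are
rescaled to the same mean). The procedure is designed for *light-source*
monitoring images, which the synthetic rig does not produce. The CNN
assembly therefore defaults to `normalize = FALSE`; the operation remains
available, config-switchable, and tested for its own invariants
(idempotence, drift removal on repeated shots of one scene).

## Numerical and degenerate-input conventions

* Histogram bins: 256 equal-width bins over [0, 65535]; binning mismatch
  between a pair is an error, never silently rebinned.
* Pairwise distance tables smooth histograms with a Jeffreys half count
  per bin by default: at desk-scale pixel counts two narrow in-mask
  distributions can occupy disjoint bins, and an infinite distance would
  make the per-wavelength Pearson correlations undefined. The smoothing
  leaves near-identical pairs at distance ~0 and maps "complete mismatch"
  to a large finite value. `smooth = 0` restores the raw statistic.
* `N/a` calories are missing values, excluded from summaries — distinct
  from printed zeros, which are true labels replaced only in the loss.
* Summary standard deviations use sample (n−1) normalization.
* Bilinear interpolation for resizing (via EBImage); constant images stay
  constant, smooth gradients stay monotone.
* Empty masks, zero-mean shots, zero-variance correlation inputs, empty
  F_C denominators, unreplaced zero truths in MAPE, and empty training
  splits are all errors, not silent coercions.
* Pooling windows that do not tile the activation exactly drop the
  trailing rows/columns (floor division), as is conventional.

## Scale of the packaged experiments

The tests and the acceptance script run the full pipeline at desk scale:
6 classes × 8 views, 64×64 network inputs, 8/16 convolution filters,
20–100 epochs, and wavelength subsets of up to 5 labels for selection
runs. At this scale the complete suite — including two classification
runs, two regression runs and five seeded selection replicates — executes
in minutes on one CPU. The same code paths scale to the full 20-channel
problem; a full-set selection run is supported but long-running, since
each candidate set trains a fresh network.

## Known limitations

* The piecewise search carries no global-optimality guarantee; its value
  is auditability (every evaluation is recorded) and cost, not
  exhaustiveness.
* Validation loss on small synthetic sets is noisy; selection decisions
  between near-equivalent wavelengths can change with the seed. The
  recovery guarantees the package tests are therefore majority-vote
  properties across seeds, not per-seed certainties.
* MAPE is asymmetric and explodes for small truths; with drink-like
  low-calorie items in the data, absolute MAPE values are large even when
  ranking behaviour is correct. Comparisons between wavelength sets use
  ratios on a fixed dataset for that reason.
* The CNN is implemented in R with im2col/BLAS matrix products. It is
  adequate for desk-scale experiments and exactly reproducible, but it is
  not a GPU training stack and is not intended for datasets of tens of
  thousands of images.
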