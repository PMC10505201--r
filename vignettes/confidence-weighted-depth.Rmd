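---
title: "Confidence-weighted scale- and shift-invariant depth supervision"
author: "cwdepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted scale- and shift-invariant depth supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwdepth)
```

## The problem

Monocular depth estimators for surgical endoscopy cannot be trained on
human-annotated depth: dense ground truth is essentially unobtainable in a
deforming, bleeding, smoke-filled operative field. A practical substitute
is *self-supervision from stereo*: a stereo matcher run on the rectified
endoscopic stereo pair produces a disparity map (proportional to inverse
depth) plus a per-pixel confidence map $q \in [0, 1]$. The supervisory
signal is dense but systematically corrupted — the left-border occlusion
band carries no disparity at all (confidence 0), and droplets, smoke and
specular highlights produce confidently wrong or low-confidence gross
outliers.

`cwdepth` implements the training objective and evaluation protocol for
this setting: a *confidence-weighted scale- and shift-invariant* (CW-SSI)
loss, robust affine alignment in inverse-depth space, the standard
scale-free depth metrics, a seeded generator of synthetic supervision with
exactly this corruption structure, and a desk-scale trainer that
demonstrates the value of confidence weighting end to end.

## The model

Monocular predictions $d$ live in inverse-depth space and are defined only
up to an affine transform. Per image, with $M$ valid pixels, the scale and
shift are first fitted by least squares,

$$(s, t) = \arg\min_{s,t} \sum_{i=1}^{M} (s\,d_i + t - d^*_i)^2,
\qquad \hat d_i = s\,d_i + t,$$

and the data term weights the squared aligned residual by a function of
the supervisory confidence:

$$L_{\mathrm{data}} = \frac{1}{2M} \sum_{i=1}^{M} w(q_i)\,
  \lVert \hat d_i - \hat d^*_i \rVert^2 .$$

Two weight functions are provided besides the uniform $w \equiv 1$:

* **Hard mask** — $w(q) = 1$ for $q \ge \theta$, else $0$: sub-threshold
  pixels are discarded, the rest count equally.
* **Soft mask** — $w(q) = e^{\lambda (q - 1)}$ for $q \ge \theta$, else
  $0$: kept pixels are graded, approaching weight 1 as $q \to 1$.

A multi-scale gradient-matching term sharpens discontinuities: with
$R^k = \hat d - \hat d^*$ the residual at pyramid level $k$ (resolution
halved per level, $K$ levels),

$$L_{\mathrm{grad}} = \frac{1}{M} \sum_{k=1}^{K} \sum_i w(q_i)
  \left( |\nabla_x R^k_i| + |\nabla_y R^k_i| \right),$$

and the per-image total is $L_{\mathrm{data}} + \alpha\,L_{\mathrm{grad}}$,
averaged over the training set.

### Defaults and units

| parameter | default | meaning |
|---|---|---|
| $\theta$ | 0.5 | confidence cut-off (dimensionless, in $[0,1]$) |
| $\lambda$ | 10 | soft-mask sharpness (dimensionless rate) |
| $\alpha$ | 0.5 | weight of the gradient term |
| $K$ | 4 | pyramid levels (halving per level) |
| $c$ | 4.685 | biweight tuning constant (in residual-scale units) |

$\theta = 0.5$ and $\lambda = 10$ are the grid-searched operating point for
stereo-transformer confidence maps on endoscopic data; $c = 4.685$ is the
classic constant giving the Tukey biweight about 95% asymptotic efficiency
under Gaussian errors.

## Design choices in the loss

Several points are open when turning the printed equations into code; the
package resolves them as follows.

**Alignment support.** The least-squares alignment inside the loss runs
over the pixels that are valid *and* carry positive confidence weight.
With the uniform mask this is exactly the plain valid-pixel alignment; for
hard and soft masks it makes the loss *exactly* independent of values at
sub-threshold pixels, which is the property the masks exist to provide — a
gross outlier at a masked-out pixel must not leak into the objective
through the fitted $(s, t)$. The exported `alignLSQ` keeps the plain
masked, unweighted contract.

**The denominator $M$.** Both terms divide by the number of *valid*
pixels, not the number of positively weighted ones: masked-out pixels
contribute zero to the numerator but stay in $M$. $M$ is defined once,
before weights enter. The gradient term applies this single
full-resolution $M$ at every level, as the per-level populations shrink
geometrically anyway.

**Pyramid construction.** Downsampling is 2×2 average pooling with
dimensions rounded up; edge blocks average the cells present. Pixels that
carry loss ("active": valid with $w > 0$) drive the gradient term; a
pooled pixel is active only when all its children are, residual pooling
averages active children only, and weight grids pool by plain block
averages. Forward differences contribute only when both participating
pixels are active, and carry the mean of the two pixels' pooled weights —
anchoring the weight at the left/top pixel alone would make the term
asymmetric under image flips, which would silently break flip
augmentation. Consequently values at inactive pixels can never reach the
gradient term at any level.

**Degenerate images.** The fitted scale can come out non-positive on
adversarial inputs although a monocular prediction should relate to its
supervision with positive scale. Such images — like all-masked ones —
contribute zero loss with a structured warning, and still count in the
batch mean so averaging stays well defined.

**Soft/hard equivalence.** $e^{0} = 1$, so a soft mask with $\lambda = 0$
reproduces the hard mask bit for bit; this doubles as a regression check.

## Robust evaluation protocol

Evaluation aligns prediction to ground truth per image in inverse-depth
space by IRLS with Tukey biweight weights
$w(u) = (1 - (u/c)^2)^2 \cdot \mathbf{1}[|u| < c]$, then converts both to
depth by reciprocal and reports the mean absolute relative error and the
threshold accuracies $\delta < 1.25, 1.25^2, 1.25^3$ (strict inequality on
the larger of the two depth ratios). Choices the protocol leaves open:

* **Residual scale inside IRLS**: MAD of the current residuals about zero,
  divided by 0.6745, recomputed each iteration; if the MAD collapses to
  zero (a majority of exact zeros) the mean absolute residual substitutes.
  Zero-centred MAD is the standard companion of redescending weights —
  centring at the median collapses under strongly asymmetric
  contamination.
* **Initialisation and stopping**: the closed-form least-squares fit;
  stop when the relative change of $(s, t)$ drops below $10^{-8}$ or at 50
  iterations.
* **Metric space**: alignment happens in inverse depth, the error metrics
  in depth after reciprocal conversion (pixels whose aligned inverse depth
  falls below $10^{-8}$ are dropped and reported). Computing the metrics
  directly in disparity space is exposed via `space = "disparity"`.
* **Aggregation** across images is the unweighted mean of per-image
  metrics, matching the per-image alignment.

The claimed ~95% Gaussian efficiency of the biweight at $c = 4.685$ is
reproduced by simulation (`simulateBiweightEfficiency`): 2000 replicates
of simple linear regression at $n = 2000$, comparing slope variances
against OLS. Note that the 95% figure is asymptotic; finite-sample
variance ratios at this design run one to two points higher (an
established robust-regression implementation, `MASS::rlm`, shows the same
behaviour on identical draws, which the test suite exploits as a
cross-check).

## What the synthetic generator emulates

`generateTruth` draws a smooth low-order (default 2) random polynomial
inverse-depth surface rescaled into `invDepthRange` (default 0.5–2
arbitrary inverse-depth units, a plausible near-field working range).
`corruptTruth` then applies the three regimes observed in stereo
supervision of surgical scenes:

1. a left occlusion band (`occlusionBorderCols`, default 8) with
   confidence 0 and no disparity — the unmatched region of the rectified
   pair;
2. low-confidence blobs (default 5 disks of radius 3–8 px) whose disparity
   is replaced by gross errors of magnitude ~`outlierMagnitude` (default
   5, several times the signal range, with a per-blob random sign) and
   whose confidence is drawn from `confLowRange` (default 0.05–0.45,
   entirely below the $\theta = 0.5$ cut) — droplets, smoke,
   specularities;
3. everywhere else, Gaussian noise (`inlierNoiseSd`, default 0.02) and
   confidence from `confHighRange` (default 0.7–1).

Outliers are *tied to low confidence by construction*. That converts the
premise of confidence weighting into a testable property — the generated
confidence is informative, and the suite asserts it on every generated
dataset. What the generator does **not** emulate: photorealistic texture,
stereo matching itself, confidently-wrong outliers (high $q$, wrong
disparity), spatially correlated inlier noise, or deformation over time.
Passing tests therefore demonstrate the mechanics and robustness of the
objective, not performance on real endoscopy.

Default scene resolution mirrors common rectified endoscopic frames
(192 × 384); tests and the comparison experiment run at reduced desk-scale
sizes (e.g. 48 × 64, four frames, ~100 descent steps), which are stated
where used and keep every property checkable in minutes on one CPU.

## The desk-scale trainer

The predictor is a low-order 2-D polynomial surface over normalised pixel
coordinates — not a network. The claims under test (scale-shift
invariance, contamination immunity of weighted masks, soft ≥ hard ≥
uniform under corruption) are properties of the *objective* and hold for
any differentiable predictor; a parametric surface keeps the experiment
dependency-free and seconds-fast. All frames of a training set observe a
single underlying scene, as repeated stereo observations of it, which is
what makes a coordinate-parameterised predictor well posed. Integration
with a real dense predictor is a contract, not a deliverable: anything
that produces an `InverseDepthMap` per frame can be trained against
`batchLoss`.

Numerical choices:

* the monomial basis is QR-orthonormalised over the pixel grid — a pure
  reparameterisation of the same function space that keeps first-order
  descent well conditioned;
* coefficients warm-start at the confidence-weighted least-squares fit of
  the supervision on the basis (the data-term minimiser before alignment
  freedom), deterministically;
* optimisation is full-batch gradient descent with forward
  finite-difference gradients, normalised steps of length
  `stepSize * stepDecay^(step-1)` (defaults 0.5 and 0.95, the decay
  mirroring per-epoch attenuation), and up to 15 halvings of the trial
  step when a proposal fails to improve — so the best-so-far trajectory is
  non-increasing by construction;
* a proposal is also rejected if it pushes additional images onto the
  degenerate zero-loss branch; without this, an optimiser can "improve"
  the objective by anti-correlating with frames until their fitted scale
  flips sign;
* augmentation (50% horizontal/vertical flips applied consistently to
  supervision and prediction grid, plus Gaussian supervisory noise)
  defaults off: for this predictor consistent flips are loss-neutral, so
  augmentation adds variance, not coverage.

`runComparison` fits three predictors differing only in mask kind on the
same contaminated frames and scores each against the clean truth after
least-squares alignment (mean absolute inverse-depth error). Under the
default corruption the uniform arm absorbs the blob outliers while the
hard and soft arms ignore them; the experiment tests the *direction* of
the effect, not its magnitude on real data.

## File formats

Maps travel as grayscale PFM ("Pf", bottom-up rows normalised to a
top-left origin on read, scale sign carrying endianness) or 16-bit
grayscale PNG with a user-supplied scale factor, where the stored integer
0 is the invalid-pixel sentinel. In memory, invalid pixels are non-finite;
validity couples finite disparity with strictly positive confidence. PFM
round trips are bit-exact; PNG round trips are exact to the quantisation
step.

## Known limitations

* The generator's corruption magnitudes are free parameters chosen to
  make the uniform/weighted contrast visible, not calibrated to any real
  stereo matcher.
* No absolute-scale recovery: everything is up to (s, t), by design.
* The trainer's predictor has six coefficients at order 2 — capacity
  questions (overfitting, resolution effects) are out of its scope.
* Whether real evaluation pipelines compute the relative error in depth
  or disparity space varies; both are exposed, depth is the default.

## A minimal session

```{r, eval = FALSE}
scene <- SceneConfig(height = 48L, width = 64L, seed = 1L)
truth <- generateTruth(scene)
sup <- corruptTruth(truth, CorruptionConfig(seed = 101L))

cfg <- LossConfig(weight = WeightConfig("soft", threshold = 0.5,
                                        sharpness = 10))
fit <- fitPredictor(list(sup), TrainConfig(maxSteps = 100L, loss = cfg))
pred <- predictSurface(fit, 48L, 64L)
evaluatePair(pred, truth)

runComparison(scene, CorruptionConfig(seed = 101L),
              TrainConfig(maxSteps = 100L, loss = cfg), nImages = 4L)
```
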