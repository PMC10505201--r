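# cwdepth

Confidence-weighted scale- and shift-invariant losses for self-supervised
monocular depth estimation, with a robust evaluation protocol — built for
the setting where the supervisory signal is stereo disparity plus a
per-pixel confidence map, as in surgical endoscopy.

## Who this is for

Dense monocular depth models for endoscopic or laparoscopic scenes cannot
be trained on human-annotated depth; the practical supervisory signal is a
stereo matcher's disparity map (proportional to inverse depth) together
with its confidence map q ∈ [0, 1]. That signal is systematically
corrupted: an occlusion band at the left image border carries no disparity
at all (q = 0), and droplets, smoke and specular highlights create
low-confidence regions with gross disparity errors. `cwdepth` provides the
training objective that exploits the confidence instead of ignoring it,
plus the machinery around it: file I/O, alignment, metrics, a synthetic
supervision generator and a desk-scale trainer.

## The objective

Per image, with M valid pixels, the prediction d is first aligned to the
supervisory disparity d\* by least squares over the pixels that carry loss:

    (s, t) = argmin Σᵢ (s dᵢ + t − d*ᵢ)²,   d̂ᵢ = s dᵢ + t

Then the confidence-weighted data term and multi-scale gradient term are

    L_data = (1/2M) Σᵢ w(qᵢ) ‖d̂ᵢ − d̂*ᵢ‖²
    L_grad = (1/M) Σₖ Σᵢ w(qᵢ) (|∇ₓ Rᵢᵏ| + |∇ᵧ Rᵢᵏ|),   Rᵏ = d̂ − d̂*

with total L_data + α·L_grad (α = 0.5, K = 4 pyramid levels). The weight
w(q) is the **hard mask** (1 for q ≥ θ, else 0), the **soft mask**
(e^{λ(q−1)} for q ≥ θ, else 0; θ = 0.5, λ = 10) or uniform. Evaluation
aligns prediction to ground truth per image by IRLS with Tukey biweight
weights (c = 4.685, ≈95% Gaussian efficiency) in inverse-depth space, then
reports Abs. Rel. and δ < 1.25, 1.25², 1.25³ threshold accuracies in depth
space.

## Worked example

```r
library(cwdepth)

scene <- SceneConfig(height = 48L, width = 64L, seed = 1L)
truth <- generateTruth(scene)                      # clean inverse depth
sup   <- corruptTruth(truth, CorruptionConfig(seed = 101L))
sup
#> SupervisionFrame
#> InverseDepthMap: 48 x 64, 2688 finite, range [-4.531, 7.786]
#> ConfidenceMap: 48 x 64, mean 0.647, 384 zero-confidence px
#> ValidityMask: 48 x 64, 2688 / 3072 valid

# the supervision carries a zero-confidence occlusion band (384 px) and
# low-confidence blobs with gross outliers (range far beyond the true
# 0.5-2); train three predictors that differ only in the confidence mask:
rep <- runComparison(scene, CorruptionConfig(seed = 101L),
                     TrainConfig(maxSteps = 100L,
                                 loss = LossConfig(weight = WeightConfig("soft"))),
                     nImages = 4L)
rep
#> ExperimentReport (mean |aligned prediction - truth|, inverse depth)
#>   uniform  recovery error 0.18513 (final loss 2.2581)
#>   hard     recovery error 0.00063 (final loss 0.020639)
#>   soft     recovery error 0.00072 (final loss 0.0065348)
#>   win margin (uniform - soft): 0.18441
```

The uniform arm absorbs the blob outliers into its surface (recovery error
≈ 0.19 inverse-depth units, ~12% of the signal range); the hard and soft
masks exclude or downweight them and recover the true surface to ~7·10⁻⁴.
The win margin is the uniform-minus-soft recovery error: positive when
confidence weighting helps.

Robust evaluation of a prediction against ground truth:

```r
pred <- predictSurface(fitPredictor(list(sup),
          TrainConfig(maxSteps = 100L,
                      loss = LossConfig(weight = WeightConfig("soft")))),
          48L, 64L)
evaluatePair(pred, truth)
#> MetricsReport: absRel 0.0010 | d<1.25 1.000 | d<1.25^2 1.000 | d<1.25^3 1.000 | 3072 px
```

A command-line front end over the same functions lives at
`inst/scripts/cwdepth-cli.R` (subcommands `align`, `loss`, `evaluate`,
`simulate`, `demo-train`).

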