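---
title: "Models and methods: quantifying haemolysis from serum colour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying haemolysis from serum colour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haemoquant)
```

## The measurement problem

Free haemoglobin (Hb) released by ruptured erythrocytes colours serum from
straw-yellow to red; its concentration in g/L is the accepted measure of
haemolysis. `haemoquant` calibrates that concentration against two kinds
of signal — the absorbance of the serum at 540 nm, and the RGB colour of a
photographed cuvette — and provides the statistics needed to decide
whether a cheap signal agrees with the reference wet-chemistry value.

This vignette records the models, the tunable parameters and the design
decisions that were genuinely open, so a maintainer can tell what is
principled, what is convention, and what is an assumption of the synthetic
test world.

## Signal models

**UV–VIS.** Beer–Lambert behaviour at 540 nm: `A = β₀ + β₁·Hb`. The
serum is measured diluted in practice, but the calibration is empirical,
so the dilution factor is absorbed into the slope; the package follows
that convention and fits absorbance directly against undiluted-serum Hb.

**Redbance.** The red channel of an 8-bit image decreases with Hb.
To obtain an absorbance-like signal the package uses the transform
`Redbance = −log₁₀(R/256)`. Two quirks are kept deliberately:

- The divisor is 256 (the number of channels), not the channel maximum
  255. A colourless sample (R = 255) therefore has a slightly positive
  Redbance; R = 256 is accepted as input only as the colourless identity
  giving exactly 0.
- Channel values are clamped to [1, 255] before the transform, so the
  darkest representable red maps to `−log₁₀(1/256) = 2.408` and `log(0)`
  can never occur.

Channel means are carried as unrounded reals (as an ImageJ region mean
would be) until this transform; nothing is quantized to the 8-bit grid
except actual image files.

**Weighted intensity.** The "weighted intensity" of an RGB triple is not
defined unambiguously by common usage; the package fixes it to the
Rec. 601 luma weights `0.299 R + 0.587 G + 0.114 B` (ImageJ's "weighted
RGB" conversion) and isolates the choice behind `weighted_intensity()`.
The plain mean `(R+G+B)/3` was the alternative; the weighted convention
was chosen because it is what the named extraction software applies when
its weighted option is on. Note that intensity is then an exact linear
blend of R, G, B — the four-column predictor matrix has rank 3, which is
why NIPALS extraction on such data cannot go past three latent factors.

**Region of interest.** Coordinates are 0-based with half-open extents
(`roi(x0, y0, width, height)`), stated explicitly because GUI conventions
are ambiguous in prose. The default ROI is a centred square covering 25 %
of the shorter image side, standing in for "the centre of the cuvette".

## The synthetic world

The generator emulates the study design: serum from each of 10 animals is
split and spiked to 7 haemolysis levels (0, 0.2, 0.5, 1, 2.5, 5, 10 %),
giving 70 samples, with serum Hb = fraction × whole-blood Hb.

| Parameter | Default | Why |
|---|---|---|
| whole-blood Hb | truncated normal, mean 110, SD 15, bounds 80–140 g/L | reference interval of healthy adult dairy cows; consistent with ~10 g/L serum Hb at 10 % haemolysis |
| absorbance line | 0.1051 + 0.0873·Hb | the published calibration line is the generating truth |
| Redbance line | 0.0929 + 0.0187·Hb | likewise; noise is injected on the Redbance scale and mapped back through `R = 256·10^−Redbance`, so the line is recoverable |
| calibration scatter | `σ = slope · sd(Hb) · √(1/r² − 1)` | closed form making the design reproduce the published correlations (r = 0.991 absorbance, 0.983 Redbance) in expectation |
| G, B channels | `G = 185 − 1.0·Hb + N(0,8)`, `B = 125 − 0.5·Hb + N(0,10)` | invented magnitudes whose only job is to keep cor(G,Hb), cor(B,Hb) below 0.5 on a study-sized design — weakly informative, as serum colour sits in the red range |
| blank baseline Hb | half-normal, SD 0.02 g/L | blanks must vary (the LOD is 3× their SD) but no blank spread is published |
| replicate noise | 0.005 A; 0.002 Redbance; 0.5 channel units (G, B) | within-run instrument repeatability — a benchtop spectrophotometer's photometric repeatability, and about one 8-bit channel unit between repeat photographs at R ≈ 200 |

The distinction between **calibration scatter** (between-sample, includes
animal-to-animal matrix effects) and **replicate noise** (within-run,
instrument only) is a modelling decision: the published detection limit
(blank SD ≈ 0.06 g/L) is far smaller than the scatter around the
calibration line (≈ 0.5 g/L in concentration units), so a single noise
scale cannot reproduce both. Precision and LOD studies therefore simulate
repeat measurements of one specimen with replicate noise only, which puts
the synthetic LOD in the 0.1–0.3 g/L neighbourhood of the published table
without being tuned to it.

What a green test does **not** establish: the generator has Gaussian,
homoscedastic noise, no icteric or lipemic chromogens, no operator or
session effects, no camera drift, and G/B models invented only to be
weakly informative. Green means the algorithms recover a stated world
correctly — not that the published real-data figures of merit are
reproduced. Table-level values (CVs, recoveries, PLSR variance
percentages, validation correlations) are bracketed by order-of-magnitude
checks only.

All randomness is seeded. `simulate_samples()` uses one seeded stream
with a fixed draw order; `calibration_recovery()` derives an explicit
per-replicate seed (`seed·1000 + i`) so replicates are independent and
reproducible. Patches are written as lossless PNG; with pixel noise
≥ ~0.5 channel units the noise also dithers the 8-bit quantization, so ROI
means recover the requested colour to the standard error of the mean.
Noiseless non-integer colours, by contrast, round to the 8-bit grid —
that is a property of the file format, not of the extraction.

## Calibration and validation machinery

**OLS** is closed-form, with 95 % confidence half-widths from Student t on
n − 2 df, and the fit retains its 2×2 normal-equations matrix `XᵀX`.
Inverse prediction `(signal − β₀)/β₁` preserves negative values: blanks
must be allowed to scatter below zero or their SD — and with it the LOD —
would be biased. Linearity is checked by the regression ANOVA
`F = (r²/(1−r²))(n−2)`; a numerically perfect fit is flagged rather than
reported with a spurious p-value.

**PLSR** is NIPALS with deflation of both blocks, on autoscaled
predictors and a centred/scaled response (conventional for this method,
whereas the network below uses min–max scaling — each is that method's
norm). At full rank it reproduces multiple OLS to 1e−8, which the tests
verify against `lm()`. The factor count is chosen by 10-fold
cross-validated RMSE with a parsimony rule: the smallest rank within 5 %
of the minimum. The 5 % band is a package choice — only the optimal rank
itself (three, on the emulated study's real data) is externally fixed —
and it is exposed as the `tol` argument. A response that cross-validates no better than its own SD
raises a noise flag instead of a confident rank.

**The network** is a 4-7-1 multilayer feed-forward perceptron with
sigmoidal transfer in every layer, trained by batch backpropagation with
momentum under the published recipe: η = 0.2, momentum 0.5, initial
weights (and biases, which are included as standard practice although
unmentioned) uniform in [−3, 3], at most 500 epochs. Decisions taken
where the recipe is silent:

- *Batch vs pattern updates.* Weights are updated once per epoch (batch),
  the reading consistent with per-epoch parameter updates, and the one
  that makes the gradient exactly testable against central differences
  (the suite checks agreement to 1e−6).
- *Sum vs mean error.* The gradient is of the summed squared error
  `E = ½Σ(o−y)²` (the classic convention). With the mean-error convention
  η = 0.2 moves ~50× too slowly to converge inside 500 epochs at the
  study's sample size; with the summed convention the published η behaves
  sensibly at n ≈ 50–70. The step is therefore scale-dependent: batch
  training on hundreds of samples would need a smaller η.
- *Target scaling.* Hb is min–max mapped to [0.1, 0.9] (a sigmoid output
  cannot reach 0 or 1), inputs to [0, 1], both fitted on training data
  only and inverted at prediction time.
- *Stopping.* Below the 500-epoch cap, training stops when the epoch-RMSE
  changes by less than 1e−7 in absolute value — absolute, because the
  momentum dynamics oscillate transiently and a signed criterion would
  stop on the first upward tick.
- *Learning-rate schedule.* η is the single constant 0.2; no adaptive
  schedule is implemented or guessed.

A known, measured limitation follows from this recipe: with a fixed step
and momentum, batch training settles into a limit cycle whose residual
floor is roughly 2 % of the target range. On a noiseless linear map at
the study's sample size, held-out R² after 500 epochs is typically
0.97–0.99 (0.989 at the package's default seed) and does not reach 0.99
reliably; lifting the cap to ~2000 epochs crosses 0.99 and plateaus near
0.994. The package keeps the published cap, and the corresponding
acceptance property is reported honestly rather than retuned.

**Splitting and cross-validation.** The 70/30 split is stratified by
haemolysis level (per-level proportions within one sample of the target,
49/21 on the full design). Nested cross-validation defaults to
animal-wise folds — with ten animals, ten folds of seven — because that is
both the stated fold count and the strongest independence (no animal on
both sides); any model selection inside the fit callback only ever sees
the training folds. With a different animal count the folds fall back,
with a warning, to level-stratified random folds whose sizes differ by at
most one. Both univariate and multivariate methods can use either scheme;
the pipeline defaults to the split for univariate and nested CV for
multivariate methods, mirroring the emulated study.

**Method comparison.** Predictions are regressed on the reference
(predicted on the vertical axis); agreement requires the 95 % CIs to
cover 0 and 1, the paired `t = x̄_d√n/s_d` to stay below its two-sided
critical value, and the point (0, 1) to fall inside the joint elliptical
confidence region
`(b − β)ᵀ XᵀX (b − β) ≤ 2 s² F(1−α; 2, n−2)`.
The quadratic form is checked in the tests against an independent
residual-sum-of-squares route (`RSS(β) − RSS(b)` against the same bound),
and its coverage of (0, 1) under a true identity line is verified by
simulation (≥ 93 % observed at α = 0.05 over 500 runs, consistent with
the nominal 95 % within binomial noise).

## Figures of merit

`CV% = SD/mean × 100` (sample SD) at 0.5, 2.5 and 10 g/L — the precision
levels are keyed in concentration units (g/L), not in per-cent haemolysis.
`LOD = 3·SD` and `LOQ = 10·SD` of ten blank
*predicted concentrations* (the concentration domain makes the limits
come out in g/L); their ratio is 10/3 by construction and the tests pin
it. Linearity is reported as LOD up to 10 g/L. Mean recovery is the mean
of `100·predicted/reference` over validation pairs **at quantifiable
levels** (reference > LOQ): the generator's blanks carry tiny positive
baseline Hb, and including sub-LOQ pairs turns the ratio into noise
(observed excursions of −364 % to +244 % before the rule was adopted).
`mean_recovery()` keeps an explicit `min_reference` argument, default 0,
for callers who want the raw convention.

## Degenerate inputs and numerical choices

- Zero-variance predictors are rejected by name; a single-level design
  simulates with zero calibrated scatter instead of dividing by zero.
- `redbance()` rejects non-positive channel values before clamping.
- A constant response gives `t_cal = 0` (zero mean difference) or ±∞
  (non-zero mean, zero SD), never NaN.
- NIPALS stops, with a warning, when the deflated predictor block is
  numerically exhausted (‖Xᵀy‖ < 1e−10) and records the achieved rank.
- The sigmoid is evaluated in its plain form, which is stable to ±700 and
  saturates cleanly beyond.
- Training aborts with the epoch index if the loss ever becomes
  non-finite.

## Known limitations

- The generator's noise is Gaussian and homoscedastic; real serum
  panels show level-dependent spread and matrix interferences (icterus,
  lipemia) that are explicitly out of scope.
- The published real-data merit values are not reproduction targets; only
  the published calibration lines, correlations, design arithmetic and
  worked statistics are.
- JPEG input is supported for extraction, but rendered fixtures are PNG:
  lossless files make the round-trip test exact, where a lossy codec
  would only bound it.
- The network implementation is deliberately faithful to a 1990s-style
  recipe; it is not a modern regressor and inherits that recipe's
  optimization floor, as quantified above.
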