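---
title: "Staging grape seeds by color, and what their texture and taste say about it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging grape seeds by color, and what their texture and taste say about it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedstage)
```

## The problem

Grape seeds ripen unevenly: at any sampling date a vineyard yields seeds
spanning a range of maturities, from greenish-yellow and pliable to dark
brown and brittle. Because seed maturity drives the tannins a wine
extracts, winemakers want seeds grouped by *actual* ripeness rather
than by calendar date. Seed color is a convenient, non-destructive
proxy: during ripening the seed coat darkens (CIELAB lightness L\*
falls) and loses colorfulness (chroma C\*ab falls). `seedstage`
implements a pipeline around that idea: photograph seeds in a
calibrated cabinet, summarize each seed's color in CIELAB, allocate
seeds to equal-size maturity stages by percentiles of a ripeness
score, and then characterize the stages instrumentally (compression
texture) and sensorially (trained panel), tying the two together with
correlation and PCA.

## Imaging and color

Images are assumed to be standard sRGB renderings under the D65
illuminant and the 2-degree observer; the conversion chain is the
textbook sRGB to linear RGB to XYZ to CIELAB sequence
(`srgbToLab()`). A calibrated-camera profile would be preferable when
available, but the sRGB assumption is the portable default for cabinet
imagery.

Seeds are photographed as dark objects on a light plate in a fixed 12
column by 8 row grid (96 seeds per image). `segmentSeedGrid()`
thresholds the lightness channel (Otsu by default, a fixed L\*
threshold optionally), labels 8-connected components, drops regions
below `minAreaPx` (default 20 px) as debris, and assigns each region
to the grid cell containing its centroid on an evenly divided image.
Two centroids in one cell abort with an ambiguity error rather than
guessing. Per-seed color is the arithmetic mean of the pixelwise
CIELAB values over the region mask — the mean is taken in CIELAB, the
measurement space, not in RGB — and chroma/hue are derived from the
averaged opponent coordinates. The choice of the mean (rather than,
say, the median) is a design decision; for the unimodal, tightly
clustered pixel distributions of a seed coat the difference is
negligible.

`fitEllipsoid()` (algebraic least-squares quadric fit) is exposed as a
standalone morphology utility for 3-D point clouds of seed surfaces;
it plays no role in staging.

## Staging by percentiles

`ripenessScore()` reduces (L\*, C\*ab) to one dimension. Both
coordinates carry ripeness information, so the default mode
standardizes them and projects onto their first principal axis, with
the sign fixed so the score *increases* as lightness *decreases*
(darker = riper); single-axis modes (-L\* or -C\*ab) are available
when only one coordinate is trusted. `classifyByPercentiles()` sorts
by score (ties broken by seed id, making the classification
deterministic and order-invariant) and cuts into k = 5 contiguous
groups whose sizes differ by at most one — exactly equal when k
divides n, with the extra seeds going to the lowest stages otherwise.
Percentiles are taken over the pooled collection, not per sampling
date: the point of the method is to re-group seeds by appearance
regardless of when they were picked. `splitSets()` then draws a
stratified random subset (default 50 seeds, 10 per stage) for the
destructive texture assays.

## Texture parameters from force–distance curves

A lyophilized seed compressed at 1.0 mm/s (500 samples/s, 5 g trigger)
shows a near-linear force rise, a sharp drop when the coat cracks, and
successive smaller subfragmentation peaks until the probe reaches half
the initial seed height. Ten parameters summarize each curve: the peak
count Np, breaking force Bf (N), breaking decline Bdc (N), elasticity
E (N/mm), breaking energy Be (mJ), deformation energy De (mJ),
thickness Th (mm), breaking distance Bd (mm), strain index Si = Bd/Th
and area ratio Ar = Be/De. Si and Ar are stored as fractions in
(0, 1], not percentages; since the test stops at half the seed height,
Si is bounded by 0.5 and Be never exceeds De.

Numerical choices, all configurable:

* **Smoothing** — a centered moving average, default window 5 samples
  (0.01 mm at the stated settings), applied *only* to locate features:
  it suppresses newton-scale wiggles that would otherwise inflate Np.
  All measured values (Bf, Bd, Bdc, E, Be, De) come from the raw
  curve at a refined index — the raw local maximum within half a
  window of the smoothed peak. Measuring on the smoothed signal would
  bias Bf down by ~2.5 N at a sharp apex and shift the break by two
  samples; the refinement keeps noise-free extraction exact to the
  sample grid.
* **Peaks** — local maxima with topographic prominence at least
  `minProminence` (default 1 N). Np counts all prominent maxima over
  the whole assay, the break included: subfragmentation peaks are not
  distinguished from the primary break when counting.
* **Break rule** — the first peak followed, before the next peak, by
  a force drop of at least 20% of the peak force (`dropFraction`) *and*
  at least `minDrop` = 4 N. The absolute floor exists because a purely
  relative rule fires on noise low on the rise (20% of a 2 N wiggle is
  0.4 N); a genuine seed crunch releases tens of newtons, so 4 N only
  guards the noise floor. Setting `minDrop = 0` restores the purely
  relative rule.
* **Elasticity** — OLS slope from the first sample at or above 10 N
  (no sub-sample interpolation) through the break sample.
* **Energies** — trapezoidal rule; N·mm is reported as mJ with no
  conversion factor. The probe-retract segment is excluded by
  truncating the curve at its maximum distance.
* **Thickness** — twice the total post-trigger travel, exact even
  under force noise.

## Panel statistics

The panel design is balanced: every judge scores every sample (stage)
in every session, once, on a structured 0–10 scale, for six
attributes (color, hardness, cracking, vegetal, bitterness,
astringency). Scores are treated as continuous. With one observation
per cell the three-way interaction is confounded with error, so
`threeWayAnova()` fits the three main effects and the three two-way
interactions and uses the three-way term as the residual; in this
balanced layout the Type I and Type III decompositions coincide.

`snkTest()` implements the Student–Newman–Keuls stepwise procedure on
the sorted means: the full range is tested against the studentized
range quantile for p means (obtained numerically from `qtukey()`, not
from tables), and sub-ranges are examined only inside significant
stretches. Groups covered by a non-significant stretch share a letter;
letters run in ascending-mean order. Unequal group sizes fall back to
the harmonic mean n. For two groups the procedure reduces exactly to
the pooled two-sample t-test, and for three or more means it never
rejects a pair that unadjusted pooled t-tests would retain.

A significant judge-by-sample interaction can mean two different
things: judges disagree about the samples, or they agree but use the
scale differently. `panelHomogeneityPca()` decides between them by a
PCA of the samples-by-judges matrix of session-averaged scores
(column-standardized): if all judge loadings on component 1 share a
sign and that component explains at least 60% of the variance
(configurable), the interaction is attributed to scale effects.
Standardization makes the diagnosis invariant to positive per-judge
rescaling. `judgeScreening()` flags judges whose within-cell
repeatability variance exceeds the panel mean by more than 1.5 panel
SDs (the cutoff is configurable because "outlying dispersion" is a
judgment call) and refuses to act if fewer than three judges would
remain.

## Integration

`stageSummary()` assembles the stage-by-variable matrix of means (10
instrumental + 6 sensory variables). Correlations
(`correlationMatrix()`) are computed across the five stage means by
default, matching the structure of published stage-level tables; a
per-seed mode is available by passing the raw matrix. Report rounding
is two decimals, half away from zero. `pruneRedundant()` drops, for
every pair with |r| > 0.80, the member later in a priority order that
prefers the mechanically interpretable parameters (Bf over Be, Bd over
Be, Si over Ar); pairs are visited in priority order so the result is
independent of column order. `pcaBiplot()` runs a column-standardized
PCA of the stage matrix and retains components with eigenvalue > 1
(Kaiser). Si and Ar are retained in the PCA input by default even
though the pruning rule often flags them: pruning is a reporting aid,
not a hard filter. With five stages a centered PCA has at most four
non-null components, which therefore explain 100% of the variance.

## What the synthetic cohort emulates — and what it does not

The generators exist so every stage of the pipeline can be tested with
known ground truth:

* **Images** (`generateSeedImage()`) — one ellipse per grid cell on a
  light-gray plate, colored from a per-stage palette running from
  (L\* 64, C\*ab 34, hue 100°: light greenish) to (L\* 32, C\*ab 11,
  hue 70°: dark brown), with per-seed SD 2 on both coordinates and
  per-pixel channel noise SD 2 (8-bit units). The palette endpoints
  and spreads are chosen to look like seed coats across veraison to
  over-ripeness; the 8-unit stage separation against a 2-unit
  within-stage SD represents the favorable case where color genuinely
  tracks maturity.
* **Curves** (`generateCurve()`) — piecewise-linear templates (rise at
  slope E, drop of Bdc, Np−1 bumps, stop at Th/2) with per-stage
  means anchored on the packaged reference table (Bf rising 50→57 N,
  Th 2.2→3.3 mm across stages). Breakpoints are snapped to the
  0.002 mm sample grid so the recorded closed-form energies equal the
  trapezoidal integrals exactly; sampled Bdc is truncated into
  [0.25, 0.9]·Bf so every synthetic curve has a detectable break.
  Force noise defaults to SD 1 N.
* **Panel scores** (`generatePanelScores()`) — `clip(gain_j · stage
  mean + bias_j + session shift + residual, 0, 10)` with gains
  N(1, 0.15), biases N(0, 0.5), residual SD 0.8 and session shifts
  zero by construction (so the session main effect is a true null).
  Stage means rise for color/hardness/cracking and fall for
  vegetal/bitterness/astringency, and the color and vegetal trends are
  linear in the stage index. Clipping at the scale bounds introduces
  mild nonlinearity; the default effect sizes keep means well away
  from the bounds.

None of this is photorealistic or biomechanical: real seed images have
specular highlights, shadows and touching seeds; real curves have
drifting baselines and non-linear pre-break compliance; real panels
drift between sessions. Passing tests on synthetic cohorts therefore
demonstrates the *statistical machinery* — segmentation accounting,
percentile balance, exact parameter recovery, ANOVA calibration,
diagnostic dichotomies — not field performance on photographs.

## Problem sizes and calibration choices

The test suite and the acceptance script run, by choice, at the scale
of the original study design: cohorts of 480 seeds (five 96-seed
images), 50-curve texture subsets (10 per stage; the per-stage count
is exposed as a parameter because the appropriate n depends on seed
availability), and 17 judges × 8 sessions × 5 stages panels. The
null calibration of the sample-effect F-test uses 1000 simulated
panels; the texture-recovery study uses 200 noisy curves (force SD
1 N) and checks median relative errors of Bf, De and Th against a 2%
bar; noise-free oracle checks use 50 curves with energies compared at
1e-9 relative tolerance and break coordinates at one sample step.

## Known limitations

* The sRGB/D65 assumption replaces a per-camera characterization;
  absolute CIELAB values from uncalibrated cameras will be biased,
  though percentile staging is invariant to monotone color shifts.
* Grid assignment assumes the photographed grid is axis-aligned and
  evenly spaced; there is no registration step.
* The break rule is heuristic; curves whose first failure releases
  less than `minDrop` newtons (very immature seeds) would be flagged
  rather than profiled.
* Correlations on five stage means rest on five observations; they
  describe the stage-level structure and carry wide sampling
  uncertainty.
* Sensory scores are modeled as continuous and homoscedastic; ordinal
  models and session-drift corrections are out of scope.
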