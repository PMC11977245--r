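---
title: "Quantifying lip desquamation from photographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lip desquamation from photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipdesq)
```

## The measurement model

Desquamated flakes on the lower lip are brighter than the surrounding
vermilion. On a cropped lip region their grayscale distribution is not a
second histogram mode but a *long right tail* attached to a unimodal bulk:
flakes cover a small area fraction and vary widely in brightness. Global
thresholds that assume bimodality (Otsu's between-class-variance rule, the
Triangle geometric rule) place their cut inside or at the edge of the bulk
and over-segment normal skin in this regime. `lipdesq` therefore treats
flake pixels as statistical outliers of the region itself:

$$T = \mathrm{Mean} + k \cdot \mathrm{SD},$$

with Mean and SD the mean and *population* standard deviation (divide by
$N$) of all grayscale values in the cropped region, and $k$ a dimensionless
multiplier. Pixels strictly above $T$ are objects (flakes); the
**desquamation rate** is $100 \cdot n_{\mathrm{object}} / n_{\mathrm{total}}$
percent. Two numerical conventions are pinned deliberately:

* **Population SD**, not the $n-1$ sample estimator: the SD here is a
  descriptive statistic of the full pixel population of the region, and the
  choice must be fixed for reproducibility (the difference is negligible at
  $N \approx 2 \times 10^4$ pixels but would still be a silent source of
  drift).
* **Strict inequality** (`> T` is object): a zero-variance region then has
  $T = \mathrm{Mean}$ and an empty mask — the only sensible degenerate
  outcome.

Grayscale conversion uses the fixed BT.601 luma weights
(0.299, 0.587, 0.114); intensities are kept real-valued in $[0, 255]$
without re-quantization so that threshold comparisons are exact.

## Target-region geometry

The analysis region is a rectangle on the lower-lip premucosa (the driest
lip sub-region), located from eight face-mesh landmarks. Width is the
larger of the two x-spans $|x_{84}-x_{87}|$ and $|x_{314}-x_{317}|$; height
is the distance between the y-midpoints of pairs 14–15 and 16–17. The
published construction fixes width and height but not the anchor, so the
package centres the rectangle horizontally on the mean x of
$\{84, 87, 314, 317\}$ and spans vertically from the 14–15 midpoint to the
16–17 midpoint — those midpoints are what bound the lower-lip centre area
vertically. Geometry is computed in floating point and rounded to integer
pixel bounds only at the end; coordinates are 0-based and ROI bounds
half-open, so area equals width × height exactly. Rectangles that would
leave the image are clipped with a warning (the alternative, padding, would
manufacture pixels). Landmark acquisition is pluggable: the package
consumes landmark JSON files (normalized or pixel coordinates), so no face
detector is needed to use or test it; only x/y are used, never z.

## Calibrating k

$k$ trades sensitivity against specificity: the rate is non-increasing in
$k$ for any image. Calibration sweeps $k$ over 1.5–4.5 in steps of 0.1
(31 values), correlating per-subject rates with final visual-assessment
scores. The published procedure — maximize correlation with VA while
minimizing omission of existing flakes — is narrative, so the package
operationalizes it deterministically: **the smallest grid $k$ whose
correlation is within a tolerance (default 5%) of the grid maximum**.
Smaller $k$ means lower $T$ and fewer missed flakes, so among
near-equivalent correlations the least-omissive choice is the smallest
$k$; with tolerance 0 the rule reduces to the argmax. The operating
default `k = 2.5` ships on [quantify()] as the calibrated optimum.
Pearson correlation is the default metric, Spearman a configuration
alternative.

## The tape-stripping comparator

The comparator instrument groups sampled corneocytes by grayscale into five
thickness classes from 80 upward in 35-unit intervals: edges 80, 115, 150,
185, 220, 255. Published group ranges share endpoints ("80–115",
"115–150"), so a bin convention must be pinned: bins are lower-closed and
half-open, the last closed at 255. This makes the quality-control rule —
exclude material below grayscale 150 — exact: 150 itself falls in G2 and
is retained. The tape-strip rate is the G2+G3+G4 proportion. Values below
80 are assigned to G0 rather than dropped; since G0 never enters the rate
this affects only the reported proportions and is fixed for determinism.

## Cohort statistics

Method agreement is summarized by Pearson r (with p) and by the mean
squared vertical residual about the OLS line of min-max-normalized rate on
VA score. Min-max normalization is pinned because the comparison figure's
bounded axis requires *some* normalization and the choice only affects
within-method MSE, which is how the quantity is used. Decade-level
contrasts use Kruskal–Wallis plus pairwise two-sided Wilcoxon rank-sum
tests, reported both Holm-adjusted and unadjusted (no adjustment is
prescribed by the protocol, so both are exposed). Shapiro–Wilk normality
p-values are logged, but the pipeline always reports both Pearson and
Spearman rather than auto-switching on a normality gate — determinism
again. Age trends are visualized with loess (span 0.75, degree 2, direct
surface so that exactly linear data is reproduced to numerical precision).

### The breakpoint scan

To locate the age at which the female trend turns, the scan tests, at every
candidate age $a$ leaving at least 30 records per side, whether the slopes
below and above $a$ differ. The default test fits the single continuous
piecewise (segmented) regression

$$\mathrm{rate} \sim \mathrm{age} + (\mathrm{age}-a)_+$$

and t-tests the slope-change (hinge) coefficient. A discontinuous
two-intercept parameterization was considered and rejected: on simulated
cohorts with a known kink its argmin-p sits systematically ~3 years above
the true break, because moving the split right lengthens the lower segment
and shrinks the standard error faster than the slope contrast decays. The
continuous model is correctly specified for a kinked-but-continuous trend
and centres on the planted break. Fitting the two segments independently
and z-testing the slope difference is available as `method = "separate"`.
The breakpoint is the candidate with minimal p, ties broken toward the
younger age; reported slopes come from the two separate segment fits.
Because the scan runs one test per candidate (~45 of them, highly
correlated), the reported significance is Bonferroni-adjusted over the
candidate count — without family-level control a pure-linear cohort would
"find" a significant break far too often. The per-age unadjusted p-values
are returned for inspection.

## The synthetic-data generators

The study's facial images are privacy-restricted, so the package ships
generators that emulate the statistical structure the method depends on,
with exact ground truth.

**Lip images** (`generate_flake_image()`). Defaults: 160 × 120 px,
background mean 120 and SD 10 grayscale units, texture correlation length
4 px, flake contrast 5 SD, nominal 8 flakes, fraction 2%. The background is
built from smoothed Gaussian noise plus slightly curved near-vertical
wrinkle ridges; the pooled field is then passed through a bounded marginal
map: the bell is kept to 1.45 SD, the next stretch is thinned, and the
extreme upper quantiles — ridge crests — collapse onto a narrow specular
"gloss shelf" just below 2.5 population-SD. The physical picture is matte
lip texture whose ridge crests carry a thin band of gloss; the statistical
consequences are the ones that matter:

* the flake-free background never crosses $T$ at $k = 2.5$, so planted
  fractions are recovered nearly bias-free;
* the shelf, separated from the bell by a thin dip, sits squarely inside
  the intensity range that Otsu's and Triangle's rules cut into, so the
  conventional baselines reproducibly over-segment exactly as they do on
  real lip histograms;
* bulk, dip, shelf and flake tail merge into a unimodal long-tailed
  histogram (checked by a prominence-filtered mode count on the smoothed
  256-bin histogram; a 5%-of-peak prominence floor ignores quantization
  ripple while still flagging genuinely bimodal images).

Flakes are flat-topped elliptical blobs with low-order Fourier boundary
perturbation, soft edges ~0.7 px wide centred on the mask boundary,
per-flake contrast jitter (0.8–1.15×), and 92% occlusion of the texture
beneath. The ground-truth mask marks flake interiors; realized area is
held within ±10% of the requested fraction. These defaults were fixed
once, by checking the generator's own contract (recovery error, mask
Jaccard, baseline failure, unimodality) on a design grid, before any
downstream analysis.

What the generator does **not** emulate: illumination gradients and pose,
colour variation between subjects, motion blur, lip boundary curvature
(regions are rectangular by construction), and flakes darker than their
surroundings. Passing tests therefore demonstrate the method's behaviour
under its stated statistical premise — bright-outlier flakes on a bounded
textured background — not robustness to acquisition artefacts.

**Cohorts.** `generate_va_cohort()` draws a latent severity per subject
(uniform 0.3–3.7, matching predominantly 1–3 observed grades), maps it
linearly to flake fraction (0.002 per severity unit, so a grade-2 subject
carries 0.4% flake coverage, the magnitude seen in adult cohorts), renders
an image per subject, and scores it with 5 raters as
round(severity + N(0, 0.5)) clamped to 0–4 — which lands mean inter-rater
correlations near the reported ~0.8. `generate_trend_cohort()` reproduces
the fitted cohort structure: 10 subjects per sex per integer age 20–69;
females rise at 0.019 %-points/yr from 0.217% at age 20 to a breakpoint at
38, then fall at 0.005/yr; males fall at 0.005/yr with the intercept placed
so the male mean is exactly 0.440%; Gaussian noise SD 0.1, truncated at
zero. One caveat is worth recording: those fitted female parameters imply
a female mean near 0.44%, whereas the study's raw female mean was lower —
a published fit need not reproduce a published raw mean, and the generator
follows the fit, since the trend structure is what the breakpoint machinery
is tested against.

All generators are bit-reproducible under a single seed; nested draws use
a documented integer seed-splitting scheme, so per-subject streams are
independent of cohort size.

## Problem sizes and runtime

The shipped tests exercise: 100 random arrays for threshold exactness; 20
images for grid monotonicity; 50 ground-truthed images (fractions 0.5–5%)
for the recovery and baseline benchmarks; a 55-subject VA cohort for
calibration; 20 replicates of the 1,000-subject cohort (plus male nulls)
for breakpoint recovery. These sizes keep the full suite under a minute on
one core while leaving the simulation-based checks comfortable margins.

## Known limitations

* The SD-outlier threshold assumes flakes are a minority of the region; at
  flake fractions approaching 5% the inflated SD raises $T$ and the rate
  is underestimated by a few tenths of a percentage point (visible in the
  benchmark at the 5% fraction).
* The false-positive floor is zero only because the synthetic background
  is bounded; on real photographs specular gloss can cross $T$ and the
  method inherits whatever floor the acquisition protocol leaves.
* The breakpoint scan assumes a single kink and reports the best single
  split; it does not model smooth curvature (use the loess view for that)
  or multiple change points.
* Landmark quality is taken as given; no pose or perspective correction is
  applied.
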