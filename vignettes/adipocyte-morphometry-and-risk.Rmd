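---
title: "Adipocyte morphometry and matched case-control risk modelling with adiposize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte morphometry and matched case-control risk modelling with adiposize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(adiposize)
library(dplyr)
```

## The scientific problem

Ductal carcinoma in situ (DCIS) is a non-obligate precursor of invasive
breast cancer: most lesions never progress, so risk stratification at
diagnosis matters. One candidate marker family lives in the tumour
microenvironment rather than the tumour itself: the breast white adipose
tissue. Hypertrophic adipocytes and adipose inflammation (crown-like
structures, CLS — a dying adipocyte ringed by CD68-positive macrophages)
accompany the metabolic states that raise breast-cancer risk.

`adiposize` implements the full quantitative chain needed to study this
question on histology and registry-style data:

1. **Morphometry** — segment intact adipocytes on calibrated H&E rasters and
   measure each one with an 18-chord centroid rule.
2. **Tissue composition** — classify tiles into adipose / stroma /
   epithelium and compute the relative adipose area.
3. **CLS detection** — separate DAB from haematoxylin by colour
   deconvolution and score peri-adipocyte rim coverage; densities are
   reported per 10 cm² of adipose tissue and dichotomised at 5.
4. **Matched case-control inference** — conditional logistic regression on
   age-matched sets, with Wald CIs, likelihood-ratio p-values, quartile
   coding, p ≤ 0.1 univariate screening and interaction terms.
5. **Expected cumulative incidence** — a competing-risk recursion over
   age-specific incidence and mortality rate tables, and the translation of
   group odds ratios into group-specific incidence curves.
6. **Synthetic data** — ground-truthed images, CD68 overlays, nested
   case-control cohorts and rate tables, so every stage is testable without
   patient data (which, for the motivating study design, are not public).

## The 18-chord centroid measurement

For a segmented vacuole the contour is extracted at sub-pixel precision
(marching-squares iso-contour of the binary mask at level 0.5, pixel-centre
coordinates, x right / y down, scaled by the µm-per-pixel calibration). From
the polygon we compute the area-weighted centroid, then pass 18 lines
through it at 10° increments (0°, 10°, …, 170°). The *chord* at angle θ is
the total in-object length of that line — identical to the
extreme-to-extreme distance for convex shapes and still well defined for
mildly irregular contours, where the even-odd intervals along the line are
summed. The object's **median diameter** is the median of the 18 chords;
with an even count this is the mean of the 9th and 10th order statistics.

Two shape-quality scores accompany each object:

* **circularity** = 4πA/P² (1 for a disc), and
* **regularity** = min(chords)/max(chords) (1 for centrally symmetric
  shapes).

```{r chords}
# a rasterized ellipse with 60/30 um semi-axes, 0.5 um/px
th <- seq(0, 2 * pi, length.out = 721)[-721]
poly <- cbind(80 + 60 * cos(th), 60 + 30 * sin(th))
wpx <- 300; mpp <- 0.5
g <- expand.grid(i = 1:wpx, j = 1:240)
m <- matrix(0.3, 240, wpx)
ok <- ((g$i - 0.5) * mpp - 80)^2 / 60^2 + ((g$j - 0.5) * mpp - 60)^2 / 30^2 <= 1
m[(g$i[ok] - 1) * 240 + g$j[ok]] <- 0.95
obj <- measure_adipocytes(calibrated_raster(array(rep(m, 3), c(240, wpx, 3)), mpp))
obj |> select(median_diameter_um, area_um2, circularity, regularity)
```

### Quality control

Objects are retained when median diameter ≥ 30 µm (the classical cut
separating mature adipocytes from artifacts and debris), circularity ≥ 0.6
and regularity ≥ 0.4. The size rule is applied to the *median* diameter,
not to individual chords: the median is the per-object size estimate, and
individual chords of an intact but irregular cell can legitimately dip
below 30 µm. The roundness and regularity cut-offs are our own defaults —
commercial vacuole modules keep theirs proprietary — so both are
configurable and every rejection carries a machine-readable reason.

### Patient summaries

A patient's size score is the **75th percentile** of their per-adipocyte
distribution (diameter and area), computed by linear interpolation between
closest ranks (`stats::quantile` type 7). The upper quartile is preferred
over the mean because damaged or immature vacuoles shrink the lower tail
far more than the upper one; a patient with zero QC-passing objects is
flagged *not assessable* rather than summarised.

## What the synthetic generator emulates — and what it does not

`generate_adipose_image()` places cells by sequential Poisson-disk
(dart-throwing) sampling, largest first, and carves each cell's polygon
with additively weighted bisectors against its neighbours (offset inward by
half the membrane thickness) capped by a 72-gon at the target diameter.
This reproduces the features the morphometry pipeline actually relies on —
packed polygonal cells, bright interiors, stained membranes of controlled
thickness, exact polygon ground truth for area and chords — plus torn
crescent artifacts (which fail circularity/regularity by construction),
sub-30-µm debris and a stromal band. Default cell diameters are lognormal
(`meanlog = log(65)`, `sdlog = 0.3` µm), chosen so per-patient p75
diameters land in the 70–90 µm range typical of breast adipose tissue; the
canvas default is 2048 px at 0.5 µm/px (a ~1 mm² field, the scale of an
annotated adipose region at 20x scanning).

The generator does **not** emulate staining variability, out-of-focus
blur, nuclei, vessels, or folded tissue; passing its tests therefore
demonstrates the correctness of the geometry and statistics, not robustness
to real-world staining artifacts. An infeasible packing request errors out
rather than silently truncating the cell count.

`generate_cd68_overlay()` flags a chosen fraction of cells as CLS and
paints an annular CD68-positive rim over a chosen arc fraction;
`render_cd68_ihc()` turns mask + scene into a DAB-brown-on-haematoxylin
raster so stain separation can be exercised end to end.

## CLS detection choices

Colour deconvolution uses the fixed Ruifrok–Johnston H-DAB optical-density
vectors; negative unmixed concentrations are clamped to zero before
thresholding (they are unphysical and would otherwise break the degenerate
threshold-0 bound). The peri-adipocyte annulus is 20 µm wide (the scale of
a macrophage rim) and is divided into 36 angular bins; a bin is positive
when more than half of its pixels are CD68-positive, and an adipocyte is
called a CLS when at least a third of its non-empty bins are positive. The
morphological definition of "surrounded by a rim" has no published numeric
equivalent, so both the annulus width and the 0.33 coverage threshold are
explicit, logged parameters rather than hidden constants. Multi-slide
aggregation sums CLS counts and adipose areas across a patient's sections
before computing the density per 10 cm², dichotomised at ≥ 5.

## Conditional logistic regression

For age-matched sets (one case, ≥ 1 control) the conditional likelihood

$$L(\beta) = \prod_s \frac{\exp(x_{case,s}'\beta)}{\sum_{j \in s} \exp(x_j'\beta)}$$

is maximised by Newton–Raphson with step-halving, converging when the
largest gradient component falls below 1e-8 (at most 50 iterations).
Standard errors come from the observed information; 95% Wald intervals use
z = 1.959964; p-values for model comparisons are likelihood-ratio based.
Design choices worth stating:

* **Set-level complete-case analysis**: a subject missing a model covariate
  removes its whole matched set (the set contributes nothing identifiable).
* **Identifiability**: a term constant within every set is an error (the
  matching absorbed it); a term linearly dependent on earlier terms is
  dropped with a warning, so an LR test against a model extended by an
  exact copy correctly returns statistic 0 on 0 df.
* **Separation** is flagged (|log OR| > 15), not corrected.
* **Model building** keeps candidates with univariate LR p ≤ 0.1, then
  optionally LR-tests pairwise interactions between included main effects.
* Continuous effects are reported per raw unit; callers rescale (per 10 µm,
  per 10³ µm², per 10%) by dividing the covariate, without standardisation.

```{r clogit}
co <- generate_cohort(cohort_spec(n_sets = 300,
                                  log_odds = c(exposed = log(2.75)),
                                  seed = 7))
fit <- clr_fit(co, "exposed")
tidy(fit)
```

The cohort generator simulates a source cohort under proportional hazards
(exponential event times, administrative censoring at 15 years), takes the
earliest events as cases and samples controls from each case's age-matched
risk set — incidence-density sampling, which makes the conditional-logistic
estimand equal the specified log rate ratio. Controls are drawn within half
the matching window of their case so the *total* within-set age spread never
exceeds the window (0.5 years by default, matching to within ±6 months).
One case per set; the default 1–2 controls per set reflects a variable
matching ratio whose true distribution is not published — a documented
modelling choice.

Crude odds ratios computed from pooled 2×2 margins are a *different*
quantity from the matched-set estimate whenever the matching variable
relates to exposure; the test suite demonstrates the divergence on
age-linked exposures rather than pretending the two agree.

## Expected cumulative incidence

Over each step of a rate table (1-year bands, piecewise-constant hazards)
the competing-risk increment is exact:

$$\Delta CI = S(t)\,\frac{\lambda}{\lambda+\mu}\left(1 - e^{-(\lambda+\mu)\Delta t}\right),$$

with S multiplied by $e^{-(\lambda+\mu)\Delta t}$. Annual steps are the
default; the recursion agrees with a 0.01-year grid to 1e-4 because the
within-step solution is exact for piecewise-constant hazards.

Group-specific curves treat odds ratios as rate ratios on the
cause-specific incidence hazard — the rare-event approximation the matched
design justifies. At every step the baseline scaling is re-solved against
the surviving group mix (starting from $c = 1/\sum_g p_g RR_g$), so the
prevalence-weighted group hazard keeps reproducing the marginal rate as
higher-risk groups deplete; mortality is never modified across risk groups.

```{r incidence}
rates <- generate_rate_table(0.01, 0.02, age_range = c(50, 80))
groups <- tibble::tibble(group = c("low_risk", "high_risk"),
                         prevalence = c(0.8, 0.2), rate_ratio = c(1, 3))
group_specific_incidence(rates, groups, start_age = 57, horizon_years = 15) |>
  filter(t == 15)
```

## Tissue composition

Tiles (64 px, stride = tile size) are summarised by nine colour-texture
features and classified by a random forest; coarse tiling is sufficient for
compartment *area fractions*, which is all the pipeline consumes
(percent adipose is a pure ratio, invariant to calibration). The features
are hand-crafted rather than learned: deterministic, desk-scale, and
adequate for separable compartments; the training composition of the
original commercial classifier is unreported, so no equivalence is claimed.

## Numerical conventions and degenerate inputs

* Quartile coding cuts at pooled type-7 percentiles with half-open
  `[low, high)` intervals, so a value equal to a published lower bound of
  the top quartile classifies upward; 4n distinct values occupy quartiles
  n/n/n/n exactly. All-identical values are an error, not a silent q1.
* Age categories proxy menopausal status: < 45, ≥ 45 and < 55, ≥ 55.
* Spearman's rho is reported with a Fisher-z interval using the
  Bonett–Wright standard error $\sqrt{(1+\rho^2/2)/(n-3)}$ (the base test
  provides no CI).
* Uniform images segment to zero objects with a warning; empty QC input
  passes through; a zero adipose denominator is an error for CLS density.
* Every generator is bit-reproducible for a fixed seed.

## Problem sizes used in the shipped checks

The packaged tests run the geometry oracles at 0.5 µm/px, segmentation
recovery on one 100-cell 2048² image, parameter recovery on 200 replicate
cohorts of 1000 matched sets (true OR 2.75) plus 500 null replicates of 150
sets for the type-I error of the likelihood-ratio test, and smaller
property checks throughout; the acceptance script repeats the same
computations at 50 replicates. These sizes make the bias, coverage and
error bounds tight enough to be meaningful while staying desk-scale.

## Known limitations

* Segmentation assumes vacuole interiors are the bright class; heavily
  eosinophilic or overexposed slides would need a fixed threshold.
* The chord rule flags strongly non-convex objects whose centroid falls
  outside the contour as unmeasurable instead of guessing.
* The OR-as-rate-ratio translation in the incidence module inherits the
  rare-event approximation; it is not a substitute for cohort follow-up.
* The tissue classifier is trained per study on its own labelled patches;
  no pretrained weights ship with the package.
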