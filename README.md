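# adiposize

Breast adipocyte morphometry and matched case-control risk modelling.

Most ductal carcinoma in situ (DCIS) lesions never progress to invasive
breast cancer, so markers that separate hazardous from indolent disease are
needed at diagnosis. The breast adipose microenvironment is one candidate:
adipocyte hypertrophy and white-adipose-tissue inflammation (crown-like
structures, CLS) track the metabolic states associated with breast-cancer
risk. `adiposize` provides the complete quantitative chain for studying
adipose features against recurrence risk, for image analysts and
biostatisticians working with histology plus registry-style case-control
data:

- **Adipocyte morphometry** — segment intact adipocytes on calibrated H&E
  rasters; measure each object by passing 18 chords through its centroid at
  10° increments and taking their median as the diameter; QC on a 30 µm
  minimum median diameter, circularity 4πA/P² and chord regularity
  min/max; summarise each patient at the 75th percentile of the
  per-adipocyte distribution (diameter^75th, area^75th).
- **Tissue composition** — random-forest tile classification into adipose /
  stroma / epithelium and percent adipose area.
- **CLS detection** — H-DAB colour deconvolution of CD68
  immunohistochemistry, peri-adipocyte annulus coverage scoring, and CLS
  density per 10 cm² of adipose tissue dichotomised at ≥ 5.
- **Matched case-control inference** — conditional logistic regression
  maximising `prod_s exp(x_case'β) / Σ_j exp(x_j'β)` by Newton–Raphson,
  Wald 95% CIs, likelihood-ratio p-values, pooled quartile coding,
  univariate screening at p ≤ 0.1 and interaction testing.
- **Expected cumulative incidence** — a competing-risk recursion over
  age-specific incidence/mortality rate tables (ΔCI = S·λ/(λ+µ)·(1−e^{−(λ+µ)Δt}))
  and group-specific curves derived from group prevalences and odds ratios
  used as rate ratios.
- **Synthetic data** — ground-truthed adipose images (Poisson-disk packing,
  weighted-bisector cell polygons, artifacts, debris, stroma), CD68 rim
  overlays, age-matched nested case-control cohorts generated by
  incidence-density sampling from a simulated proportional-hazards cohort,
  and rate tables — so every stage is verifiable without patient data.

## Worked example

Generate a ground-truthed image, run the morphometry pipeline, and fit a
matched case-control model on a synthetic cohort:

```r
library(adiposize)
library(dplyr)

g <- generate_adipose_image(adipo_image_spec(n_cells = 100, seed = 7))
obj <- measure_adipocytes(calibrated_raster(g$image, g$microns_per_pixel))
obj |> select(object_id, area_um2, median_diameter_um, circularity, qc_pass) |> head(4)
#> # A tibble: 4 × 5
#>   object_id area_um2 median_diameter_um circularity qc_pass
#>       <int>    <dbl>              <dbl>       <dbl> <lgl>
#> 1         1    3041.               62.3       0.892 TRUE
#> 2         2    2618.               57.8       0.893 TRUE
#> 3         3    3162.               63.5       0.898 TRUE
#> 4         4    1964.               50.1       0.899 TRUE

summarize_patients(obj, "patient_07")
#> # A tibble: 1 × 5
#>   patient_id n_objects_measured diameter_p75_um area_p75_um2 mean_area_um2
#> 1 patient_07                100            80.6        5107.         4289.
```

All 100 placed cells are recovered; areas and median diameters agree with
the exact polygon ground truth to well under 2%. The patient-level score is
the rank-interpolated 75th percentile: this patient's adipocyte area^75th
is 5107 µm², diameter^75th 80.6 µm.

```r
co <- generate_cohort(cohort_spec(n_sets = 300,
                                  log_odds = c(exposed = log(2.75)),
                                  seed = 7))
clr_fit(co, "exposed")
#> Conditional logistic regression (300 matched sets, 745 subjects)
#> # A tibble: 1 × 8
#>   term    estimate std.error    or conf.low conf.high statistic  p.value
#> 1 exposed    0.987     0.161  2.68     1.96      3.68      6.13 9.00e-10
```

The generator's conditional-likelihood estimand is the specified log odds
ratio (here ln 2.75 ≈ 1.01); the fit recovers OR 2.68 (95% CI 1.96–3.68)
on 300 sets. Expected cumulative incidence under competing mortality, from
a constant-rate table (λ = 0.01, µ = 0.02 per person-year):

```r
rates <- generate_rate_table(0.01, 0.02, age_range = c(50, 80))
expected_cumulative_incidence(rates, start_age = 57, horizon_years = 15) |> tail(3)
#> # A tibble: 3 × 4
#>       t    ci cum_mort     s
#> 1    13 0.108    0.215 0.677
#> 2    14 0.114    0.229 0.657
#> 3    15 0.121    0.242 0.638
```

The methods vignette
(`vignettes/adipocyte-morphometry-and-risk.Rmd`) documents the model
choices, tunable parameters, the synthetic generator's scope, and known
limitations.

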