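# anthrobias

Child anthropometric prevalence indicators — stunting, wasting,
underweight — are tail probabilities: the share of height-for-age (HAZ),
weight-for-height (WHZ) or weight-for-age (WAZ) z-scores below −2.
Zero-mean ("non-directional") measurement error, whatever its source —
height, weight, transcription, or age estimation — leaves a z-score
distribution's mean intact but inflates its standard deviation, and an
inflated SD moves a tail probability. `anthrobias` quantifies that
movement and turns it into a survey data-quality diagnostic for
nutrition analysts and survey methodologists working with per-child
anthropometry data, especially from low- and middle-income-country
surveys.

For z-scores Normal(μ, σ²) and cutoff T = −2, the indicator is
p(μ, σ) = Φ((T − μ)/σ). Anchored at the reference SD σ_ref = 1.0 a
carefully collected survey should show (plausibly 0.8–1.2), the
prevalence bias attributable to non-directional error is

    b(μ, σ) = Φ((T − μ)/σ) − Φ((T − μ)/σ_ref)

— positive (overestimation) for μ > −2, negative below, zero at μ = −2
regardless of σ, maximal near μ = −0.75 and μ = −3.25. The package
computes this closed form, replicates it by Monte Carlo with exact
false-positive/false-negative crossing bookkeeping, maps it over a
(μ, σ) grid, and applies it to survey files alongside age-heaping and
digit-preference diagnostics. The bias estimate is a *vulnerability*
measure; it must not be used as a correction to reported prevalence.

## Worked example

Inject unit non-directional noise into an ideal stunting distribution
(mean −1, SD 1) and watch the indicator inflate:

```r
library(anthrobias)
r <- run_injection_experiment(normal_params(-1, 1), noise_spec(1),
                              n = 500000, seed = 1)
r
#> Error-injection experiment (mean -1, sd 1, noise sd 1, n = 500000)
#>   prevalence below -2: 15.8% -> 23.9%  (net bias +8.07 pp)
#>   sample SD: 1.002 -> 1.417
#>   crossings: FP 65496, FN 25158
```

The SD inflates from 1.0 to ≈1.4 (= √2), and because false positives
(children pushed below −2 purely by noise) outnumber false negatives,
measured stunting rises from ~16% to ~24% — a +8 percentage-point bias
with no change in the population. The closed form gives the same number
without simulation, and an interval acknowledging that a clean survey's
SD could genuinely sit anywhere in 0.8–1.2:

```r
estimate_bias(-1, 1.4)
#> [1] 0.07887001
realistic_bias_range(-1, 1.4)
#> Likely prevalence bias at mean -1, sd 1.4 (refs 0.8-1.2): [+3.5, +13.2] pp
```

Assessing a collection of surveys (here synthetic ones, generated with
age heaping linked to HAZ noise) produces per-survey weighted moments,
bias estimates, heaping ratios, and the cross-survey correlation that
asks whether inflated SDs track age data quality:

```r
tabs <- generate_survey_collection(k = 21, n_children = 1000, seed = 1)
coll <- assess_survey_collection(tabs)
coll$summary[1:3, c("survey_id", "heaping_ratio", "haz_sd", "haz_bias_point")]
#>      survey_id heaping_ratio    haz_sd haz_bias_point
#> 1 synthetic-01         0.153 0.9736871   -0.004746014
#> 2 synthetic-02         0.168 0.9699164   -0.005765195
#> 3 synthetic-03         0.171 0.9762215   -0.004261290
coll$correlation
#> Pearson rho(age heaping ratio, haz weighted SD) = 0.98 over 21 surveys
```

A heaping ratio near 15% is what a uniform 0–59-month age distribution
produces; values far above it, and a strong heaping–SD correlation,
point at age estimation as the driver of SD inflation. Real survey files
are read with `read_survey()` (CSV columns exactly
`age,haz,whz,waz,wt`) and assessed the same way.

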