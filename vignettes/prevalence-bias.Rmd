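---
title: "How non-directional measurement error biases anthropometric prevalence indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How non-directional measurement error biases anthropometric prevalence indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthrobias)
```

## The model

Child anthropometric prevalence indicators — stunting, wasting,
underweight — are tail probabilities: the proportion of height-for-age
(HAZ), weight-for-height (WHZ) or weight-for-age (WAZ) z-scores below
−2. Treating a survey's z-score distribution as Normal(μ, σ²), the
indicator is

$$ p(\mu, \sigma) = \Phi\!\left(\frac{T - \mu}{\sigma}\right), \qquad T = -2 .$$

Measurement error splits into a *directional* component (shifts μ) and a
*non-directional* component: zero-mean noise from any mix of sources —
height, weight, transcription, age estimation — that leaves μ untouched
but inflates σ. If the latent z-score is ideal with SD σ₀ and the total
non-directional error has SD σₑ, the observed SD is
√(σ₀² + σₑ²): adding unit noise to a unit-SD distribution yields an
observed SD of √2 ≈ 1.4.

Because the indicator is a tail probability, SD inflation moves it. The
mechanism is visible observation by observation: noise pushes some
children across the −2 cutoff. Children spuriously pushed *below* it are
*false positives* in this framing; children spuriously pushed *above* it
are *false negatives* ([classify_crossings()] keeps the tally, and the
prevalence shift equals (FP − FN)/n by construction). When μ > −2 the
below-threshold tail is the thinner one, false positives dominate, and
prevalence is overestimated; when μ < −2 the situation mirrors and
prevalence is underestimated; at μ = −2 the two flows balance exactly
and the indicator is immune to non-directional error at any σ.

Field experience is that a carefully collected survey's z-score SD falls
between about 0.8 and 1.2; a clean survey is conventionally anchored at
the midpoint 1.0. The *prevalence bias* attributable to SD inflation is
therefore

$$ b(\mu, \sigma) = \Phi\!\left(\frac{T-\mu}{\sigma}\right)
                  - \Phi\!\left(\frac{T-\mu}{\sigma_{\mathrm{ref}}}\right),
   \qquad \sigma_{\mathrm{ref}} = 1 .$$

`estimate_bias()` evaluates this directly; `build_bias_map()` tabulates
it over a (μ, σ) grid. The surface is antisymmetric about μ = −2,
monotone in σ on either side, and its magnitude decays to zero far from
the cutoff. On the default grid the largest overestimate occurs at
μ = −0.75 and the largest underestimate at μ = −3.25, both on the upper
SD boundary:

```{r extrema}
locate_bias_extrema(bias_grid_spec())
```

Because genuine nutritional heterogeneity makes any SD in 0.8–1.2
plausible for a clean survey, `realistic_bias_range()` anchors the bias
at both ends of that range and reports an interval of likely biases
rather than a single point.

The estimate is a *diagnostic*, not a correction. It assumes (i) the
z-score distribution is adequately normal, (ii) the SD would have been
near 1.0 absent non-directional error, and (iii) directional error is
small, so the observed mean is trustworthy. Under those assumptions it
bounds how vulnerable a reported prevalence is to data-quality problems;
subtracting it from the reported prevalence would compound, not remove,
error, and the package deliberately provides no function to do so.

## Engines and numerical choices

Two engines compute every prevalence. The **closed form** (`pnorm`) is
exact and deterministic and is the default wherever a single number or a
map is reported. The **Monte Carlo** engine draws samples and counts —
the construction that makes per-observation crossing bookkeeping
possible — and is validated against the closed form cellwise within four
binomial standard errors. Conventions:

* *Threshold comparison is strict* (`z < −2`); a value exactly at the
  cutoff counts as not-below. Ties are measure-zero for continuous
  draws, and a fixed convention keeps the empirical counter
  deterministic.
* *Proportions live in [0, 1] internally*; percentages appear only in
  printed output, avoiding double-scaling.
* *All randomness is seeded.* The generator (Mersenne–Twister, inversion
  normals) is pinned and recorded in sample metadata; noise draws use a
  sub-seed derived from the experiment seed so the same base sample can
  be re-perturbed reproducibly.
* *Grid spacing.* The default map uses a mean step of 0.25 — which
  places the bias extrema −0.75/−3.25 on grid points — and an SD step of
  0.1, which places the reference anchors 0.8/1.0/1.2 on grid points.
  Both are configurable. Extremum location requires the closed-form
  engine because Monte Carlo noise can flip a near-flat argmax between
  adjacent cells.
* *Degenerate inputs* (non-positive SDs, empty samples, zero-cell grids,
  mismatched pair lengths) raise immediate errors rather than NaNs.

## Survey assessment

`read_survey()` ingests per-child CSV files with columns named exactly
`age` (months), `haz`, `whz`, `waz` and `wt` (positive survey weight).
Missing z-scores are kept as `NA` and dropped per indicator — the three
indicators typically have different missingness patterns — never
listwise. Weighted moments use expansion-weight (population) forms,

$$ \bar z_w = \frac{\sum w_i z_i}{\sum w_i}, \qquad
   s_w = \sqrt{\frac{\sum w_i (z_i - \bar z_w)^2}{\sum w_i}}, $$

with no finite-sample correction: survey weights are frequency-like, the
correction is negligible at survey sizes, and both moments are invariant
to rescaling all weights. No biological-plausibility exclusion is
applied by default — the assessment is of the distribution *as
collected* — but `plausibility_filter()` offers the WHO windows with
flag counts logged.

Two age-quality diagnostics accompany the moments. The **age heaping
ratio** is the fraction of children whose age, rounded to the nearest
month, lies within ±1 month (inclusive) of 24, 36 or 48 months —
clustering at whole years is the signature of caregiver age estimation.
Under a uniform 0–59-month age distribution the expectation is
9/60 = 15%. The 12-month cluster is excluded from the default targets
because young infants commonly fall under different survey eligibility
rules; the target set, window, and denominator are configurable, and the
ratio is defined on raw counts (weights never enter). The **digit
preference test** is a chi-square goodness-of-fit of recorded-value
digits against a uniform null — first decimal digit for heights and
weights, integer month for ages. "Simple screen" is the operative
phrase: the digit extraction and the uniform null are this package's
stated construction, and the test is flagged unreliable below 30 values.
Across surveys, `heaping_sd_correlation()` computes the Pearson
correlation between heaping ratio and HAZ weighted SD; a strong positive
value indicates SD inflation tracks age-estimation quality rather than
genuine heterogeneity.

## What the synthetic generator emulates — and what it does not

`generate_survey()` produces tables in the same five-column schema from
an explicit generative model: true ages uniform over 0–59 months;
recorded ages that with probability `heaping_fraction` snap to the
nearest of 24/36/48 (applied only to children ≥ 18 months, the group for
which whole-year estimation is typical); latent z-scores
Normal(true_mean, true_sd²) per indicator; recorded z-scores with
independent Normal(0, noise_sd²) error added; log-normal weights
normalized to mean 1; independent per-indicator missingness. Defaults
describe a clean mid-sized LMIC survey chosen once: 1000 children,
latent means −1.5 (HAZ), −0.3 (WHZ), −1.0 (WAZ), latent SD 1.0, no added
noise or heaping, weight CV 0.3, 2% missingness.
`generate_survey_collection()` builds a 21-survey set in which the HAZ
noise SD rises linearly with the heaping fraction (default
σₑ = 2·heaping over heaping 0–0.5, spanning observed HAZ SDs of about
1.0–1.4), planting the positive heaping–SD association the cross-survey
correlation should detect.

The generator validates the machinery, not the world. Real heaping comes
from caregiver estimation with idiosyncratic rounding, not a clean snap;
real z-scores can be skewed or heavy-tailed; real designs have household
and cluster structure that the independent log-normal weights ignore;
and the link between heaping and HAZ noise is a modeling convenience for
property tests, not an empirical claim. Passing parameter-recovery tests
therefore demonstrates that the estimators and the bias relationship are
implemented correctly — not that any particular real survey satisfies
the normality and clean-mean assumptions.

## Problem sizes and validation

The package's own validation uses the closed form as the oracle for
every Monte Carlo path. Test problem sizes were chosen as the smallest
that keep four-standard-error checks sharp: 20,000–50,000 draws per
simulated distribution, 500,000 (the headline experiment size) for the
SD-inflation check, grids of a few hundred cells, and synthetic surveys
of 300–10,000 children. The 21-survey case-study reproduction requires
the original per-survey data, which must be obtained separately and
placed under `inst/extdata/s1-dataset/`; all other checks are fully
self-contained.

## Known limitations

Normality is assumed throughout; skewed or kurtotic z-score
distributions are out of scope, as is computing z-scores from raw
measurements against growth standards (inputs are already z-scores).
Directional error is representable (`noise_spec(error_mean = )`) but the
bias map excludes it by assumption. No design-based confidence intervals
are computed for survey prevalences. And once more: the bias estimate
should never be used to correct a reported prevalence.
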