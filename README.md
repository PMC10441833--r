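# lgentropy

Quantifying myocardial tissue heterogeneity on late gadolinium
enhancement (LGE) cardiac MR, and testing whether that heterogeneity
predicts adverse outcomes.

In hypertrophic cardiomyopathy the myocardium is rarely a clean split of
"normal tissue" versus "bright focal scar": diffuse micro-fibrosis,
perivascular fibrosis and interstitial remodelling spread pixel signal
intensities over a wide range that threshold-based scar metrics ignore.
**LV entropy** summarises that spread in one number: the Shannon entropy
of the binned probability distribution of myocardial pixel intensities,

```
H = − Σᵢ pᵢ log₂ pᵢ        (bits; 0·log 0 := 0)
```

where `pᵢ` is the fraction of myocardial pixels (blood pool excluded)
falling in intensity bin *i*. A perfectly homogeneous myocardium has
`H = 0`; a myocardium whose intensities fill all `B` bins evenly attains
the maximum `log₂ B`. Alongside it the package implements the
conventional **FWHM scar extent** (pixels at or above half of the
maximal myocardial intensity, as % of myocardium) and the full
prognostic workflow used to evaluate such imaging markers:

* seeded **synthetic data** — short-axis ring phantoms with controllable
  heterogeneity, focal scar and Gaussian/Rician noise, plus simulated
  cohorts whose event hazard rises with entropy under exponential
  proportional hazards with independent censoring;
* **survival statistics** — group comparison, Pearson correlation,
  Kaplan–Meier with median dichotomization, log-rank, univariate →
  multivariable Cox selection (p < 0.1 rule, tolerance/VIF collinearity
  screen), Harrell C-index, continuous NRI and IDI with bootstrap CIs,
  and ICC for observer agreement;
* an **end-to-end pipeline** (`runStudy()` / `renderReport()`, with a
  thin command-line wrapper in `inst/cli/lgee.R`) producing
  reproducible CSV report tables.

It is aimed at imaging researchers who want a tested, reproducible
reference implementation of the entropy statistic and its outcome
analysis, without access to patient data.

## Worked example

```r
library(lgentropy)

## render a phantom: ring myocardium, blood pool, 15% scar sector
img <- generatePhantom(phantomSpec(scarFraction = 0.15, seed = 42))
img
#> PhantomImage 128 x 128, spacing 1.40 mm/px
#>   myocardium 1564 px | blood pool 1264 px | scar 235 px

entropyFromImage(img)
#> LV entropy: 5.5290 bits (1564 pixels, 128 bins, shannon formula)

fwhmLge(img, gate = "remote_sd")
#> FWHM LGE extent: 15.41% (threshold 156.53, remote gate applied)

## simulate a cohort and run the variable-selection workflow
cohort <- generateCohort(cohortSpec(seed = 42))
sel <- selectMultivariable(cohort, c("age", "la_diam", "lge_pct", "entropy"),
                           endpoint = "secondary")
sel$fit
#> Cox model (secondary endpoint): 337 subjects, 28 events
#>           coef     se    HR             CI       p
#> entropy 1.3222 0.4883 3.752 (1.441, 9.769) 0.00677

modelImprovement(cohort, baseCovariates = c("age", "la_diam", "lge_pct"),
                 addedCovariate = "entropy", endpoint = "secondary",
                 seed = 1)
#> C-index: base 0.574 -> extended 0.649
#> NRI 0.632 (0.278, 0.989); IDI 0.019 (0.004, 0.035); 24-month horizon
```

The entropy of 5.53 bits sits in the clinically reported 5.5–6.5 range
for a 128-bin histogram; the FWHM extent recovers the 15% scar sector
(235/1564 ≈ 15.0%). In the simulated cohort, entropy survives the
p < 0.1 univariate gate, carries a hazard ratio of 3.75 per entropy
unit, and adding it to the base risk model (age, LA diameter, LGE%)
raises the C-index and yields positive NRI/IDI — the qualitative
behaviour expected when entropy truly drives the hazard.

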