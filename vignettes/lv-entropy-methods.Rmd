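---
title: "LV entropy from LGE imaging: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LV entropy from LGE imaging: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgentropy)
```

## The statistic

LV entropy treats the myocardium on a late gadolinium enhancement (LGE)
image as a bag of pixel intensities. The epicardial/endocardial contours
define the myocardial mask; the blood pool is excluded because its
uniformly bright signal would dominate the histogram. Intensities are
pooled over all short-axis slices (one entropy value per subject, not a
per-slice average), binned into $B$ equal-width bins spanning the
myocardial min–max range, and summarised as Shannon entropy

$$H = -\sum_{i=1}^{B} p_i \log_2 p_i, \qquad 0 \log 0 := 0,$$

in bits. $H$ is zero exactly when one bin holds all mass (a perfectly
homogeneous myocardium) and attains $\log_2 B$ exactly when all bins are
equally occupied. Because the bin edges are derived from the data's own
range, $H$ is invariant to any positive rescaling of the intensities —
the property that makes the statistic comparable across scanners with
arbitrary signal scaling — and it is trivially invariant to pixel order.

### Why not $-\sum p_i \log(1-p_i)$?

A variant of the formula with $\log(1-p_i)$ in place of $\log p_i$
circulates in parts of the applied literature. It is not an entropy: it
diverges as any $p_i \to 1$, so a homogeneous image maps to infinity
rather than zero, contradicting the zero-entropy property that motivates
the measure and breaking the $[0, \log_2 B]$ bounds. We implement
Shannon entropy as the default and keep the variant available behind
`computeEntropy(..., formula = "printed")` for comparison; it is never
used elsewhere in the package.

### Numerical choices

* **Bin count** (`nBins`, default 128): the literature rarely states the
  bin count used. With 128 bins the entropy of a realistically
  heterogeneous myocardium lands on a 0–7 bit scale, consistent with
  clinically reported values around 5.5–6.2 bits. Absolute entropy
  values are *not* comparable across bin counts or binning schemes, only
  within a fixed pipeline; this is an inherent limitation of the
  statistic, not of the implementation.
* **Log base** (default 2, i.e. bits): configurable; recorded in every
  `EntropyResult` so results are self-describing.
* **Constant sample**: a zero-range sample cannot define equal-width
  bins, so all mass is assigned to a designated first bin over a
  unit-width surrogate range. This makes a homogeneous phantom flow
  through the full pipeline to entropy exactly 0 instead of erroring.
* **Masks** are half-open pixel-index sets; no sub-pixel contour
  interpolation is attempted (manual tracing is out of scope).

## FWHM scar quantification

The full-width-at-half-maximum rule thresholds at half of the maximal
myocardial intensity and reports the hyperenhanced fraction as a
percentage. Applied verbatim to a scar-free myocardium it labels nearly
everything (all pixels sit near the maximum), so cohort-level runs apply
a remote-reference gate first: the maximum must exceed the mean of the
lowest-intensity tertile (the "remote" myocardium) by `gateK` (default
5) of that tertile's SDs, otherwise the scan is called scar-free. The
gate reliably rejects homogeneous or near-homogeneous myocardium; it is
not a noise-calibrated detector — the remote tertile's SD is compressed
by the tail truncation, so strong diffuse heterogeneity without focal
scar can still pass the gate. Unit-level calls default to the bare
definition (`gate = "none"`), matching the textbook formula.

## What the generators simulate

**Phantoms** (`generatePhantom`) are short-axis rings: blood pool inside
`innerRadius` at a fixed bright intensity (2.5× the myocardial base, as
blood is hyperintense on LGE), myocardium between the radii with
intensities $\mathcal N(\mathrm{base}, \sigma)$ truncated at 0, and a
scar occupying a contiguous angular sector (the focal morphology the
FWHM rule assumes; a `scattered` mode exists) at
`base × scarIntensityMultiplier`. Noise — Gaussian, or Rician because MR
magnitude images are Rician — is applied last; Gaussian is the default
for analytic transparency. Defaults (base 100, σ = 20, 10% scar at 3×,
noise SD 5, 1.4 mm pixels) put the 128-bin entropy in the clinical
range. What phantoms do **not** emulate: partial-volume edges, surface
coil bias fields, motion artefact, contrast kinetics, or anatomically
realistic scar geometry. Tests passing on phantoms therefore validate
the *statistics*, not robustness to real acquisition physics.

**Cohorts** (`generateCohort`) draw per-subject entropy
$\mathcal N(\mu, s)$ and give each subject an exponential event time
with hazard

$$\lambda(e) = \lambda_0 \exp\{\beta\,(e - \mu)\},$$

independent exponential censoring truncated at the administrative
follow-up limit, and auxiliary covariates (age, LA diameter, LGE%)
drawn correlated with entropy and conditionally independent of each
other given entropy. The exponential proportional-hazards generator is
the simplest one whose true coefficient $\beta$ is *exactly* the Cox
estimand, which is what makes parameter-recovery simulations a clean
bias check. Defaults emulate a single-centre hypertrophic
cardiomyopathy cohort: $n = 337$, entropy $5.67 \pm 0.42$ bits,
$\beta = 1$ per entropy unit, $\lambda_0 = 0.004$/month, censoring
0.02/month, 48-month horizon — together giving roughly 10–15% composite
events and a median follow-up near two years. The composite
("secondary") endpoint always contains the primary (heart-failure
readmission) events; a `primaryEventFraction` of 0.75 reflects HF
readmissions dominating such composites. For speed, entropy is
simulated directly rather than measured from a rendered phantom per
subject; an end-to-end `phantomPerSubject` mode exists (off by default)
that renders an image per subject, measures entropy and FWHM LGE% from
it, and then simulates outcomes from the *measured* entropy.

## The outcome workflow

`runStudy()` chains the stages in the conventional order: baseline
comparison of subjects with and without composite events (Welch t /
chi-square); Pearson correlations of entropy with the other LV
parameters; median dichotomization of entropy (ties to the high group,
the convention used when a cohort is split at a published median) with
Kaplan–Meier curves and log-rank tests per endpoint; univariate Cox per
candidate with retention at p < 0.1; a tolerance/VIF collinearity
screen (pass: Tol > 0.1 and VIF < 10) on the retained set, dropping the
worst offender with a warning if it fails; one multivariable model per
endpoint; and finally the incremental value of entropy over the base
risk model (age + LA diameter + LGE%) via Harrell C-index, continuous
NRI and IDI.

Design decisions where the field leaves room:

* **Cox ties**: Efron (standard for month-resolution data); Breslow
  behind a flag. Wald p-values and $\exp(\beta \pm 1.96\,\mathrm{se})$
  CIs, matching the HR-with-CI presentation convention.
* **NRI flavour**: continuous (category-free), since no established
  risk categories exist for this marker; categorical NRI would require
  caller-supplied thresholds.
* **Risk scale**: C-index uses the linear predictor (rank-invariant);
  NRI/IDI use predicted event probabilities at a fixed 24-month horizon
  (a typical median follow-up) from the Breslow baseline cumulative
  hazard, $1 - \exp\{-\hat H_0(t)\,e^{\mathrm{lp}}\}$.
* **Bootstrap CIs**: percentile, 1,000 replicates by default, seeded;
  resamples with no events (or no non-events) are dropped rather than
  redrawn.
* **ICC**: two-way, absolute-agreement, single-measure — ICC(A,1) —
  assembled from the two-way ANOVA mean squares, the standard choice
  for intra-/inter-observer agreement of a continuous measurement.
* **Sub-seeds**: every pipeline stage derives its stream as
  `subSeed(globalSeed, stageName)`, so adding a stage never perturbs
  the randomness of earlier stages and one seed reproduces
  byte-identical report files.

## Simulation sizes and calibration checks

The test suite checks estimator calibration at sizes chosen to keep
Monte-Carlo error well inside each tolerance band: parameter recovery
uses 50 cohorts of n = 500 with true log-HR 0.5 and **no censoring**
(the bias check should be dominated by estimator variance at 500 events
per fit, not by censoring-inflated noise); the log-rank size and the
p < 0.1 noise-retention rate use 500 replicates of n = 200 cohorts at
the default ~12% event rate, judged against ±3 binomial SDs of the
nominal 5% and 10%. Oracle-equivalence checks (brute-force pair
enumeration for the C-index, grid search of a hand-coded partial
likelihood for Cox, hand product-limit for KM, per-pixel bin tallying
for entropy) run on deliberately tiny inputs where exhaustive
computation is exact.

## Limitations

* Masks are inputs (or synthesized); no automatic segmentation, no
  DICOM ingestion (NIfTI and CSV only), no T1 mapping/ECV, no
  17-segment regional analysis.
* Absolute entropy values depend on the binning pipeline and are not
  transferable across implementations that do not document bin count
  and log base.
* The simulated cohorts obey proportional hazards exactly; none of the
  model-misspecification behaviour of real cohorts (time-varying
  effects, competing risks, informative censoring) is represented, so
  passing calibration tests here says nothing about robustness to those
  violations.
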