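---
title: "Methods: scoring and validating implicit activity preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating implicit activity preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatools)
```

## The task and its score

The Activity Preference Assessment presents a child with every unordered
pair of 16 leisure activities — 8 sedentary, 8 physical — and asks them to
pick, as quickly as possible, the one they most want to do. That yields
120 unique pairs (64 cross-category, 28 within-sedentary, 28
within-physical), administered as 4 blocks of 30 with breaks. Only the
cross-category pairs carry information about the sedentary-versus-physical
contrast, and only they are scored.

The implicit bias score combines *which* category won with *how fast* it
won. For `N` responded cross-category trials,

$$IW_{SED} = WIN_{SED}\frac{RT_{ALL}}{RT_{SED}} -
             WIN_{PA}\frac{RT_{ALL}}{RT_{PA}},\qquad
  IW_{PA} = -IW_{SED},\qquad raw = IW_{SED} - IW_{PA}.$$

The intuition: a win achieved faster than the respondent's overall pace
(`RT_category < RT_ALL`) is up-weighted, because fast forced choices
signal stronger implicit wanting. The score is antisymmetric by
construction — relabeling the two categories exactly negates it — and
invariant to a common rescaling of all reaction times, since only RT
ratios enter.

### Normalization and numerical choices

The raw score spans approximately $[-2N, +2N]$, while the published score
range is $-100\ldots+100$. We scale by $100/(2N)$, the mildest
transformation that maps the all-one-category, equal-pace respondent to
exactly $\pm 100$ and the balanced equal-pace respondent to 0. Because the
RT ratios can exceed 1, the scaled score can overshoot the nominal range
slightly; we clip to $[-100, 100]$ and set a `clipped` flag rather than
silently rescaling. Three further conventions:

* **Zero-win terms.** If a category never won, its RT mean is undefined;
  the corresponding term contributes exactly 0 and the undefined mean is
  never evaluated.
* **RT central tendency** is the arithmetic mean over responded
  cross-category trials. The defining formulas say only "reaction time";
  the arithmetic mean is the plainest reading and keeps the exact-anchor
  algebra (±100) intact. Trimming beyond the cleaning window below is
  deliberately not applied.
* **Non-responses** are excluded and `N` reduced accordingly; a log with
  zero responded cross-category trials has no defined score and errors.

Trial cleaning (`clean_trials()`) drops reaction times outside
[0.2 s, 10 s] by default — below ~200 ms a response cannot reflect the
stimulus; above 10 s the "as quickly as possible" instruction has clearly
lapsed. Both bounds are configurable and a no-cleaning mode exists; the
cleaning thresholds are pipeline plumbing, not part of the score's
definition.

## Schedule construction

Two aspects of the task's trial order are not fixed by its published
description, so the generator makes them explicit, seeded choices:

* **Block allocation** is a uniform random partition *stratified by pair
  type*, giving every block 16 cross-category + 7 + 7 within-category
  pairs. Stratification prevents a pathological block (e.g. all
  within-category, hence unscoreable) and keeps block composition
  comparable; we document this as our choice, not an inference about the
  original software's behavior.
* **Screen side** is randomized with the sedentary-on-left count balanced
  to within one trial across cross-category pairs, removing side bias as
  a confound in simulated data.

Identical seeds reproduce schedules byte-for-byte.

## The synthetic respondent

No generative choice model is published for this task, so the simulator
uses the simplest mechanism that makes both win counts and RT ratios
informative — i.e., that exercises every term of the score:

* each activity has a latent utility; sedentary utilities are drawn
  around $+\theta/2$, physical around $-\theta/2$ (`utility_sd = 0.3`
  within-category spread), so $\theta$ = mean sedentary − mean physical
  utility is the latent sedentary preference;
* the left option is chosen with probability
  $\mathrm{logit}^{-1}(\beta\,(u_L - u_R))$ (default sensitivity
  $\beta = 4$);
* reaction time is $rt_{base}\,e^{-rt_{slope}\,|u_L - u_R|}$ times
  lognormal noise (defaults 1.2 s, 0.3, SD 0.25): easy choices are
  faster, which is exactly the regularity the RT weighting rewards;
* VAS liking/wanting are affine maps of utility ($50 + 25u$) plus noise,
  clipped to 0–100.

The RT defaults give ~1 s median responses, consistent with a task a
child completes in about 10 minutes. Under these defaults the computed
bias recovers the latent $\theta$ with Spearman correlation above 0.9
across 200 simulated respondents — the mechanism is identified, not
merely plausible.

## The synthetic cohort

The cohort generator draws the validation measures from a multivariate
normal per sex stratum, with marginal means/SDs matching the validation
sample's descriptives (bias 18.8 ± 46.2; free-play percent sedentary
57 ± 36; daily sedentary 151 ± 49 min; daily MVPA 45 ± 17 min; VO2peak
40.5 ± 8.1 mL/kg FFM/min; BMI z 0.69 ± 1.24; percent body fat
31.5 ± 9.0). Fat mass index descriptives are not reported with the rest;
we use 7.5 ± 3.6 kg/m², a plausible value for a mixed-weight-status
pediatric sample with ~31% mean body fat. The latent correlations encode
the reported associations (free play 0.38, VO2peak −0.52, BMI z 0.35,
percent body fat 0.43, fat mass index 0.44, retest 0.59); the
accelerometer MVPA association is sex-dependent (−0.41 in girls, 0 in
boys), implemented by giving each sex stratum its own correlation matrix.
Cells among the validation measures themselves are unreported; we filled
them with values typical of pediatric body-composition/fitness data
(adiposity indices intercorrelated 0.80–0.90, fitness negatively related
to adiposity ≈ −0.5) and verified positive definiteness of both
per-stratum matrices, which `cohort_spec()` re-checks on every
construction and reports the offending eigenvalue when violated. The
second bias administration relates to other measures only through the
first (its cross-correlations are attenuated by the retest correlation).

Two deliberate simplifications, and what they imply about test coverage:

* **Margins are Gaussian and unclipped.** Simulated free-play percentages
  can fall outside [0, 100] and bias outside ±100; clipping would bend
  the correlations away from their targets, and the generator's job is
  distribution-correctness, not per-value physical plausibility. Tests
  that pass on these cohorts demonstrate the *statistics layer* recovers
  known targets; they do not validate distributional shape against real
  children.
* **Covariates are independent of the measures** (age uniform 8–17,
  50/50 sex, 42% white / 58% racial-ethnic minority). The study found
  its associations independent of these covariates, so the generator
  builds that independence in; consequently adjusted and raw correlations
  coincide in expectation, and the covariate-adjustment code is checked
  for correctness (against projection oracles) rather than for
  confound removal on realistic confounding.

## Measurement rules

* **Accelerometry.** Counts per 15-s epoch are classified by the
  pediatric Evenson cut-points — sedentary 0–25, light 26–573, moderate
  574–1002, vigorous ≥ 1003 CPE, inclusive bounds partitioning the
  non-negative integers. Daily summaries count awake-wear epochs only
  (0.25 min each); wear/sleep annotation is consumed as an input column
  (non-wear detection is a distinct published algorithm, out of scope
  here). A measurement period is valid with ≥ 4 days of ≥ 10 awake-wear
  hours including ≥ 1 weekend day; all three thresholds are arguments.
  Percent-time metrics are of awake wear, not of 24 h.
* **Free-choice play.** 15-s interval codes use a three-level taxonomy
  {SEDENTARY, STANDING, MOVING}, the minimal refinement of the defining
  rule "sedentary = not standing or moving"; only the
  sedentary/non-sedentary split feeds the headline percent-sedentary
  metric. Inter-rater agreement is plain percent agreement.
* **Fitness.** VO2peak attainment requires ≥ 2 of: VO2 plateau (change
  < 2.1 mL/kg/min across an increase in workload, evaluated between
  consecutive stages with increased watts), RER ≥ 1.0, HR ≥ 90% of
  predicted maximum, RPE ≥ 19. The predicted-HR model is unstated in the
  source protocol; we default to the pediatric-appropriate
  $208 - 0.7\,\mathrm{age}$ and accept any user function. A criterion
  whose channel is missing is reported as not evaluable rather than
  failed. VO2peak is expressed per kg fat-free mass because adiposity
  confounds weight-relative fitness in children.
* **Body composition.** Percent body fat $= 100\,\mathrm{fat}/\mathrm{weight}$;
  fat mass index $= \mathrm{fat}/\mathrm{height}^2$; weight-status classes
  use the BMI-percentile cut-offs (≥ 85 overweight, ≥ 95 obesity,
  ≥ 120% of the 95th-percentile BMI severe). The underweight bound is
  unstated in the source; we default to percentile < 5, configurable.
  Growth-reference percentiles arrive as inputs — computing them is a
  separate published reference, not reimplemented here.
* **Questionnaires.** The MFQ (13 items, 0–2, summed 0–26) ships fully
  scoreable. The PSDQ-S and BES ship as *skeletons*: item counts,
  response ranges and subscale names are declared, but the item-to-
  subscale keys belong to the instruments' own publications and are
  user-supplied configuration; scoring an unconfigured subscale is an
  explicit error, never a guess. The missing-data rule (score a subscale
  when ≥ 80% of items are present, prorated) is our convention and is
  configurable.

## Validation statistics

Pearson correlations use pairwise deletion and the t transform for
p-values. Partial correlations residualize both variables on the covariate
design (with intercept) by least squares and correlate the residuals with
$df = n - 2 - k$; race/ethnicity defaults to the binary white vs
racial/ethnic-minority coding used in the study's own contrast, and any
factor covariate is dummy-coded. Test–retest reliability is the
**single-measure, absolute-agreement, two-way mixed ICC**,

$$ICC(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with F-based 95% confidence limits (Satterthwaite degrees of freedom).
With two sessions the published reliability is consistent with the
single-measure form, which we implement as primary; the average-measure
form is not offered. Group contrasts use the pooled-variance t-test. No
multiple-testing correction is applied anywhere, matching the source
analysis. Missingness: pairwise for correlations, listwise for the ICC.
The report runner treats every cell independently — a failing cell yields
`NA` plus the error message, never an aborted grid.

## Problem sizes and reproducibility

The recovery simulations use the study's own sizes: retest reliability is
checked as the mean ICC over 1,000 simulated cohorts of n = 60 × 2
sessions; validity recovery as 1,000-replicate means at n = 60 (adiposity,
free play) and n = 30 (the fitness subsample); parameter recovery over 200
respondents × 120 trials. These sizes make the Monte-Carlo error of the
replicate means (≈ 0.003–0.004 on a correlation) an order of magnitude
smaller than the recovery tolerances, so a failure would indicate a
defect, not noise. All randomness flows through explicit integer seeds;
every simulation is bit-reproducible given its seed.

## Known limitations

* The normalization constant $100/(2N)$ reproduces the published score
  range, but the original scoring script is unpublished; if it surfaces
  with a different constant, scores differ by a fixed scale factor only.
* The respondent model is a stand-in: it generates the regularities the
  score exploits (category-consistent choices, gap-dependent speed), not
  a fitted account of children's decision processes, and the package
  deliberately offers no model fitting.
* The cohort generator reproduces pairwise correlations and margins; the
  true joint distribution of the validation measures is unknown beyond
  those, and the Gaussian choice is a modeling convenience.
* Within-category choice structure (e.g. preferences among the 8 physical
  activities) is logged but unmodeled and unscored.
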