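---
title: "Estimating MCIDs for COPD health-status instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating MCIDs for COPD health-status instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcidpr)
```

## The problem

Health-status questionnaires — the Clinical COPD Questionnaire (CCQ, total
score 0–6), the COPD Assessment Test (CAT, 0–40) and the St George's
Respiratory Questionnaire (SGRQ, 0–100), all scored so that higher is worse —
are primary outcomes in pulmonary rehabilitation. A statistically significant
change on any of them is not automatically a change the patient notices. The
*minimal clinically important difference* (MCID) is the smallest score change
patients perceive as beneficial, and it is the yardstick against which
treatment effects should be read. No single estimation method is accepted as
a gold standard, so `mcidpr` implements the full battery of standard
approaches and pools them:

**Anchor-based methods** tie the questionnaire change between the start (T0)
and end (T1) of rehabilitation to an external marker of change.

* *Patient-referencing*: a global rating of change (GRC, −7..+7) is collected
  at T1. Ratings of 0/±1 mean no or hardly any change, ±2/±3 minimal
  clinically relevant change, ±4/±5 moderate and ±6/±7 major change. The MCID
  is the mean change score of patients rating themselves +2 or +3. Within
  each stratum the change is tested with a paired *t*-test when the sample
  passes a Shapiro–Wilk normality gate (α = 0.05) and a Wilcoxon signed-rank
  test otherwise; rank-branch intervals are Hodges–Lehmann, and the branch is
  labelled in the output because the construction matters for
  interpretation.
* *Criterion-referencing*: an exacerbation during rehabilitation is taken as
  an unambiguously relevant health event. The MCID is the difference in
  *baseline* score between patients with and without such an event. Groups
  are compared with a Welch *t*-test on the normal branch (the groups are
  far from equal-sized, so a pooled-variance *t* would be inappropriate) and
  a Mann–Whitney U otherwise; on the rank branch the reported interval
  around the mean difference is a normal approximation so that the point
  estimate always lies inside its own CI, and this is flagged in the output.
* *Questionnaire-referencing*: one instrument's change is anchored on
  another instrument with an established MCID. An anchor is eligible only
  when the change-score correlation is at least 0.50. Three sub-methods are
  run per (target, anchor) pair: an OLS regression of target change on
  anchor change evaluated at the anchor's MCID (with the confidence band of
  the mean prediction); the mean target change among patients achieving vs
  failing the anchor's MCID (achievement is `change <= -anchor MCID`,
  boundary inclusive — the closure is not fixed by convention, so it is a
  package decision, applied consistently); and a ROC analysis using anchor
  achievement as the state variable and the target improvement magnitude as
  the classifier score.

**Distribution-based methods** use only the statistical variability of the
scores: the standard error of measurement SEM = σ~x~·√(1 − r~xx~), where σ~x~
is the *baseline* standard deviation and r~xx~ the test–retest reliability
(ICC) taken from the literature (0.94 CCQ, 0.80 CAT, 0.91 SGRQ — ICC cannot
be estimated from two-timepoint intervention data, where change is expected);
1.96·SEM; and half the standard deviation *of the change score*. The pairing
of inputs — baseline s.d. for the SEM, change s.d. for 0.5 s.d. — is fixed by
the defining formulas and verifiable against the reference values the package
tests reproduce.

**Pooling.** For each total score the five method families
(patient-referencing, criterion-referencing, a questionnaire-referencing
summary, SEM, 0.5 s.d.) enter with weight 1/5 each. Domain scores (CCQ
symptoms/functional/mental, SGRQ symptoms/activities/impact) have only the
two subject-level anchors, and the criterion estimate enters the average only
when its group difference is significant. The collapse of the six
questionnaire-referencing estimates (two anchors × three sub-methods) into
one summary value is not standardised anywhere; the default is the mean of
the revised-anchor pass, and `mcid_config(qr_summary = )` exposes the
alternatives, because reasonable choices differ and the pooled total moves by
a few hundredths of a point between them.

## ROC cut-point selection

Candidate cut-offs are the midpoints between consecutive distinct observed
scores, plus one cut-off below the minimum and one above the maximum, so
sensitivity and specificity are well defined at ties and the curve always
reaches (0,0) and (1,1). A subject is classified improved when the
improvement magnitude is at least the cut-off. The AUC is the trapezoid over
the resulting curve (equal to the tie-corrected Mann–Whitney statistic; the
test suite checks both identities). The selection rule: among cut-offs with
sensitivity and specificity both ≥ 0.70, take the one with maximal
sensitivity (ties: maximal Youden J, then the smaller cut-off). When no
cut-off reaches the joint floor, the maximal Youden J is used, preferring
sensitivity ≥ specificity on ties, and the result is marked
`selection_rule_satisfied = FALSE` rather than silently reported.

## Iterative anchor revision

The questionnaire-referencing pass is run twice. The first pass uses the
literature anchor MCIDs (CCQ 0.40, CAT 2.00, SGRQ 4.00). When the package's
own cross-method estimates disagree with the literature, a second pass uses
revised anchors: the mean of the patient-referencing, criterion-referencing,
SEM and 0.5 s.d. estimates per instrument, rounded to reporting granularity
(0.05 points for CCQ, whole points for CAT and SGRQ). The 1.96·SEM is
excluded from this average: it is an interval-width criterion rather than a
point criterion, and including it would pull the revised anchors above every
anchor-based estimate. Under the default synthetic calibration the revised
anchors come out at CCQ 0.50, CAT 3.00 and SGRQ 7.00.

## The synthetic cohort generator

The study data this package is designed around are not deposited, so
`simulate_cohort()` provides a cohort with the same statistical skeleton at
any size; `cohort_params()` defaults encode the emulated study conditions
(n = 451; the baseline/change moments of all nine scales; change-score
correlations 0.63/0.54/0.59; GRC rank correlations 0.29/0.23/0.30; GRC class
frequencies 12/98/196/123/25; 10% exacerbation prevalence with baseline
elevations 0.62/2.96/9.28 points; 1/2/4 missing T1 questionnaires).

The construction is Gaussian-copula-style, chosen because only moments and
correlations of the real cohort are reported — heavier-tailed alternatives
would be unidentifiable:

1. Baseline totals are correlated truncated normals. Baseline
   cross-instrument correlations are not reported for the emulated cohort;
   0.70 is used as a typical value for these instruments.
2. Change totals come from a correlated trivariate normal; T1 = T0 + change
   is clipped into the scale range. Clipping is not cosmetic — about 6% of
   latent CCQ T1 values fall below 0 — so the pre-clip parameters are
   recalibrated until the *post-clip* moments hit their targets: baseline
   scales by closed-form clipped-normal moments, change scales by a
   deterministic 301-point quadrature grid over the two independent latents;
   both iterate at most 20 rounds to a 1% tolerance.
3. The GRC is a latent weighted combination of the sign-flipped standardized
   change latents plus noise, with weights solved from the change
   correlation matrix so the latent correlations hit the targets (inflated
   by a fixed factor 1.08 ≈ 1/0.9549 plus a discretization allowance, tuned
   once against the generator's own rank-correlation targets). It is then
   discretized by quantile so the realized class counts match the target
   frequencies to integer rounding — guaranteeing the strata sizes of the
   patient-referencing analysis — and spread uniformly over the integer GRC
   values of each class.
4. The exacerbation flag follows a logistic model on a weighted combination
   of the baseline latents. The direction is chosen so the three induced
   per-instrument baseline shifts are proportional to their targets
   (an unweighted severity mean cannot satisfy all three), and the scale and
   intercept are solved deterministically by Gaussian quadrature and root
   finding so prevalence and shift magnitude are hit in expectation.
5. Domain scores share a 0.80 latent correlation with their instrument
   total and are calibrated marginally like the totals.
6. T1 questionnaires go missing completely at random, per instrument —
   the emulated study reports counts but no mechanism.

A fixed seed reproduces the cohort byte for byte. `calibration_report()`
pairs every target with its realized value; at n = 10,000 all moments sit
within three Monte-Carlo standard errors plus the calibration tolerance.

What the generator does *not* emulate: item-level responses (scores are
generated at scale level; item scoring is exercised separately), baseline
dependence of change (regression to the mean), any GRC–exacerbation
association beyond what the change scores induce, the one missing GRC of the
real cohort, floor/ceiling pathologies (the real CCQ mental domain shows
one; clipped normals only approximate it), and longitudinal structure beyond
two timepoints. Tests passing on synthetic cohorts therefore demonstrate
estimator correctness and calibration, not robustness to those real-data
features.

## Numerical choices and degenerate inputs

* Scores are kept at full precision; rounding to 2 decimals, half away from
  zero (matching published clinical tables; base R rounds half-to-even),
  happens only in the rounded report columns.
* Estimates are reported as improvement magnitudes; when a CI straddles
  zero, the magnitude interval starts at 0.
* Empty or one-subject strata and groups yield flagged undefined estimates,
  never silent zeros; constant samples short-circuit the normality gate with
  a degeneracy flag and zero-width intervals.
* A cohort of three subjects runs end to end, with flags where methods are
  undefined; a single achievement class flags the ROC rows instead of
  aborting the grid.
* The Shapiro–Wilk gate subsamples above n = 5000 (the test's
  implementation limit); the gate itself, its α, and both anchor thresholds
  (0.50 eligibility, 0.70 sens/spec floor) are configuration.

## Problem sizes used in the checks

The test suite exercises the generator at n = 10,000 for moment checks, 200
default-size cohorts (n = 451) for parameter recovery of the anchor
estimators, 1,000 random small instances (≤ 50 subjects) for brute-force ROC
oracle equivalence, and 2,000 simulations for CI coverage. Two reference
values reproduce only to within one unit in the last printed digit from
printed inputs (the CAT effect size 0.42 vs 0.43 and the SGRQ 0.52 vs 0.53):
both are rounding artifacts of consuming 2-decimal inputs, documented rather
than hidden.

## Known limitations

* MCIDs here are for *improvement* in moderate to very severe COPD in
  inpatient rehabilitation; deterioration MCIDs may differ and are not
  estimated (deteriorated subjects are excluded from improvement strata and
  reported separately).
* SGRQ scores are consumed as given; its proprietary item weights are not
  reimplemented.
* The GRC anchor's correlation with change scores (≈ 0.3) sits below the
  0.50 eligibility bar applied to questionnaire anchors — a known weakness
  of global ratings that the package reports but cannot repair.
* Pooling weights are equal by construction, not variance-based; the pooled
  value is a summary, not a meta-analytic estimate.
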