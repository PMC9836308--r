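---
title: "Methods: scoring and validating a brief cognitive screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating a brief cognitive screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haisac)
```

## The instrument and its scoring model

The HAI-SAC is a brief screen for staging cognitive status in suspected
Alzheimer's disease. It combines three objective memory subtests with two
informant questions:

* **CNOCD** (0--16): confrontational naming of six everyday objects, their
  colors, and one graded detail question (reading the time on a watch:
  4 points fully correct, 2 for hour and minute, 1 for minute only).
* **ML** (0--12): re-arranging the six object photos in their original
  positions; two points per correct placement.
* **RFO** (0--12): recalling two functions per object, one point each.
* **CD** (0 or 8) and **FD** (0 or 12): the informant reports whether the
  participant shows cognitive decline and whether that decline interferes
  with daily life; a *negative* report scores the points.

The objective subscore (HAI-SAC-3, 0--40), informant subscore (HAI-SAC-I,
0--20) and total (0--60) are plain sums. Lower scores indicate more
impairment, so all discrimination analyses treat the lower-scoring group
as the positive (impaired) class.

Two scoring rules required a design decision because the verbal
description and the printed subtest maxima conflict:

* **ML cap.** Two points per photo with six photos plus a two-point
  perfect bonus would allow 14 points, but the printed maximum is 12. We
  score `min(2 * count, 10)` plus a 2-point bonus only for a perfect
  six-of-six arrangement, which preserves both the per-photo rule and the
  printed bound. The consequence is that five correct placements score 10
  and the bonus only distinguishes a perfect response.
* **NPI-SB.** The neuropsychiatric inventory description multiplies
  frequency, severity *and* caregiver distress (720-point maximum), while
  its printed maximum is 144 = 12 items x 4 x 3. We compute
  `sum(frequency * severity)`; distress ratings are accepted in the
  interface but never enter the summary score.

The two CASI composites are implemented exactly as printed
(`0.5 * (short + long delayed recall) + 0.6 * recognition`;
`0.5 * (reading + writing) + 0.3 * naming + commands`), with no rounding
anywhere in the scoring layer. Watch-time grading is an enumerated input;
judging the correctness of free-text responses is out of scope.

```{r scoring-example}
score_haisac(perfect_item_record())[
  c("cnocd", "ml", "rfo", "haisac3", "haisaci", "haisac_total")]
```

## The synthetic cohort generator

No subject-level data accompany the published study, but its tables print
per-group means and SDs for every variable at the published sizes
(CU n = 133, MCI n = 231, DAT n = 397). `default_group_params()` ships
this calibration verbatim, with one repair: the printed FD row duplicates
the IADL row and contradicts the identity HAI-SAC-I = CD + FD (for CU,
2.71 + 7.79 is not 14.53), so FD is calibrated as HAI-SAC-I minus CD and
its SD as the binomial SD of a 0/12 item at the implied probability.

`simulate_cohort()` draws group-conditional normals at two fidelity
levels:

* **untruncated** -- plain normal draws. This is the calibration under
  which the published AUCs are reproduced: the Mann-Whitney AUC of two
  normal samples converges to the binormal value
  `pnorm(|mu1 - mu2| / sqrt(sd1^2 + sd2^2))`, and the printed AUCs agree
  with that formula at the printed moments to within 0.01, which is
  strong evidence the published figures are moment-consistent.
* **bounded** -- draws clipped to the instrument ranges and snapped to
  each score grid (CD to {0, 8}, FD to {0, 12}, ML to its even-score
  grid with the 12-point bonus, CDR-SB to half points, integers
  elsewhere). This mode exercises the scoring engine and produces the
  integer "a/b" cutoff rendering.

Variables are drawn independently within group unless
`within_group_correlation` is positive, in which case one shared
standard-normal subject factor is mixed into every standardized variable
-- the minimal one-parameter structure capable of mimicking the strong
between-test correlations in the published correlation table, which
prints no within-group covariance to calibrate against.

`simulate_item_cohort()` adds an item-level fidelity: per subject two
correlated latent factors generate the five standardized item scores
through a loading matrix, and the continuous targets are discretized into
valid raw responses (naming/color flags, watch grade, counts, informant
booleans). The default loadings are the published pattern (0.95/0.96/0.55
on the memory factor; 0.97 on the informant factor with the functional
item cross-loading 0.48/0.45). The inter-factor correlation is not
printed; we fix it at 0.5 because the informant factor correlates
0.46--0.55 with the cognitive tests while the memory factor correlates
0.78--0.89 with them, implying an inter-factor correlation near 0.5. This
value was chosen once, from those correlations, and is not tuned.

What the generator deliberately does **not** emulate: the skewed,
ceiling-compressed shape of real screening scores (CU cohorts pile up
near the maximum), any covariate structure (age and education are drawn
independently of the test scores), missing data, and longitudinal change.
The practical consequence is that *moment-determined* quantities (F
statistics, AUCs) reproduce, while *shape-dependent* quantities (optimal
cutoffs, sensitivity/specificity pairs) do not: under normality at the
printed moments the Youden cutoff for the total score in the CU-vs-MCI
contrast lands near 42 with sensitivity ~0.6 and specificity ~0.87,
whereas the study reports 0.87/0.58 at the same cutoff -- the printed
moments demonstrably do not determine those operating points under a
normal model. The pipeline therefore reports cutoffs and operating
points but the package only asserts AUC-level reproduction.

## Reliability and factor analysis

`reliability()` bundles Cronbach's alpha (sample variances, n-1
denominator, the conventional choice for reliability reporting), the
Kaiser-Meyer-Olkin index (partial correlations from the inverse
correlation matrix), and Bartlett's sphericity test
(`chi2 = -(n - 1 - (2p + 5) / 6) * log det R` on `p(p-1)/2` degrees of
freedom).

`efa()` implements the published extraction pipeline: iterated
principal-axis factoring followed by varimax and then promax (power 4,
the classical default; the study does not state it). Numerical choices:

* communalities initialize at the squared multiple correlations and
  iterate to a max-abs change below 1e-6;
* the iteration cap is 10000: with a weak or two-indicator trailing
  factor the communality sequence converges geometrically with ratio
  close to 1 and routinely needs several hundred to a few thousand
  cycles; each cycle is one small eigendecomposition, so the cap is
  cheap. A communality exceeding 1 is flagged as a Heywood case
  (warning, never silently clipped); a communality growing past 1.5 is
  diagnosed as a divergent Heywood case and aborts with an error,
  because the sequence then increases without bound (~1/iteration) and
  the model is inadmissible for the data;
* the default factor count is the number of eigenvalues above 1 of the
  reduced (SMC-diagonal) correlation matrix, overridable by an explicit
  `n_factors`;
* factors are ordered by variance explained (sums of squared structure
  loadings over the item count) and signed so each column's
  largest-|loading| item is positive, giving stable, testable output.

Factor scores follow the published weighted-sum rule -- per subject,
`sum(loading * item score)` -- rather than regression scores.

### What parameter recovery can and cannot show

Two facts limit how far an EFA on synthetic item cohorts can reproduce
the published loadings, and both are properties of the *problem*, not of
the implementation:

1. **The generating configuration is not identified.** With five items,
   two oblique factors and a cross-loading, the model
   `R = L Phi L' + Psi` has at least as many free parameters as
   off-diagonal moments. Running the extraction pipeline on the *exact
   population* correlation matrix implied by the default specification
   returns a different, equally exact solution (CD pattern ~0.82,
   communality ~0.59, factor correlation ~0.67 instead of the generating
   0.97/0.94/0.50); maximum-likelihood factoring agrees with that
   alternative. No estimator can recover parameters the correlation
   matrix does not pin down. What *is* recoverable -- and what the test
   suite verifies -- is the population promax solution: at n = 5000 the
   sample pattern matches it within 0.10 entrywise.
2. **Dichotomization attenuates.** The informant items are observed as
   binaries, and the Pearson correlation of a thresholded normal with
   any other variable is the latent correlation times
   `dnorm(tau) / sqrt(p (1 - p))`, at most 0.798 and far less for
   extreme prevalences (about 0.57 at the pooled no-decline prevalence
   of ~0.10). A 0.97 loading on a binary item is therefore invisible to
   correlation-based EFA regardless of sample size; on the re-scored
   battery the two-factor iteration in fact Heywood-diverges. The same
   attenuation, combined with the dominant pooled severity gradient that
   draws all five items onto one factor, is why the default synthetic
   cohort yields a one-factor solution where the real data yielded two:
   real informant responses are not thresholded Gaussians, and their
   dependence structure is exactly the information the published tables
   do not carry.

The suite encodes both limits: the attenuation law is asserted
quantitatively, estimation consistency is asserted against the
identifiable estimand, and the literal published-loading recovery checks
are retained and allowed to fail as documentation of the boundary.

## Discrimination analyses

`empirical_roc()` sweeps thresholds over the pooled unique scores with
the screening orientation (positive call: score at or below the
threshold). The AUC is the Mann-Whitney estimate with ties counted one
half, verified in the tests against exhaustive pair enumeration. The
optimal cutoff maximizes Youden's J = sensitivity + specificity - 1;
ties are broken toward the lowest cutoff (highest specificity), the
conservative choice for screening referral, and integer-scale cutoffs
are rendered in the conventional "a/b" bracket form. Confidence
intervals use the DeLong placement-value variance with a normal
approximation clipped to [0, 1].

`delong_paired_test()` compares two AUCs measured on the same subjects
via the placement-value covariance estimator and a chi-square(1)
statistic; it is the standard correlated-ROC method consistent with the
chi-square statistics the study reports, whose exact SAS procedure is
not specified. Following the study, the three diagnostic contrasts reuse
subjects and no multiplicity correction is applied to AUC comparisons.

`binormal_auc()` provides the analytic companion used for calibration
(see above).

## Group comparisons

`anova_from_summary()` reconstructs the exact one-way F test from group
sizes, means and SDs -- printed SDs are treated as sample (n-1) SDs,
which reproduces the published F values to within printed rounding --
and is proven in the tests to coincide with the raw-data ANOVA to 1e-9
on exact-moment reconstructions. Pairwise contrasts are pooled-variance
t tests flagged at the published corrected alpha of 0.017. The sex-ratio
comparison is Pearson's chi-square without continuity correction.
Correlation strength bands follow the published convention (moderate at
|r| >= 0.4, strong at |r| >= 0.7), with unadjusted p-values.

`steiger_dependent_correlation_test()` compares two overlapping
correlations (education against two tests on the same subjects) using
Fisher transforms with the back-transformed average correlation in the
covariance term. Worth noting: the study's printed post-hoc Z values are
closer to what an *independent*-samples Fisher z test yields than to the
dependent-correlation statistic; the package implements the proper
dependent test and does not assert the printed values.

## Problem sizes and determinism

Every simulation is driven by an explicit integer seed; library calls
without one draw a seed from the clock and record it in the output
attributes, and the file-level interfaces require a seed so outputs are
byte-reproducible. The test suite uses cohorts at the published sizes
(761 subjects) for pipeline checks, n = 5000 single-group cohorts for
factor-recovery checks, 200 replicate cohorts for the AUC reproduction
(standard error of each mean AUC below 0.002), and 300 replicates for
the DeLong power check at n = 400 per group.

## Known limitations

* Untruncated draws can fall outside instrument ranges by design;
  bounded mode is the one to use when valid score grids matter.
* The generator's independence (or single-shared-factor) structure
  within groups is a modeling convenience; real within-group covariance
  is unknown.
* Optimal cutoffs and operating points from synthetic cohorts describe
  the normal model, not the study population (see above).
* MMSE here is simply a provided column, as the extraction mapping from
  the longer instrument is not published.
* Clinical staging criteria, administration-time analyses and
  caregiver-distress-weighted symptom scores are out of scope.
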