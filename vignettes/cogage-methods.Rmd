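---
title: "Methods: cohort classification and multimodal group comparison in cogage"
author: "cogage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort classification and multimodal group comparison in cogage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogage)
```

## The problem

Some older adults keep cognitive abilities comparable to middle-aged
adults. Identifying such a "successful cognitive aging" (SCA) group in a
large biobank-style cohort, and asking which brain measurements and
lifestyle indicators distinguish it, requires three statistical
components: a defensible composite cognitive score and selection rule, a
confound-aware treatment of image-derived phenotypes (IDPs), and a
multiple-testing-aware comparison harness. `cogage` implements all three,
plus a synthetic cohort generator, because the motivating data (biobank
phenotype extracts) are access-restricted: every stage of the pipeline
must be testable against data whose generative truth is known.

## The classification model

**Generic cognitive score.** The battery has nine tests spanning memory,
reasoning, processing speed and executive function. Raw scores are kept in
each test's native direction — durations (reaction time, trail-making) and
error counts (pair-matching) improve *downwards* — and `orientScores()`
negates those columns so that "higher = better" holds uniformly. Oriented
scores are standardized per test with the pooled mean and SD of the
middle-aged + older sample, and the first principal component of that
matrix is the generic cognitive score, sign-oriented to correlate
positively with the mean standardized score. On data generated under a
one-factor law with loadings around 0.55 and unit residual noise, PC1
explains roughly 30% of the battery variance; the package warns when the
fitted fraction drops below 0.15, since the composite is then a poor
summary.

We fit the component once on the pooled sample and project both strata
with that single loading vector. A per-stratum fit is the other defensible
reading of the procedure; we chose the pooled fit because the retention
rule is applied identically to both strata and a shared basis makes the
two reference standardizations commensurable. The choice matters little
under a common factor model, where both estimands coincide in population.

**Dual-reference standardization and the cascade.** Every score is
Z-standardized twice: against the older stratum's own mean and SD
("self"), and against the middle-aged stratum's ("middle"). An older
subject is labelled SCA iff

1. *generic stage*: self-referenced generic Z strictly above 0.67 (the
   printed upper-quartile cut; the exact 0.75 normal quantile is 0.6745)
   **and** middle-referenced generic Z strictly above 0; and
2. *specific stage*: on each of four tests (matrix pattern completion,
   tower rearranging, fluid intelligence, numeric memory), self-referenced
   Z strictly above 0 **and** middle-referenced Z strictly above −0.67.

All inequalities are strict, reading "exceed"/"surpass" literally: a Z
exactly at a cut fails. We use 0.67 as printed rather than the exact
quantile. Subjects failing the generic stage are labelled nonSCA without
specific-stage evaluation, and `stageCounts()` reports the retention at
every stage, so `nFinalSca + nFinalNonSca = nOlderInput` always holds.
Reference statistics are computed on the full older and middle strata
(complete cases on the nine tests; dropped subjects are counted). When
older and middle-aged generic distributions coincide, the generic-stage
retention converges to `1 − Φ(0.67) ≈ 0.2514`, a law the tests check at
n = 100,000.

One source-description ambiguity is worth flagging: the pair-matching test
is described in one place as a count of *correct* associations and in
another as a count of *incorrect* matches. We follow the tabulated
description (incorrect matches, lower is better); `testBattery()` accepts
an override for users who prefer the other reading.

## Deconfounding

Volumetric T1 IDPs are multiplied by the subject's T1 head-size scaling
factor (the native-to-standard-space volumetric scaling), which removes
head-size variation; thicknesses, diffusion measures and network
amplitudes are not rescaled. Every IDP is then replaced by its residual
from an ordinary least-squares fit on intercept + centered age, age²,
height, head motion, and scanner table position. The design is fitted via
a QR factorization on the pooled older sample — both outcome groups
together, never per group, so genuine group differences are not absorbed —
and group labels are never part of the design. Sex is deliberately *not* a
confound: the sex split of the SCA group is itself a finding; an override
exists. Residuals are orthogonal to every design column at 1e−8 relative
tolerance and residualization is idempotent, both asserted by tests. For
the follow-up comparison the middle-aged stratum is adjusted with the
coefficients estimated on the older fit (no refitting), keeping the
adjustment identical on both sides of that contrast. Order of operations:
head-size normalization → residualization → testing.

## Group comparison

Each variable is routed by scale and distribution: nominal → Pearson
chi-square (no continuity correction; levels with zero margin are
collapsed with a warning, and a flag is raised when > 20% of expected
counts fall below 5); continuous → one-way ANOVA if both groups pass a
normality check at α = 0.05, otherwise a two-sided Mann–Whitney U with
midrank ties (exact enumeration when the smaller group has ≤ 8
observations and no ties; normal approximation with tie and continuity
corrections otherwise). The normality rule is the D'Agostino–Pearson K²
omnibus test, implemented in-package from the published moment
approximations because no installed package provides it, and validated
against an independent reference implementation; below 20 observations per
group, where the K² approximations are unreliable, Shapiro–Wilk is used
instead. K² was chosen over Shapiro–Wilk as the primary rule because it
has no sample-size ceiling at biobank scale.

Raw p-values are adjusted by the Benjamini–Hochberg step-up rule
*within each modality family* (T1, dMRI skeleton, dMRI tract-weighted
means, rs-fMRI network amplitudes, demographics) at q ≤ 0.01; a pooled
adjustment is available as a switch (`pool = TRUE`). Family-wise
adjustment mirrors the per-modality structure in which such results are
reported; whether demographics were originally FDR-adjusted is not
documented, so they are treated like any other family here. Variables
significant in the primary SCA vs nonSCA contrast are re-tested against
the middle-aged stratum, two-sided and uncorrected at α = 0.05; a
follow-up p above 0.05 is recorded as "similar to middle-aged" — the
signature of interest. Per-variable failures (degenerate data, absent
columns) become flagged rows, never batch aborts.

## The synthetic cohort generator

`syntheticDesign()` encodes the generative law; `simulateCohort()` draws
from it deterministically given the seed. Defaults are the study
conditions the pipeline was designed around, fixed once:

* strata of 9050 middle-aged (ages 45–64) and 8022 older (65–81)
  subjects, cut at 65;
* one latent general-cognition factor *g* per subject, standard normal
  within stratum; the older stratum mean is shifted by −0.5 SD and *g*
  declines by 0.03 SD per year of age within stratum (the source reports
  neither; these are conventional magnitudes for cross-sectional cognitive
  aging, and they reproduce the qualitative age skew of the selected
  group);
* nine battery scores `0.55·g + N(0,1)` emitted in native direction, so
  PC1 explains ≈ 32% of the variance, matching the ~30% the composite is
  expected to capture;
* IDP families at reduced desk-scale dimensionality (20/20/20/21 instead
  of hundreds per family; configurable upward), each variable = planted
  effect × high-*g* indicator + confound contributions + Gaussian noise.
  The planted effect *d* is expressed in units of the variable's residual
  SD and the high-*g* indicator is a within-stratum median split, so the
  realized between-arm Cohen's *d* equals *d* when confound weights are
  zero;
* five confounds with plausible scales (height by sex, log-normal head
  motion, a T1 scaling factor around 1.1) entering IDPs through
  standardized weights, and volumetric IDPs emitted in native space so
  head-size normalization has real work to do;
* twelve demographic indicators (six continuous, six nominal) with
  optional planted shifts (continuous) or a logistic tilt of level
  probabilities along *g* (nominal), both zero by default.

`simulateNullCohort()` forces every planted effect to zero while keeping
the confound structure — the calibration fixture for FDR checks. What the
generator does *not* emulate: non-Gaussian IDP marginals, within-family
correlation between IDPs, missingness, scanner batch structure, and any
nonlinear confound effects. Passing tests therefore demonstrate the
*procedural* correctness and calibration of the pipeline under a known
law, not the reproduction of any real-data effect sizes.

## Numerical choices and problem sizes

* PCA via `prcomp` on per-test standardized data; the retained component
  is always PC1 (automating scree inspection would invent a criterion).
* OLS residuals via QR; orthogonality asserted at 1e−8 relative tolerance.
* Strict inequalities at all four cascade thresholds; ties fail.
* Errors carry stable machine-readable codes
  (`cogage_error_schema`, `cogage_error_degenerate`, ...); batch
  comparisons convert per-variable errors to flagged rows.
* Test-suite problem sizes are chosen so the full suite runs in a couple
  of minutes on one core: Monte-Carlo checks use 10⁵–10⁶ draws where a
  law is being verified (generic retention, cascade oracle), 200
  replicate cohorts of 1000 variables for FDR calibration, and a few
  hundred subjects elsewhere. The cascade oracle exploits the affine
  invariance of Z-scoring: pooled standardization constants cancel, so
  the five threshold events can be evaluated directly under the latent
  law.

## Reproducibility

Every stochastic function is a pure function of its seed
(`withr::with_seed`), and `runPipeline()` writes a provenance record plus
a deterministic log, so identical configuration and seed give
byte-identical artifacts. Fixtures round-trip through CSV with field-ID
aliases for the nine tests, with a DCF provenance sidecar.

## Known limitations

* The cascade's headline retention counts on real restricted data are not
  reproducible from synthetic cohorts; only distributional laws and
  procedural invariants are.
* The normality-routing rule and the FDR family structure are documented
  conventions (the original description is silent); both are configurable.
* Cross-sectional only: no longitudinal modelling of cognitive
  trajectories.
* No raw-image processing: inputs begin at the IDP table.
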