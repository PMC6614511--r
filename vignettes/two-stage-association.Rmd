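---
title: "Two-stage cognitive–mobility association analysis: methods and design"
author: "cogmob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage cognitive–mobility association analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmob)
```

## Scientific setting

Studies of aging cohorts often collect two blocks of measurements per
participant: a battery of cognitive test scores (grouped into domains such
as executive function, processing speed, memory, and language) and a set of
wearable-sensor mobility metrics (gait speed, stride variability, turn
duration, sit-to-stand transitions, and the like). The scientific question
is which cognitive measures are associated with which mobility measures
after removing the common influence of age and gender — a question that
involves hundreds of correlated hypotheses on modest sample sizes.

`cogmob` implements a complete pipeline for this problem:

1. **Per-variable transformation.** Each variable is transformed toward
   normality by the best member of a fixed catalog; transforms that reverse
   order are multiplied by −1 so that higher always retains its original
   meaning.
2. **Covariate-adjusted outlier removal.** Each variable is regressed on
   age and gender; cells whose Bonferroni-corrected p-value for the
   externally studentized residual falls strictly below 4/n are set missing
   for that variable only.
3. **Limited-range exclusion.** Variables in which a single value accounts
   for at least 80% of the non-missing observations are dropped: rank
   methods carry no usable information about them.
4. **Partial Spearman correlation.** Every (cognitive, motor) pair is
   tested with a rank correlation adjusted for age and gender over the
   pair's pairwise-complete cases.
5. **Two-stage multiple testing.** Pairs are grouped into hypothesis
   families — one family per (motor variable, cognitive domain). Families
   are screened by their Simes p-value at α = 0.05 (strict inequality);
   inside each selected family, the Benjamini–Hochberg (BH) step-up
   procedure is applied at q = 0.05.

## The statistical procedures in detail

### Partial Spearman correlation

`partialSpearman()` ranks both variables (average ranks for ties) over
their pairwise-complete cases, residualizes both rank vectors on an
intercept plus the covariates by least squares, and takes the Pearson
correlation of the residuals. The p-value uses the t statistic
ρ·√((n−k−2)/(1−ρ²)) on n−k−2 degrees of freedom, where k is the number of
covariates. With no covariates this reduces exactly to the classical
Spearman correlation, which the test suite verifies against the closed-form
1 − 6Σd²/(n(n²−1)) on tie-free data.

### Transform catalog

The catalog in `selectTransform()` contains the identity, shifted log,
shifted square root, reciprocal, profile-likelihood Box–Cox (λ on a grid
from −2 to 2 in steps of 0.25), and the rank-based inverse-normal transform
with Blom offsets, (r − 3/8)/(n + 1/4). Shifts are chosen automatically as
1 − min(x) where a positive domain is required. Selection maximizes the
Shapiro–Wilk statistic, with ties broken by catalog order; it is therefore
fully deterministic.

Two properties matter downstream. First, every catalog member is strictly
monotone (the reciprocal is decreasing, hence its output is negated), so
Spearman correlations are invariant to the chosen transform; the transform
stage matters only for the residual-based outlier test, which assumes
roughly Gaussian errors. Second, the rank-based inverse-normal transform
maximizes the Shapiro–Wilk statistic essentially by construction, so
automatic selection picks it for almost every continuous variable. That is
accepted behavior, not a flaw: the other catalog members exist for
explicit per-variable overrides (`rowData`'s `transform` column), for
`transformSelection = "none"`, and because a fixed published catalog makes
the procedure auditable. One consequence worth knowing: the inverse-normal
transform compresses extreme observations into the Gaussian tail, so gross
outliers may be *normalized away* rather than flagged when automatic
selection is active. Use an identity or log override where the raw scale of
a variable is meaningful and outlier detection is a priority.

### Outlier rule

`detectOutliers()` uses externally studentized residuals (leave-one-out
variance, `stats::rstudent`), two-sided t tails on n−k−2 degrees of
freedom, Bonferroni correction by the number of cases used, and a strict
cutoff at 4/n. The expected number of false flags per variable under a
correct model is therefore about 4 regardless of n — a deliberately
conservative, scale-free rule. Flagged cells are set missing for that
variable only; subjects are never dropped. The test suite checks the
implementation cell-for-cell against a literal leave-one-out refit oracle.

### Why two stages

With V_c cognitive and V_m motor variables there are V_c·V_m pairwise
hypotheses (630 on the default inventory). Flat BH across all pairs is
valid but diffuse. The two-stage procedure instead asks a coarser question
first — *is this motor variable associated with this cognitive domain at
all?* — using the Simes combination of the family's member p-values, which
is a valid global-null test under independence or positive dependence.
Only inside families passing the screen is member-level BH applied. The
family definition (one motor variable crossed with one cognitive domain)
gives each family 3–14 members on realistic inventories and makes every
pair a member of exactly one family.

The procedure controls the within-family false discovery rate at q inside
each selected family, and simulation shows the pooled FDR is also near q in
signal regimes. Two caveats are worth stating plainly:

* **Falsely selected families always reject.** The Simes p-value of a
  family equals the minimum BH-adjusted p-value of its members, so a family
  that passes the α = 0.05 screen is guaranteed at least one member
  rejection at q = 0.05. Under a global null, about 5% of families are
  selected and each contributes false rejections. The screen is a
  gatekeeper, not an extra layer of protection for null families that slip
  through.
* **Pooled FDR across families is not controlled at q in general.** When
  many null families accompany few signal families, the pooled false
  discovery proportion can exceed q. `pipelineConfig(selectionAdjustedBH =
  TRUE)` offers the classical remedy — scaling the within-family level by
  the fraction of families selected — at a cost in power; the default
  reproduces the plain procedure.

`estimateOperatingCharacteristics()` makes these trade-offs measurable for
any configuration.

## The synthetic cohort generator

Real cohorts of this kind are not redistributable, so `cogmob` ships a
generator whose defaults mirror the target study conditions: n = 124
subjects, truncated-Gaussian ages (mean 61.5, SD 11.9, range 27–80), 56.5%
female. Each variable is built from a latent Gaussian score

> score = β_block · age (per decade, standardized) + γ · gender + ε,

with cognitive scores declining and (lower-is-better) motor scores
worsening with age, so that age and gender genuinely confound the two
blocks. Planted cognitive–motor links are induced by a shared latent
factor whose loadings are chosen through Greiner's relation
(r = 2 sin(πρ/6)) so that the *population partial Spearman correlation*
equals the configured ρ exactly — the test suite verifies this at
n = 2000. Monotone marginal distortions (exponential, heavy-tailed,
bounded) can be applied per variable to exercise the transform stage
without touching rank structure. Ground truth — planted links, injected
outlier cells (residuals displaced to ±6 SD), degenerate variables with an
exact modal count — is recorded in a `TruthSet` attached to the cohort.

What the generator deliberately does **not** emulate: longitudinal
structure, missing-not-at-random patterns, floor/ceiling effects beyond the
degenerate-variable mechanism, measurement error correlated across
variables within a block beyond the single shared factor per planted link,
and non-monotone distortions. Results from it certify the *procedure*, not
any substantive claim about real cohorts.

### Scenario presets

`scenarioConfig()` provides three presets used by the release tests:

* `"null"` — the default cohort size with no planted links; used to check
  the calibration of the screening stage.
* `"signal"` — n = 500, two cognitive × two motor variables in one domain,
  two planted links of ρ = 0.5. Every family contains a planted link, so
  families are selected with probability near 1 and the measured
  false-discovery proportion isolates the BH stage. This design is
  intentional: in regimes where most families are pure null, pooled FDP
  reflects the screen's 5% family-wise leakage rather than the BH stage
  (see the caveats above).
* `"power"` — n = 500, three planted links of ρ = 0.5 across two domains;
  used to verify that the pipeline recovers all planted links in at least
  90% of replicates.

## Numerical choices

* Ranks use `rank(, ties.method = "average")`; correlations are clamped to
  [−1, 1] before the t transformation, and 1 − ρ² is floored at machine
  epsilon.
* The Simes statistic is min over i of m·p(i)/i, capped at 1; BH adjusted
  p-values come from `stats::p.adjust(method = "BH")`, and rejection is
  *inclusive* (adjusted p ≤ q) while family screening is *strict*
  (Simes p < α), matching the published procedure.
* Studentized residuals whose leave-one-out variance collapses to zero
  (numerically negative by rounding) are treated as infinitely outlying
  when the raw residual is nonzero and as non-outlying when it is zero.
* Replicate seeds in the Monte-Carlo harness are derived from the master
  seed via `sample.int`, and all seeded code restores the caller's RNG
  state afterwards.

## Worked example

```{r example}
ce <- simulateCohort(scenarioConfig("signal"), seed = 11)
rep <- runPipeline(ce)
rep
reportTable(rep)
familyLog(rep)
```

The operating characteristics of any configuration can be estimated
directly (more replicates give tighter Monte-Carlo error):

```{r oc}
oc <- estimateOperatingCharacteristics(scenarioConfig("signal"),
                                       nReplicates = 50, seed = 12)
oc
```

## Limitations

* The Simes combination assumes independence or positive dependence of
  member p-values; strong negative dependence within a family voids its
  level guarantee.
* Partial Spearman residualizes *ranks* linearly on covariates; strongly
  non-linear covariate effects on the rank scale are only partially
  removed.
* The outlier rule assumes a linear age/gender model with roughly Gaussian
  errors after transformation; automatic inverse-normal selection can mask
  gross outliers (see above).
* p-values for the partial correlation use the large-sample t
  approximation; below roughly n = 15 per pair they are approximate, and
  pairs with fewer than k + 3 complete cases are reported untestable with
  p = 1 (conservative) rather than dropped, to keep family sizes stable.
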