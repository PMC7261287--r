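---
title: "The offspring-of-siblings liability model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The offspring-of-siblings liability model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinliab)
```

## The scientific problem

Offspring of parents with a history of suicidal behavior (suicide attempt
or death by suicide) are themselves at elevated risk.  The open question
is *how* that risk is transmitted: through genetic factors shared across
generations, through comorbid parental behavioral-health problems, or
through environmental exposure to the parent's behavior itself.  kinliab
implements the offspring-of-siblings design for this question: cousins
whose parents are full siblings share about 12.5% of their segregating
alleles, cousins whose parents are maternal half-siblings about 6.25%,
and that known contrast lets a structural model separate genetic from
environmental transmission without measuring genotypes.

## The liability-threshold transmission model

Each person's propensity toward suicidal behavior is modeled as an
unobserved normally distributed liability; the binary lifetime phenotype
is expressed when the liability exceeds a generation-specific threshold
$\tau$ (probit scale), so observed 2x2 tables identify tetrachoric
(liability-scale) correlations.

The parent liability is an ACE decomposition with unit variance,

$$L_p = a_p A_p + c_p C_p + e_p E_p,$$

and the offspring liability adds a *direct phenotypic transmission path*
$\beta$ from the parent's total liability to the offspring's:

$$L_o = \beta L_p + a_o A_o + c_o C_o + e_o E_o,$$

with the residual components again summing to unit variance, so the
implied offspring variance is
$s_o^2 = 1 + \beta^2 + 2\beta\,(0.5\, r_g a_p a_o)$ and observed
offspring correlations are standardized by $s_o$.  The parental and
offspring phenotypes are allowed to be genetically distinct traits: their
additive factors correlate $r_g$, so a parent and their own child's
genetic factors correlate $0.5\,r_g$.  Sibling parents share genetics
$g$ (0.25 maternal half, 0.5 full or DZ, 1 MZ), giving the avuncular
genetic overlap $0.5\,g\,r_g$ and the cousin overlap $0.25\,g$.  The key
decomposition is the share of the implied parent-offspring covariance
attributable to the direct path,

$$\text{covariance due to } \beta =
  100 \times \frac{\beta}{\beta + 0.5\, r_g a_p a_o}\ \%,$$

computed by `covariance_share_beta()` with a delta-method CI in
`fit_ml()` output.

Shared environment follows the standard children-of-siblings convention:
$C$ correlates 1 between co-reared sibling parents and between offspring
of the same parent, and 0 across nuclear families.  The path diagrams of
this design usually omit $C$ because the estimated shares are null for
this phenotype, but both $c_p^2$ and $c_o^2$ are estimated here unless
the `c2_zero` constraint is requested.

## Estimation

`fit_ml()` maximizes the exact orthant-probability likelihood of the
binary family observations (two same-sex sibling parents, up to two
offspring each; members with missing phenotypes are marginalized out).
Families with identical structure and response pattern share one orthant
computation, so the grouped likelihood cost is independent of the number
of families when no person-specific covariates enter.

Numerical choices worth knowing:

* **Orthant probabilities.** All $2^d$ pattern probabilities of a family
  are assembled from the $2^d$ subset CDFs by inclusion-exclusion, which
  shares every lower-dimensional integral.  CDFs use deterministic
  algorithms: closed forms in 1-2 dimensions, Plackett/TVPACK in 3,
  Miwa quadrature in 4-7 (quasi-Monte Carlo with a fixed internal seed
  only beyond that), with absolute accuracy near $10^{-7}$ at the
  default 128 quadrature steps inside the fit and below $10^{-8}$ at the
  512 steps used by `orthant_probability()` itself.  Accuracy matters:
  coarser quadrature (e.g. 32 steps) visibly biases estimates once
  $10^4$-$10^5$ families contribute.
* **Parameterization.** Variance shares are optimized through a
  multinomial-logit (simplex) transform - a single logit when `c2_zero`
  is set - $r_g$ through tanh, $\beta$ and thresholds untransformed;
  iterates therefore always satisfy the model constraints.  Wald
  standard errors come from the observed information on the transformed
  scale; monotone transforms map CI endpoints back, simplex shares use
  the delta method, so every CI contains its point estimate.
* **Convergence and starts.** `nlminb` with relative tolerance $10^{-9}$
  and box bounds $\pm 12$ on the transformed scale.  When a variance
  share sits on its boundary the likelihood is one-sided flat and the
  optimizer reports "false convergence"; the fit is then accepted and
  annotated (`boundary_note`) rather than restarted.  Jittered restarts
  (seeded) are used only when no start reaches an acceptable state, and
  `options$n_starts` requests unconditional multi-starts; the default is
  a single start because the grouped likelihood has been unimodal from
  the neutral start in every recovery experiment we ran, and
  unconditional multi-starts multiply the cost of the slowest fits
  several-fold.  Ties are broken by likelihood, then by smaller
  $|\beta|$.
* **Identification.** The variance decomposition is identified only by
  the half/full contrast in $g$; with a single sibling type the fit
  warns that components are not separately identified, and a
  near-singular observed information matrix triggers a pseudo-inverse
  with a warning.

`solve_moments()` is the complementary estimator: a least-squares
inversion of the implied-correlation system (with $c^2 = 0$) from the
seven informative relationship correlations - parent siblings (half and
full), parent-offspring, avuncular (half and full), and cousins (half
and full).  On model-implied input the round trip is exact to optimizer
tolerance, and the residual norm flags inconsistent input.

Sensitivity constraints mirror the design's standard checks: `rg_zero`
and `rg_one` pin the cross-generation genetic correlation, `equal_h2`
ties the parent and offspring heritabilities, and `compare_models()`
tabulates log-likelihood, AIC and likelihood-ratio statistics for nested
pairs.

## Propensity adjustment

`fit_propensity()` builds role-specific logistic models of the lifetime
phenotype: education (six levels plus an own missing category), country
of origin, severe mental illness, substance use and criminal conviction
for parents; birth year, parity and maternal age at childbearing for
offspring.  Scores enter the liability model as the *logit* (linear
predictor), shifting a member's threshold by $-\gamma^\top x$ - a
linear-on-liability (probit-scale) adjustment, which is better behaved
than adjusting on the probability scale.  With person-specific shifts
the grouped likelihood is unavailable and the fit evaluates one orthant
per family, so adjusted fits cost roughly `n_families` times one
integral per likelihood evaluation; they are intended for moderate
sample sizes or three-member family layouts.

## Survival models

The survival stage uses age as the time scale with entry at exact age 12
(the phenotype is defined from age 12) and half-open person-time
intervals; follow-up ends at the first of event, death, emigration and
the end of study.  `km_estimate()` reports the product-limit cumulative
incidence per 10,000.  `fit_cox()` is the population Cox model (Breslow
ties by default, matching the defaults of the statistical software
generation the design comes from; Efron optional), with cluster-robust
variance when a person contributes several rows.  `fit_stratified_cox()`
stratifies the partial likelihood on the cousin-pair identifier, so only
pairs discordant on both exposure and outcome contribute, and clusters
the sandwich variance on person id because an offspring can appear in
several pairs.  Exposure is parental suicidal behavior strictly before
the offspring's 18th birthday (events before birth included); events at
or after the 18th birthday are "late-exposed" and analyzed as unexposed
by default (switchable to exclusion) - the source design says "prior to
age 18" without fixing the boundary convention, so the strict boundary
is this package's choice.

## The synthetic registry

Real multi-generation registry data cannot be redistributed, so
`generate_registry()` simulates the statistical structure the analyses
need, with full ground truth retained for testing: three linked
generations (grandparents, two sibling index parents with co-parents,
offspring), a configurable mixture of parent sibling types (default 82%
full, 15% maternal-half, 2% DZ, 1% MZ - half-sibships and twin births are
minority family structures at roughly these rates in Nordic registers),
one or two offspring per parent, liabilities drawn at the A/C/E
component level under the generating model (default: the published
minimally-adjusted estimates $\beta = 0.04$, $r_g = 0.39$,
$a_p^2 = 0.50$, $a_o^2 = 0.61$, $c^2 = 0$), covariates drawn from
frequencies matching the cohort's descriptive table and shifting
liabilities linearly on the probit scale, and thresholds *calibrated by
exact enumeration of the covariate-shift distribution* so the marginal
lifetime prevalences hit their targets (3.16% mothers, 2.81% fathers,
3.82% offspring).  Co-parent covariates correlate with the index
parent's through a Gaussian copula (latent correlation 0.2 by default)
to let tests exercise assortative-mating-style confounding.

Event ages for cases come from a Weibull distribution truncated to
[12, 41] years (shape 2, scale 30), giving a realistic concentration of
first events in the late teens and twenties; the lifetime indicator is
drawn first from the liability threshold, so the SEM's marginal
structure is exact and the event-age model only supplies time axes for
the survival stage.  Death and emigration are independent exponentials
from age 12 (defaults 0.0003 and 0.002 per person-year).  Lifetime
phenotypes and event dates are recorded in the persons table regardless
of censoring - the behavior-genetic stage analyzes lifetime indicators,
exactly as the SEM does, while `make_survival_records()` applies
death/emigration/end-of-study (2013-12-31) censoring when constructing
person-time.  By default the generator is "exclusion-safe": offspring
first events are pushed after the parents' so the event-order exclusion
rule removes nothing unless violations are injected deliberately
(`inject_violations`), which is how the exclusion ledger is tested
count-for-count.

What the generator does *not* emulate: calendar-time trends in
prevalence or diagnostic-code revisions, dependence of censoring on
liability, assortative mating beyond the covariate copula, repeated
events, and any gene-environment interaction.  Passing tests therefore
demonstrate internal consistency of the estimators under the stated
generating model, not robustness to those real-data features.

## Problem sizes used in the checks

The parameter-recovery harness simulates 50,000 extended families per
replicate (20 replicates) at $\beta = 0.10$, $r_g = 0.40$,
$a_p^2 = 0.50$, $a_o^2 = 0.60$, $c^2 = 0$, thresholds at 10% prevalence
to boost information, an even half/full mixture, and one offspring per
parent - the minimal identifying structure of the design's path diagram;
fits use the `c2_zero` constraint matching the generating model.  The
model-selection check instead uses two offspring per parent, because the
offspring-sibling correlations carry the offspring-heritability
information that separates the equal-heritability constraint from the
free model; orthant accuracy is
checked against a $10^7$-draw Monte-Carlo oracle and an independent
conditional-quadrature oracle; survival recovery uses 20,000 frailty
pairs (within-pair HR 2) and a population cohort of 100,000 (HR 2.74,
the published general-population estimate, as the generating truth).
Prevalence calibration is verified on a 200,000-family registry.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "kinliab-demo",
  generator = registry_config(n_extended_families = 2000,
                              parent_sex = "female",
                              offspring_per_parent = c("1" = 1),
                              seed = 1),
  seed = 11)
manifest <- run_pipeline(cfg)
cat(render_report(manifest), sep = "\n")
```

The demo configuration keeps one offspring per parent: with two-offspring
families the free fit evaluates 5- and 6-dimensional integrals and takes
minutes rather than seconds, and at 2,000 families the extra offspring
add little information.  Within-pair hazard ratios from cohorts this
small rest on a handful of doubly discordant pairs and can diverge (the
fit flags a monotone partial likelihood); population-scale behavior
needs the larger simulations used in the test suite.

## Known limitations

* Adjusted (covariate-shifted) liability fits scale linearly in
  families per likelihood evaluation; at registry scale the grouped
  (unadjusted) likelihood or the moment solver is the practical route.
* The moment solver fixes $c^2 = 0$; freeing shared environment there
  would need additional relationship classes (e.g. non-co-reared
  siblings) that the design does not provide.
* The tetrachoric CI uses the observed information; exact small-sample
  intervals are out of scope.
* `fit_ml()` treats families as independent; the pedigree stage's
  de-duplication (uniform-random, seeded, greedy person-disjoint
  selection - the source design states only that repeated extended
  families were randomly removed) is what justifies that assumption.
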