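# kinliab

Intergenerational transmission of suicidal behavior with
offspring-of-siblings designs: liability-threshold structural models,
cousin-comparison survival analysis, and a fully synthetic
multi-generation registry for testing it all.

## The problem

Children of parents with a history of suicidal behavior (suicide attempt
or suicide) are at elevated risk themselves, but the association mixes
three mechanisms: genes shared across generations, comorbid parental
behavioral-health problems, and environmental exposure to the parent's
behavior.  Cousins whose parents are full siblings share ~12.5% of their
segregating alleles; cousins whose parents are maternal half-siblings
share ~6.25%.  That contrast identifies a two-generation
liability-threshold model in which each binary lifetime phenotype
reflects a latent normal liability exceeding a threshold:

    L_p = a_p A_p + c_p C_p + e_p E_p
    L_o = beta * L_p + a_o A_o + c_o C_o + e_o E_o

with cross-generation genetic correlation `r_g` (a parent and own child's
genetic factors correlate `0.5 r_g`) and a direct phenotypic transmission
path `beta`.  The share of the parent-offspring liability covariance due
to the direct path,

    100 * beta / (beta + 0.5 r_g a_p a_o)  %

is the quantity of interest: the part of the intergenerational
association not explained by shared genes.  The package complements the
structural model with Kaplan-Meier estimates and Cox proportional-hazards
models — population-level and stratified within cousin pairs
(fixed-effects, cluster-robust) — and constructs maternal, paternal and
offspring propensity scores for covariate adjustment.

Who it is for: quantitative-genetic and psychiatric epidemiologists who
work with multi-generation registry data (or want to prototype such
analyses on synthetic data with known truth).

## Worked example

Simulate a registry of 2,000 extended families of sister parents, build
the cohort and cousin pairs, fit propensity scores, the structural model
and the Cox models, and render a report:

```r
library(kinliab)

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

The report (synthetic data, so these numbers are reproducible with these
seeds) prints the structural-model table next to the generating truth
and the hazard-ratio comparison:

```
| parameter | estimate (95% CI) | truth |
|---|---|---|
| beta | 0.01 (-0.39, 0.41) | 0.04 |
| r_g | 0.62 (-0.90, 0.99) | 0.39 |
| a2_p | 0.34 (-0.18, 0.86) | 0.50 |
...
| comparison | HR (95% CI) | events |
|---|---|---|
| population_unadjusted | 1.13 (0.36, 3.57) | 90 |
| within_pair_unadjusted_full | 3.00 (0.50, 17.95) | 75 |
...
Kaplan-Meier cumulative incidence of offspring suicidal behavior by
age 30: 303 per 10,000.
```

`beta` is the direct transmission path on the liability scale; `r_g` the
cross-generation genetic correlation; `a2/c2/e2` the ACE variance shares
per generation; the hazard-ratio block compares the population estimate
for exposure to maternal suicidal behavior with the within-cousin-pair
estimate, which strips everything cousins share.  At 2,000 families
every interval is wide and boundary estimates occur — separating `beta`
from `r_g` needs the half/full-sibling contrast at scale; the test suite
demonstrates calibrated coverage at 50,000 families.

Lower-level entry points: `generate_registry()`, `build_cohort()`,
`enumerate_cousin_pairs()`, `select_bg_families()`, `fit_ml()`,
`solve_moments()`, `tetrachoric_estimate()`, `fit_propensity()`,
`km_estimate()`, `fit_cox()`, `fit_stratified_cox()`.  Fits have
broom-style `tidy()`/`glance()` methods and `autoplot()` displays.  A
thin command-line wrapper lives at `inst/cli/kinliab`
(`kinliab run-all --out DIR --seed 1 ...`).

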