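---
title: "Methods: mediation, confounding and gene-environment correlation with polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediation, confounding and gene-environment correlation with polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgepath)
```

## The estimation problem

A father's education predicts his child's education. Three mechanisms can
carry that association: his behaviour (involvement in the child's school and
leisure life), the alleles he transmits (summarized by the child's education
polygenic score, PGS), and everything the two share. `rgepath` estimates the
mediated shares of the transmission, the mutual confounding of the
behavioural and genetic mediators, and the type of gene-environment
correlation (rGE) linking the PGS to father involvement.

### The path system

All analysis variables are z-scored. With child education $y$, father
education $x$, mediators $M_1$ (school involvement), $M_2$ (leisure
involvement), $M_3$ (PGS), controls $C$ (mother's education and involvement,
residence indicators, age, sex, enrolment) and genetic principal components
$P$:

$$M_k = a_k x + (\gamma_k' P)\,[k = 3] + \varepsilon_k, \qquad
  y = c' x + \sum_k b_k M_k + \delta' C + \varepsilon_y .$$

The indirect effect through mediator $k$ is $a_k b_k$, the proportion
mediated $100\,a_k b_k / c$ with $c$ the total effect, and the three nested
models M1 (behavioural mediators), M2 (PGS) and M3 (both) give the
confounding percentages $100(b^{M1}_k - b^{M3}_k)/b^{M1}_k$ (genetic) and
$100(b^{M2}_3 - b^{M3}_3)/b^{M2}_3$ (social).

**Estimation substitute.** The system is recursive and linear, so each
equation is estimated by ordinary least squares with household-cluster-robust
covariance (CR1, small-sample factor $\tfrac{G}{G-1}\tfrac{n-1}{n-k}$)
rather than by a joint multilevel structural fit; point estimates for the
same linear paths coincide asymptotically, and inference for derived
quantities (products, percent reductions) is available through the household
cluster bootstrap (percentile intervals, default $B = 1000$, seed
mandatory). This is a deliberate substitution: a random-intercept maximum
likelihood path system is *not* reimplemented, and users who need one should
fit it in dedicated SEM software. The applied literature this design follows
does not state whether every equation or only the outcome carried a random
intercept, so we chose the estimator whose assumptions we can state exactly.

**Control placement.** By default (`control_placement = "outcome"`) the
control set enters the outcome equation only and the PCs enter the PGS
equation only, mirroring the applied specification. With that placement the
identity $c_\text{reduced form} = c' + \sum_k a_k b_k$ holds only
approximately, because the mediator equations condition on different sets.
`control_placement = "common"` puts controls and PCs in every equation and
restores the identity exactly (the suite asserts it to $10^{-8}$); this is
the configuration to use when exact decomposition accounting matters.

**Degenerate inputs.** Rank-deficient designs are an error, never silently
dropped; a zero total effect flags the proportions as undefined; percent
reduction is undefined at a zero base coefficient. Percentages are computed
unrounded and displayed at one decimal (two where the first decimal is
ambiguous).

### The three rGE estimators

* *Correlated effects*: child education is regressed on both parents'
  education, 10 PCs and all controls in a household random-intercept model;
  the conditional residuals are then regressed separately on the PGS and on
  each involvement scale, and the Pearson correlation of the two fitted-value
  vectors is reported with a Fisher-z interval. Since the stage-2 fits are
  univariate, the statistic algebraically equals the raw PGS-involvement
  correlation signed by the product of the two slopes — the suite asserts
  this identity on every dataset, and it is why the statistic is best read as
  "the correlation between the two predicted components of education".
* *Between-family*: a household random-intercept model of the z-scored scale
  on the z-scored PGS plus 10 PCs; the PGS fixed effect is the standardized
  beta. The random-intercept model is fitted by exact profiled REML: the
  single variance ratio is optimized numerically and polished by root-finding
  on the analytic restricted score, which reproduces the balanced one-way
  ANOVA closed form to machine precision and matches `lme4` on unbalanced
  designs (both are test-suite cross-checks). Boundary estimates
  ($\sigma^2_b = 0$) are allowed and flagged.
* *Within-family*: for households with a complete sibling pair (first pair
  by ascending person id when more exist — the estimate is order-invariant,
  the rule only pins down intermediate signs), the Pearson correlation of
  $\Delta$PGS with $\Delta$involvement, Fisher-z interval, no PC adjustment
  (siblings share ancestry). The equivalent difference-regression slope is
  also emitted.

Fisher-z intervals are a design choice for all reported correlations; the
cluster bootstrap is available as an alternative. Passive rGE predicts a
between-family association with a null within-family one (the shared
parental cause is differenced away); evocative/active rGE predicts a
surviving within-family correlation.

## The synthetic cohort generator

The generator exists so that every estimator can be validated against a
known truth; its defaults define the package's reference conditions and are
not tuning knobs.

* **Scale**: 4,000 households, 10% contributing exactly two genotyped
  children (~400 sibling pairs, the same order as the ~380 pairs of the
  motivating cohort design), parents unobserved in the analysis except
  through reported education.
* **Genetics**: 200 independent biallelic loci with base frequencies uniform
  on (0.1, 0.9), Gaussian per-locus weights; children receive one allele per
  parent per locus as a Binomial(1, dosage/2) draw — fair Mendelian
  transmission, which makes the per-locus sibling dosage correlation 1/2 and
  the child PGS midparent-unbiased, two properties the suite checks. 200
  loci is a deliberately scaled stand-in for a genome-wide panel: enough for
  a continuous PGS and informative PCs while keeping hundreds of simulated
  cohorts cheap.
* **Assortative mating**: spouses are coupled by ranking mothers' latent
  education against a noisy copy of the fathers' (Gaussian copula-style rank
  matching) to hit a target spousal correlation, default 0.3.
* **Phenotypes**: parental latent education is $0.4 \times$ own standardized
  PGS plus noise, thresholded onto the documented survey categories (fixed
  cut points chosen once so the simulated means land near 13.7 parent /
  14.8 child years, close to the reference descriptives; exact marginal
  matching is not a goal). Involvement items are Bernoulli-logistic with
  intercepts set to the reference scale means (school 1.16/3, leisure
  1.44/5), a father-education effect (0.30 / 0.25 on the logit), a shared
  household intercept (SD 0.4), a *passive* path from the father's PGS
  (0.25 / 0.15) and an *evocative* path from the child's PGS (0 by default).
  The passive defaults were set by a moment calculation so the passive path
  alone implies between-family PGS-involvement correlations near the high
  single digits; the father-education path adds to this, so realized
  between-family betas sit around 0.11-0.16 — the same order as published
  estimates, intentionally not an exact match. Child education is linear in
  parental latent education (0.18 / 0.15), the involvement counts
  (0.05 / 0.03 per item), the child PGS (0.25), small control effects, a
  household intercept (SD 0.2) and noise (SD 0.8), thresholded onto the
  child categories.
* **Stratification**: optional two-subpopulation mode with symmetric
  allele-frequency shifts (total divergence 0.2) and a latent education
  shift (0.5) — the simplest structure that makes PCs meaningful. Under the
  stratified null (no phenotypic PGS effects) the naive PGS-education
  association is spurious and PC adjustment removes it; both directions are
  asserted in the suite.
* **Scenarios**: `passive` (the defaults), `evocative`, `no_rge`, `null`
  (all structural paths zero) and `stratified_null`, used as the
  demonstration and validation conditions.

What the generator does **not** emulate: linkage disequilibrium and real
GWAS weights, continuous admixture, more than two children, missing-data
patterns and attrition, time-varying involvement, measurement error in
reported education beyond categorization, and the unconventional published
0-1.05 scaling of the PGS (scores here are z-scored; the published scaling
is undocumented and deliberately not reproduced). Passing tests therefore
demonstrate estimator correctness under a linear-Gaussian/logistic family
process, not robustness to every feature of real survey-genomic data.

## Survey coding rules

Education categories are recoded to years through two fixed maps (13 child
categories onto {8,...,20}; 10 parent categories onto {0,...,18}) shipped as
auditable CSV files; lookups are case- and whitespace-insensitive and an
unknown label is an error, never silent missingness. Child education prefers
the later wave with a generic two-column coalesce (`coalesce_waves`); the
conflict-reconciliation rule is wave preference only. Involvement scales are
the sums of their binary items (3 school, 5 leisure); a person missing any
item is dropped for that scale (listwise rule), and the selection cascade is
logged step by step. Cronbach's alpha uses the standard
$\frac{k}{k-1}(1 - \sum_j s^2_j / s^2_\text{total})$ with $n-1$ variances.

## Numerical choices and problem sizes

* OLS via QR; CR1 sandwich assembled from cluster score sums; both are
  oracle-tested (normal equations to $10^{-10}$; a hand-built 3-cluster
  sandwich to $10^{-12}$; `sandwich::vcovCL` as an independent
  cross-check).
* REML: golden-section bracket then analytic-score root polish
  (tolerance $10^{-14}$ on the variance ratio).
* Bootstrap: percentile intervals, resamples drawn at household level,
  failed resamples redrawn and counted, mandatory seed, identical seed gives
  byte-identical intervals.
* Validation problem sizes were chosen to keep the default suite fast while
  leaving Monte-Carlo error well inside the asserted bands: parameter
  recovery compares a 4,000-household fit against a 40,000-household
  reference fit of the same process within 3 SEs; the rGE mode
  classification uses 100 passive + 100 evocative cohorts at the default
  size; bootstrap coverage uses 500 replicates at 200 clusters; transmission
  physics use 5,000 sibling pairs.

## Known limitations

Involvement enters the analysis model linearly although it is generated (and
in surveys, measured) as bounded counts, so analysis a-paths are linear
projections of a nonlinear generative mechanism; the package validates them
against large-sample reference fits rather than against the logit
coefficients. Cluster-robust per-equation estimation forgoes the efficiency
of a joint multilevel fit. The within-family estimator uses full sibling
pairs only and cannot separate active from evocative rGE. None of the
estimators identify causal effects under assortative mating on unmeasured
traits or under parental-genotype effects not captured by the transmitted
PGS.
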