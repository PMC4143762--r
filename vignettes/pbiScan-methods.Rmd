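---
title: "Partition-based G×E interaction testing: model, permutation schemes, and validation design"
author: "pbiScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-based GxE interaction testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbiScan)
```

## The statistic

For a categorical partition of $n$ subjects into cells $i$ of size $n_i$,
with cell means $\bar Y_i$, grand mean $\bar Y$, and phenotype variance
$s_y^2$, the partition score is

$$I \;=\; \sum_i \frac{n_i}{n}\,
      \frac{(\bar Y_i - \bar Y)^2}{s_y^2 / n_i}
  \;=\; \sum_i \frac{n_i^2\,(\bar Y_i - \bar Y)^2}{n\, s_y^2},$$

summed over cells that actually contain subjects. Each term is the squared
standardized deviation of a cell mean, weighted by the cell's share of the
sample; the score is dimensionless, nonnegative, invariant under affine
transformation of the phenotype and under relabeling of the cells. Useful
closed forms (all tested): one cell gives $I = 0$; all-singleton cells with
distinct phenotypes give $I = (n-1)/n$.

A SNP coded as minor-allele dosage (0/1/2) and a discretized environment
(0/1/2) jointly define up to $3\times3 = 9$ cells. With $I_T$ the joint
score and $I_G$, $I_E$ the marginal scores, the interaction score is

$$I_{G\times E} \;=\; I_T - \max(I_G,\, I_E).$$

If the joint structure is explicable by either margin alone, $I_T$ does not
exceed the larger marginal and $I_{G\times E} \le 0$; only genuinely
non-additive structure pushes it positive. The score is reported
untruncated — negative values are informative and keep the permutation
reference distribution honest.

**Non-monotonicity under refinement.** Because cells enter with weight
$n_i^2$, splitting a cell into subcells with the *same* mean strictly
decreases its contribution ($\sum_j n_{ij}^2 < n_i^2$). Two consequences
matter in practice. First, the classical bilinear term
$\beta_{ge} G E$ induces marginal effects whose concentrated contribution
to $I_G$ and $I_E$ exceeds the diluted joint contribution to $I_T$: the
observed $I_{G\times E}$ is then *negative* at any effect size, and the test
has essentially no power. This is a real property of the max-subtraction,
documented here as a limitation: the method targets interactions that are
**not** mere accompaniments of dominant marginal effects. Second, it is why
the validation experiments below isolate *pure* interactions (zero expected
marginals), in both a linear and a non-monotone form.

**Variance convention.** The definition leaves the denominator of $s_y^2$
open; we use the unbiased convention ($n-1$), exposed as `varMethod`. The
choice rescales every score by the constant $n/(n-1)$ and therefore cancels
exactly in permutation p-values; only users comparing raw scores across
sample sizes need to care.

**Degenerate inputs.** A constant phenotype has no scoreable variation and
is rejected with an explicit error — except when all subjects fall in one
joint cell, where all four scores are zero by definition and are returned
as such. Missing values are handled complete-case *per test*: a subject
missing any of phenotype, genotype, or environment is dropped from that
triple only, and `n_used` is reported. Empty cells contribute nothing,
which uniformly handles binary factors, SNPs with unobserved classes, and
monomorphic sites (the scan flags the latter as untestable since the
statistic is then identically zero across permutations).

## Permutation inference

Significance comes from permuting the phenotype only — genotype and
environment labels are never moved. Three schemes:

* **global**: a uniform rearrangement of all phenotypes; exact when
  subjects are exchangeable.
* **local**: rearrangement within each pedigree; preserves per-pedigree
  phenotype multisets (hence means) exactly, and remains valid when
  phenotypes are family-correlated.
* **residual**: decompose $y_{ij} = \bar y_{i\cdot} + e_{ij}$ by pedigree,
  shuffle all residuals globally, reattach:
  $y^*_{ij} = \bar y_{i\cdot} + e^*_{ij}$. Preserves the grand sum exactly;
  additionally assumes residuals share one distribution across pedigrees.

The p-value is the add-one estimator $p = (1+r)/(1+B)$ with ties counted as
exceedances ($r = \#\{b: T_b \ge T_{obs}\}$) — valid (never
anti-conservative), never zero, and with $B = 199$ the event
$p \le 0.05$ has probability exactly 0.05 under exchangeability. If a
permuted phenotype is degenerate (possible only under the residual scheme),
the draw counts as an exceedance, with a warning — conservative by
construction.

Two degenerate pedigree structures are worth knowing. With singleton
pedigrees, local and residual permutation are the identity, so their
p-values are exactly 1 — family-aware schemes carry no information without
within-family replication. With a single pedigree spanning everyone, all
three schemes coincide draw-for-draw (residual shifts by the grand mean,
which the affine-invariant statistic ignores).

**Reproducibility contract.** Every (SNP, environment, outcome, scheme)
test derives its own RNG stream from the base seed by hashing the context
tokens, so scan output is byte-identical across runs and independent of
evaluation order. The permutation engine evaluates draws in vectorized
blocks (group sums over an $n \times B$ matrix); a unit test pins it
draw-for-draw to the naive one-permutation-at-a-time path. Optional
adaptive stopping (halt a test once 50 exceedances accumulate) bounds scan
time on desk-scale hardware but is off by default.

## The comparator

The linear comparator fits $y = \beta_0 + \beta_1 G + \beta_2 E +
\beta_3 GE + \varepsilon$ by OLS on the *identical* complete-case subjects
and tests $\beta_3$ with the two-sided t-test. The discretized 0/1/2
environment level enters as the numeric score by default, so both methods
see the same predictors (`lrmEnv = "raw"` substitutes the raw covariate).
The comparator deliberately ignores family structure — it represents the
standard single-level regression practice the partition test is compared
against, not a best-possible mixed model.

## Covariate pipeline

Longitudinal records (up to 4 visits) are collapsed per subject: mean over
non-missing visits for age and the blood-pressure outcomes, sum for the
binary smoking and medication indicators. A subject with no usable visit
gets a missing summary, which propagates to complete-case filtering rather
than erroring. Discretization: empirical tertiles for continuous
covariates (quantile type 7, right-closed assignment: the realized
boundaries are data-derived); the count recode $0 \to 0,\ 1 \to 1,\ \ge 2
\to 2$ for summed indicators (stated as $\ge 2$ so it generalizes beyond 4
visits); binary factors pass through. Genotypes are recoded to count the
*sample* minor allele; at an exact 50/50 allele-frequency tie the reference
allele is treated as major, a documented cosmetic tie-break (the score is
label-invariant). Multi-allelic sites are skipped with a warning.

## What the simulator emulates — and what it does not

`simulateCohort()` draws pedigrees with an exchangeable shared intercept
(sd `sigmaFam`), Hardy–Weinberg genotypes at the configured MAF, a
three-level environment, and a phenotype
$y = \mu + a_{ped} + f(G,E) + \varepsilon$. Two realism switches exist
because the permutation comparison demands them:

* `genoModel = "sibship"`: pedigree members are siblings of two
  Hardy–Weinberg parents (Mendelian transmission), so genotypes correlate
  within families as real family genotypes do. With everything i.i.d.
  across subjects, global permutation is *exactly valid* even under strong
  family effects (the partition labels are independent of the phenotype),
  so no scheme contrast can appear.
* `envModel = "family"`: each pedigree has a base environment level that
  members adopt with probability `envRho` (default 0.8), emulating
  covariates such as age band, medication use, or smoking that cluster in
  families.

With both switches on and `sigmaFam/sigmaE = 2`, the family-confounding
experiment reproduces the qualitative ordering observed on real family
data: global permutation over-rejects (≈ 0.14 at nominal 0.05 in our runs),
local permutation stays calibrated, and residual permutation runs slightly
conservative — consistent with local permutation flagging more markers than
residual on real data. Interestingly, with family-clustered genotypes but
an i.i.d. environment, global permutation is *conservative* for
$I_{G\times E}$ (the confounding loads onto the observed $I_G$, which the
max-subtraction removes); the direction of the distortion depends on which
partition factors carry the family structure.

The crossing interaction model uses the cell-mean table
$M_{ge} = d\, a_g v_e$ with $v = (-1, 2, -1)$ and $a$ chosen so the
HWE-weighted column means and the row means vanish: a pure interaction with
exactly zero expected marginals, in which genotype class 1 falls then rises
across environment levels while class 0 does the opposite. The default
amplitude is $d = 0.5$ trait units against residual sd 1.

Not emulated: linkage disequilibrium between SNPs, genotype imputation
uncertainty, within-subject longitudinal correlation beyond the shared
intercept, kinship gradations within a pedigree, and ascertainment. Passing
the validation suite therefore demonstrates correctness of the statistic
and calibration of the schemes under the stated generating models — not
performance on any particular real cohort.

## Study conditions and numerical choices

The validation experiments run at fixed, seeded conditions:

* **Type-I calibration**: exchangeable null (`sigmaFam = 0`), 20 pedigrees
  × 10 subjects (n = 200), B = 199, 1000 replicates; each scheme and the
  comparator must land inside the exact binomial 99% band around 0.05.
* **Power contrast**: n = 500 (20 × 25), B = 199, 500 replicates, pure
  crossing vs pure linear interaction (`betaG = betaE = 0`,
  `betaGE = 0.5`, centred). Expected outcome: all three schemes ≈ 1.0 vs
  comparator ≈ 0.05 on crossing; everything above 0.9 on linear.
* **Family confounding**: null with `sigmaFam = 2`, sibship genotypes,
  family environment, n = 200, 1000 replicates; asserted directionally
  (global ≥ local).
* **Determinism**: a 1000-SNP scan at B = 999 rerun to byte identity.

Other numerical choices: scores are finite sums — no iteration, tolerance
1e-12 against a brute-force oracle; tertile breakpoints use linear
interpolation of order statistics; the add-one p-value floor is
$1/(B+1)$; derived RNG seeds are kept below $2^{31}$; rank-deficient
comparator designs (e.g. a constant environment) are flagged and skipped
rather than fitted.

## Known limitations

* $I_{G\times E}$ is blind to interactions dominated by their induced
  marginal effects (see the refinement note above); it targets crossing and
  other marginal-free patterns, which is precisely where the linear test
  fails.
* The permutation null is "no association at all", not "no interaction
  given marginals": a strong purely additive signal can, in principle,
  displace $I_{G\times E}$ from its permutation reference. This matches the
  method as published and is not corrected here.
* Residual permutation assumes identically distributed residuals across
  pedigrees; heterogeneous within-family variances degrade its calibration
  (it drifts conservative in our family-confounding runs).
* The comparator is plain OLS; on family data its p-values inherit the
  usual clustering caveats.
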