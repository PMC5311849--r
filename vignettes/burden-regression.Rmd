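---
title: "Multi-phenotype burden regression for rare variants"
author: "rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phenotype burden regression for rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The model

Single-variant tests are underpowered for rare variants (RVs; here, minor
allele frequency below 5%), and single-phenotype tests leave power on the
table when a locus influences several correlated traits.  rvburden combines
the two standard remedies: it *collapses* the rare variants of a genomic
region into one per-individual score, and it tests that score against
*multiple phenotypes jointly* by reverse regression — the genetic quantity is
the outcome and the phenotypes are the predictors, so a joint test of K
phenotypes is an ordinary K-slope linear model.

For individual $i$, let $r_i$ be the number of minor alleles carried at the
region's rare variants and $n_i$ the number of those variants successfully
genotyped or imputed for that individual.  The burden outcome is the
proportion of minor alleles $z_i$, modelled as

$$ z_i = \alpha + \boldsymbol{\beta} \mathbf{y}_i + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \sigma^2 / w_i), \qquad w_i = n_i, $$

where $\mathbf{y}_i$ is the vector of the K analysed phenotype values.  The
precision weight $w_i = n_i$ expresses that a proportion over more typed
variants is better measured; it enters the Gaussian likelihood, so the fit is
weighted least squares and the maximized log-likelihood is

$$ \ell = \tfrac{1}{2}\textstyle\sum_i \ln w_i
   - \tfrac{N}{2}\left(\ln(2\pi\hat\sigma^2) + 1\right), \qquad
   \hat\sigma^2 = \tfrac{1}{N}\textstyle\sum_i w_i e_i^2 . $$

Significance comes from the likelihood ratio against the intercept-only null
($\boldsymbol\beta = 0$) fitted on the same individuals and weights;
$2(\ell_1 - \ell_0)$ is referred to a $\chi^2$ distribution with K degrees of
freedom.  Every non-empty phenotype subset — $2^K - 1$ models — is fitted on
one shared complete-case sample, and each model's Bayesian Information
Criterion, $(K_m + 2)\ln N - 2\ell$, ranks the combinations; the subset with
the lowest BIC is the best-supported description of which traits share the
regional rare-variant signal.

### The proportion's denominator

With diploid genotypes an individual can carry up to $2 n_i$ minor alleles,
so the literal ratio $r_i / n_i$ can exceed 1.  rvburden computes the
proportion over allele copies, $z_i = r_i / (2 n_i)$, which keeps
$z_i \in [0, 1]$.  This is purely a change of scale: it halves $\alpha$ and
every $\beta_k$ (and their standard errors) and leaves the LRT statistic,
p-values, BIC differences and model ranking unchanged, because rescaling the
outcome shifts all log-likelihoods of a region by the same constant.  The
`denominator = "variants"` switch restores the literal $r_i/n_i$ for
comparison with other implementations.

### Parameter conventions that matter

* $\hat\sigma^2$ is the maximum-likelihood estimate (divide by $N$) so that
  log-likelihood and BIC are mutually coherent; standard errors use the
  unbiased estimate (divide by $N - K - 1$), the usual regression-output
  convention.
* The BIC parameter count is $K_m + 2$: intercept, the model's slopes, and
  the residual variance.  Any fixed offset convention cancels in the
  comparisons between sub-models of one region, which is the only use BIC is
  put to.
* Absolute log-likelihoods depend on the weighted-likelihood normalization
  (the $\tfrac12\sum\ln w_i$ term); only differences across models of the
  same region are meaningful, and those are invariant to rescaling all
  weights by a constant.
* The LRT statistic is clamped to zero when it is negative by less than
  1e-8 (floating-point noise); a larger violation of nesting raises an
  internal-consistency error instead of being silently absorbed.

## From genotype probabilities to the burden

Input genotypes are SNPTEST v2 probability triplets
$(p_{AA}, p_{AB}, p_{BB})$ per individual and variant, which accommodates
genotyped, imputed and sequenced data alike.

* **Missingness.** A triplet summing to less than 0.1 is a missing genotype
  (the GEN convention writes `0 0 0`).  Sums between 0.1 and 1.02 are
  renormalized to 1 — imputation output legitimately carries probability
  mass below 1, and up to 0.02 of rounding excess above 1 is tolerated —
  while larger sums indicate a corrupt line and are rejected with its line
  number.
* **Allele frequency and orientation.** Each variant's allele-B frequency is
  the mean expected dose $(p_{AB} + 2 p_{BB})/2$ over non-missing, included
  individuals — always from expected dosages, once per variant, after
  individual-level exclusions, so the frequency does not move with the
  calling threshold.  The minor allele is the one with frequency
  $\le 0.5$ (a tie designates allele B, a deterministic convention), and
  `maf` is the folded frequency.
* **Rare-variant filter.** A variant enters a region's burden iff its
  position lies inside the region (1-based, inclusive on both ends, matching
  UCSC-style gene lists), $0 < \mathrm{maf} <$ `rare_thresh` (default 0.05;
  the inequality is strict, and monomorphic variants are reported with their
  own reason), and it survives the optional extract/exclude rs-id lists.
* **Per-individual dose.** Under `method = "expected"` the contribution is
  the expected minor-allele dosage; under `method = "threshold"` the triplet
  is converted to a hard genotype when its largest probability reaches
  `call_thres` (default 0.9) and is otherwise missing for that individual.
  $n_i$ counts, per individual, the variants with a usable genotype under
  the chosen method, so an uncertain genotype costs that individual one unit
  of weight rather than injecting noise.

Variants whose triplets are missing for every included individual have no
defined frequency; they are dropped and logged and never counted in any
$n_i$.  Individuals with $n_i = 0$ are excluded from the regression and
flagged.

## What the synthetic generator emulates — and what it does not

`simSpec()` fixes the simulated study: its defaults are 500 individuals, 20
rare variants with MAFs spread evenly over 0.5–4%, 2% missing triplets, 0.98
probability mass on the true genotype, and three phenotypes with the
pairwise correlations 0.37 / 0.18 / 0.19 of a metabolic-trait triple
(triglycerides, fasting insulin, waist-to-hip ratio) in a population cohort
— a realistic operating point for a gene-based scan.  Genotypes are
independent binomial draws per variant; phenotypes are multivariate normal.

In *effect mode* the generator runs the model generatively in the same
direction the estimator assumes: phenotypes are drawn first, then
$z_i = \alpha + \boldsymbol\beta \mathbf{y}_i + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \mathrm{residualSd}^2 / n_i)$, and $z_i$ is
projected back to integer minor-allele counts ($r_i = \mathrm{round}(2 n_i
z_i)$, re-distributed over the individual's typed variants with at most two
copies each).  This is the correct parameter-recovery design for reverse
regression — the data-generating process is exactly the fitted model — and
the rounding projection perturbs each $z_i$ by at most $1/(4 n_i)$,
symmetrically, so recovery tests can demand unbiasedness to Monte-Carlo
precision.  Effect sizes that would push more than 1% of draws outside
$[0,1]$ are rejected with advice rather than silently truncated.

The generator deliberately omits linkage disequilibrium, haplotype
structure, population stratification and genotyping batch effects, and its
uncertainty model (a symmetric `certainty` smear) is cruder than calibrated
imputation posteriors — with `certainty` below 1 the smear inflates expected-
dosage allele frequencies by a known offset, which real imputation output
does not.  Passing calibration and recovery tests on these fixtures
therefore demonstrates the statistics and the file plumbing, not robustness
to confounding in real cohorts; phenotypes should be pre-adjusted for
covariates and transformed toward normality upstream, as is standard
practice for burden scans.

## Numerical and design choices

* Collinear phenotype sets yield a singular weighted cross-product; the
  model is reported with status `singular` rather than an arbitrary
  coefficient drop, and the remaining sub-models are unaffected.  A constant
  outcome (for instance, no minor alleles in the region at all) gives
  $\hat\sigma^2 = 0$; the fit is flagged `degenerate` and no p-value is
  produced.
* The shared complete-case rule (an individual missing *any* analysed
  phenotype leaves *all* sub-models) is what makes the BIC comparison
  between sub-models meaningful: BIC values on different samples are not
  comparable.  A region with fewer than $K + 3$ complete cases is skipped
  with that reason.
* Regions are processed from one streaming pass over the GEN file with
  per-region accumulators, so memory scales with the number of regions and
  individuals, not with the file length or with K.  Overlapping regions are
  legal; a variant contributes to every region containing it.  Analysis is
  deterministic — reruns are byte-identical.
* The region file is the 3-column `name start end` dialect; a 4-column
  variant with a leading chromosome is accepted, in which case GEN field 1
  is matched as a chromosome code (and the log says so prominently).
  Extract/exclude lists match GEN field 2, the rs id.
* Output p-values are never adjusted for multiple testing;
  `bonferroniThreshold()` is provided to compute the conventional
  genome-wide thresholds (e.g. $0.05/30{,}000 = 1.7\times10^{-6}$ for a
  gene-based scan) for the user's reporting.

## Verification

The test-suite sizes are chosen to give stable Monte-Carlo verdicts on a
single CPU: the weighted fit is checked against an independent brute-force
normal-equations solver on 200 random instances (agreement to 1e-8
relative); null calibration uses 5,000 single-region replicates at the
generator's default operating point, requiring the full-model rejection rate
at $\alpha = 0.05$ to lie in $[0.04, 0.06]$ and the LRT statistic to pass a
$\chi^2_3$ Kolmogorov–Smirnov check at $p > 0.01$; parameter recovery uses
1,000 effect-mode replicates and requires the mean estimates to sit within 3
Monte-Carlo standard errors of the truth.  `scripts/acceptance.R` recomputes
all of these from scratch.

One note on model counts: all non-empty subsets of K phenotypes give
$2^K - 1$ fitted models (3 for K = 2, 15 for K = 4, 255 for K = 8), which is
what `enumerateModels()` returns and the tests assert.

## Limitations

Binary outcomes are handled as 0/1 phenotypes inside the linear model (no
logistic reverse regression); covariate adjustment happens upstream of the
sample file; variants are unweighted within the burden (no functional
annotation weights) and variance-component (SKAT-type) alternatives, which
are more powerful when effect directions oppose each other across variants,
are out of scope.  The $\chi^2$ reference is asymptotic: for very small
regions-by-sample combinations the complete-case guard ($N \ge K + 3$) keeps
the fit defined but p-values in tiny samples should be treated with care.
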