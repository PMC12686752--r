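---
title: "Multi-breed single-step genomic evaluation: models, matrices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-breed single-step genomic evaluation: models, matrices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Local beef cattle breeds are evaluated for growth traits measured on young
bulls in station performance tests: average daily gain (ADG, kg/day), weight
at one year (WEI, kg) and muscularity (MUS, score). Each breed alone has few
phenotypes and genotypes, so single-breed genetic evaluations have limited
accuracy, especially for breeds with low heritability. Two remedies are on
the table: adding genomic information through single-step GBLUP (ssGBLUP),
and borrowing information across breeds and across correlated traits with
multi-breed (MB) and multi-trait (MT) mixed models. `mbssgblup` implements
the full tool chain needed to build and compare such evaluations, and a
synthetic three-breed data generator so every stage can be exercised and
validated without access to any proprietary herdbook data.

# Models

The base single-trait animal model is

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Zu} + \mathbf{e}, \qquad
\mathbf{u} \sim N(0, \sigma^2_u \mathbf{K}), \qquad
\mathbf{e} \sim N(0, \sigma^2_e \mathbf{I}),$$

with fixed effects `b` = contemporary groups (breed x birth month x birth
year) and farm of origin. `K` is the pedigree relationship matrix **A** in
pBLUP and the combined matrix **H** in ssGBLUP. Two multivariate extensions
share the machinery through a Kronecker genetic covariance
$\mathrm{Var}(\mathbf{u}) = \mathbf{G}_0 \otimes \mathbf{K}$:

* **correlated-trait multi-breed** (MTMB): ADG is a different trait per
  breed; each animal carries a record only for its own breed's trait, and
  between-breed genetic covariances in $\mathbf{G}_0$ (3x3 over breeds) link
  the populations;
* **three-trait**: ADG, WEI and MUS per breed (or pooled across breeds),
  with WEI carrying an initial-test-weight covariate and MUS an
  age-at-measurement covariate.

Residuals are uncorrelated within and across effective traits (diagonal
$\mathbf{R}_0$); records with a missing trait simply drop out of that
trait's rows, which is exact under a diagonal residual covariance.

# Relationship matrices

* **A** by the tabular recursion; inbreeding by the recursive
  (Meuwissen-Luo style) ancestor-accumulation algorithm, which is exact and
  O(n x ancestors); **A^-1** assembled sparsely by Henderson's rules with
  Mendelian-sampling variances `0.5 - 0.25(F_s + F_d)` (and the one-parent
  and founder variants).
* **A22** (pedigree relationships among genotyped animals) is obtained
  without forming dense A, by solving `A^-1 X = E` on the genotyped unit
  columns through a sparse Cholesky factorization.
* **G** variants: VanRaden method 1 (`MM'/Σ2pq`, mean-imputed missing
  codes), the breed-wise scaling that centers and scales each animal by its
  own breed's allele frequencies (cross-breed blocks use the geometric mean
  of the two breeds' scaling sums), and the 0.5-frequency base `ZZ'/(m/2)`
  used with metafounders.
* **H^-1** = `A^-1 + [[0,0],[0, Gb^-1 - A22^-1]]` on the genotyped block,
  with `Gb = 0.95 G + 0.05 A22` guarding positive definiteness. The blend
  weight is a fixed default, not a tuning knob.
* **Metafounders**: one pseudo-founder per breed with self- and
  cross-relationships $\Gamma$, estimated by the moment estimator
  $\gamma_b = 8\,\mathrm{Var}_m(p_{bm})$,
  $\gamma_{bb'} = 8\,\mathrm{Cov}_m(p_{bm}, p_{b'm})$ with population
  (1/m) moments, eigen-clipped to positive semi-definite. A($\Gamma$) is
  built by the tabular recursion on the augmented pedigree (metafounder
  block initialized to $\Gamma$, every unknown parent replaced by its
  breed's metafounder), and the sparse augmented inverse by generalized
  Henderson rules with `m_i = a_ii - 0.25(a_ss + 2a_sd + a_dd)` plus a
  $\Gamma^{-1}$ block. Genetic variances estimated on the ordinary base are
  moved to the $\Gamma$ base by dividing by
  `k = 1 + mean(diag Γ)/2 - mean(Γ)`; the direction (division) follows the
  metafounder literature's change-of-base argument, and the LR statistics
  that depend on $\sigma^2_u$ therefore use the rescaled value.

# Genotype quality control

A single deterministic pass, in this order: SNP call rate < 0.95 removed,
animal call rate < 0.95 removed, MAF < 0.05 removed (exactly 0.05 is
retained, matching a strict "less than" rule), and SNPs with
parent-offspring opposite-homozygote conflicts above a configurable rate
(default: any conflict) removed. QC runs within breed for single-breed
evaluations and pooled for multi-breed ones. Markers monomorphic within one
breed (but polymorphic pooled) contribute zero to that breed's centering and
scaling in the breed-wise G rather than raising an error, which is how the
breed-wise formula treats them naturally.

# Variance components by Gibbs sampling

The sampler draws all location effects jointly from their multivariate
normal full conditional via one sparse Cholesky factorization per cycle
(symbolic analysis reused across cycles), the genetic covariance
$\mathbf{G}_0$ from its inverse-Wishart full conditional with scale
$\mathbf{U}'\mathbf{K}^{-1}\mathbf{U}$, and each residual variance from a
scaled inverse-chi-square. Joint location sampling was chosen over
single-site scanning because it removes the dominant autocorrelation at
these problem sizes; chains of a few thousand cycles then deliver effective
sample sizes that single-site updating would need orders of magnitude more
cycles to reach. The stationary distribution is identical.

**Priors.** Defaults are flat on the (co)variance scale: degrees of freedom
`-(T+1)` with a negligible scale floor (`1e-8` of the phenotypic variance)
for the genetic covariance, and the `nu = -2` flat equivalent for
residuals. We initially considered a "minimally informative" inverse-Wishart
with `nu = T + 2` and a small scale; its density behaves like
$g^{-(T+3)/2}$ near zero and, with a tiny scale matrix, concentrates an
enormous prior spike just above zero variance. Cross-checking the sampler
against an exact two-dimensional grid integration of the restricted
likelihood showed both (correctly) collapsing the heritability posterior
toward zero at realistic data sizes while REML on the same data sat near
the simulated truth. Flat priors remove that artifact; informative
inverse-Wishart priors remain available through the `priors` argument.

Chain settings mirror common practice (long chains, burn-in, thinning of
10); the correlated-trait multi-breed scenarios restrict VCE to
phenotyped-and-genotyped animals so that phenotypes with no genomic link
between breeds do not enter, and use longer chains. Convergence is checked
by split-chain potential scale reduction (warn above 1.1) and a crude
autocorrelation-based effective sample size (warn below 100), on top of the
traditional graphical inspection.

# LR forward validation

Phenotypes of all animals born on or after a cutoff date (half-open
comparison on year and month) are set to missing in the partial evaluation.
The focal group is, per breed, the phenotyped bulls born on/after the
cutoff. With whole- and partial-data EBVs $\hat u_w, \hat u_p$ over the
focal group:

$$\widehat{acc}_p = \sqrt{\frac{\mathrm{cov}(\hat u_w, \hat u_p)}
{(1-\bar F)\,\sigma^2_u}}, \qquad
\hat b_p = \frac{\mathrm{cov}(\hat u_w, \hat u_p)}{\mathrm{var}(\hat u_p)},
\qquad
\hat\Delta_p = \frac{\overline{\hat u_p} - \overline{\hat u_w}}
{\sqrt{\sigma^2_u}},$$

with expectation 1 for dispersion (within 15% considered acceptable) and 0
for level bias (in genetic standard deviations). Two conventions the
literature sometimes leaves implicit are fixed here: the accuracy carries
the square root (the covariance-over-variance ratio itself estimates a
squared accuracy), and the level bias divides by the genetic standard
deviation, not the variance. $\bar F$ is the mean pedigree inbreeding of
the focal group and $\sigma^2_u$ the per-breed additive variance from the
scenario's own whole-data components. Standard errors come from
bootstrapping focal animals (pairs of whole/partial EBVs jointly), 10,000
samples by default; degenerate resamples are skipped and counted. EBVs are
rebased per breed to the mean of a base cohort (phenotyped bulls of the
two earliest phenotyped birth years by default) before validation; this
shifts both evaluations essentially equally and leaves dispersion untouched.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* three breeds drifted from a common ancestral allele-frequency pool
  (ancestral p ~ U(0.1, 0.9), drift variance `d p(1-p)`, default d = 0.05,
  clipping to (0.02, 0.98)) — enough divergence for breed-wise scaling and
  $\Gamma$ estimation to have something to estimate;
* discrete generations of within-breed random mating (default 120 founders,
  4 offspring generations of 300, 25-sire teams per generation), birth
  dates spread over 7-year blocks from 1988 with four station-intake months
  per year, giving contemporary groups of realistic size and a multi-decade
  span for forward validation;
* gene-dropped genotypes (2,000 independent markers by default) and
  marker-effect breeding values whose (trait x breed) covariance hits the
  configured targets: per-breed ADG heritabilities 0.25/0.18/0.35, ADG-WEI
  correlation 0.95, breed-specific moderate ADG-MUS and WEI-MUS
  correlations, between-breed ADG correlation 0.4 by default; trait means
  and phenotypic spreads match published performance-test descriptives
  (ADG ~1.6 +- 0.24 kg/d, WEI ~548 +- 57 kg, MUS ~380 +- 62);
* phenotypes on young bulls only (configurable), with contemporary-group
  and farm effects and the two covariates; an infinitesimal
  (pedigree-based) mode exists for pedigree-only studies where gene
  dropping would be wasted work.

What it deliberately does **not** emulate: linkage and LD structure beyond
drift (markers are independent), selection (matings are random, so
validation statistics have their textbook expectations), genotyping-error
processes, and cross-breed matings. Passing tests on these data therefore
demonstrate correctness of the machinery and the qualitative behaviour of
the estimators, not calibration to any real population.

# Numerical choices

* Fixed-effect identifiability: contemporary groups keep all levels; the
  farm factor drops one level per connected component of the record-level
  CG-farm graph (farms are nested in breeds, so pooled multi-breed models
  need one constraint per breed). A logged `1e-8` ridge on the fixed block
  is the fallback for residual confounding.
* Solver: sparse Cholesky throughout, relative-residual tolerance `1e-10`;
  dense linear algebra only on genotyped-block matrices.
* Degenerate inputs: empty contemporary groups are dropped with the
  record subset; an all-missing marker, an empty focal or base group, a
  non-positive-definite blended G, and a non-positive metafounder scaling
  factor k all raise informative errors rather than propagating.
* Problem sizes in the test-suite simulations (a few hundred to ~3,000
  animals, 200-2,000 markers, chains of 1,000-40,000 cycles) were chosen as
  the smallest at which the checked statistical properties are expected to
  hold with comfortable Monte-Carlo margins.

# Known limitations

No reliabilities from the MME inverse, no unknown-parent groups outside the
metafounder path, no maternal or repeated-record models, no APY-style
sparse-G approximations, mean imputation only. The between-breed
correlation structure of the generator ties cross-breed, cross-trait
correlations to the product of the between-breed ADG correlation and the
averaged within-breed pattern, eigen-clipped to PSD — a pragmatic choice;
other couplings are conceivable.
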