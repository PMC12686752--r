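# mbssgblup

Multi-breed single-step genomic evaluation of beef performance-test traits,
with forward-in-time LR validation and a synthetic data generator.

## What this package is for

Local beef cattle breeds are selected on station performance tests of young
bulls — average daily gain (ADG, kg/day), weight at one year (WEI, kg) and
muscularity (MUS, score) — but each breed alone has few phenotypes and
genotypes. This package implements, end to end, the evaluation designs used
to quantify what genomic data, multi-breed models and correlated companion
traits each contribute to prediction accuracy:

* **Relationship matrices**: pedigree **A** (tabular), its sparse Henderson
  inverse with inbreeding (recursive Meuwissen-Luo-style F), `A22`,
  metafounder **A(Γ)** and its sparse augmented inverse; genomic **G** by
  VanRaden method 1, by breed-wise allele-frequency scaling (Wientjes), and
  on the 0.5-frequency metafounder base; the single-step combined inverse

  `H⁻¹ = A⁻¹ + [[0, 0], [0, (0.95 G + 0.05 A22)⁻¹ − A22⁻¹]]`.

* **Mixed models**: single- and multi-trait animal models with
  `Var(u) = G₀ ⊗ K` (K = A or H), contemporary-group and farm fixed
  effects, covariates for WEI/MUS, sparse-Cholesky solving, and rebasing of
  EBVs to a per-breed base cohort.
* **Variance components** by Gibbs sampling (blocked location updates,
  inverse-Wishart/inverse-chi-square full conditionals, flat default
  priors), with posterior heritabilities, genetic correlations, split-chain
  Rhat and effective-sample-size diagnostics.
* **LR validation**: truncate phenotypes at a cutoff birth date, re-evaluate,
  and compute over the focal group (phenotyped young bulls born after the
  cutoff)

  `acc_p = sqrt( cov(û_w, û_p) / ((1 − F̄) σ²_u) )`,
  `b_p = cov(û_w, û_p) / var(û_p)` (expectation 1, ±15% acceptable),
  `Δ_p = (mean û_p − mean û_w) / sqrt(σ²_u)` (expectation 0, in genetic SD),

  with bootstrap standard errors.
* **Ten ready-made scenarios** (`scenario_table()`): single-/multi-breed x
  pedigree/single-step x ADG-only/three-trait, including the
  correlated-trait multi-breed models with VanRaden, breed-wise and
  metafounder G variants.
* **A synthetic three-breed generator** (drifted allele frequencies,
  discrete-generation pedigrees, gene-dropped genotypes, marker-effect
  breeding values hitting configured heritabilities and genetic
  correlations, station contemporary groups) so the whole pipeline is
  testable without any proprietary data.

The methods vignette (`vignettes/multibreed-ssgblup.Rmd`) documents the
models, the estimators, the generator's assumptions and every numerical
choice.

## Worked example

Simulate two breeds with a shared genetic architecture (between-breed
genetic correlation 1) but different heritabilities (0.15 vs 0.40), then ask
whether pooling them in a single-trait multi-breed ssGBLUP helps the
low-heritability breed:

```r
library(mbssgblup)

cfg <- sim_config(breeds = c("LOW", "HIGH"), h2_adg = c(LOW = 0.15, HIGH = 0.40),
                  rg_between = 1, founders_per_breed = 60, offspring_per_gen = 150,
                  generations = 4, markers = 500, genotyping_prop = 0.9, seed = 42)
ds <- simulate_dataset(cfg)

sb <- run_scenario("SB_ssGBLUP", ds, control = list(bootstrap_B = 1000))
mb <- run_scenario("STMB_ssGBLUP", ds, control = list(bootstrap_B = 1000))

cols <- c("scenario", "breed", "acc_p", "acc_p_se", "b_p", "b_p_se", "delta_p", "delta_p_se")
print(rbind(sb$metrics[, cols], mb$metrics[, cols]), digits = 3, row.names = FALSE)
```

```
     scenario breed acc_p acc_p_se   b_p b_p_se delta_p delta_p_se
   SB_ssGBLUP  HIGH 0.375   0.0367 1.028 0.1454 -0.0928     0.0482
   SB_ssGBLUP   LOW 0.334   0.0266 1.074 0.0875  0.0261     0.0324
 STMB_ssGBLUP  HIGH 0.397   0.0348 1.190 0.1325 -0.0517     0.0432
 STMB_ssGBLUP   LOW 0.411   0.0321 0.977 0.0848  0.0110     0.0396
```

Each row is one breed's forward validation: `acc_p` is the accuracy of the
truncated-data EBVs, `b_p` their dispersion (1 = none), `delta_p` the level
bias in genetic standard deviations (0 = none), each with its bootstrap SE.
Here pooling lifts the low-heritability breed's accuracy from 0.33 to 0.41
while leaving dispersion near 1 — borrowed information from the correlated
high-heritability partner. The comparison helper flags any dispersion
outside the 15% band:

```r
print(compare_scenarios(mb, sb)[, c("breed", "d_acc_p", "d_b_p", "dispersion_flag")],
      digits = 3, row.names = FALSE)
```

```
 breed d_acc_p   d_b_p dispersion_flag
  HIGH  0.0222  0.1620            TRUE
   LOW  0.0769 -0.0968           FALSE
```

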