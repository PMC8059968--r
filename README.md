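# phylomi

Comparative trait analyses routinely discard most of their species because a
single predictor is unrecorded: behavioural and life-history tables for wild
mammals are typically ~25% empty, and listwise deletion both shrinks the
sample and biases it toward well-studied clades. `phylomi` implements a
pipeline that keeps every species instead: phylogenetically informed multiple
imputation of the trait table, Bayesian phylogenetic mixed models fitted on
every completed dataset, and pooling of all runs into a single inference. It
was built around the classic question of what predicts relative brain size
(endocranial volume conditional on body mass) across a marsupial-scale
radiation, but every stage is generic.

## What it computes

**Phylogenetic MICE with predictive mean matching.** Missing cells are
imputed column by column with chained equations. Each conditional model is a
Brownian-motion PGLS, `y = Xβ + ε`, `ε ~ N(0, σ²C)`, where `C[i,j]` is the
shared root-to-MRCA branch length. Coefficients are drawn from their
approximate joint posterior (`σ²* = σ̂²·df/χ²_df`, `β* ~ N(β̂, σ²*(XᵀC⁻¹X)⁻¹)`),
each row is scored by its conditional expectation given the observed rows
(the phylogenetic BLUP for missing rows, a leave-one-out mean for observed
ones), and each missing cell copies the value of one of the k = 5
nearest-score donors — so imputations are always real observed values. The
number of imputed datasets follows the percent-missing rule (25% missing →
m = 25).

**Phylogenetic mixed models ("animal model").** On every completed dataset,
`y = Xβ + u + e` with `u ~ N(0, σ²ₐC)`, `e ~ N(0, σ²ₑI)` is sampled by a
blocked Gibbs sampler (flat prior on β, inverse-gamma(0.001, 0.001) on both
variances), two chains per dataset, with effective sample size and
split-R̂ diagnostics. Reported per model: phylogenetic heritability
`h² = σ²ₐ/(σ²ₐ+σ²ₑ)`, the deviance information criterion, and for each
coefficient the fraction of posterior mass above zero (≥95% on one side ⇒
significant).

**Rubin's rules pooling.** Per-run posterior means/variances combine as
`Q̄ = mean(Q)`, `T = Ū + (1+1/m)B`; posterior tail fractions pool by sample
concatenation across all dataset × chain runs.

**Evolutionary mode selection.** Brownian motion, Ornstein–Uhlenbeck and
early-burst models fitted by maximum likelihood per landmass subset and
ranked by AIC; plus a phylogenetic ANCOVA (nested-model F-test in the C⁻¹
metric) with variance inflation factors.

**Missing-data diagnostics.** Per-column patterns, co-missingness, and the
Fritz–Purvis D statistic of each column's missingness indicator (D ≈ 1:
phylogenetically random gaps; D ≈ 0: clade-clumped gaps).

A synthetic-data generator (`simulate_study()`, `paper_emulation_config()`)
evolves a 176-species, 16-trait table with known effect sizes,
threshold-model categorical traits and per-column MCAR / MAR /
phylogenetically clumped missingness, so the entire pipeline is testable
without any external data.

## Worked example

```r
library(phylomi)

cfg <- analysis_config(
  data       = paper_emulation_config(seed = 42, n_tips = 120),
  imputation = imputation_config(m = 3, n_iter = 6, seed = 42),
  sampler    = sampler_settings(),                 # 3000 iter, 2 chains
  registry   = model_registry()["developmental"],  # litter size + weaning age
  seed       = 42, d_perm = 150)
report <- run_full_analysis(cfg)
print(report)
```

```
=== pooled model table ===
         model        term    beta     se pct_above_zero         significance
 developmental (Intercept)  0.8275 0.3267          99.70 significant-positive
 developmental    log_body  0.7618 0.0476         100.00 significant-positive
 developmental litter_size -0.2003 0.0407           0.00 significant-negative
 developmental weaning_age  0.0303 0.0368          80.20      not significant
 mean_dic mean_h2
     -108   0.986
...
=== phylogenetic ANCOVA ===
phylogenetic ANCOVA: F = 4.407 on 2 and 116 df, p = 0.0143
max VIF: 3.60
```

Reading it: the allometric slope of log brain on log body is ~0.76; the
generator's built-in negative litter-size effect (−0.2) is recovered at
−0.20 with essentially all posterior mass below zero, while the null
weaning-age coefficient stays non-significant; phylogeny absorbs ~99% of
residual variance (h²); and the ANCOVA compares allometries with and
without origin-specific slopes. `report$evo_table` holds the per-landmass
BM/OU/EB ranking and `report$diagnostics` the missingness pattern, D
statistics and imputation convergence summary.

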