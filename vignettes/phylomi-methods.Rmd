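---
title: "Methods: phylogenetic multiple imputation and Bayesian comparative models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic multiple imputation and Bayesian comparative models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the choices that were genuinely open and how they were settled, the
defaults and why, and what the synthetic-data tests do and do not
demonstrate about real data.

## The problem

Species trait tables in comparative biology are sparse — behavioural traits
especially can be missing for more than half the species — and species are
not independent observations: closely related species resemble each other
in proportion to their shared evolutionary history. `phylomi` treats both
problems jointly. Its covariance workhorse is the Brownian-motion matrix
`C` of a time-calibrated phylogeny, `C[i, j]` = branch length shared from
the root to the most recent common ancestor of tips *i* and *j*. Trees with
zero-length branches (a common device for recording polytomies) are
repaired by `resolve_zero_branches()`: every zero branch is set to 1e-4
times the median *positive* branch length — zeros are excluded from the
median because including them would drag it toward zero — and terminal
branches are then extended so all tips again reach the maximum depth. Tip
order is lexicographic everywhere, so every derived matrix is reproducible.

## Phylogenetic chained-equation imputation

`chained_equations()` is multiple imputation by chained equations in which
every conditional model is a Brownian-motion PGLS and every fill-in is a
predictive-mean-matching (PMM) donor draw:

1. *Initialization.* Each missing cell starts as a random draw from its
   column's observed values (seeded).
2. *Sweeps.* Incomplete columns are visited in ascending order of
   missingness (the best-observed columns stabilize first) for `n_iter`
   sweeps. Eligibility as a predictor requires a missing fraction below
   `predictor_max_missing` (default 0.35), judged on the original
   missingness pattern.
3. *One column update* (`pmm_impute_variable()`): fit
   `y = Xβ + ε, ε ~ N(0, σ²C_oo)` on the observed rows (`C_oo` by
   row/column deletion — the correct marginal of a multivariate normal);
   draw `σ²* = σ̂²·df/χ²_df` and `β* ~ N(β̂, σ²*(XᵀC_oo⁻¹X)⁻¹)`; score every
   row; give each missing row the observed value of one of its `k = 5`
   nearest-score donors, chosen uniformly.

**Scores are conditional expectations, not bare fitted values.** A missing
row's score is `xᵀβ* + C_mo C_oo⁻¹ (y_obs − X_obs β*)` — the phylogenetic
best linear unbiased prediction given the observed relatives — and an
observed row's score is its leave-one-out conditional mean
`y_i − (C_oo⁻¹ r)_i / (C_oo⁻¹)_ii` under `β̂`. This was a genuinely open
design point: matching on fixed-effect scores alone would make the
phylogeny nearly irrelevant to the imputations (only through the modest
efficiency gain in `β̂`), and measurably fails to outperform a
non-phylogenetic ablation. With conditional scores the phylogeny enters
where it matters — a species' gap is filled by donors whose values sit
where its clade sits — and setting `C = I` recovers exactly the ordinary
PMM fitted-value matching, which is the ablation contrast the test suite
exercises. The asymmetry (β* for missing rows, β̂ for observed rows) is
deliberate: it is the "type-1" matching convention, which propagates
parameter uncertainty into imputations without destabilizing the donor
ranking.

Other fixed conventions: donor ties in |score difference| break by taxon
label before the uniform draw (reproducibility); categorical targets are
integer-coded over the sorted observed level set, regressed as numbers, and
filled with donor *categories*, so imputed levels are always valid — a
dedicated polytomous model was considered out of scope. The number of
datasets follows the percent-missing rule (`choose_m()`): 25% missing
information → 25 imputations, floored at 2.

`convergence_summary()` regresses per-sweep imputed-cell means on the sweep
index over the final half of the chain (pooled across datasets) and flags a
column converged when the slope is statistically indistinguishable from
zero; the between/within-dataset variance ratio of those means is reported
alongside. This is a numerical stand-in for the strip/density plots usually
inspected by eye.

## The phylogenetic mixed model

Each completed dataset feeds `fit_phylo_glmm()`:
`y = Xβ + u + e`, `u ~ N(0, σ²ₐC)`, `e ~ N(0, σ²ₑI)`. Priors are flat on β
and inverse-gamma(0.001, 0.001) on both variances — the conjugate
approximation to "flat and uninformative"; a truly flat variance prior
breaks conjugacy, so the hyperparameters are exposed
(`sampler_settings(prior_shape=, prior_rate=)`) rather than asserted.
Categorical fixed effects use treatment coding with the alphabetically
first level as baseline.

The sampler works in the eigenbasis of `C = U D Uᵀ`: with `ỹ = Uᵀy`,
`X̃ = UᵀX`, `v = Uᵀu`, the model becomes diagonal
(`v ~ N(0, σ²ₐD)`, rotated residuals i.i.d.). One sweep draws β from its
conditional with `v` integrated out (a diagonal-weight GLS — jointly with
the subsequent `v | β` draw this is a blocked (β, u) update by
composition), then both variances from their conjugate inverse-gamma
conditionals. Cost is O(np²) per sweep after the one-off
eigendecomposition, so desk-scale chains run in seconds. Chains start at
overdispersed heritabilities (0.1 and 0.9) to make split-R̂ meaningful.

Defaults are desk-scale — 3000 iterations, 500 burn-in, thinning 5, two
chains — chosen so the full test suite and the acceptance script complete
in minutes while posterior means are stable to well under the pooled
standard errors; long-run settings (1 000 042 iterations, 150 000 burn-in,
thinning 250) sit behind `sampler_settings(paper_scale = TRUE)`.

**DIC** is computed on the *marginal* likelihood
`y ~ N(Xβ, σ²ₐC + σ²ₑI)` — evaluable from the stored draws (β, σ²ₐ, σ²ₑ)
alone — as `DIC = D̄ + (D̄ − D(θ̄))`. Tools that condition on the random
effects report a hierarchical deviance instead; the two orderings usually
agree on model *ranking* but not on absolute values, so DIC here is for
comparing models fitted by this package to each other.

**Significance** follows the posterior-mass rule: a coefficient with ≥95%
of its mass above (below) zero is labelled significant-positive
(-negative). Note this rule trips for roughly 10% of truly null
coefficients (it is a credibility statement, not a calibrated test); the
end-to-end null-preset test allows for exactly that behaviour.

## Pooling

`rubin_pool()` implements Q̄, Ū, B, T = Ū + (1 + 1/m)B with Barnard–Rubin
degrees of freedom for intervals. Runs are dataset × chain units, so m
imputations × 2 chains pool as 2m runs. Posterior tail fractions are *not*
Rubin-pooled — the rules are defined for point estimates — but computed on
the concatenation of all runs' samples, weighting runs equally; pooled
fractions therefore always lie between the per-run extremes. DIC and
heritability pool as plain means. Both √T (primary, reported as `se`) and
the mean posterior SD (`se_within`) are emitted, since either convention
appears in published tables.

## Evolutionary mode selection

`fit_bm`, `fit_ou`, `fit_eb` are exact maximum-likelihood fits with the
mean and rate profiled out analytically; OU's pull α and EB's decay a are
the only numerically optimized parameters (coarse grid + golden-section
polish; α ∈ [1e-8, 50/depth] log-spaced, a ∈ [−10/depth, 0]). The OU
covariance uses the fixed-root parameterization
`V_ij = σ²/(2α)·e^(−α d_ij)(1 − e^(−2α t_ij))` with the root at the
optimum (z₀ = θ): unlike the stationary-root form it nests Brownian motion
exactly as α → 0 (implemented with `expm1` so the limit is numerically
clean), which both the simulators and the nesting tests rely on. EB is a
branch-length transform, `ℓ' = (e^(a t₂) − e^(a t₁))/a` per branch segment.
AIC (not AICc) ranks the three fits; `bootstrap_assessment()` additionally
offers a parametric-bootstrap adequacy check (simulate under the fitted
model, locate the observed variance and mean standardized contrast in the
simulated distribution) for users who prefer a simulation-based
assessment. `per_landmass_analysis()` prunes the tree per group level and
requires ≥10 tips per subset by default — below that the ML fits of
three-parameter models are not meaningfully comparable.

## Fritz–Purvis D

`phylo_d()` sums, over internal nodes, the absolute differences between
daughter-clade values under equal-weights node averaging (equivalently:
the sum over edges of |child − parent| node values), then scales the
observed sum between two null means — tip-label shuffles (D = 1) and
thresholded Brownian liabilities matched to the observed prevalence
(D = 0). Because the sum is invariant under 0↔1 relabeling, the Brownian
null thresholds at the minority-state count, making D exactly symmetric
under relabeling. Missingness indicators (1 = missing) feed this per
column in `missingness_signal()`.

## The synthetic study

`paper_emulation_config()` fixes the generator's study conditions: 176
species on a unit-depth pure-birth tree; 16 trait columns (6 continuous,
10 categorical) named for a marsupial-style dataset; brain size
`log_ecv = 0.5 + 0.75·log_body − 0.2·litter_size + BM(0.1) + N(0, 0.05²)`
with all other effects zero; every predictor latent loading 0.3 on
centered body mass so predictors are realistically intercorrelated;
categorical traits cut from Brownian liabilities at empirical quantiles
(so they carry phylogenetic signal, which the imputer needs to be
testable). Missingness is exact-count per column — `round(rate·n)` cells —
because the generator's contract promises realized rates within ±2
percentage points, which Bernoulli masking cannot guarantee at n = 176:
`play` 120/176 (68%) and `torpor` 94/176 (53%) are clade-clumped
(thresholded Brownian liabilities), `home_range` and `status` depend on
body mass (MAR, weighted sampling without replacement), the rest are MCAR,
and the incomplete-column rates average exactly 25%. `fmr` is 40% missing,
above the 0.35 predictor-eligibility threshold, leaving 13
predictor-eligible columns. A pure-birth tree is used rather than a
coalescent one deliberately: coalescent trees have vanishingly short
terminal branches whose GLS whitening pathologically magnifies tip-level
noise.

What the generator does *not* emulate: measurement error on endocranial
volumes, body-mass dimorphism, non-Gaussian continuous traits, and any
particular true dependence structure among the predictors beyond the
shared body-mass loading. Passing tests therefore demonstrate that the
pipeline recovers effects *when its covariance model is approximately
right*, not that real marsupial data satisfy that model.

## Pipeline and reproducibility

`run_full_analysis()` executes: diagnose → impute → fit (every registry
model × dataset × chain) → pool → evolutionary models per origin →
phylogenetic ANCOVA (default contrast: allometry with vs without
origin-specific slopes, F on the C⁻¹-metric residual sums) with VIFs
computed on the Cholesky-whitened design (intercept used in the auxiliary
regressions but not reported). Every stage derives its own seed from the
master seed by hashing stage labels, so any configuration replays
bit-identically; a failing stage aborts with its name. The registry ships
eight hypothesis-driven specifications (developmental, environmental,
social, metabolic, torpor, play, vulnerability, origin — all with the
body-size covariate); it is an ordinary named list of `model_spec()`s, so
callers can pass any other set. Configuration is an R object
(`analysis_config()`) or a YAML file (`read_analysis_config()`); the
package's functions are the interface — there is no separate shell tool
beyond `scripts/acceptance.R`, which replays the whole analysis and writes
its headline numbers as JSON.

## Known limitations

* Gaussian responses only; categorical traits are handled in imputation
  (via donor matching) but not as GLMM responses.
* A single phylogeny: no multi-tree uncertainty propagation.
* No Pagel's λ / κ / δ branch transforms in the PGLS; the residual
  structure is pure Brownian.
* The chained-equation imputer assumes each conditional is approximately
  linear-Gaussian after log transformation of continuous traits.
* DIC values are marginal-likelihood based (see above) and not comparable
  to conditional-deviance DICs from other software.
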