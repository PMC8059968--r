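fake_draws <- function(beta, var_phylo, var_resid, chain_id = NULL) {
  structure(list(fixed_effects = beta, var_phylo = var_phylo,
                 var_resid = var_resid,
                 chain_id = chain_id %||% rep(1L, length(var_phylo))),
            class = "posterior_draws")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("heritability is the phylogenetic variance fraction", {
  d <- fake_draws(matrix(0, 4, 1), c(1, 2, 3, 1e6), c(1, 2, 3, 1e-6))
  h <- heritability(d)
  expect_equal(h[1:3], rep(0.5, 3))
  expect_gt(h[4], 1 - 1e-9)
  expect_true(all(h >= 0 & h <= 1))
})

test_that("the 95% posterior-mass rule labels coefficients", {
  expect_equal(significance(0.9694), "significant-positive")
  expect_equal(significance(0.0474), "significant-negative")
  expect_equal(significance(0.50), "not significant")
  expect_equal(significance(0.95), "significant-positive")
  expect_equal(significance(0.05), "significant-negative")
  expect_equal(significance(0.9), "not significant")
})

test_that("DIC matches a termwise deviance oracle", {
  skip_if_not_installed("mvtnorm")
  tr <- simulate_tree(10, seed = 3)
  C <- phylo_vcv(tr)
  set.seed(4)
  X <- cbind("(Intercept)" = 1, x = rnorm(10))
  y <- drop(X %*% c(1, 0.5)) + simulate_bm(tr, 1, 0)

  # degenerate single-sample chain: pD = 0, DIC = D(theta)
  d1 <- fake_draws(matrix(c(1, 0.5), 1, 2), 1.2, 0.4)
  dev1 <- -2 * mvtnorm::dmvnorm(y, drop(X %*% c(1, 0.5)),
                                1.2 * C + 0.4 * diag(10), log = TRUE)
  expect_equal(dic(d1, y, X, C), dev1, tolerance = 1e-8)

  # five hand-set samples against the explicit formula
  set.seed(9)
  B <- matrix(rnorm(10, sd = 0.3), 5, 2) + rep(c(1, 0.5), each = 5)
  vp <- runif(5, 0.5, 2); vr <- runif(5, 0.1, 0.8)
  d5 <- fake_draws(B, vp, vr)
  devs <- vapply(1:5, function(s)
    -2 * mvtnorm::dmvnorm(y, drop(X %*% B[s, ]),
                          vp[s] * C + vr[s] * diag(10), log = TRUE),
    numeric(1))
  dhat <- -2 * mvtnorm::dmvnorm(y, drop(X %*% colMeans(B)),
                                mean(vp) * C + mean(vr) * diag(10),
                                log = TRUE)
  expect_equal(dic(d5, y, X, C), mean(devs) + (mean(devs) - dhat),
               tolerance = 1e-8)
})

test_that("convergence diagnostics behave on designed chains", {
  set.seed(12)
  n <- 2000
  white <- fake_draws(matrix(rnorm(2 * n), ncol = 1),
                      abs(rnorm(2 * n)) + 0.1, abs(rnorm(2 * n)) + 0.1,
                      chain_id = rep(1:2, each = n))
  cv <- convergence(white)
  expect_gt(cv$ess[1], 0.5 * 2 * n)
  expect_lt(abs(cv$gelman_rubin[1] - 1), 0.05)

  shifted <- fake_draws(matrix(c(rnorm(n), rnorm(n, 10)), ncol = 1),
                        rep(1, 2 * n), rep(1, 2 * n),
                        chain_id = rep(1:2, each = n))
  cvs <- convergence(shifted)
  expect_gt(cvs$gelman_rubin[1], 1.1)
  expect_false(cvs$pass)

  single <- fake_draws(matrix(rnorm(n), ncol = 1), rep(1, n), rep(1, n))
  expect_warning(cv1 <- convergence(single), "fewer than 2 chains")
  expect_true(is.na(cv1$gelman_rubin[1]))
  expect_true(is.finite(cv1$ess[1]))
})

test_that("with no phylogenetic signal the posterior mean matches OLS", {
  tr <- simulate_tree(150, seed = 21)
  C <- phylo_vcv(tr)
  set.seed(22)
  body <- rnorm(150)
  y <- 1 + 0.5 * body + rnorm(150, 0, 0.5)   # iid errors: sigma2_a = 0 truth
  tt <- toy_table(tr, y, body)
  fit <- fit_phylo_glmm(tt, C, model_spec("ols", ~ log_body),
                        quick_sampler(), seed = 23)
  ols <- coef(lm(y ~ body))
  post <- colMeans(fit$draws$fixed_effects)
  se <- apply(fit$draws$fixed_effects, 2, sd)
  expect_lt(abs(post[1] - ols[1]), 3 * se[1] + 0.05)
  expect_lt(abs(post[2] - ols[2]), 3 * se[2] + 0.05)
  expect_lt(mean(fit$heritability_samples), 0.6)
})

test_that("the sampler is seed-reproducible and recovers heritability", {
  tr <- simulate_tree(120, seed = 31)
  C <- phylo_vcv(tr)
  h2 <- 0.8
  u <- simulate_bm(tr, h2, 0, seed = 32)
  set.seed(33)
  y <- 2 + u + rnorm(120, 0, sqrt(1 - h2))
  tt <- toy_table(tr, y)
  f1 <- fit_phylo_glmm(tt, C, model_spec("m", ~ 1), quick_sampler(), seed = 7)
  f2 <- fit_phylo_glmm(tt, C, model_spec("m", ~ 1), quick_sampler(), seed = 7)
  expect_identical(f1$draws$fixed_effects, f2$draws$fixed_effects)
  expect_identical(f1$draws$var_phylo, f2$draws$var_phylo)
  expect_equal(f1$dic, f2$dic)
  expect_gt(mean(f1$heritability_samples), 0.5)
  expect_lt(mean(f1$heritability_samples), 0.98)
})

test_that("halving the retained samples leaves posterior means stable", {
  tr <- simulate_tree(60, seed = 41)
  C <- phylo_vcv(tr)
  y <- simulate_bm(tr, 1, 1, seed = 42)
  tt <- toy_table(tr, y)
  f_thin1 <- fit_phylo_glmm(tt, C, model_spec("m", ~ log_body),
                            sampler_settings(n_iter = 2200, burnin = 200,
                                             thin = 2), seed = 5)
  f_thin2 <- fit_phylo_glmm(tt, C, model_spec("m", ~ log_body),
                            sampler_settings(n_iter = 2200, burnin = 200,
                                             thin = 4), seed = 5)
  expect_equal(nrow(f_thin2$draws$fixed_effects),
               nrow(f_thin1$draws$fixed_effects) / 2)
  expect_equal(colMeans(f_thin1$draws$fixed_effects),
               colMeans(f_thin2$draws$fixed_effects), tolerance = 0.1)
})

test_that("adding a pure-noise fixed effect tends to raise the DIC", {
  set.seed(51)
  worse <- replicate(12, {
    s <- sample.int(1e6, 1)
    tr <- simulate_tree(60, seed = s)
    C <- phylo_vcv(tr)
    y <- 1 + simulate_bm(tr, 1, 0, seed = s + 1)
    set.seed(s + 2)
    noise <- rnorm(60)
    df <- data.frame(row.names = tr$tip.label, log_ecv = as.numeric(y),
                     log_body = noise)
    tt <- trait_table(df, c(log_ecv = "continuous", log_body = "continuous"))
    f0 <- fit_phylo_glmm(tt, C, model_spec("null", ~ 1),
                         quick_sampler(), seed = s + 3)
    f1 <- fit_phylo_glmm(tt, C, model_spec("noise", ~ log_body),
                         quick_sampler(), seed = s + 4)
    f1$dic > f0$dic
  })
  expect_gt(mean(worse), 0.5)
})
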