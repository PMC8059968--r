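random_problem <- function(n, p, seed) {
  set.seed(seed)
  tr <- simulate_tree(n, seed = seed)
  C <- phylo_vcv(tr)
  X <- cbind("(Intercept)" = 1,
             matrix(rnorm(n * (p - 1)), n,
                    dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + simulate_bm(tr, 0.5, 0)
  list(y = y, X = X, C = C, tree = tr)
}

test_that("GLS reduces to OLS under the identity and solves exactly", {
  set.seed(1)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "a", "b")
  y <- rnorm(n)
  fit <- fit_pgls(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$beta_hat), unname(ols$coefficients),
               tolerance = 1e-12)

  # exact linear response: zero residual scale, exact coefficients
  yy <- drop(X %*% c(1, 2, -3))
  fit2 <- fit_pgls(yy, X, diag(n))
  expect_equal(unname(fit2$beta_hat), c(1, 2, -3), tolerance = 1e-9)
  expect_lt(fit2$sigma2_hat, 1e-16)
})

test_that("PGLS matches the explicit normal-equations oracle", {
  for (s in 1:5) {
    pb <- random_problem(8, 3, seed = 40 + s)
    fit <- fit_pgls(pb$y, pb$X, pb$C)
    Ci <- solve(pb$C)
    beta_oracle <- solve(t(pb$X) %*% Ci %*% pb$X,
                         t(pb$X) %*% Ci %*% pb$y)
    expect_equal(unname(fit$beta_hat), unname(drop(beta_oracle)),
                 tolerance = 1e-8)
    r <- pb$y - drop(pb$X %*% beta_oracle)
    expect_equal(fit$sigma2_hat,
                 drop(t(r) %*% Ci %*% r) / (8 - 3), tolerance = 1e-8)
  }
})

test_that("the PGLS log-likelihood is the multivariate normal density", {
  skip_if_not_installed("mvtnorm")
  pb <- random_problem(12, 2, seed = 77)
  fit <- fit_pgls(pb$y, pb$X, pb$C)
  mu <- drop(pb$X %*% fit$beta_hat)
  expect_equal(fit$loglik,
               mvtnorm::dmvnorm(pb$y, mu, fit$sigma2_hat * pb$C,
                                log = TRUE),
               tolerance = 1e-8)
})

test_that("PGLS is invariant to taxon permutation and covariance scaling", {
  pb <- random_problem(15, 3, seed = 13)
  fit <- fit_pgls(pb$y, pb$X, pb$C)
  perm <- sample(15)
  fitp <- fit_pgls(pb$y[perm], pb$X[perm, ], pb$C[perm, perm])
  expect_equal(fitp$beta_hat, fit$beta_hat, tolerance = 1e-9)
  fits <- fit_pgls(pb$y, pb$X, 7 * pb$C)
  expect_equal(fits$beta_hat, fit$beta_hat, tolerance = 1e-9)
  expect_equal(fits$sigma2_hat, fit$sigma2_hat / 7, tolerance = 1e-9)
})

test_that("PGLS agrees with gls(corBrownian) on a random tree", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(25, seed = 3)
  C <- phylo_vcv(tr)
  x <- simulate_bm(tr, 1, 0, seed = 8)
  y <- 1 + 0.5 * x + simulate_bm(tr, 0.3, 0, seed = 9)
  df <- data.frame(y = y, x = x, row.names = tr$tip.label)
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corBrownian(1, tr, form = ~1))
  fit <- fit_pgls(y, cbind("(Intercept)" = 1, x = x), C)
  expect_equal(unname(fit$beta_hat), unname(coef(g)), tolerance = 1e-6)
})

test_that("rank deficiency is reported with offending columns", {
  set.seed(2)
  X <- cbind("(Intercept)" = 1, a = rnorm(10), dup = 0)
  X[, "dup"] <- X[, "a"]
  expect_error(fit_pgls(rnorm(10), X, diag(10)), "rank deficient")
})

test_that("posterior coefficient draws have the right moments and are seeded", {
  pb <- random_problem(40, 2, seed = 21)
  fit <- fit_pgls(pb$y, pb$X, pb$C)
  set.seed(5)
  draws <- t(replicate(10000, draw_beta_posterior(fit)))
  expect_equal(colMeans(draws), fit$beta_hat, tolerance = 0.05)
  # E[sigma2*] = sigma2_hat * df / (df - 2)
  target_cov <- fit$sigma2_hat * fit$df_resid / (fit$df_resid - 2) *
    fit$XtCiX_inv
  expect_equal(unname(cov(draws)), unname(target_cov), tolerance = 0.15)
  set.seed(9); d1 <- draw_beta_posterior(fit)
  set.seed(9); d2 <- draw_beta_posterior(fit)
  expect_identical(d1, d2)
})

test_that("the nested-model F-test matches anova() under the identity", {
  set.seed(31)
  n <- 40
  X_full <- cbind(1, rnorm(n), rnorm(n), rnorm(n))
  colnames(X_full) <- c("(Intercept)", "a", "b", "c")
  y <- drop(X_full %*% c(1, 0.5, 0, 0)) + rnorm(n)
  fit_f <- fit_pgls(y, X_full, diag(n))
  fit_r <- fit_pgls(y, X_full[, 1:2], diag(n))
  res <- pgls_ancova_ftest(fit_f, fit_r)
  lm_f <- lm(y ~ X_full[, -1])
  lm_r <- lm(y ~ X_full[, 2])
  an <- anova(lm_r, lm_f)
  expect_equal(res$F, an$F[2], tolerance = 1e-9)
  expect_equal(res$p, an$`Pr(>F)`[2], tolerance = 1e-9)

  expect_error(pgls_ancova_ftest(fit_r, fit_f), "nested|more parameters")
  fit_other <- fit_pgls(y, cbind(z = rnorm(n)), diag(n))
  expect_error(pgls_ancova_ftest(fit_f, fit_other), "nested")
})

test_that("F-test p-values are near-uniform when the extra predictor is noise", {
  set.seed(17)
  ps <- replicate(200, {
    n <- 25
    tr <- simulate_tree(n, seed = sample.int(1e6, 1))
    C <- phylo_vcv(tr)
    x <- rnorm(n); noise <- rnorm(n)
    y <- 1 + x + simulate_bm(tr, 1, 0)
    Xf <- cbind("(Intercept)" = 1, x = x, noise = noise)
    pgls_ancova_ftest(fit_pgls(y, Xf, C),
                      fit_pgls(y, Xf[, 1:2], C))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.05)
})

test_that("variance inflation factors match the auxiliary-regression oracle", {
  set.seed(8)
  n <- 50
  z <- rnorm(n)
  X <- cbind("(Intercept)" = 1, a = z + rnorm(n, 0, 0.5),
             b = z + rnorm(n, 0, 0.5), c = rnorm(n))
  v <- vif(X, diag(n))
  for (j in c("a", "b", "c")) {
    r2 <- summary(lm(X[, j] ~ X[, setdiff(colnames(X), c(j, "(Intercept)"))]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-6)
  }
  expect_true(all(v >= 1))

  # orthonormal design: all VIF exactly 1
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  colnames(Q) <- c("q1", "q2", "q3")
  expect_equal(unname(vif(Q, diag(n), intercept_label = "none")),
               rep(1, 3), tolerance = 1e-9)

  Xd <- cbind(X, dup = X[, "a"])
  expect_warning(vd <- vif(Xd, diag(n)), "collinearity")
  expect_true(is.infinite(vd["dup"]) || is.infinite(vd["a"]))
})
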