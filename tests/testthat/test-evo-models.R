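test_that("Brownian fit has closed forms on the star tree and exact AIC", {
  star <- newick_tree("(A:2,B:2,C:2,D:2,E:2);")
  y <- setNames(c(1, 3, 2, 5, 4), LETTERS[1:5])
  fit <- fit_bm(y, star)
  expect_equal(fit$z0, mean(y))
  expect_equal(fit$sigma2, mean((y - mean(y))^2) / 2)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$n_params, 2L)

  expect_error(fit_bm(setNames(rep(1, 5), LETTERS[1:5]), star),
               "degenerate trait")
})

test_that("fitted log-likelihoods equal the multivariate normal density", {
  skip_if_not_installed("mvtnorm")
  tr <- simulate_tree(20, seed = 2)
  y <- simulate_bm(tr, 1.5, 3, seed = 3)
  C <- phylo_vcv(tr)
  fit <- fit_bm(y, tr)
  expect_equal(fit$loglik,
               mvtnorm::dmvnorm(y, rep(fit$z0, 20), fit$sigma2 * C,
                                log = TRUE), tolerance = 1e-8)
  fou <- suppressWarnings(fit_ou(y, tr))
  Vou <- ou_vcv(tr, fou$sigma2, fou$alpha)
  expect_equal(fou$loglik,
               mvtnorm::dmvnorm(y, rep(fou$z0, 20), Vou, log = TRUE),
               tolerance = 1e-6)
})

test_that("OU and EB nest Brownian motion in the limit and never fit worse", {
  for (s in 1:6) {
    tr <- simulate_tree(25, seed = 60 + s)
    y <- simulate_bm(tr, 1, 0, seed = 70 + s)
    bm <- fit_bm(y, tr)
    ou <- suppressWarnings(fit_ou(y, tr))
    eb <- fit_eb(y, tr)
    expect_gte(ou$loglik, bm$loglik - 1e-6)
    expect_gte(eb$loglik, bm$loglik - 1e-6)
  }
  # explicit limits of the model covariances
  tr <- simulate_tree(15, seed = 5)
  C <- phylo_vcv(tr)
  expect_equal(ou_vcv(tr, 2, 0), 2 * C)
  expect_equal(ou_vcv(tr, 2, 1e-9), 2 * C, tolerance = 1e-6)
  expect_equal(eb_vcv(tr, 2, 0), 2 * C)
  expect_equal(eb_vcv(tr, 2, -1e-9), 2 * C, tolerance = 1e-6)
})

test_that("the early-burst transform matches hand-integrated branch lengths", {
  tr <- balanced3()  # ((A:1,B:1):1,C:2)
  a <- -0.5
  tt <- eb_transform_tree(tr, a)
  seg <- function(t1, t2) (exp(a * t2) - exp(a * t1)) / a
  # C's pendant branch spans 0..2; the internal branch 0..1; tips A,B 1..2
  Ceb <- phylo_vcv(tt)
  expect_equal(Ceb["C", "C"], seg(0, 2), tolerance = 1e-12)
  expect_equal(Ceb["A", "B"], seg(0, 1), tolerance = 1e-12)
  expect_equal(Ceb["A", "A"], seg(0, 1) + seg(1, 2), tolerance = 1e-12)
  expect_equal(eb_vcv(tr, 3, a), 3 * Ceb)
})

test_that("the profiled optimum beats random parameter values", {
  tr <- simulate_tree(30, seed = 8)
  y <- simulate_ou(tr, 1, alpha = 2, theta = 1, seed = 9)
  fou <- suppressWarnings(fit_ou(y, tr))
  feb <- fit_eb(y, tr)
  set.seed(10)
  for (alpha in exp(runif(25, log(1e-6), log(40)))) {
    ll <- phylomi:::mvn_profile_fit(y[tr$tip.label],
                                    ou_vcv(tr, 1, alpha))$loglik
    expect_gte(fou$loglik, ll - 1e-6)
  }
  for (a in runif(25, -8, 0)) {
    ll <- phylomi:::mvn_profile_fit(y[tr$tip.label],
                                    eb_vcv(tr, 1, a))$loglik
    expect_gte(feb$loglik, ll - 1e-6)
  }
})

test_that("fits shift correctly under trait translation", {
  tr <- simulate_tree(18, seed = 12)
  y <- simulate_bm(tr, 1, 0, seed = 13)
  f0 <- fit_bm(y, tr)
  f7 <- fit_bm(y + 7, tr)
  expect_equal(f7$z0, f0$z0 + 7, tolerance = 1e-9)
  expect_equal(f7$sigma2, f0$sigma2, tolerance = 1e-9)
  expect_equal(f7$loglik, f0$loglik, tolerance = 1e-9)
})

test_that("model comparison ranks by AIC and reports deltas", {
  tr <- simulate_tree(40, seed = 15)
  y <- simulate_bm(tr, 1, 0, seed = 16)
  cmp <- compare_models(y, tr)
  expect_setequal(cmp$table$model, c("BM", "OU", "EB"))
  expect_true(all(diff(cmp$table$aic) >= 0))
  expect_equal(cmp$table$delta_aic[1], 0)
  expect_equal(cmp$table$aic,
               2 * cmp$table$n_params - 2 * cmp$table$loglik)
})

test_that("the per-landmass analysis prunes, fits and skips small subsets", {
  st <- simulate_study(paper_emulation_config(seed = 17, n_tips = 90))
  tab <- per_landmass_analysis(st$table, st$tree, floor = 10)
  groups <- table(st$table$data$origin)
  expect_equal(nrow(tab), sum(groups >= 10) * 2 * 3)
  expect_true(all(tab$delta_aic >= 0))

  # force a tiny subset: floor above the largest group size skips all
  expect_error(suppressWarnings(
    per_landmass_analysis(st$table, st$tree, floor = 1000)),
    "no subset")
  expect_warning(per_landmass_analysis(st$table, st$tree,
                                       floor = max(groups)),
                 "skipped")
})

test_that("bootstrap adequacy places model-consistent data centrally", {
  tr <- simulate_tree(40, seed = 19)
  y <- simulate_bm(tr, 1, 0, seed = 20)
  fit <- fit_bm(y, tr)
  ba <- bootstrap_assessment(y, tr, fit, n_sim = 99, seed = 21)
  expect_true(all(ba$bootstrap_quantile > 0.005 &
                    ba$bootstrap_quantile < 0.995))
})
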