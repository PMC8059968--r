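test_that("the imputation-count rule follows the missing percentage", {
  expect_equal(choose_m(0.25), 25)
  expect_equal(choose_m(0), 0)
  expect_equal(choose_m(0.53), 53)
  expect_equal(choose_m(0.01), 2)   # floored at 2 when anything is missing
})

test_that("predictor selection applies the missingness threshold", {
  st <- simulate_study(paper_emulation_config(seed = 2))
  expect_length(select_predictors(st$table, 0.35), 13)
  expect_length(select_predictors(st$complete, 0.35), 16)
  expect_false("fmr" %in% select_predictors(st$table, 0.35))  # 40% missing
  expect_false("litter_size" %in%
                 select_predictors(st$table, 0.35, target = "litter_size"))
  empty <- trait_table(data.frame(row.names = c("a", "b"),
                                  x = c(1, NA)), c(x = "continuous"))
  expect_error(select_predictors(empty, 0.4), "empty predictor set")
})

test_that("predictive mean matching imputes from observed donors only", {
  tr <- simulate_tree(60, seed = 14)
  C <- phylo_vcv(tr)
  pred <- simulate_bm(tr, 1, 0, seed = 15)
  y0 <- 0.8 * pred + simulate_bm(tr, 0.5, 0, seed = 16)
  X <- cbind("(Intercept)" = 1, pred = pred)

  # no missing cells: unchanged
  expect_identical(pmm_impute_variable(y0, X, C, k = 5), y0)

  set.seed(20)
  y <- y0; y[sample(60, 15)] <- NA
  for (s in 1:5) {
    set.seed(s)
    filled <- pmm_impute_variable(y, X, C, k = 5)
    expect_false(anyNA(filled))
    expect_true(all(filled[is.na(y)] %in% y[!is.na(y)]))
    expect_identical(filled[!is.na(y)], y[!is.na(y)])
  }
  expect_error(pmm_impute_variable(rep(NA_real_, 60) * 1, X, C, 5),
               "no observed")
})

test_that("k = 1 returns the nearest-score donor (hand-replayed oracle)", {
  tr <- simulate_tree(25, seed = 33)
  C <- phylo_vcv(tr)
  pred <- simulate_bm(tr, 1, 0, seed = 34)
  y <- 0.6 * pred + simulate_bm(tr, 0.4, 0, seed = 35)
  X <- cbind("(Intercept)" = 1, pred = pred)
  mis <- 7
  ymis <- y; ymis[mis] <- NA

  set.seed(55)
  got <- pmm_impute_variable(ymis, X, C, k = 1)[mis]

  # replay the algorithm by hand with the same RNG stream
  set.seed(55)
  obs <- setdiff(seq_len(25), mis)
  fit <- fit_pgls(y[obs], X[obs, ], C[obs, obs])
  beta_star <- draw_beta_posterior(fit)
  Coo_inv <- chol2inv(chol(C[obs, obs]))
  r_hat <- y[obs] - drop(X[obs, ] %*% fit$beta_hat)
  score_obs <- y[obs] - drop(Coo_inv %*% r_hat) / diag(Coo_inv)
  r_star <- y[obs] - drop(X[obs, ] %*% beta_star)
  score_mis <- drop(X[mis, , drop = FALSE] %*% beta_star) +
    drop(C[mis, obs, drop = FALSE] %*% (Coo_inv %*% r_star))
  donor <- obs[order(abs(score_mis - score_obs), names(y)[obs])][1]
  expect_identical(unname(got), unname(y[donor]))
})

test_that("chained equations are deterministic and preserve observed cells", {
  st <- simulate_study(paper_emulation_config(seed = 6, n_tips = 80))
  cfg <- imputation_config(m = 2, n_iter = 3, seed = 10)
  r1 <- chained_equations(st$table, st$tree, cfg)
  r2 <- chained_equations(st$table, st$tree, cfg)
  expect_identical(lapply(r1$datasets, `[[`, "data"),
                   lapply(r2$datasets, `[[`, "data"))
  expect_identical(r1$chain_stats, r2$chain_stats)

  obs_mask <- !is.na(st$table$data)
  for (ds in r1$datasets) {
    expect_false(anyNA(ds$data))
    expect_identical(as.matrix(ds$data)[obs_mask],
                     as.matrix(st$table$data)[obs_mask])
    # categorical imputations are valid observed levels
    for (nm in names(ds$data)[st$table$types == "categorical"])
      expect_true(all(ds$data[[nm]] %in%
                        unique(na.omit(st$table$data[[nm]]))))
  }
})

test_that("a complete table yields m identical copies", {
  st <- simulate_study(paper_emulation_config(seed = 6, n_tips = 40))
  r <- chained_equations(st$complete, st$tree,
                         imputation_config(m = 3, n_iter = 2, seed = 1))
  expect_equal(r$m, 3)
  for (ds in r$datasets) expect_identical(ds$data, st$complete$data)
  expect_equal(nrow(r$chain_stats), 0)
  cs <- convergence_summary(r)
  expect_equal(nrow(cs), 0)
})

test_that("imputed-cell means track the truth under MCAR masking", {
  set.seed(61)
  devs <- replicate(20, {
    r <- sample.int(1e6, 1)
    tr <- simulate_tree(80, seed = r)
    C <- phylo_vcv(tr)
    pred <- simulate_bm(tr, 1, 0, seed = r + 1)
    truth <- 0.7 * pred + simulate_bm(tr, 0.5, 0, seed = r + 2)
    mis <- sample(80, 20)
    y <- truth; y[mis] <- NA
    filled <- pmm_impute_variable(y, cbind(1, pred), C, k = 5)
    se <- sd(truth[mis]) / sqrt(20)
    (mean(filled[mis]) - mean(truth[mis])) / se
  })
  expect_lt(abs(mean(devs)), 3 / sqrt(20) * 3)  # pooled 3-SE band
  expect_gt(mean(abs(devs) < 3), 0.8)
})

test_that("convergence summary flags stable chains and reports trends", {
  st <- simulate_study(paper_emulation_config(seed = 8, n_tips = 60))
  r <- chained_equations(st$table, st$tree,
                         imputation_config(m = 2, n_iter = 12, seed = 2))
  cs <- convergence_summary(r)
  expect_setequal(cs$column, unique(r$chain_stats$column))
  expect_true(all(is.finite(cs$slope)))
  expect_true(all(cs$slope_p >= 0 & cs$slope_p <= 1))
  # stationary chains should mostly be flagged converged
  expect_gt(mean(cs$converged), 0.5)
})

test_that("imputation results round-trip through CSV export", {
  st <- simulate_study(paper_emulation_config(seed = 12, n_tips = 40))
  r <- chained_equations(st$table, st$tree,
                         imputation_config(m = 2, n_iter = 2, seed = 3))
  dir <- withr::local_tempdir()
  write_imputations(r, dir)
  expect_true(file.exists(file.path(dir, "imputed_1.csv")))
  back <- read_trait_csv(file.path(dir, "imputed_2.csv"))
  expect_equal(back$data$log_ecv, r$datasets[[2]]$data$log_ecv,
               tolerance = 1e-8)
})
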