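#' Specify a phylogenetic mixed model
#'
#' @param name Identifier used in reports.
#' @param fixed Right-hand-side formula of fixed effects (the body-size
#'   covariate should be included explicitly, e.g.
#'   `~ log_body + litter_size`).
#' @param response Response column (default `"log_ecv"`).
#' @return List of class `"model_spec"`.
#' @export
model_spec <- function(name, fixed, response = "log_ecv") {
  stopifnot(inherits(fixed, "formula"))
  structure(list(name = name, response = response, fixed = fixed),
            class = "model_spec")
}

#' The shipped model registry
#'
#' Eight hypothesis-driven model specifications over the synthetic trait
#' columns, every one including the body-size covariate: developmental
#' (litter size, weaning age), environmental (activity period, shelter
#' safety, diet, home range), social (group living, parental care, mating
#' system), metabolic (field metabolic rate and its body interaction),
#' torpor, play and vulnerability (each with a body interaction), and
#' geographic origin.
#'
#' @return Named list of [model_spec()]s.
#' @export
model_registry <- function() {
  list(
    developmental = model_spec("developmental",
                               ~ log_body + litter_size + weaning_age),
    environmental = model_spec("environmental",
                               ~ log_body + activity + shelter_safety +
                                 diet + home_range),
    social        = model_spec("social",
                               ~ log_body + group_living + parental_care +
                                 mating_system),
    metabolic     = model_spec("metabolic", ~ log_body * fmr),
    torpor        = model_spec("torpor", ~ log_body * torpor),
    play          = model_spec("play", ~ log_body * play),
    vulnerability = model_spec("vulnerability", ~ log_body * status),
    origin        = model_spec("origin", ~ log_body + origin)
  )
}

#' Sampler settings
#'
#' Desk-scale defaults keep a full test run fast; the long-run settings
#' used for final inference (1 000 042 iterations, 150 000 burn-in,
#' thinning 250) are available via `paper_scale = TRUE`.
#'
#' @param n_iter Total MCMC iterations per chain.
#' @param burnin Burn-in iterations discarded.
#' @param thin Thinning interval.
#' @param chains Number of chains (>= 2 for the Gelman-Rubin diagnostic).
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters on both
#'   variance components; the small default (0.001, 0.001) approximates a
#'   flat, uninformative prior while preserving conjugacy.
#' @param paper_scale If `TRUE`, override with the long-run settings.
#' @return List of class `"sampler_settings"`.
#' @export
sampler_settings <- function(n_iter = 3000, burnin = 500, thin = 5,
                             chains = 2, prior_shape = 0.001,
                             prior_rate = 0.001, paper_scale = FALSE) {
  if (paper_scale) {
    n_iter <- 1000042L; burnin <- 150000L; thin <- 250L
  }
  stopifnot(n_iter > burnin, thin >= 1, chains >= 1)
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 chains = chains, prior_shape = prior_shape,
                 prior_rate = prior_rate),
            class = "sampler_settings")
}

# One Gibbs chain for y = X b + u + e, u ~ N(0, sa2 C), e ~ N(0, se2 I).
# Works in the eigenbasis of C (C = U D U'): with yt = U'y, Xt = U'X and
# v = U'u, the model is yt = Xt b + v + et with v ~ N(0, sa2 D) and
# et ~ N(0, se2 I). The (b, v) block is updated jointly by composition --
# b from its conditional with v integrated out (a diagonal-weight GLS),
# then v | b elementwise -- followed by conjugate inverse-gamma updates of
# both variances. O(n p^2) per sweep after the one-off eigendecomposition.
run_gibbs_chain <- function(yt, Xt, d, settings, seed, init_h2) {
  set.seed(seed)
  n <- length(yt); p <- ncol(Xt)
  a0 <- settings$prior_shape; b0 <- settings$prior_rate
  vy <- stats::var(yt)
  sa2 <- max(init_h2 * vy, 1e-6)
  se2 <- max((1 - init_h2) * vy, 1e-6)
  keep <- seq(settings$burnin + settings$thin, settings$n_iter,
              by = settings$thin)
  S <- length(keep)
  beta_out <- matrix(NA_real_, S, p, dimnames = list(NULL, colnames(Xt)))
  sa2_out <- numeric(S); se2_out <- numeric(S)
  s <- 0L
  for (it in seq_len(settings$n_iter)) {
    w <- 1 / (sa2 * d + se2)
    Xw <- Xt * w
    A <- crossprod(Xt, Xw)              # X' W X
    Ua <- chol(A)
    bhat <- backsolve(Ua, backsolve(Ua, crossprod(Xw, yt),
                                    transpose = TRUE))
    beta <- drop(bhat + backsolve(Ua, stats::rnorm(p)))
    r <- yt - drop(Xt %*% beta)
    sv <- (sa2 * d * se2) * w           # conditional variance of v
    v <- stats::rnorm(n, r * (sa2 * d) * w, sqrt(sv))
    sa2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(v^2 / d) / 2)
    se2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum((r - v)^2) / 2)
    if (s < S && it == keep[s + 1L]) {
      s <- s + 1L
      beta_out[s, ] <- beta
      sa2_out[s] <- sa2; se2_out[s] <- se2
    }
  }
  list(beta = beta_out, var_phylo = sa2_out, var_resid = se2_out)
}

#' Fit a Bayesian phylogenetic mixed model ("animal model")
#'
#' Samples from the posterior of `y = X beta + u + e` with
#' `u ~ N(0, sigma2_a C)` and `e ~ N(0, sigma2_e I)` by blocked Gibbs:
#' flat prior on `beta`, inverse-gamma priors on both variances. Chains are
#' started at overdispersed heritability values (0.1 and 0.9, then spread
#' in between) so the Gelman-Rubin diagnostic is meaningful.
#'
#' @param table A complete [trait_table()] (one imputed dataset).
#' @param C Phylogenetic covariance matrix aligned with the table.
#' @param spec A [model_spec()].
#' @param settings A [sampler_settings()].
#' @param seed Integer seed; chain c uses a seed derived from it.
#' @return Object of class `"glmm_result"`: `draws` (fixed-effect matrix,
#'   variance vectors, chain ids, ESS, Gelman-Rubin), `heritability_samples`,
#'   `dic`, `frac_above_zero`, plus `y`, `X` and the spec.
#' @export
fit_phylo_glmm <- function(table, C, spec,
                           settings = sampler_settings(), seed = 1) {
  des <- build_design(table, stats::as.formula(
    paste(spec$response, paste(deparse(spec$fixed[[2]]), collapse = ""),
          sep = " ~ ")))
  y <- des$y; X <- des$X
  stopifnot(nrow(C) == length(y))
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) <= 0)
    stop("C is not positive definite; resolve zero-length branches first")
  U <- eig$vectors; d <- eig$values
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  colnames(Xt) <- colnames(X)

  inits <- seq(0.1, 0.9, length.out = max(settings$chains, 2))
  chains <- lapply(seq_len(settings$chains), function(cc)
    run_gibbs_chain(yt, Xt, d, settings,
                    seed = derive_seed(seed, "chain", cc),
                    init_h2 = inits[cc]))
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  var_phylo <- unlist(lapply(chains, `[[`, "var_phylo"))
  var_resid <- unlist(lapply(chains, `[[`, "var_resid"))
  chain_id <- rep(seq_len(settings$chains),
                  each = nrow(chains[[1]]$beta))
  draws <- structure(list(fixed_effects = beta, var_phylo = var_phylo,
                          var_resid = var_resid, chain_id = chain_id),
                     class = "posterior_draws")
  diag_ <- convergence(draws)
  draws$ess <- diag_$ess
  draws$gelman_rubin <- diag_$gelman_rubin
  h2 <- heritability(draws)
  res <- structure(list(draws = draws,
                        heritability_samples = h2,
                        dic = NA_real_,
                        frac_above_zero = colMeans(beta > 0),
                        spec = spec, y = y, X = X,
                        settings = settings),
                   class = "glmm_result")
  res$dic <- dic(draws, y, X, C)
  res
}

#' @export
print.glmm_result <- function(x, ...) {
  cat("phylogenetic mixed model:", x$spec$name, "\n")
  print(data.frame(mean = colMeans(x$draws$fixed_effects),
                   frac_above_zero = x$frac_above_zero))
  cat(sprintf("posterior mean h2 = %.3f, DIC = %.1f\n",
              mean(x$heritability_samples), x$dic))
  invisible(x)
}

#' Phylogenetic heritability per posterior sample
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` -- the proportion of trait
#' variance attributable to phylogeny; always in `[0, 1]`.
#'
#' @param draws A `posterior_draws` object.
#' @return Numeric vector of per-sample heritabilities.
#' @export
heritability <- function(draws) {
  stopifnot(all(draws$var_phylo > 0), all(draws$var_resid > 0))
  draws$var_phylo / (draws$var_phylo + draws$var_resid)
}

# Marginal log-likelihood of y ~ N(X beta, sa2 C + se2 I) via the
# eigendecomposition of C (cheap per posterior sample).
marginal_loglik <- function(beta, sa2, se2, yt, Xt, d) {
  vdiag <- sa2 * d + se2
  r <- yt - drop(Xt %*% beta)
  -0.5 * (length(yt) * log(2 * pi) + sum(log(vdiag)) + sum(r^2 / vdiag))
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `D(theta) = -2 loglik(theta)`, `Dbar` the
#' posterior mean deviance and `pD = Dbar - D(posterior means)`. The
#' likelihood is the marginal one, `y ~ N(X beta, sigma2_a C + sigma2_e I)`,
#' evaluable from the stored draws alone.
#'
#' @param draws A `posterior_draws` object.
#' @param y,X Response and design used in the fit.
#' @param C Phylogenetic covariance.
#' @return DIC (scalar).
#' @export
dic <- function(draws, y, X, C) {
  eig <- eigen(C, symmetric = TRUE)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  d <- eig$values
  S <- nrow(draws$fixed_effects)
  dev <- vapply(seq_len(S), function(s)
    -2 * marginal_loglik(draws$fixed_effects[s, ], draws$var_phylo[s],
                         draws$var_resid[s], yt, Xt, d), numeric(1))
  if (any(!is.finite(dev))) stop("non-finite deviance at a posterior sample")
  dbar <- mean(dev)
  dhat <- -2 * marginal_loglik(colMeans(draws$fixed_effects),
                               mean(draws$var_phylo),
                               mean(draws$var_resid), yt, Xt, d)
  dbar + (dbar - dhat)
}

# Split each chain in half and compute the potential scale reduction
# factor on the 2*chains half-chains.
split_rhat <- function(x, chain_id) {
  halves <- list()
  for (cc in unique(chain_id)) {
    xs <- x[chain_id == cc]
    h <- floor(length(xs) / 2)
    halves <- c(halves, list(xs[seq_len(h)], xs[h + seq_len(h)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for posterior draws
#'
#' Per-parameter effective sample size (autocorrelation-based, via
#' [coda::effectiveSize()]) and split potential scale reduction factor
#' (split-Rhat). The pass flag requires ESS >= `ess_min` and
#' Rhat < `rhat_max` for every parameter.
#'
#' @param draws A `posterior_draws` object.
#' @param ess_min,rhat_max Pass thresholds (defaults 3000 and 1.1).
#' @return List: `ess`, `gelman_rubin` (named vectors over parameters
#'   beta..., var_phylo, var_resid), `pass`.
#' @export
convergence <- function(draws, ess_min = 3000, rhat_max = 1.1) {
  pars <- cbind(draws$fixed_effects,
                var_phylo = draws$var_phylo,
                var_resid = draws$var_resid)
  ess <- vapply(seq_len(ncol(pars)), function(j) {
    per_chain <- tapply(pars[, j], draws$chain_id, function(xs)
      as.numeric(coda::effectiveSize(coda::mcmc(xs))))
    sum(per_chain)
  }, numeric(1))
  names(ess) <- colnames(pars)
  n_chains <- length(unique(draws$chain_id))
  if (n_chains < 2) {
    warning("fewer than 2 chains: Gelman-Rubin diagnostic unavailable")
    rhat <- stats::setNames(rep(NA_real_, ncol(pars)), colnames(pars))
  } else {
    rhat <- vapply(seq_len(ncol(pars)), function(j)
      split_rhat(pars[, j], draws$chain_id), numeric(1))
    names(rhat) <- colnames(pars)
  }
  list(ess = ess, gelman_rubin = rhat,
       pass = all(ess >= ess_min) &&
         (all(is.na(rhat)) || all(rhat < rhat_max, na.rm = TRUE)))
}

#' Significance label from posterior mass above zero
#'
#' A coefficient is called significant when at least 95% of its posterior
#' mass lies on one side of zero.
#'
#' @param frac_above_zero Fraction of posterior samples above 0.
#' @return One of `"significant-positive"`, `"significant-negative"`,
#'   `"not significant"`.
#' @export
significance <- function(frac_above_zero) {
  stopifnot(frac_above_zero >= 0, frac_above_zero <= 1)
  if (frac_above_zero >= 0.95) "significant-positive"
  else if (frac_above_zero <= 0.05) "significant-negative"
  else "not significant"
}
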