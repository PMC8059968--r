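#' Ornstein-Uhlenbeck tip covariance on a tree
#'
#' Fixed-root parameterization (root at the optimum), which nests Brownian
#' motion at `alpha = 0`:
#' `V_ij = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))`
#' with `t_ij` the root-to-MRCA depth and `d_ij` the patristic distance
#' between tips i and j.
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 Brownian rate.
#' @param alpha Pull strength (>= 0); values below `1e-10` return the
#'   Brownian covariance exactly.
#' @return Symmetric covariance matrix over the tips.
#' @export
ou_vcv <- function(tree, sigma2 = 1, alpha = 0) {
  stopifnot(alpha >= 0)
  C <- suppressWarnings(phylo_vcv(tree))
  if (alpha < 1e-10) return(sigma2 * C)
  ti <- diag(C)
  D <- outer(ti, ti, "+") - 2 * C          # patristic distances
  # -expm1() keeps the alpha -> 0 limit numerically exact
  sigma2 / (2 * alpha) * exp(-alpha * D) * (-expm1(-2 * alpha * C))
}

#' Early-burst branch-length transform
#'
#' Under an early burst the Brownian rate decays as `exp(a t)` with
#' `a <= 0`; the equivalent Brownian tree has each branch's length replaced
#' by the integral of the rate over its time interval,
#' `(exp(a t2) - exp(a t1)) / a` for a branch running from age `t1` to
#' `t2` measured from the root.
#'
#' @param tree A `"phylo"` object.
#' @param eb_rate Decay rate `a <= 0` (0 returns the tree unchanged).
#' @return The transformed tree.
#' @export
eb_transform_tree <- function(tree, eb_rate) {
  stopifnot(eb_rate <= 0)
  if (eb_rate == 0) return(tree)
  depth <- ape::node.depth.edgelength(tree)
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  tree$edge.length <- (exp(eb_rate * t2) - exp(eb_rate * t1)) / eb_rate
  tree
}

#' Early-burst tip covariance
#'
#' @inheritParams eb_transform_tree
#' @param sigma2 Initial (time-zero) Brownian rate.
#' @return Covariance matrix: the Brownian covariance of the transformed
#'   tree times `sigma2`.
#' @export
eb_vcv <- function(tree, sigma2 = 1, eb_rate = 0) {
  sigma2 * suppressWarnings(phylo_vcv(eb_transform_tree(tree, eb_rate)))
}

# ML fit of y ~ N(z0 * 1, sigma2 * V0): z0 by GLS, sigma2 by the ML
# divisor n, log-likelihood of the profiled model.
mvn_profile_fit <- function(y, V0) {
  n <- length(y)
  L <- chol(V0)
  yw <- backsolve(L, y, transpose = TRUE)
  ow <- backsolve(L, rep(1, n), transpose = TRUE)
  z0 <- sum(ow * yw) / sum(ow^2)
  rw <- yw - z0 * ow
  q <- sum(rw^2)
  if (q <= 0) stop("degenerate trait: zero residual variance")
  sigma2 <- q / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(L))) + n)
  list(z0 = z0, sigma2 = sigma2, loglik = loglik)
}

new_evo_fit <- function(model, fit, n_params, extra = list()) {
  structure(c(list(model = model, sigma2 = fit$sigma2, z0 = fit$z0,
                   loglik = fit$loglik, n_params = n_params,
                   aic = 2 * n_params - 2 * fit$loglik),
              extra),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("%s fit: sigma2 = %.4g, z0 = %.4g", x$model, x$sigma2, x$z0))
  if (!is.null(x$alpha)) cat(sprintf(", alpha = %.4g", x$alpha))
  if (!is.null(x$eb_rate)) cat(sprintf(", a = %.4g", x$eb_rate))
  cat(sprintf("; loglik = %.3f, AIC = %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Maximum-likelihood Brownian-motion fit of a continuous trait
#'
#' Closed form: the root state is the GLS mean under C and the rate is the
#' mean squared C-whitened deviation (ML divisor n). Two parameters.
#'
#' @param y Named trait vector over the tree's tips.
#' @param tree A `"phylo"` object.
#' @return An `"evo_fit"` with fields `model = "BM"`, `sigma2`, `z0`,
#'   `loglik`, `n_params`, `aic`.
#' @export
fit_bm <- function(y, tree) {
  stopifnot(length(y) >= 3)
  y <- y[tree$tip.label]
  C <- suppressWarnings(phylo_vcv(tree))
  new_evo_fit("BM", mvn_profile_fit(y, C), 2L)
}

# Coarse grid then golden-section polish of a 1-D profile likelihood.
profile_optimize <- function(obj, grid) {
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  if (obj(grid[i]) > opt$objective)
    list(par = grid[i], value = vals[i], at_bound = i == length(grid))
  else
    list(par = opt$maximum, value = opt$objective,
         at_bound = i == length(grid))
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit
#'
#' The pull strength `alpha` is optimized by a log-spaced grid search
#' polished with golden-section search; root state (`z0 = theta`) and rate
#' are profiled out analytically at each `alpha`. Three parameters. A fit
#' at the upper `alpha` bound triggers a white-noise-limit warning.
#'
#' @inheritParams fit_bm
#' @param alpha_max Upper search bound as a multiple of 1/tree depth
#'   (default 50).
#' @return An `"evo_fit"` with additional fields `alpha` and `theta`.
#' @export
fit_ou <- function(y, tree, alpha_max = 50) {
  y <- y[tree$tip.label]
  if (!is_ultrametric(tree, 1e-6))
    warning("OU fit assumes an ultrametric tree")
  depth <- max(tip_depths(tree))
  obj <- function(la) mvn_profile_fit(y, ou_vcv(tree, 1, exp(la)))$loglik
  grid <- log(exp(seq(log(1e-8), log(alpha_max / depth), length.out = 25)))
  best <- profile_optimize(obj, grid)
  alpha <- exp(best$par)
  ll_bm <- mvn_profile_fit(y, phylo_vcv(tree))$loglik
  if (ll_bm >= best$value) {            # BM boundary alpha -> 0
    fit <- mvn_profile_fit(y, phylo_vcv(tree))
    alpha <- 0
  } else fit <- mvn_profile_fit(y, ou_vcv(tree, 1, alpha))
  if (best$at_bound && alpha > 0)
    warning("alpha at upper bound: white-noise limit")
  new_evo_fit("OU", fit, 3L, list(alpha = alpha, theta = fit$z0))
}

#' Maximum-likelihood early-burst fit
#'
#' The decay rate `a` is optimized over `[-rate_min/depth, 0]` by grid
#' search plus golden-section polish; at each `a` the model is a Brownian
#' fit on the transformed tree ([eb_transform_tree()]). Three parameters;
#' `a = 0` reproduces the Brownian fit exactly.
#'
#' @inheritParams fit_bm
#' @param rate_min Lower search bound as a multiple of 1/tree depth
#'   (default 10).
#' @return An `"evo_fit"` with additional field `eb_rate`.
#' @export
fit_eb <- function(y, tree, rate_min = 10) {
  y <- y[tree$tip.label]
  depth <- max(tip_depths(tree))
  obj <- function(a) mvn_profile_fit(y, eb_vcv(tree, 1, a))$loglik
  grid <- seq(-rate_min / depth, 0, length.out = 25)
  best <- profile_optimize(obj, grid)
  ll_bm <- obj(0)
  a <- if (ll_bm >= best$value) 0 else best$par
  fit <- mvn_profile_fit(y, eb_vcv(tree, 1, a))
  new_evo_fit("EB", fit, 3L, list(eb_rate = a))
}

#' Fit and rank BM, OU and EB models by AIC
#'
#' @inheritParams fit_bm
#' @return List of class `"model_comparison"`: `fits` (ascending AIC),
#'   `table` (data.frame with model, loglik, n_params, aic, delta_aic).
#' @export
compare_models <- function(y, tree) {
  fits <- list(fit_bm(y, tree),
               suppressWarnings(fit_ou(y, tree)),
               fit_eb(y, tree))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ord <- order(aics)
  fits <- fits[ord]
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    n_params = vapply(fits, `[[`, integer(1), "n_params"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"))
  tab$delta_aic <- tab$aic - tab$aic[1]
  structure(list(fits = fits, table = tab), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Parametric-bootstrap adequacy check of a fitted evolutionary model
#'
#' Simulates `n_sim` trait vectors under the fitted model and locates the
#' observed trait's summary statistics (variance and mean absolute
#' standardized contrast) within the simulated distributions -- an optional
#' complement to AIC-based selection.
#'
#' @param y Named trait vector.
#' @param tree A `"phylo"` object.
#' @param fit An `"evo_fit"`.
#' @param n_sim Number of simulations.
#' @param seed Integer seed.
#' @return data.frame with statistic, observed value and bootstrap
#'   two-sided quantile position.
#' @export
bootstrap_assessment <- function(y, tree, fit, n_sim = 199, seed = 1) {
  y <- y[tree$tip.label]
  V <- switch(fit$model,
              BM = fit$sigma2 * phylo_vcv(tree),
              OU = ou_vcv(tree, fit$sigma2, fit$alpha),
              EB = eb_vcv(tree, fit$sigma2, fit$eb_rate))
  set.seed(seed)
  stat <- function(v) c(var = stats::var(v),
                        contrast = mean(abs(ape::pic(v, ape::multi2di(tree)))))
  obs <- stat(y)
  sims <- replicate(n_sim, stat(mvn_tips(V, fit$z0)))
  pos <- vapply(seq_along(obs), function(i) mean(sims[i, ] <= obs[i]),
                numeric(1))
  data.frame(statistic = names(obs), observed = obs,
             bootstrap_quantile = pos, row.names = NULL)
}

#' Per-landmass evolutionary model comparison
#'
#' Prunes the tree to each level of a grouping column (e.g. geographic
#' origin) and ranks BM/OU/EB for each analysed trait within each subset.
#' Subsets below the tip floor are skipped with a warning.
#'
#' @param table A complete [trait_table()].
#' @param tree The phylogeny.
#' @param subset_column Grouping categorical column (default `"origin"`).
#' @param traits Continuous traits to analyse (default brain and body
#'   size).
#' @param floor Minimum subset size (default 10).
#' @return data.frame: subset, trait, model, loglik, n_params, aic,
#'   delta_aic (one row per subset x trait x model).
#' @export
per_landmass_analysis <- function(table, tree,
                                  subset_column = "origin",
                                  traits = c("log_ecv", "log_body"),
                                  floor = 10) {
  al <- align_to_tree(table, tree)
  groups <- al$table$data[[subset_column]]
  out <- list()
  for (g in sort(unique(groups))) {
    tips <- al$table$species[groups == g]
    if (length(tips) < floor) {
      warning("subset '", g, "' has ", length(tips),
              " tips (< ", floor, "); skipped")
      next
    }
    sub_tree <- sort_tips(ape::keep.tip(al$tree, tips))
    for (tr in traits) {
      y <- stats::setNames(al$table$data[tips, tr], tips)
      cmp <- compare_models(y, sub_tree)
      tab <- cmp$table
      tab <- cbind(subset = g, trait = tr, tab)
      out[[length(out) + 1L]] <- tab
    }
  }
  if (length(out) == 0) stop("no subset reached the tip floor")
  do.call(rbind, out)
}
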