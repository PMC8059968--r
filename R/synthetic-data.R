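# Deterministic seed derivation: every stage and replicate gets its own
# stream from one master seed, so whole pipelines replay bit-identically.
# Mixes the label bytes into the seed with a Lehmer-style recurrence kept
# below 2^31 (and below 2^53 at every intermediate step).
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(paste(c(...), collapse = "/")))
    h <- (h * 69069 + b) %% 2147483647
  as.integer(h)
}

#' Simulate an ultrametric phylogeny
#'
#' Draws a pure-birth (Yule) tree -- the standard null for species
#' phylogenies, with terminal branch lengths long enough that tip-level
#' noise is not pathologically magnified by GLS whitening -- rescales it to
#' unit root-to-tip depth and sorts tips lexicographically. Unit depth
#' makes rate parameters comparable across simulated trees.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return An ultrametric `"phylo"` object with tips `t001, t002, ...`.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%03d", seq_len(n_tips))
  tree$edge.length <- tree$edge.length / max(tip_depths(tree))
  sort_tips(tree)
}

# Draw one multivariate-normal trait vector with covariance V and constant
# mean, consuming exactly n standard normals (so nested models with the
# same seed produce comparable streams).
mvn_tips <- function(V, mean_value, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(V)
  z <- stats::rnorm(n)
  U <- chol(V + diag(1e-12 * max(diag(V), 1), n))
  stats::setNames(mean_value + drop(crossprod(U, z)), rownames(V))
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Tip values are drawn from the exact multivariate normal with mean
#' `root_state` and covariance `sigma2 * C`, where C is the phylogenetic
#' variance-covariance matrix of the tree.
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param root_state Trait value at the root.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named numeric vector over the tips.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_state = 0, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  C <- suppressWarnings(phylo_vcv(tree))
  if (sigma2 == 0) {
    if (!is.null(seed)) set.seed(seed)
    stats::rnorm(nrow(C)) # keep the stream aligned with sigma2 > 0 draws
    return(stats::setNames(rep(root_state, nrow(C)), rownames(C)))
  }
  mvn_tips(sigma2 * C, root_state, seed)
}

#' Simulate an Ornstein-Uhlenbeck trait on a tree
#'
#' Exact multivariate-normal draw under the fixed-root OU covariance (see
#' [ou_vcv()]); at `alpha = 0` this is identical, draw for draw, to
#' [simulate_bm()] with the same seed.
#'
#' @inheritParams simulate_bm
#' @param alpha Pull strength towards the optimum, >= 0.
#' @param theta Optimum; also the mean under the fixed-root parameterization
#'   with the root at the optimum.
#' @export
simulate_ou <- function(tree, sigma2 = 1, alpha = 0, theta = 0, seed = NULL) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  V <- ou_vcv(tree, sigma2, alpha)
  mvn_tips(V, theta, seed)
}

#' Simulate an early-burst trait on a tree
#'
#' Exact multivariate-normal draw under the early-burst covariance (see
#' [eb_vcv()]); at `eb_rate = 0` identical to [simulate_bm()].
#'
#' @inheritParams simulate_bm
#' @param eb_rate Exponential decay rate `a <= 0` of the Brownian rate
#'   through time.
#' @export
simulate_eb <- function(tree, sigma2 = 1, eb_rate = 0, root_state = 0,
                        seed = NULL) {
  if (eb_rate > 0) stop("eb_rate must be <= 0")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  V <- eb_vcv(tree, sigma2, eb_rate)
  mvn_tips(V, root_state, seed)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator
#' produces a brain-size-style response (`log_ecv`) as a linear function of
#' a body-size covariate (`log_body`) and optional predictor effects, plus
#' a Brownian residual on the tree; categorical traits arise from a
#' threshold (liability) model on latent Brownian traits, which gives them
#' tunable phylogenetic signal.
#'
#' @param n_tips Number of species.
#' @param seed Master seed for the whole dataset.
#' @param sigma2 Brownian rate of the latent traits.
#' @param intercept,slope Allometric intercept and slope of `log_ecv` on
#'   `log_body`.
#' @param effect_sizes Named numeric vector of regression coefficients
#'   linking predictor latents to `log_ecv` (e.g.
#'   `c(litter_size = -0.2)`); names must be generated columns.
#' @param resid_sigma2 Brownian rate of the phylogenetic residual of
#'   `log_ecv` (0 for a noise-free response).
#' @param resid_iid_sd Standard deviation of i.i.d. residual noise on
#'   `log_ecv`.
#' @param body_weight Loading of `log_body` on every predictor latent,
#'   inducing realistic predictor-covariate correlation.
#' @param alpha,theta,eb_rate OU / early-burst parameters for
#'   [simulate_ou()] / [simulate_eb()] style traits when used.
#' @param missingness Named list, one entry per column to mask:
#'   `list(mechanism = "mcar"|"mar"|"phylo", rate = r, driver = col)`
#'   (driver only for MAR).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_tips = 176, seed = 1, sigma2 = 1,
                       intercept = 0.5, slope = 0.75,
                       effect_sizes = c(litter_size = -0.2),
                       resid_sigma2 = 0.1, resid_iid_sd = 0.05,
                       body_weight = 0.3,
                       alpha = 1, theta = 0, eb_rate = -1,
                       missingness = list()) {
  stopifnot(sigma2 >= 0, resid_sigma2 >= 0, resid_iid_sd >= 0,
            alpha >= 0, eb_rate <= 0)
  for (ms in missingness)
    if (ms$rate < 0 || ms$rate >= 1) stop("missingness rates must be in [0,1)")
  structure(list(n_tips = n_tips, seed = seed, sigma2 = sigma2,
                 intercept = intercept, slope = slope,
                 effect_sizes = effect_sizes,
                 resid_sigma2 = resid_sigma2, resid_iid_sd = resid_iid_sd,
                 body_weight = body_weight,
                 alpha = alpha, theta = theta, eb_rate = eb_rate,
                 missingness = missingness),
            class = "sim_config")
}

# Column layout of the generated table: 6 continuous + 10 categorical
# traits named after a marsupial-style comparative dataset. Categorical
# specs give level labels and prevalences used by the threshold rule.
synthetic_columns <- function() {
  list(
    continuous = c("log_ecv", "log_body", "litter_size", "weaning_age",
                   "home_range", "fmr"),
    categorical = list(
      origin         = list(levels = c("America", "Australia", "NewGuinea"),
                            probs = c(0.35, 0.50, 0.15)),
      activity       = list(levels = c("crepuscular", "diurnal", "nocturnal"),
                            probs = c(0.15, 0.15, 0.70)),
      shelter_safety = list(levels = c("closed", "intermediate", "open"),
                            probs = c(0.4, 0.35, 0.25)),
      diet           = list(levels = c("carnivore", "herbivore", "omnivore",
                                       "fungivore"),
                            probs = c(0.3, 0.4, 0.25, 0.05)),
      group_living   = list(levels = c("no", "yes"), probs = c(0.7, 0.3)),
      parental_care  = list(levels = c("low", "high"), probs = c(0.6, 0.4)),
      mating_system  = list(levels = c("monogamous", "polygynous",
                                       "promiscuous"),
                            probs = c(0.2, 0.45, 0.35)),
      torpor         = list(levels = c("no", "yes"), probs = c(0.55, 0.45)),
      play           = list(levels = c("none", "social", "complex"),
                            probs = c(0.5, 0.3, 0.2)),
      status         = list(levels = c("least_concern", "near_threatened",
                                       "vulnerable"),
                            probs = c(0.6, 0.25, 0.15))
    )
  )
}

# Threshold rule: cut a latent liability at its empirical quantiles so the
# realized level frequencies match the requested prevalences.
threshold_categorize <- function(liability, levels, probs) {
  cuts <- stats::quantile(liability, cumsum(probs)[-length(probs)],
                          names = FALSE)
  idx <- findInterval(liability, cuts) + 1L
  stats::setNames(factor(levels[idx], levels = levels), names(liability))
}

#' Generate a complete synthetic trait table on a tree
#'
#' Evolves 16 traits on the tree: a body-size covariate and predictor
#' latents as Brownian traits (each loading weakly on body size),
#' categorical traits via a threshold rule on their latents, and the
#' response `log_ecv = intercept + slope*log_body + effects + residual`
#' with a Brownian residual plus i.i.d. noise. The latent liabilities of
#' categorical traits are kept as attribute `"latents"` so effect sizes can
#' reference them.
#'
#' @param tree A `"phylo"` object (tips define the species set).
#' @param config A [sim_config()].
#' @return A complete [trait_table()] with columns flagged complete:
#'   `log_ecv`, `log_body`, `origin`, `activity`.
#' @export
simulate_dataset <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  cols <- synthetic_columns()
  unknown <- setdiff(names(config$effect_sizes),
                     c(cols$continuous, names(cols$categorical)))
  if (length(unknown))
    stop("effect_sizes reference absent predictors: ",
         paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  log_body <- simulate_bm(tree, config$sigma2, root_state = 6,
                          seed = derive_seed(config$seed, "log_body"))
  body_c <- log_body - mean(log_body)

  latent_names <- setdiff(c(cols$continuous, names(cols$categorical)),
                          c("log_ecv", "log_body"))
  latents <- list()
  for (nm in latent_names) {
    bm <- simulate_bm(tree, config$sigma2, 0,
                      seed = derive_seed(config$seed, "latent", nm))
    latents[[nm]] <- config$body_weight * body_c + bm
  }

  effects <- numeric(n)
  for (nm in names(config$effect_sizes))
    effects <- effects + config$effect_sizes[[nm]] *
      (if (nm == "log_body") body_c else latents[[nm]])

  resid <- simulate_bm(tree, config$resid_sigma2, 0,
                       seed = derive_seed(config$seed, "resid"))
  set.seed(derive_seed(config$seed, "iid"))
  iid <- if (config$resid_iid_sd > 0) stats::rnorm(n, 0, config$resid_iid_sd)
         else numeric(n)
  log_ecv <- config$intercept + config$slope * log_body + effects +
    resid + iid

  data <- data.frame(row.names = tree$tip.label)
  data$log_ecv <- as.numeric(log_ecv)
  data$log_body <- as.numeric(log_body)
  for (nm in setdiff(cols$continuous, c("log_ecv", "log_body")))
    data[[nm]] <- as.numeric(latents[[nm]])
  for (nm in names(cols$categorical)) {
    sp <- cols$categorical[[nm]]
    data[[nm]] <- as.character(threshold_categorize(latents[[nm]],
                                                    sp$levels, sp$probs))
  }
  types <- c(stats::setNames(rep("continuous", length(cols$continuous)),
                             cols$continuous),
             stats::setNames(rep("categorical", length(cols$categorical)),
                             names(cols$categorical)))
  tt <- trait_table(data, types,
                    complete_cols = c("log_ecv", "log_body",
                                      "origin", "activity"))
  attr(tt, "latents") <- latents
  tt
}

#' Impose missingness on a trait table
#'
#' Masks cells column by column according to the mechanisms in the config.
#' Counts are exact -- `round(rate * n)` cells per column -- so realized
#' rates match requested ones to within rounding:
#' * `mcar`: a uniform random subset of rows;
#' * `mar`: rows sampled without replacement with probability increasing in
#'   an observed driver column (default `log_body`);
#' * `phylo`: the rows whose Brownian liability (simulated on the tree)
#'   exceeds its (n-k)-th order statistic, producing clade-clumped gaps.
#'
#' @param table A complete [trait_table()].
#' @param config A [sim_config()] whose `missingness` field names the
#'   columns to mask.
#' @param tree The phylogeny (required for the `phylo` mechanism).
#' @return The masked [trait_table()].
#' @export
impose_missingness <- function(table, config, tree = NULL) {
  data <- table$data
  n <- nrow(data)
  for (nm in names(config$missingness)) {
    ms <- config$missingness[[nm]]
    if (!nm %in% names(data)) stop("unknown column: ", nm)
    if (nm %in% table$complete_cols)
      stop("column '", nm, "' is flagged always-complete")
    if (ms$rate < 0 || ms$rate >= 1) stop("rate must be in [0,1)")
    k <- round(ms$rate * n)
    if (k == 0) next
    set.seed(derive_seed(config$seed, "miss", nm))
    rows <- switch(ms$mechanism,
      mcar = sample.int(n, k),
      mar = {
        driver <- ms$driver %||% "log_body"
        z <- scale(as.numeric(data[[driver]]))[, 1]
        sample.int(n, k, prob = stats::plogis(1.5 * z))
      },
      phylo = {
        if (is.null(tree)) stop("phylo mechanism requires a tree")
        liab <- simulate_bm(tree, 1, 0,
                            seed = derive_seed(config$seed, "liab", nm))
        order(liab[rownames(data)], decreasing = TRUE)[seq_len(k)]
      },
      stop("unknown mechanism: ", ms$mechanism))
    data[rows, nm] <- NA
  }
  trait_table(data, table$types, table$complete_cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paper-emulation simulation preset
#'
#' The default study conditions of the synthetic generator: 176 species, 16
#' trait columns (6 continuous, 10 categorical) of which 4 are complete
#' (`log_ecv`, `log_body`, `origin`, `activity`), a built-in negative
#' litter-size effect on relative brain size, and per-column missingness
#' whose incomplete-column average is exactly 25% -- with `play` at 68%
#' (120/176) and `torpor` at 53% (94/176) masked by phylogenetically
#' clumped mechanisms, `fmr` at 40% (above the 35% predictor-eligibility
#' threshold), and the rest MCAR/MAR at moderate rates, leaving 13
#' predictor-eligible columns.
#'
#' @param seed Master seed.
#' @param n_tips Number of species (default 176).
#' @param litter_effect Coefficient of litter size on `log_ecv`.
#' @return A [sim_config()].
#' @export
paper_emulation_config <- function(seed = 1, n_tips = 176,
                                   litter_effect = -0.2) {
  counts <- c(litter_size = 18, weaning_age = 21, shelter_safety = 26,
              diet = 32, home_range = 35, group_living = 28,
              parental_care = 35, mating_system = 21, status = 28,
              fmr = 70, torpor = 94, play = 120)
  mech <- c(litter_size = "mcar", weaning_age = "mcar",
            shelter_safety = "mcar", diet = "mcar", home_range = "mar",
            group_living = "mcar", parental_care = "mcar",
            mating_system = "mcar", status = "mar", fmr = "mcar",
            torpor = "phylo", play = "phylo")
  missingness <- lapply(names(counts), function(nm)
    list(mechanism = unname(mech[nm]), rate = unname(counts[nm]) / 176))
  names(missingness) <- names(counts)
  sim_config(n_tips = n_tips, seed = seed,
             effect_sizes = c(litter_size = litter_effect),
             missingness = missingness)
}

#' Generate tree + masked table under a config
#'
#' Convenience wrapper: simulates the tree, the complete table and the
#' masked table in one call.
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `complete` (pre-masking table) and `table`
#'   (masked table).
#' @export
simulate_study <- function(config) {
  tree <- simulate_tree(config$n_tips, derive_seed(config$seed, "tree"))
  complete <- simulate_dataset(tree, config)
  masked <- impose_missingness(complete, config, tree)
  list(tree = tree, complete = complete, table = masked)
}
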