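#' Missing-data pattern summary
#'
#' @param table A [trait_table()].
#' @return List of class `"missing_pattern"`: `per_column` (data.frame of
#'   counts and fractions), `overall_fraction` (all cells),
#'   `mean_incomplete_fraction` (average over columns that have any
#'   missingness), `co_missing` (pairwise fraction of jointly missing
#'   cells) and `co_missing_cor` (correlation of missingness indicators --
#'   a stand-in collinearity-of-missingness summary).
#' @export
missing_pattern <- function(table) {
  ind <- vapply(table$data, is.na, logical(nrow(table$data)))
  counts <- colSums(ind)
  frac <- counts / nrow(ind)
  co <- crossprod(ind) / nrow(ind)
  inc <- frac[frac > 0]
  cc <- if (length(inc) >= 2)
    suppressWarnings(stats::cor(ind[, names(inc), drop = FALSE]))
  else NULL
  structure(list(per_column = data.frame(column = names(counts),
                                         n_missing = as.integer(counts),
                                         fraction = as.numeric(frac),
                                         row.names = NULL),
                 overall_fraction = mean(ind),
                 mean_incomplete_fraction =
                   if (length(inc)) mean(inc) else 0,
                 co_missing = co, co_missing_cor = cc),
            class = "missing_pattern")
}

#' @export
print.missing_pattern <- function(x, ...) {
  print(x$per_column, row.names = FALSE)
  cat(sprintf("overall %.1f%% missing; %.1f%% on average over incomplete columns\n",
              100 * x$overall_fraction, 100 * x$mean_incomplete_fraction))
  invisible(x)
}

# Sum of sister-clade differences for binary traits: node values are the
# means of their children's values (computed tips-to-root), and each
# internal node contributes the summed absolute deviations of its children
# from their mean (|v1 - v2| at a bifurcation) -- equivalently, the sum
# over edges of |child value - parent value|. Operates on a tips x m
# matrix so permutation nulls run in one vectorized pass.
d_sum_matrix <- function(values, tree) {
  values <- as.matrix(values)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  m <- ncol(values)
  nodeval <- matrix(NA_real_, ntip + tree$Nnode, m)
  nodeval[seq_len(ntip), ] <- values
  acc <- matrix(0, ntip + tree$Nnode, m)
  acc_n <- integer(ntip + tree$Nnode)
  ne <- nrow(po$edge)
  for (e in seq_len(ne)) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    acc[par, ] <- acc[par, ] + nodeval[ch, ]
    acc_n[par] <- acc_n[par] + 1L
    # postorder lists a parent's child edges contiguously, children first
    if (e == ne || po$edge[e + 1, 1] != par)
      nodeval[par, ] <- acc[par, ] / acc_n[par]
  }
  colSums(abs(nodeval[po$edge[, 2], , drop = FALSE] -
                nodeval[po$edge[, 1], , drop = FALSE]))
}

d_sum <- function(values, tree) d_sum_matrix(values, tree)[1]

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic signal in a binary character by locating the
#' observed sum of sister-clade differences between two null distributions:
#' a label-shuffling null (phylogenetically random; D scales to 1 there)
#' and a Brownian-threshold null (traits clumped as a thresholded Brownian
#' liability; D scales to 0). `D = (d_obs - mean_d_bm) /
#' (mean_d_random - mean_d_bm)`. The Brownian null matches the observed
#' prevalence by thresholding each simulated liability at its k-th order
#' statistic.
#'
#' @param indicator Named binary vector (0/1 or logical) over the tips;
#'   both states must be present.
#' @param tree A `"phylo"` object.
#' @param n_perm Number of permutations/simulations per null (>= 100).
#' @param seed Integer seed.
#' @return List of class `"dstat_result"`: `d`, `d_obs`, `mean_d_random`,
#'   `mean_d_bm`, `p_random` (probability a random null is at least as
#'   clumped as observed), `p_bm` (probability a Brownian null is at least
#'   as overdispersed as observed), `n_perm`.
#' @export
phylo_d <- function(indicator, tree, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  x <- as.numeric(indicator)
  names(x) <- names(indicator)
  if (!is.null(names(x))) x <- x[tree$tip.label]
  if (anyNA(x)) stop("indicator must cover every tip without NA")
  if (length(unique(x)) < 2)
    stop("signal undefined: indicator is monomorphic")
  n <- length(x)
  # the d sum is invariant under 0<->1 relabeling, so the Brownian null
  # thresholds at the minority-state count; this makes D exactly symmetric
  k <- min(sum(x == 1), sum(x == 0))
  d_obs <- d_sum(x, tree)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) sample(x), numeric(n))
  d_random <- d_sum_matrix(perm, tree)
  C <- suppressWarnings(phylo_vcv(tree))
  U <- chol(C + diag(1e-12, nrow(C)))
  liab <- crossprod(U, matrix(stats::rnorm(n * n_perm), n, n_perm))
  bm_ind <- apply(liab, 2, function(l)
    as.numeric(l >= sort(l, decreasing = TRUE)[k]))
  d_bm <- d_sum_matrix(bm_ind, tree)
  mr <- mean(d_random); mb <- mean(d_bm)
  structure(list(d = (d_obs - mb) / (mr - mb),
                 d_obs = d_obs,
                 mean_d_random = mr, mean_d_bm = mb,
                 p_random = mean(d_random <= d_obs),
                 p_bm = mean(d_bm >= d_obs),
                 n_perm = n_perm),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("Fritz-Purvis D = %.3f (d_obs %.2f; nulls: random %.2f, BM %.2f)\n",
              x$d, x$d_obs, x$mean_d_random, x$mean_d_bm))
  cat(sprintf("P(random null <= obs) = %.3f, P(BM null >= obs) = %.3f, n_perm = %d\n",
              x$p_random, x$p_bm, x$n_perm))
  invisible(x)
}

#' Phylogenetic signal in missingness, per column
#'
#' Computes [phylo_d()] on the missingness indicator (1 = missing) of each
#' incomplete column with both states present.
#'
#' @param table A [trait_table()].
#' @param tree The phylogeny.
#' @param n_perm Permutations per null.
#' @param seed Integer seed (per-column seeds derived from it).
#' @return Named list of `dstat_result`s.
#' @export
missingness_signal <- function(table, tree, n_perm = 1000, seed = 1) {
  frac <- missing_fractions(table)
  cols <- names(frac)[frac > 0 & frac < 1]
  out <- list()
  for (nm in cols) {
    ind <- stats::setNames(as.numeric(is.na(table$data[[nm]])),
                           table$species)
    out[[nm]] <- phylo_d(ind, tree, n_perm,
                         seed = derive_seed(seed, "phylo_d", nm))
  }
  out
}
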