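#' Number of imputed datasets from the missing-data fraction
#'
#' Follows the rule of thumb that the number of imputations should match
#' the percentage of missing information: `round(100 * fraction)`, floored
#' at 2 whenever anything is missing, and 0 for complete data.
#'
#' @param missing_fraction Overall fraction of missing cells, in `[0, 1]`.
#' @return Integer number of datasets to impute.
#' @export
choose_m <- function(missing_fraction) {
  stopifnot(missing_fraction >= 0, missing_fraction <= 1)
  if (missing_fraction == 0) return(0L)
  max(2L, as.integer(round(100 * missing_fraction)))
}

#' Select predictor-eligible columns for imputation
#'
#' Columns whose missing fraction is strictly below `max_missing` are
#' usable as predictors; at use time the target column is removed from its
#' own predictor set.
#'
#' @param table A [trait_table()].
#' @param max_missing Eligibility threshold on the missing fraction
#'   (default 0.35).
#' @param target Optional column to exclude.
#' @return Character vector of predictor column names.
#' @export
select_predictors <- function(table, max_missing = 0.35, target = NULL) {
  frac <- missing_fractions(table)
  keep <- names(frac)[frac < max_missing]
  keep <- setdiff(keep, target)
  if (length(keep) == 0) stop("empty predictor set at max_missing = ",
                              max_missing)
  keep
}

#' Imputation configuration
#'
#' @param m Number of imputed datasets (>= 2), or `NULL` to use
#'   [choose_m()] on the table's overall missing fraction.
#' @param n_iter Chained-equation sweeps per dataset (>= 1).
#' @param k_donors Donor pool size for predictive mean matching.
#' @param predictor_max_missing Predictor-eligibility threshold.
#' @param seed Master seed.
#' @return List of class `"imputation_config"`.
#' @export
imputation_config <- function(m = 5, n_iter = 15, k_donors = 5,
                              predictor_max_missing = 0.35, seed = 1) {
  stopifnot(is.null(m) || m >= 2, n_iter >= 1, k_donors >= 1,
            predictor_max_missing > 0, predictor_max_missing <= 1)
  structure(list(m = m, n_iter = n_iter, k_donors = k_donors,
                 predictor_max_missing = predictor_max_missing,
                 seed = seed),
            class = "imputation_config")
}


#' Impute one variable by phylogenetic predictive mean matching
#'
#' The elementary step of the chained-equation imputer:
#' 1. fit a Brownian-motion PGLS of the target on the predictors over the
#'    observed rows (C restricted to those rows by deletion -- the correct
#'    marginal of the multivariate normal);
#' 2. draw `beta*` from the approximate joint posterior
#'    ([draw_beta_posterior()]), injecting parameter uncertainty;
#' 3. compute a predicted score for every row as the *conditional*
#'    expectation of its value given the observed rows: missing rows get
#'    `X beta* + C_mo C_oo^-1 (y_obs - X_obs beta*)` (the phylogenetic
#'    best linear unbiased prediction), observed rows their leave-one-out
#'    conditional mean `y_i - (C_oo^-1 r)_i / (C_oo^-1)_ii` under
#'    `beta_hat` (type-1 matching). With `C = I` both reduce to plain
#'    fitted values, which makes the identity ablation the exact
#'    non-phylogenetic counterpart;
#' 4. for each missing row take the `k` observed rows with the smallest
#'    absolute score difference (ties broken by taxon label for
#'    reproducibility) and copy the observed value of one of them, chosen
#'    uniformly at random.
#'
#' Imputed values are therefore always members of the observed value set.
#'
#' @param target Numeric vector with `NA` for missing cells, named by
#'   taxon.
#' @param X Numeric design matrix over all rows (complete; include an
#'   intercept column), rows aligned with `target` and `C`.
#' @param C Phylogenetic covariance over all rows.
#' @param k Donor pool size.
#' @return Completed numeric vector (same names and order).
#' @export
pmm_impute_variable <- function(target, X, C, k = 5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  miss <- is.na(target)
  if (!any(miss)) return(target)
  obs <- which(!miss)
  if (length(obs) == 0) stop("no observed values to donate from")
  if (length(obs) < k) {
    warning("fewer observed values (", length(obs), ") than k = ", k,
            "; truncating donor pool")
    k <- length(obs)
  }
  # aliasing is judged on the observed rows: a dummy level absent among
  # donors must leave the design for this sweep
  q <- qr(X[obs, , drop = FALSE], tol = 1e-9)
  keep <- sort(q$pivot[seq_len(min(q$rank, max(length(obs) - 2L, 1L)))])
  X <- X[, keep, drop = FALSE]
  Xobs <- X[obs, , drop = FALSE]
  Coo <- C[obs, obs, drop = FALSE]
  fit <- fit_pgls(target[obs], Xobs, Coo)
  beta_star <- draw_beta_posterior(fit)
  Coo_inv <- chol2inv(chol(Coo))
  y_obs <- target[obs]
  # observed rows: leave-one-out conditional mean under beta_hat
  r_hat <- y_obs - drop(Xobs %*% fit$beta_hat)
  score_obs <- y_obs - drop(Coo_inv %*% r_hat) / diag(Coo_inv)
  # missing rows: BLUP given all observed rows under beta*
  r_star <- y_obs - drop(Xobs %*% beta_star)
  Cmo <- C[miss, obs, drop = FALSE]
  score_mis <- drop(X[miss, , drop = FALSE] %*% beta_star) +
    drop(Cmo %*% (Coo_inv %*% r_star))
  labels_obs <- names(target)[obs]
  mis_idx <- which(miss)
  for (j in seq_along(mis_idx)) {
    d <- abs(score_mis[j] - score_obs)
    pool <- obs[order(d, labels_obs)][seq_len(k)]
    target[mis_idx[j]] <- target[pool[sample.int(k, 1)]]
  }
  target
}

# Encode one column as numeric for PMM: categorical levels become integer
# codes over the sorted level set of the *observed* values.
encode_column <- function(values, type) {
  if (type == "continuous") return(as.numeric(values))
  lev <- sort(unique(values[!is.na(values)]))
  list(codes = as.numeric(match(values, lev)), levels = lev)
}

# Build the numeric predictor design (intercept + continuous columns +
# treatment dummies) from currently-complete data.
predictor_design <- function(data, types, predictors) {
  df <- data[, predictors, drop = FALSE]
  for (nm in predictors)
    if (types[[nm]] == "categorical")
      df[[nm]] <- factor(df[[nm]], levels = sort(unique(df[[nm]])))
  stats::model.matrix(~ ., df)
}

#' Multiple imputation by phylogenetic chained equations
#'
#' For each of `m` datasets: initialize every missing cell by sampling the
#' observed values of its column, then sweep the incomplete columns in
#' ascending order of missingness for `n_iter` iterations, re-imputing each
#' with [pmm_impute_variable()] conditional on the predictor-eligible
#' columns ([select_predictors()], eligibility judged on the original
#' missingness pattern). Categorical targets are integer-coded for the
#' regression; donors return actual observed categories, so imputed levels
#' are always valid.
#'
#' @param table A [trait_table()] with missing cells.
#' @param tree Phylogeny covering the table's species.
#' @param config An [imputation_config()].
#' @return Object of class `"imputation_result"`: `datasets` (list of `m`
#'   completed trait tables), `chain_stats` (long data.frame: dataset,
#'   iteration, column, mean, sd of imputed cells), `config`, and `m`.
#' @export
chained_equations <- function(table, tree, config = imputation_config()) {
  al <- align_to_tree(table, tree)
  table <- al$table; tree <- al$tree
  C <- suppressWarnings(phylo_vcv(tree))
  frac <- missing_fractions(table)
  for (nm in names(frac))
    if (all(is.na(table$data[[nm]])))
      stop("column '", nm, "' has zero observed values")
  m <- config$m %||% max(choose_m(mean(frac[frac > 0])), 2L)
  incomplete <- names(frac)[frac > 0]
  visit <- incomplete[order(frac[incomplete])]  # most-missing last
  miss_mask <- lapply(table$data, is.na)

  if (length(incomplete) == 0) {
    datasets <- replicate(max(m, 2L), table, simplify = FALSE)
    return(structure(list(datasets = datasets,
                          chain_stats = data.frame(dataset = integer(),
                                                   iteration = integer(),
                                                   column = character(),
                                                   mean = numeric(),
                                                   sd = numeric()),
                          config = config, m = length(datasets)),
                     class = "imputation_result"))
  }

  datasets <- vector("list", m)
  stats_list <- list()
  for (i in seq_len(m)) {
    set.seed(derive_seed(config$seed, "impute", i))
    data <- table$data
    for (nm in incomplete) {
      na_rows <- miss_mask[[nm]]
      pool <- data[[nm]][!na_rows]
      data[na_rows, nm] <- sample(pool, sum(na_rows), replace = TRUE)
    }
    for (it in seq_len(config$n_iter)) {
      for (nm in visit) {
        preds <- select_predictors(table, config$predictor_max_missing,
                                   target = nm)
        X <- predictor_design(data, table$types, preds)
        enc <- encode_column(data[[nm]], table$types[[nm]])
        if (table$types[[nm]] == "continuous") {
          y <- enc
          names(y) <- rownames(data)
          y[miss_mask[[nm]]] <- NA
          data[[nm]] <- pmm_impute_variable(y, X, C, config$k_donors)
        } else {
          y <- enc$codes
          names(y) <- rownames(data)
          y[miss_mask[[nm]]] <- NA
          filled <- pmm_impute_variable(y, X, C, config$k_donors)
          data[[nm]] <- enc$levels[filled]
        }
        imputed <- data[miss_mask[[nm]], nm]
        imp_num <- if (table$types[[nm]] == "continuous") as.numeric(imputed)
                   else as.numeric(match(imputed, enc$levels))
        stats_list[[length(stats_list) + 1L]] <-
          data.frame(dataset = i, iteration = it, column = nm,
                     mean = mean(imp_num),
                     sd = if (length(imp_num) > 1) stats::sd(imp_num) else 0)
      }
    }
    datasets[[i]] <- trait_table(data, table$types,
                                 complete_cols = names(data))
    # observed cells must survive untouched
    for (nm in names(data))
      stopifnot(identical(data[[nm]][!miss_mask[[nm]]],
                          table$data[[nm]][!miss_mask[[nm]]]))
  }
  structure(list(datasets = datasets,
                 chain_stats = do.call(rbind, stats_list),
                 config = config, m = m),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: m = %d datasets, %d sweeps, columns: %s\n",
              x$m, x$config$n_iter,
              paste(unique(x$chain_stats$column), collapse = ", ")))
  invisible(x)
}

#' Convergence summary of the chained equations
#'
#' For every imputed column, regresses the per-sweep mean of the imputed
#' cells on the sweep index over the final half of the sweeps (pooled over
#' datasets). A column is flagged converged when that slope is
#' statistically indistinguishable from zero (t-test p > 0.05). Also
#' reports the ratio of between-dataset to within-dataset variance of
#' those means.
#'
#' @param result An [chained_equations()] result with `n_iter >= 10`.
#' @return data.frame: column, slope, slope_p, between_within_ratio,
#'   converged.
#' @export
convergence_summary <- function(result) {
  cs <- result$chain_stats
  if (nrow(cs) == 0)
    return(data.frame(column = character(), slope = numeric(),
                      slope_p = numeric(), between_within_ratio = numeric(),
                      converged = logical()))
  n_iter <- max(cs$iteration)
  half <- cs[cs$iteration > n_iter / 2, ]
  out <- lapply(split(half, half$column), function(d) {
    if (length(unique(d$iteration)) < 2 || stats::var(d$mean) == 0) {
      slope <- 0; p <- 1
    } else {
      fit <- stats::summary.lm(stats::lm(mean ~ iteration, data = d))
      slope <- fit$coefficients["iteration", "Estimate"]
      p <- fit$coefficients["iteration", "Pr(>|t|)"]
    }
    per_ds <- tapply(d$mean, d$dataset, mean)
    within <- mean(tapply(d$mean, d$dataset, stats::var), na.rm = TRUE)
    ratio <- if (is.finite(within) && within > 0)
      stats::var(per_ds) / within else NA_real_
    data.frame(column = d$column[1], slope = slope, slope_p = p,
               between_within_ratio = ratio, converged = p > 0.05)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write imputed datasets to CSV files
#'
#' @param result An [chained_equations()] result.
#' @param dir Output directory; files are `imputed_<i>.csv` plus
#'   `chain_stats.csv`.
#' @return The directory, invisibly.
#' @export
write_imputations <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(result$datasets))
    write_trait_csv(result$datasets[[i]],
                    file.path(dir, sprintf("imputed_%d.csv", i)))
  utils::write.csv(result$chain_stats, file.path(dir, "chain_stats.csv"),
                   row.names = FALSE)
  invisible(dir)
}
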