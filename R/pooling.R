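#' Pool point estimates across imputations with Rubin's rules
#'
#' `Q_bar = mean(estimates)`, within variance `U_bar = mean(variances)`,
#' between variance `B = var(estimates)` (sample variance), total variance
#' `T = U_bar + (1 + 1/m) B`, standard error `sqrt(T)`. Degrees of freedom
#' for pooled intervals use the Barnard-Rubin small-sample formula.
#'
#' @param estimates Numeric vector of m per-run point estimates (m >= 2).
#' @param variances Numeric vector of m per-run variances (>= 0).
#' @param df_com Complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment (optional; `Inf` gives the classic large-sample df).
#' @return List of class `"pooled_estimate"`: `q_bar`, `u_bar`, `b`, `t`,
#'   `se`, `m`, `df`.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf) {
  m <- length(estimates)
  if (m < 2) stop("need m >= 2 runs to estimate between-imputation variance")
  stopifnot(length(variances) == m, all(variances >= 0))
  q_bar <- mean(estimates)
  u_bar <- mean(variances)
  b <- stats::var(estimates)
  t <- u_bar + (1 + 1 / m) * b
  # Barnard-Rubin degrees of freedom
  r <- if (u_bar > 0) (1 + 1 / m) * b / u_bar else Inf
  df_old <- if (b > 0) (m - 1) * (1 + 1 / r)^2 else Inf
  df <- if (is.finite(df_com)) {
    lambda <- (1 + 1 / m) * b / t
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    1 / (1 / df_old + 1 / df_obs)
  } else df_old
  structure(list(q_bar = q_bar, u_bar = u_bar, b = b, t = t,
                 se = sqrt(t), m = m, df = df),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate: Q = %.4g (se %.4g) from m = %d runs\n",
              x$q_bar, x$se, x$m))
  invisible(x)
}

#' Pool phylogenetic mixed-model fits across imputations and chains
#'
#' Per run, each coefficient contributes its posterior mean (point
#' estimate) and posterior variance (within-run variance); these are
#' combined by [rubin_pool()]. The posterior fraction above zero is
#' computed on the concatenation of all runs' samples (equal weight per
#' run), since Rubin's rules apply to point estimates, not tail
#' probabilities. DIC and heritability are pooled as plain means.
#'
#' @param results List of `glmm_result` objects sharing one [model_spec()].
#' @return data.frame of class `"pooled_model"`: one row per coefficient
#'   with `model`, `term`, `beta` (pooled), `se` (sqrt of total variance),
#'   `se_within` (mean posterior SD), `frac_above_zero`, `significance`,
#'   `mean_dic`, `mean_h2`, `m`.
#' @export
pool_posterior <- function(results) {
  stopifnot(length(results) >= 2)
  labels <- colnames(results[[1]]$draws$fixed_effects)
  for (r in results)
    if (!identical(colnames(r$draws$fixed_effects), labels))
      stop("mismatched coefficient sets across runs")
  m <- length(results)
  rows <- lapply(labels, function(term) {
    est <- vapply(results, function(r)
      mean(r$draws$fixed_effects[, term]), numeric(1))
    vr <- vapply(results, function(r)
      stats::var(r$draws$fixed_effects[, term]), numeric(1))
    pooled <- rubin_pool(est, vr)
    all_samples <- unlist(lapply(results, function(r)
      r$draws$fixed_effects[, term]))
    frac <- mean(all_samples > 0)
    data.frame(model = results[[1]]$spec$name, term = term,
               beta = pooled$q_bar, se = pooled$se,
               se_within = mean(sqrt(vr)),
               frac_above_zero = frac,
               significance = significance(frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mean_dic <- mean(vapply(results, `[[`, numeric(1), "dic"))
  out$mean_h2 <- mean(vapply(results, function(r)
    mean(r$heritability_samples), numeric(1)))
  out$m <- m
  class(out) <- c("pooled_model", class(out))
  out
}

#' Write a pooled model table as CSV and JSON
#'
#' Emits the report in the familiar regression-table shape: model, term,
#' beta, s.e., percent of posterior above zero, mean DIC, mean phylogenetic
#' heritability.
#'
#' @param pooled A [pool_posterior()] result (or several rbind-ed).
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @return `pooled`, invisibly.
#' @export
write_pooled_report <- function(pooled, path_csv = NULL, path_json = NULL) {
  tab <- as.data.frame(pooled)
  tab$pct_above_zero <- 100 * tab$frac_above_zero
  if (!is.null(path_csv)) utils::write.csv(tab, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    writeLines(to_json(split(tab, tab$model)), path_json)
  invisible(pooled)
}

# Minimal JSON emitter for report export (lists, data.frames, scalars).
to_json <- function(x, indent = "") {
  if (is.data.frame(x)) {
    rows <- apply(x, 1, function(r)
      paste0("{", paste(sprintf('"%s": %s', names(r),
                                vapply(r, json_scalar, character(1))),
                        collapse = ", "), "}"))
    paste0("[", paste(rows, collapse = ", "), "]")
  } else if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      sprintf('"%s": %s', nm, to_json(x[[nm]])), character(1))
    paste0("{", paste(items, collapse = ", "), "}")
  } else json_scalar(x)
}

json_scalar <- function(v) {
  if (is.na(suppressWarnings(as.numeric(v))))
    sprintf('"%s"', as.character(v))
  else as.character(as.numeric(v))
}
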