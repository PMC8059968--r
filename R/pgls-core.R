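#' Phylogenetic generalized least squares fit
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * C)` by GLS. The model is
#' whitened through the Cholesky factor of C, so the estimate is exactly
#' ordinary least squares on the transformed data:
#' `beta_hat = (X' C^-1 X)^-1 X' C^-1 y`. The residual scale uses the
#' unbiased divisor `n - p`, and the log-likelihood is the multivariate
#' normal density of `y` at `(beta_hat, sigma2_hat)`.
#'
#' @param y Response vector (taxa order must match `C`).
#' @param X Design matrix with column names; full column rank required.
#' @param C Phylogenetic covariance matrix from [phylo_vcv()] (identity
#'   gives ordinary least squares).
#' @return Object of class `"pgls_fit"`: `beta_hat`, `beta_cov`,
#'   `sigma2_hat`, `df_resid`, `loglik`, `design_labels`, plus the
#'   whitening factor and transformed data for downstream use.
#' @export
fit_pgls <- function(y, X, C) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  if (n <= p) stop("need n > p observations")
  L <- tryCatch(chol(C), error = function(e)
    stop("C is singular or not positive definite; consider inflating ",
         "zero-length branches (resolve_zero_branches)"))
  # whiten: solve L' z = y  (C = L'L with upper-triangular L)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear columns include: ",
         paste(bad, collapse = ", "))
  }
  beta_hat <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta_hat
  rss <- sum(resid_w^2)
  df_resid <- n - p
  sigma2_hat <- rss / df_resid
  XtCiX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtCiX_inv) <- list(colnames(X), colnames(X))
  logdetC <- 2 * sum(log(diag(L)))
  loglik <- if (sigma2_hat > 0)
    -0.5 * (n * log(2 * pi * sigma2_hat) + logdetC + rss / sigma2_hat)
  else Inf
  structure(list(beta_hat = stats::setNames(drop(beta_hat), colnames(X)),
                 beta_cov = sigma2_hat * XtCiX_inv,
                 XtCiX_inv = XtCiX_inv,
                 sigma2_hat = sigma2_hat, rss = rss,
                 df_resid = df_resid, loglik = loglik,
                 design_labels = colnames(X),
                 n = n, yw = yw, Xw = Xw),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", x$n, "taxa,", length(x$beta_hat), "coefficients\n")
  print(data.frame(estimate = x$beta_hat,
                   se = sqrt(diag(x$beta_cov))))
  cat(sprintf("sigma2_hat = %.4g, df = %d, loglik = %.3f\n",
              x$sigma2_hat, x$df_resid, x$loglik))
  invisible(x)
}

#' Draw regression coefficients from the approximate joint posterior
#'
#' The standard normal-inverse-chi-square draw used by predictive mean
#' matching: `sigma2* = sigma2_hat * df / chisq(df)`, then
#' `beta* ~ N(beta_hat, sigma2* (X'C^-1 X)^-1)`. Propagates both
#' coefficient and residual-scale uncertainty into the imputations.
#'
#' @param fit A [fit_pgls()] result.
#' @return Named coefficient vector; consumes RNG state (seed the caller).
#' @export
draw_beta_posterior <- function(fit) {
  if (fit$df_resid <= 0) stop("df_resid must be positive")
  sigma2_star <- fit$sigma2_hat * fit$df_resid /
    stats::rchisq(1, fit$df_resid)
  U <- chol(fit$XtCiX_inv + diag(1e-14, ncol(fit$XtCiX_inv)))
  z <- stats::rnorm(length(fit$beta_hat))
  stats::setNames(fit$beta_hat + sqrt(sigma2_star) * drop(crossprod(U, z)),
                  fit$design_labels)
}

#' Phylogenetic ANCOVA F-test for nested PGLS models
#'
#' Compares a full and a reduced PGLS model on the same response and
#' covariance with the classical nested-model F statistic, computed on
#' residual sums of squares in the `C^-1` metric:
#' `F = [(RSS_r - RSS_f)/(p_f - p_r)] / [RSS_f / df_f]`, upper-tail p.
#'
#' @param fit_full,fit_reduced [fit_pgls()] results; the reduced design's
#'   columns must be a subset of the full design's.
#' @return List of class `"pgls_ancova"`: `F`, `p`, `df_num`, `df_den`,
#'   `df_full`, `df_reduced` (model parameter counts).
#' @export
pgls_ancova_ftest <- function(fit_full, fit_reduced) {
  if (!all(fit_reduced$design_labels %in% fit_full$design_labels))
    stop("models are not nested: reduced design must be a column subset ",
         "of the full design")
  if (fit_full$n != fit_reduced$n)
    stop("models fit to different numbers of taxa")
  p_f <- length(fit_full$beta_hat)
  p_r <- length(fit_reduced$beta_hat)
  if (p_f <= p_r) stop("full model must have more parameters")
  df_num <- p_f - p_r
  df_den <- fit_full$df_resid
  Fstat <- ((fit_reduced$rss - fit_full$rss) / df_num) /
    (fit_full$rss / df_den)
  Fstat <- max(Fstat, 0)
  structure(list(F = Fstat,
                 p = stats::pf(Fstat, df_num, df_den, lower.tail = FALSE),
                 df_num = df_num, df_den = df_den,
                 df_full = p_f, df_reduced = p_r),
            class = "pgls_ancova")
}

#' @export
print.pgls_ancova <- function(x, ...) {
  cat(sprintf("phylogenetic ANCOVA: F = %.3f on %d and %d df, p = %.4g\n",
              x$F, x$df_num, x$df_den, x$p))
  invisible(x)
}

#' Variance inflation factors under a phylogenetic correlation structure
#'
#' Whitens the design through the Cholesky factor of C and computes, for
#' every non-intercept column, `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes
#' from regressing the whitened column j on all other whitened columns.
#' Perfectly collinear columns are reported as `Inf` with a warning.
#'
#' @param X Design matrix (include the intercept column; it is used in the
#'   auxiliary regressions but not reported).
#' @param C Phylogenetic covariance matrix (identity for ordinary VIF).
#' @param intercept_label Name of the intercept column to exclude from the
#'   report (default `"(Intercept)"`; ignored if absent).
#' @return Named numeric vector of VIFs, all >= 1.
#' @export
vif <- function(X, C, intercept_label = "(Intercept)") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  L <- chol(C)
  Xw <- backsolve(L, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  report <- setdiff(colnames(X), intercept_label)
  out <- stats::setNames(numeric(length(report)), report)
  for (j in report) {
    xj <- Xw[, j]
    others <- Xw[, setdiff(colnames(X), j), drop = FALSE]
    fit <- stats::lm.fit(others, xj)
    tss <- sum((xj - mean(xj))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity for '", j, "'; VIF is infinite")
      out[j] <- Inf
    } else out[j] <- max(1 / (1 - r2), 1)
  }
  out
}

#' Build a design matrix from a trait table and a formula
#'
#' Thin wrapper over [stats::model.matrix()]: categorical columns become
#' treatment-coded factors with the alphabetically first level as baseline.
#'
#' @param table A [trait_table()] (must be complete over the used columns).
#' @param formula Model formula, e.g. `log_ecv ~ log_body + litter_size`.
#' @return List with `y` (response vector) and `X` (design matrix), rows in
#'   table species order.
#' @export
build_design <- function(table, formula) {
  df <- table$data
  for (nm in names(df))
    if (table$types[[nm]] == "categorical")
      df[[nm]] <- factor(df[[nm]], levels = sort(unique(df[[nm]])))
  mf <- stats::model.frame(formula, df, na.action = stats::na.fail)
  list(y = stats::model.response(mf),
       X = stats::model.matrix(attr(mf, "terms"), mf))
}
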