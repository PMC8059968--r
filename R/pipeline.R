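#' Assemble a full-analysis configuration
#'
#' One declarative object drives [run_full_analysis()]: the data source
#' (a [sim_config()] preset or file paths), the imputation and sampler
#' settings, the model registry, and one master seed from which every
#' stage derives its own stream.
#'
#' @param data A [sim_config()] (synthetic study) or
#'   `list(tree = <newick path>, table = <csv path>)`.
#' @param imputation An [imputation_config()].
#' @param sampler A [sampler_settings()].
#' @param registry Named list of [model_spec()]s (default
#'   [model_registry()]).
#' @param seed Master seed.
#' @param d_perm Permutations per null for the missingness D statistics.
#' @param evo_floor Minimum subset size for the per-landmass comparison.
#' @param ancova_full,ancova_reduced Formulas of the phylogenetic ANCOVA
#'   pair (defaults: allometry with and without an origin-specific slope).
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(data = paper_emulation_config(),
                            imputation = imputation_config(),
                            sampler = sampler_settings(),
                            registry = model_registry(),
                            seed = 1,
                            d_perm = 200,
                            evo_floor = 10,
                            ancova_full = log_ecv ~ log_body + log_body:origin,
                            ancova_reduced = log_ecv ~ log_body) {
  structure(list(data = data, imputation = imputation, sampler = sampler,
                 registry = registry, seed = seed, d_perm = d_perm,
                 evo_floor = evo_floor, ancova_full = ancova_full,
                 ancova_reduced = ancova_reduced),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognized top-level keys: `seed`, `d_perm`, `evo_floor`, `data`
#' (either `preset: paper-emulation` with optional overrides, or `tree:` /
#' `table:` paths), `imputation`, `sampler` (field names as in the
#' constructors, plus `paper_scale`), and `registry` (map of model name to
#' fixed-effect formula string).
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  data <- if (!is.null(y$data$preset)) {
    stopifnot(y$data$preset == "paper-emulation")
    paper_emulation_config(seed = y$data$seed %||% seed,
                           n_tips = y$data$n_tips %||% 176,
                           litter_effect = y$data$litter_effect %||% -0.2)
  } else list(tree = y$data$tree, table = y$data$table)
  imp <- do.call(imputation_config,
                 c(y$imputation, list(seed = y$imputation$seed %||% seed))
                 [!duplicated(c(names(y$imputation), "seed"))])
  sam <- do.call(sampler_settings, y$sampler %||% list())
  reg <- if (!is.null(y$registry))
    mapply(function(nm, f) model_spec(nm, stats::as.formula(f)),
           names(y$registry), y$registry, SIMPLIFY = FALSE)
  else model_registry()
  analysis_config(data = data, imputation = imp, sampler = sam,
                  registry = reg, seed = seed,
                  d_perm = y$d_perm %||% 200,
                  evo_floor = y$evo_floor %||% 10)
}

# Split a multi-chain glmm_result into one pseudo-result per chain so that
# pooling can treat every (dataset x chain) run as a unit.
split_chains <- function(result, C) {
  lapply(unique(result$draws$chain_id), function(cc) {
    sel <- result$draws$chain_id == cc
    draws <- structure(list(
      fixed_effects = result$draws$fixed_effects[sel, , drop = FALSE],
      var_phylo = result$draws$var_phylo[sel],
      var_resid = result$draws$var_resid[sel],
      chain_id = rep(1L, sum(sel))), class = "posterior_draws")
    structure(list(draws = draws,
                   heritability_samples = heritability(draws),
                   dic = dic(draws, result$y, result$X, C),
                   frac_above_zero = colMeans(draws$fixed_effects > 0),
                   spec = result$spec, y = result$y, X = result$X),
              class = "glmm_result")
  })
}

#' Complete-case PGLS validation of a model specification
#'
#' Listwise-deletes every species with a missing value in the model's
#' variables and fits a plain Brownian-motion PGLS on the survivors --
#' the classical analysis the imputation pipeline is designed to improve
#' on, reported beside it as a sanity check.
#'
#' @param table A [trait_table()] (may contain missing cells).
#' @param tree The phylogeny.
#' @param spec A [model_spec()].
#' @return A [fit_pgls()] result with extra fields `n_complete` and
#'   `model`.
#' @export
complete_case_validation <- function(table, tree, spec) {
  al <- align_to_tree(table, tree)
  vars <- c(spec$response, all.vars(spec$fixed))
  keep <- stats::complete.cases(al$table$data[, vars, drop = FALSE])
  sub <- al$table$data[keep, , drop = FALSE]
  des0 <- build_design(
    trait_table(sub, al$table$types),
    stats::as.formula(paste(spec$response,
                            paste(deparse(spec$fixed[[2]]), collapse = ""),
                            sep = " ~ ")))
  if (sum(keep) < ncol(des0$X) + 3)
    stop("too few complete cases: ", sum(keep), " retained")
  tips <- al$table$species[keep]
  sub_tree <- sort_tips(ape::keep.tip(al$tree, tips))
  C <- suppressWarnings(phylo_vcv(sub_tree))
  y <- des0$y[match(sub_tree$tip.label, rownames(sub))]
  X <- des0$X[match(sub_tree$tip.label, rownames(sub)), , drop = FALSE]
  fit <- fit_pgls(y, X, C)
  fit$n_complete <- sum(keep)
  fit$model <- spec$name
  fit
}

#' Run the full comparative analysis
#'
#' Executes the pipeline end to end: load or simulate the data; diagnose
#' missingness (pattern + phylogenetic signal of the gaps); impute m
#' completed datasets by phylogenetic chained equations; fit every model
#' in the registry on every dataset with the Gibbs sampler (two chains
#' each); pool all (dataset x chain) runs per model with Rubin's rules and
#' label significance by posterior mass; compare BM/OU/EB per landmass for
#' brain and body size; and run the phylogenetic ANCOVA with variance
#' inflation factors. All randomness derives from the master seed, so a
#' given configuration reproduces bit-identically.
#'
#' @param config An [analysis_config()], or a path to a YAML file.
#' @return Object of class `"analysis_report"` with fields `model_table`,
#'   `evo_table`, `ancova` (including `vif`), `diagnostics` (missingness
#'   pattern, D statistics, imputation convergence), `complete_case`,
#'   `imputation` (the full result) and `provenance`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dat <- stage("data", {
    if (inherits(config$data, "sim_config")) {
      simulate_study(config$data)
    } else {
      tree <- resolve_zero_branches(read_newick(config$data$tree))
      table <- read_trait_csv(config$data$table)
      al <- align_to_tree(table, tree)
      list(tree = al$tree, table = al$table, complete = NULL)
    }
  })
  C <- suppressWarnings(phylo_vcv(dat$tree))

  diagnostics <- stage("diagnose", {
    list(pattern = missing_pattern(dat$table),
         d_stats = missingness_signal(dat$table, dat$tree,
                                      n_perm = config$d_perm,
                                      seed = derive_seed(config$seed, "d")))
  })

  imputation <- stage("impute", {
    cfg <- config$imputation
    cfg$seed <- derive_seed(config$seed, "impute")
    chained_equations(dat$table, dat$tree, cfg)
  })
  diagnostics$convergence <- convergence_summary(imputation)

  model_rows <- list()
  cc_fits <- list()
  for (spec in config$registry) {
    runs <- stage(paste0("fit:", spec$name), {
      fits <- lapply(seq_along(imputation$datasets), function(i)
        fit_phylo_glmm(imputation$datasets[[i]], C, spec,
                       settings = config$sampler,
                       seed = derive_seed(config$seed, "glmm",
                                          spec$name, i)))
      unlist(lapply(fits, split_chains, C = C), recursive = FALSE)
    })
    model_rows[[spec$name]] <- stage(paste0("pool:", spec$name),
                                     pool_posterior(runs))
    cc_fits[[spec$name]] <- stage(paste0("complete_case:", spec$name),
                                  complete_case_validation(dat$table,
                                                           dat$tree, spec))
  }
  model_table <- do.call(rbind, model_rows)
  rownames(model_table) <- NULL

  evo_table <- stage("evomodels",
                     per_landmass_analysis(dat$table, dat$tree,
                                           floor = config$evo_floor))

  ancova <- stage("ancova", {
    full <- build_design(dat$table, config$ancova_full)
    red <- build_design(dat$table, config$ancova_reduced)
    fit_full <- fit_pgls(full$y, full$X, C)
    fit_red <- fit_pgls(red$y, red$X, C)
    res <- pgls_ancova_ftest(fit_full, fit_red)
    res$vif <- vif(full$X, C)
    res
  })

  structure(list(model_table = model_table,
                 evo_table = evo_table,
                 ancova = ancova,
                 diagnostics = diagnostics,
                 complete_case = cc_fits,
                 imputation = imputation,
                 provenance = list(seed = config$seed,
                                   m = imputation$m,
                                   chains = config$sampler$chains,
                                   n_iter = config$sampler$n_iter,
                                   package_version =
                                     as.character(utils::packageVersion("phylomi")),
                                   r_version = R.version.string)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("=== pooled model table ===\n")
  tab <- x$model_table
  tab$pct_above_zero <- sprintf("%.2f", 100 * tab$frac_above_zero)
  print(tab[, c("model", "term", "beta", "se", "pct_above_zero",
                "significance", "mean_dic", "mean_h2")],
        row.names = FALSE, digits = 3)
  cat("\n=== evolutionary models (best per subset x trait) ===\n")
  best <- x$evo_table[x$evo_table$delta_aic == 0, ]
  print(best[, c("subset", "trait", "model", "aic")], row.names = FALSE)
  cat("\n=== phylogenetic ANCOVA ===\n")
  print(x$ancova)
  cat("max VIF:", sprintf("%.2f", max(x$ancova$vif)), "\n")
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' @param report An [run_full_analysis()] result.
#' @param dir Output directory; emits `model_table.csv`, `evo_table.csv`,
#'   `ancova.json`, `missing_pattern.csv` and `provenance.json`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$model_table, file.path(dir, "model_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$evo_table, file.path(dir, "evo_table.csv"),
                   row.names = FALSE)
  writeLines(to_json(list(F = report$ancova$F, p = report$ancova$p,
                          df_num = report$ancova$df_num,
                          df_den = report$ancova$df_den,
                          vif = max(report$ancova$vif))),
             file.path(dir, "ancova.json"))
  utils::write.csv(report$diagnostics$pattern$per_column,
                   file.path(dir, "missing_pattern.csv"), row.names = FALSE)
  writeLines(to_json(report$provenance), file.path(dir, "provenance.json"))
  invisible(dir)
}
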