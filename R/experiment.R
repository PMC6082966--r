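#' Scenario configuration for the full comparison experiment
#'
#' Describes the grid the study runs: QTL counts, replicates, the models to
#' compare, and the simulation settings. Replicate seeds are derived
#' deterministically from `base_seed` by a counter scheme so replicates are
#' independent of execution order.
#'
#' @param qtl_counts QTL numbers per scenario (default `c(105, 60, 15)`).
#' @param n_replicates stochastic replicates per scenario (default 10).
#' @param base_seed integer seed the replicate seeds derive from.
#' @param models list of [model_spec()]s (default: all eight models).
#' @param output_dir directory for per-replicate artifacts and tables.
#' @param sim a [sim_config()].
#' @param arch a [trait_architecture()].
#' @param genome_args extra arguments to [genome_spec()] (e.g. smaller
#'   `n_markers` for a smoke profile).
#' @param pca_threshold cumulative-variance retention threshold.
#' @param cv_folds cross-validation folds.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(qtl_counts = c(105, 60, 15), n_replicates = 10,
                            base_seed = 1, models = default_models(),
                            output_dir = "pcgp_out", sim = sim_config(),
                            arch = trait_architecture(), genome_args = list(),
                            pca_threshold = 0.999, cv_folds = 5) {
  stopifnot(n_replicates >= 1, length(qtl_counts) >= 1)
  structure(list(qtl_counts = qtl_counts, n_replicates = n_replicates,
                 base_seed = as.integer(base_seed), models = models,
                 output_dir = output_dir, sim = sim, arch = arch,
                 genome_args = genome_args, pca_threshold = pca_threshold,
                 cv_folds = cv_folds),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param niter,burnin,thin MCMC controls shared by the Bayesian models.
#' @export
default_models <- function(niter = 12000, burnin = 2000, thin = 5) {
  lapply(c("ridge", "brr", "bayesa", "bayesb",
           "pcr-normal", "pcr-t", "pcr-lasso", "pcr-eigen"),
         model_spec, niter = niter, burnin = burnin, thin = thin)
}

#' @rdname scenario_config
#' @param qtl scenario QTL count.
#' @param replicate replicate index.
#' @export
replicate_seed <- function(base_seed, qtl, replicate) {
  as.integer((as.numeric(base_seed) + 7919 * qtl + 101 * replicate) %%
               2147483647)
}

#' Run one simulation replicate end to end
#'
#' Simulates the historical and recent populations for one QTL scenario,
#' applies SNP QC and PCA on the pooled training generations, fits every
#' requested model with five-fold cross-validation, and measures persistency
#' of accuracy over the candidate generations using one fit trained on the
#' whole reference population.
#'
#' @param n_qtl QTL count for this scenario.
#' @param seed replicate seed (all randomness flows from it).
#' @param models list of [model_spec()]s.
#' @param sim a [sim_config()].
#' @param arch a [trait_architecture()].
#' @param genome_args extra arguments to [genome_spec()].
#' @param pca_threshold retention threshold for [fit_pca()].
#' @param cv_folds cross-validation folds.
#' @return list with elements `counts` (SNPs and PCs retained), `cv`
#'   (per-fold report), `cv_summary`, `persistency`, `heritability`
#'   (realised var(TBV)/var(phenotype) in the training cohort), and `basis`
#'   metadata.
#' @export
run_replicate <- function(n_qtl, seed, models = default_models(),
                          sim = sim_config(), arch = trait_architecture(),
                          genome_args = list(), pca_threshold = 0.999,
                          cv_folds = 5) {
  set.seed(seed)
  spec <- do.call(genome_spec, c(list(n_qtl = n_qtl), genome_args))
  hist <- simulate_historical(spec, sim)
  spec <- assign_qtl_effects(spec, arch, hist)
  cohorts <- simulate_recent(hist, spec, arch, sim)
  train <- bind_cohorts(cohorts[paste0("gen", sim$training_generations)])

  md_train <- filter_snps(marker_data(marker_genotypes(train, spec)))
  basis <- fit_pca(md_train, threshold = pca_threshold)
  k <- basis$retained_k
  scores_train <- project(md_train, basis)[, seq_len(k), drop = FALSE]
  lambda_ret <- basis$values[seq_len(k)]
  X <- sex_design(train$sex)

  cand_gens <- sim$candidate_generations
  cand_md <- lapply(cohorts[paste0("gen", cand_gens)], function(co)
    apply_snp_filter(marker_data(marker_genotypes(co, spec)), md_train))
  cand_tbv <- lapply(cohorts[paste0("gen", cand_gens)], `[[`, "tbv")

  cv_all <- list(); per_all <- list()
  for (ms in models) {
    is_pc <- ms$predictor_source == "pc"
    design <- if (is_pc) scores_train else md_train$genotypes
    eigv <- if (ms$model == "pcr-eigen") lambda_ret else NULL
    cv <- five_fold_cv(ms, design, train$phenotype, train$tbv, X,
                       k = cv_folds, sigma2_a = arch$additive_variance,
                       sigma2_e = arch$residual_variance, eigenvalues = eigv)
    fit <- fit_model(ms, design, train$phenotype, X,
                     sigma2_a = arch$additive_variance,
                     sigma2_e = arch$residual_variance,
                     eigenvalues = eigv,
                     basis = if (is_pc) basis else NULL)
    per <- persistency(fit, cand_md, cand_tbv, generations = cand_gens)
    cv_all[[ms$model]] <- cv
    per_all[[ms$model]] <- per
  }
  cv <- do.call(rbind, cv_all); rownames(cv) <- NULL
  per <- do.call(rbind, per_all); rownames(per) <- NULL
  class(cv) <- class(per) <- c("eval_report", "data.frame")
  list(
    counts = data.frame(snp = ncol(md_train$genotypes), pc = k),
    heritability = var(train$tbv) / var(train$phenotype),
    cv = cv,
    cv_summary = cbind(model = names(cv_all),
                       do.call(rbind, lapply(cv_all, attr, "summary"))),
    persistency = per,
    variance_profile = variance_profile(basis))
}

.rep_paths <- function(dir, qtl, rep) {
  base <- file.path(dir, "replicates", sprintf("qtl%d_rep%02d", qtl, rep))
  list(cv = paste0(base, "_cv.tsv"),
       per = paste0(base, "_persistency.tsv"),
       counts = paste0(base, "_counts.tsv"))
}

#' Run the whole scenario grid and emit the study tables
#'
#' Loops over scenarios and replicates (resuming past completed replicates
#' whose artifact files already exist), then aggregates four tables:
#' SNP/PC counts, cross-validated accuracy per model and scenario, bias
#' regression coefficients, and the per-generation persistency series. All
#' outputs are TSV; a YAML manifest records seeds and runtimes.
#'
#' @param cfg a [scenario_config()].
#' @param resume reuse existing per-replicate artifacts (default `TRUE`).
#' @return invisibly, a list of the four aggregated tables.
#' @export
run_scenario <- function(cfg, resume = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(file.path(cfg$output_dir, "replicates"),
             recursive = TRUE, showWarnings = FALSE)
  manifest <- list(base_seed = cfg$base_seed, replicates = list())
  cv_rows <- list(); per_rows <- list(); count_rows <- list()
  for (qtl in cfg$qtl_counts) {
    for (r in seq_len(cfg$n_replicates)) {
      seed <- replicate_seed(cfg$base_seed, qtl, r)
      paths <- .rep_paths(cfg$output_dir, qtl, r)
      key <- sprintf("qtl%d_rep%02d", qtl, r)
      if (resume && all(file.exists(unlist(paths)))) {
        cv <- as.data.frame(data.table::fread(paths$cv))
        per <- as.data.frame(data.table::fread(paths$per))
        counts <- as.data.frame(data.table::fread(paths$counts))
      } else {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(
          run_replicate(qtl, seed, cfg$models, cfg$sim, cfg$arch,
                        cfg$genome_args, cfg$pca_threshold, cfg$cv_folds),
          error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("%s failed: %s; aggregating without it",
                          key, conditionMessage(res)))
          manifest$replicates[[key]] <- list(seed = seed, status = "failed",
                                             message = conditionMessage(res))
          next
        }
        cv <- cbind(qtl = qtl, replicate = r, res$cv)
        per <- cbind(qtl = qtl, replicate = r, res$persistency)
        counts <- cbind(qtl = qtl, replicate = r, res$counts,
                        heritability = res$heritability)
        data.table::fwrite(cv, paths$cv, sep = "\t")
        data.table::fwrite(per, paths$per, sep = "\t")
        data.table::fwrite(counts, paths$counts, sep = "\t")
        manifest$replicates[[key]] <-
          list(seed = seed, status = "ok",
               seconds = round(proc.time()[["elapsed"]] - t0, 1))
      }
      cv_rows[[key]] <- cv; per_rows[[key]] <- per; count_rows[[key]] <- counts
    }
  }
  if (!length(cv_rows)) stop("no replicate completed")
  cv <- do.call(rbind, cv_rows); per <- do.call(rbind, per_rows)
  counts <- do.call(rbind, count_rows)

  agg <- function(df, keys, metrics) {
    sp <- split(df, df[keys], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
      # one value per replicate first (fold-weighted mean), then SE across
      # replicates
      per_rep <- lapply(metrics, function(mm)
        tapply(d[[mm]], d$replicate, mean, na.rm = TRUE))
      stats <- lapply(per_rep, function(v)
        c(mean(v, na.rm = TRUE),
          if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
          else NA_real_))
      cbind(d[1, keys, drop = FALSE], n_replicates = length(unique(d$replicate)),
            stats::setNames(as.data.frame(as.list(unlist(stats))),
                            as.vector(t(outer(metrics, c("mean", "se"),
                                              paste, sep = "_")))))
    }))
    rownames(out) <- NULL
    out
  }
  table1 <- agg(counts, "qtl", c("snp", "pc", "heritability"))
  table2 <- agg(cv, c("qtl", "model"), "accuracy")
  table3 <- agg(cv, c("qtl", "model"), c("b0", "b1", "r2"))
  series <- agg(per, c("qtl", "model", "generation"), c("accuracy", "b1"))

  out <- list(counts = table1, accuracy = table2, bias = table3,
              persistency = series)
  for (nm in names(out))
    data.table::fwrite(out[[nm]],
                       file.path(cfg$output_dir, paste0("table_", nm, ".tsv")),
                       sep = "\t")
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  invisible(out)
}

#' Read a scenario configuration file
#'
#' YAML with nested sections mirroring [scenario_config()],
#' [sim_config()], [genome_spec()] and [trait_architecture()] field names;
#' a `models` section lists model names plus optional shared `niter`,
#' `burnin`, `thin`.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  models <- if (is.null(y$models)) default_models() else {
    mc <- y$models
    lapply(mc$names, model_spec,
           niter = mc$niter %||% 12000,
           burnin = mc$burnin %||% 2000,
           thin = mc$thin %||% 5)
  }
  scenario_config(
    qtl_counts = y$qtl_counts %||% c(105, 60, 15),
    n_replicates = y$n_replicates %||% 10,
    base_seed = y$base_seed %||% 1,
    models = models,
    output_dir = y$output_dir %||% "pcgp_out",
    sim = do.call(sim_config, y$sim %||% list()),
    arch = do.call(trait_architecture, y$arch %||% list()),
    genome_args = y$genome %||% list(),
    pca_threshold = y$pca_threshold %||% 0.999,
    cv_folds = y$cv_folds %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
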