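#' Bias regression of true on estimated breeding values
#'
#' Ordinary least squares of TBV on GEBV. A slope near 1 indicates
#' predictions that are neither inflated nor deflated; the reported R2 is
#' the squared correlation.
#'
#' @param tbv true breeding values.
#' @param gebv genomic estimated breeding values.
#' @return named vector `c(b0, b1, r2)`; all `NA` (with a warning) when the
#'   GEBV variance is zero.
#' @export
bias_regression <- function(tbv, gebv) {
  stopifnot(length(tbv) == length(gebv))
  if (length(tbv) < 3) stop("need at least 3 pairs")
  vg <- var(gebv)
  if (!is.finite(vg) || vg == 0) {
    warning("zero GEBV variance; bias regression undefined")
    return(c(b0 = NA_real_, b1 = NA_real_, r2 = NA_real_))
  }
  b1 <- stats::cov(tbv, gebv) / vg
  b0 <- mean(tbv) - b1 * mean(gebv)
  c(b0 = b0, b1 = b1, r2 = cor(tbv, gebv)^2)
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBV and TBV (the standard simulation-study
#' accuracy, where TBV is known).
#'
#' @param gebv,tbv numeric vectors.
#' @return scalar correlation, `NA` if either side has zero variance.
#' @export
accuracy <- function(gebv, tbv) {
  if (sd(gebv) == 0 || sd(tbv) == 0) return(NA_real_)
  cor(gebv, tbv)
}

.eval_row <- function(gebv, tbv, ...) {
  acc <- accuracy(gebv, tbv)
  br <- if (is.na(acc)) c(b0 = NA_real_, b1 = NA_real_, r2 = NA_real_)
        else bias_regression(tbv, gebv)
  data.frame(..., n = length(tbv), accuracy = acc,
             b0 = br[["b0"]], b1 = br[["b1"]], r2 = br[["r2"]])
}

#' Five-fold cross-validation within the training population
#'
#' Randomly partitions the training animals into `k` folds (uniform,
#' unstratified); each fold in turn is held out, the model is fitted on the
#' remainder, and accuracy plus the bias regression are computed on the
#' held-out animals against their TBVs. A fold whose held-out TBVs have zero
#' variance yields `NA` accuracy (with a warning) and is excluded from the
#' mean.
#'
#' @param spec a [model_spec()].
#' @param design full training predictor matrix (genotypes or PC scores).
#' @param y training phenotypes.
#' @param tbv training true breeding values.
#' @param X fixed-effect design for the training animals.
#' @param k number of folds (default 5).
#' @param sigma2_a,sigma2_e,eigenvalues passed to [fit_model()].
#' @return data.frame of per-fold results (class `eval_report`) with a
#'   `summary` attribute holding mean and SE (sd/sqrt(k)) per metric.
#' @export
five_fold_cv <- function(spec, design, y, tbv, X, k = 5,
                         sigma2_a = 0.25, sigma2_e = 0.75,
                         eigenvalues = NULL) {
  n <- length(y)
  stopifnot(n == nrow(design), n == length(tbv), k >= 2)
  fold <- sample(rep_len(seq_len(k), n))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_model(spec, design[!test, , drop = FALSE], y[!test],
                     X[!test, , drop = FALSE],
                     sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                     eigenvalues = eigenvalues)
    gebv <- predict_gebv(fit, design[test, , drop = FALSE])
    if (sd(tbv[test]) == 0)
      warning(sprintf("fold %d: zero TBV variance; accuracy undefined", f))
    rows[[f]] <- .eval_row(gebv, tbv[test], model = spec$model, fold = f)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  attr(out, "summary") <- summarize_eval(out)
  attr(out, "folds") <- fold
  out
}

#' Summarise an evaluation report
#'
#' Mean and standard error (sd/sqrt(number of non-missing units)) of each
#' metric across folds, generations or replicates.
#'
#' @param report an `eval_report` data.frame.
#' @param by optional grouping column name.
#' @return data.frame of means and SEs.
#' @export
summarize_eval <- function(report, by = NULL) {
  metrics <- c("accuracy", "b0", "b1", "r2")
  one <- function(df) {
    vals <- lapply(metrics, function(mm) {
      v <- df[[mm]][!is.na(df[[mm]])]
      c(mean = mean(v), se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
    })
    stats::setNames(
      as.data.frame(as.list(unlist(vals))),
      as.vector(t(outer(metrics, c("mean", "se"), paste, sep = "_"))))
  }
  if (is.null(by)) return(one(report))
  parts <- split(report, report[[by]])
  out <- do.call(rbind, lapply(parts, one))
  out <- cbind(stats::setNames(data.frame(names(parts)), by), out)
  rownames(out) <- NULL
  out
}

#' Persistency of accuracy across selection-candidate generations
#'
#' Applies a single fit (trained once on the reference population) to each
#' candidate generation in turn and reports per-generation accuracy and bias
#' regression. LD between markers and QTL erodes with recombination, so
#' accuracy is expected to decline with generation.
#'
#' @param fit a `gp_fit` trained on the reference population.
#' @param candidates named list of candidate inputs (design matrices or
#'   [marker_data()] objects, projected through the fit's basis when
#'   present).
#' @param tbvs list of TBV vectors parallel to `candidates`.
#' @param generations generation labels (defaults to `names(candidates)`).
#' @return an `eval_report` data.frame, one row per generation.
#' @export
persistency <- function(fit, candidates, tbvs,
                        generations = names(candidates)) {
  stopifnot(length(candidates) == length(tbvs))
  if (is.null(generations)) generations <- seq_along(candidates)
  rows <- Map(function(newdata, tbv, g) {
    gebv <- predict_gebv(fit, newdata)
    .eval_row(gebv, tbv, model = fit$model, generation = g)
  }, candidates, tbvs, generations)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @rdname summarize_eval
#' @param file output TSV path.
#' @export
write_eval_report <- function(report, file) {
  data.table::fwrite(report, file, sep = "\t")
  invisible(file)
}
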