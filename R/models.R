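#' Fixed-effect design matrix for mean + sex
#'
#' @param sex character/factor vector with levels "M"/"F".
#' @return an n x 2 design matrix (intercept, male indicator).
#' @export
sex_design <- function(sex) {
  cbind(`(Intercept)` = rep(1, length(sex)), sexM = as.numeric(sex == "M"))
}

# drop non-estimable fixed-effect columns (confounded sex/mean) with warning
.estimable_X <- function(X) {
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("fixed-effect design is singular; dropping ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

.new_fit <- function(model, prior, effects, fixed, sigma2_e, design, basis,
                     extra = list()) {
  out <- c(list(
    model = model, prior = prior,
    predictor_effects = as.vector(effects),
    fixed_effects = fixed,
    sigma2_e = sigma2_e,
    design_colnames = colnames(design),
    fitted_gebv = as.vector(design %*% effects),
    basis = basis), extra)
  class(out) <- "gp_fit"
  out
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> %s: %d predictors, sigma2_e = %.4g\n",
              x$model, length(x$predictor_effects), x$sigma2_e))
  invisible(x)
}

# solve the mixed-model equations
#   [X'X  X'Z ; Z'X  Z'Z + diag(ridge)] [s; b] = [X'y; Z'y]
# by a symmetric positive-definite (Cholesky) factorisation
.solve_mme <- function(Z, y, X, ridge) {
  p <- ncol(Z); q <- ncol(X)
  C <- matrix(0, q + p, q + p)
  C[1:q, 1:q] <- crossprod(X)
  C[1:q, (q + 1):(q + p)] <- crossprod(X, Z)
  C[(q + 1):(q + p), 1:q] <- t(C[1:q, (q + 1):(q + p)])
  C[(q + 1):(q + p), (q + 1):(q + p)] <- crossprod(Z) + diag(ridge, p)
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  R <- chol(C)
  sol <- backsolve(R, forwardsolve(t(R), rhs))
  list(fixed = stats::setNames(sol[1:q], colnames(X)),
       b = sol[(q + 1):(q + p)])
}

#' Ridge-regression BLUP on a design matrix
#'
#' Deterministic SNP-BLUP: every column of `Z` gets the common prior
#' variance `sigma2_a / m` (m = number of predictors), and the mixed-model
#' equations are solved by Cholesky decomposition. Fixed effects are
#' unpenalised.
#'
#' @param Z n x m predictor design (e.g. -1/0/1 genotypes or PC scores).
#' @param y phenotype vector.
#' @param X fixed-effect design (see [sex_design()]).
#' @param sigma2_a additive genetic variance assigned to the whole design.
#' @param sigma2_e residual variance.
#' @return a `gp_fit`.
#' @export
fit_ridge_blup <- function(Z, y, X, sigma2_a, sigma2_e) {
  Z <- as.matrix(Z)
  X <- .estimable_X(X)
  stopifnot(length(y) == nrow(Z), nrow(X) == nrow(Z),
            sigma2_a > 0, sigma2_e > 0)
  lambda <- sigma2_e / (sigma2_a / ncol(Z))
  sol <- .solve_mme(Z, y, X, rep(lambda, ncol(Z)))
  .new_fit("ridge", "fixed_isotropic", sol$b, sol$fixed, sigma2_e, Z,
           basis = NULL,
           extra = list(sigma2_b = sigma2_a / ncol(Z), ridge = lambda))
}

#' Eigenvalue-weighted principal-component BLUP (PCR-Eigen)
#'
#' Each PC score's prior variance is proportional to its eigenvalue:
#' `sigma2_pc_j = sigma2_a * lambda_j`. Because the retained components no
#' longer carry the full variance, the retained eigenvalues are by default
#' renormalised to sum to one before scaling; `normalize = FALSE` keeps the
#' raw eigenvalues.
#'
#' @param scores n x k PC score matrix (see [project()]).
#' @param y phenotype vector.
#' @param X fixed-effect design.
#' @param sigma2_a additive genetic variance.
#' @param lambda eigenvalues of the retained components.
#' @param sigma2_e residual variance.
#' @param normalize renormalise retained eigenvalues to sum to 1 (default
#'   `TRUE`).
#' @return a `gp_fit`.
#' @export
fit_pcr_eigen <- function(scores, y, X, sigma2_a, lambda, sigma2_e,
                          normalize = TRUE) {
  scores <- as.matrix(scores)
  X <- .estimable_X(X)
  stopifnot(length(lambda) == ncol(scores), sigma2_a > 0, sigma2_e > 0)
  if (any(lambda <= 0))
    stop("zero eigenvalue among retained components; check the retention rule")
  lam <- if (normalize) lambda / sum(lambda) else lambda
  var_pc <- sigma2_a * lam
  sol <- .solve_mme(scores, y, X, sigma2_e / var_pc)
  .new_fit("pcr-eigen", "fixed_eigen", sol$b, sol$fixed, sigma2_e, scores,
           basis = NULL, extra = list(sigma2_bj = var_pc))
}

# BGLR-style weakly informative hyperparameters: the prior mode of each
# effect variance equals R2 * var(y) / sum of design column variances, and
# the prior mode of the residual variance equals (1 - R2) * var(y).
.default_hyper <- function(design, y, R2 = 0.5, df_b = 5, df_e = 5) {
  vy <- var(y)
  msx <- sum(apply(design, 2, var))
  if (msx <= 0) msx <- sum(colMeans(design^2))
  mode_b <- R2 * vy / msx
  list(S_b = mode_b * (df_b + 2) / df_b,
       S_e = (1 - R2) * vy * (df_e + 2) / df_e,
       init_b = mode_b,
       init_e = (1 - R2) * vy)
}

#' Bayesian whole-genome regression by single-site Gibbs sampling
#'
#' One sampler covers the four shrinkage priors: `"gaussian"` (Bayesian
#' ridge / PCR-Normal: one common effect variance), `"scaled_t"` (BayesA /
#' PCR-t: locus-specific variances, scaled-t marginal), `"spike_slab_t"`
#' (BayesB: point mass at zero mixed with a t slab, mixing proportion pi
#' learned with a Beta prior), and `"double_exponential"` (Bayesian Lasso /
#' PCR-Lasso: normal scale mixture with exponential local scales and a
#' Gamma-distributed global rate). Fixed effects carry a flat prior; the
#' residual variance a scaled inverse chi-square. Hyperparameter scales
#' default to a weakly informative rule: the prior mode of each effect
#' variance equals `R2 * var(y)` divided by the summed column variances of
#' the design, and the prior mode of the residual variance equals
#' `(1 - R2) * var(y)`, with `R2 = 0.5` and 5 degrees of freedom.
#'
#' @param design n x p predictor matrix (genotypes or PC scores).
#' @param y phenotype vector.
#' @param X fixed-effect design.
#' @param prior one of `"gaussian"`, `"scaled_t"`, `"spike_slab_t"`,
#'   `"double_exponential"`.
#' @param niter,burnin,thin chain length controls (defaults 12000 / 2000 / 5).
#' @param R2 prior fraction of phenotypic variance attributed to the
#'   predictors (default 0.5).
#' @param df_b,df_e degrees of freedom of the scaled inverse chi-square
#'   priors on effect and residual variances.
#' @param S_b optional explicit scale for the effect-variance prior,
#'   overriding the R2 rule.
#' @param pi_beta length-2 Beta prior (shape1, shape2) for the BayesB
#'   proportion of zero effects (default `c(5, 5)`: mean 0.5, weight 10).
#' @param gamma_prior shape and rate of the Gamma prior on the Lasso global
#'   rate parameter.
#' @param fixed_sigma2_e,fixed_sigma2_b,fixed_pi pin the corresponding
#'   parameter at a value instead of sampling it (degenerate hyperpriors,
#'   mainly for validation against conjugate closed forms).
#' @param keep_effect_draws store post-burn-in effect draws (memory heavy;
#'   for diagnostics on small problems).
#' @param seed optional seed applied just before sampling.
#' @return a `gp_fit` with posterior means and a thinned `sigma2_e_chain`.
#' @export
fit_bayes <- function(design, y, X,
                      prior = c("gaussian", "scaled_t", "spike_slab_t",
                                "double_exponential"),
                      niter = 12000, burnin = 2000, thin = 5,
                      R2 = 0.5, df_b = 5, df_e = 5, S_b = NULL,
                      pi_beta = c(5, 5), gamma_prior = c(shape = 1, rate = 1e-4),
                      fixed_sigma2_e = NULL, fixed_sigma2_b = NULL,
                      fixed_pi = NULL, keep_effect_draws = FALSE,
                      seed = NULL) {
  prior <- match.arg(prior)
  design <- as.matrix(design)
  X <- .estimable_X(X)
  stopifnot(length(y) == nrow(design), nrow(X) == nrow(design),
            niter > burnin, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  hp <- .default_hyper(design, y, R2, df_b, df_e)
  if (is.null(S_b)) S_b <- hp$S_b
  prior_code <- match(prior, c("gaussian", "scaled_t", "spike_slab_t",
                               "double_exponential")) - 1L
  res <- cpp_gibbs(design, as.numeric(y), X, prior_code,
                   as.integer(niter), as.integer(burnin), as.integer(thin),
                   df_b, S_b, df_e, hp$S_e,
                   pi_beta[1], pi_beta[2],
                   gamma_prior[["shape"]], gamma_prior[["rate"]],
                   !is.null(fixed_sigma2_e),
                   if (is.null(fixed_sigma2_e)) hp$init_e else fixed_sigma2_e,
                   !is.null(fixed_sigma2_b),
                   if (is.null(fixed_sigma2_b)) hp$init_b else fixed_sigma2_b,
                   !is.null(fixed_pi),
                   if (is.null(fixed_pi)) 0.5 else fixed_pi,
                   keep_effect_draws)
  extra <- list(
    sigma2_b = res$sigma2_b, sigma2_bj = res$sigma2_bj,
    sigma2_e_chain = res$sigma2_e_chain, n_saved = res$n_saved,
    hyper = list(df_b = df_b, S_b = S_b, df_e = df_e, S_e = hp$S_e, R2 = R2))
  if (prior == "spike_slab_t") extra$pi_zero <- res$pi_zero
  if (prior == "double_exponential") extra$gamma2 <- res$gamma2
  if (keep_effect_draws) extra$b_draws <- res$b_draws
  fit <- .new_fit(paste0("bayes_", prior), prior, res$b,
                  stats::setNames(res$fixed, colnames(X)),
                  res$sigma2_e, design, basis = NULL, extra = extra)
  fit
}

#' Specify a prediction model by its name in the comparison study
#'
#' The eight models: `"ridge"` (Ridge-R), `"brr"` (Bayes-Ridge), `"bayesa"`,
#' `"bayesb"` on SNP genotypes; `"pcr-eigen"`, `"pcr-normal"`, `"pcr-t"`,
#' `"pcr-lasso"` on retained PC scores.
#'
#' @param model model name (see above).
#' @param niter,burnin,thin MCMC controls for the Bayesian models.
#' @param ... further arguments stored and passed to the fitting routine.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = c("ridge", "brr", "bayesa", "bayesb",
                                 "pcr-eigen", "pcr-normal", "pcr-t",
                                 "pcr-lasso"),
                       niter = 12000, burnin = 2000, thin = 5, ...) {
  model <- match.arg(model)
  source <- if (startsWith(model, "pcr")) "pc" else "snp"
  prior <- switch(model,
    ridge = "fixed_isotropic", `pcr-eigen` = "fixed_eigen",
    brr = "gaussian", `pcr-normal` = "gaussian",
    bayesa = "scaled_t", `pcr-t` = "scaled_t",
    bayesb = "spike_slab_t", `pcr-lasso` = "double_exponential")
  structure(list(model = model, predictor_source = source, prior = prior,
                 mcmc = list(niter = niter, burnin = burnin, thin = thin),
                 args = list(...)),
            class = "model_spec")
}

#' Fit any of the eight models on a prepared design
#'
#' Dispatches a [model_spec()] to [fit_ridge_blup()], [fit_pcr_eigen()] or
#' [fit_bayes()]. For PC-based models pass the score matrix as `design`,
#' the retained eigenvalues, and (optionally) the `pca_basis` so that
#' [predict_gebv()] can project new genotypes automatically.
#'
#' @param spec a [model_spec()].
#' @param design predictor matrix (genotypes or PC scores).
#' @param y phenotype vector.
#' @param X fixed-effect design.
#' @param sigma2_a,sigma2_e variances plugged into the deterministic BLUP
#'   solvers (the simulation truth 0.25 / 0.75 by default).
#' @param eigenvalues retained eigenvalues (PCR-Eigen only).
#' @param basis optional `pca_basis` stored in the fit for projection.
#' @return a `gp_fit`.
#' @export
fit_model <- function(spec, design, y, X, sigma2_a = 0.25, sigma2_e = 0.75,
                      eigenvalues = NULL, basis = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  fit <- switch(spec$model,
    ridge = fit_ridge_blup(design, y, X, sigma2_a, sigma2_e),
    `pcr-eigen` = {
      if (is.null(eigenvalues)) stop("pcr-eigen requires the retained eigenvalues")
      do.call(fit_pcr_eigen,
              c(list(design, y, X, sigma2_a, eigenvalues, sigma2_e),
                spec$args))
    },
    do.call(fit_bayes,
            c(list(design, y, X, prior = spec$prior,
                   niter = spec$mcmc$niter, burnin = spec$mcmc$burnin,
                   thin = spec$mcmc$thin),
              spec$args)))
  fit$model <- spec$model
  fit$basis <- basis
  fit
}

#' Genomic estimated breeding values for new individuals
#'
#' GEBV = design x posterior-mean (or BLUP) predictor effects; fixed effects
#' are excluded. If the fit carries a `pca_basis` and `newdata` is a
#' [marker_data()], genotypes are first projected through the stored basis
#' (training means/sds); for SNP-based fits the -1/0/1 genotype matrix is
#' used directly.
#'
#' @param fit a `gp_fit`.
#' @param newdata a design matrix, or a `marker_data` over the fit's locus
#'   set.
#' @return numeric GEBV vector.
#' @export
predict_gebv <- function(fit, newdata) {
  p <- length(fit$predictor_effects)
  if (inherits(newdata, "marker_data")) {
    design <- if (!is.null(fit$basis))
      project(newdata, fit$basis, k = p)
    else
      newdata$genotypes
  } else {
    design <- as.matrix(newdata)
  }
  if (ncol(design) != p)
    stop(sprintf("design has %d columns but the fit has %d predictor effects",
                 ncol(design), p))
  as.vector(design %*% fit$predictor_effects)
}
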