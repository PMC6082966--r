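#' Eigen-decomposition of the marker correlation matrix
#'
#' Computes the m x m Pearson correlation matrix W of the training genotype
#' matrix and its symmetric eigen-decomposition W = U D U'. Eigenvalues are
#' clipped at zero (tiny negative values are numerical noise), eigenvector
#' signs are fixed by making the largest-magnitude element of each column
#' positive, and the number of retained components is the smallest k whose
#' cumulative eigenvalue fraction reaches `threshold`. Training column means
#' and standard deviations are stored so that any cohort can later be
#' projected onto the same basis.
#'
#' @param train a [marker_data()] for the training population (post QC).
#' @param threshold cumulative-variance retention threshold (default 0.999).
#' @return an object of class `pca_basis` with fields `rotation` (U),
#'   `values` (descending eigenvalues), `center`, `scale`, `retained_k`,
#'   `threshold`.
#' @export
fit_pca <- function(train, threshold = 0.999) {
  stopifnot(inherits(train, "marker_data"), threshold > 0, threshold <= 1)
  g <- train$genotypes
  if (nrow(g) < 2) stop("need at least 2 training individuals")
  ctr <- colMeans(g)
  sds <- apply(g, 2, sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero-variance marker reaches PCA (QC should have removed it): ",
         paste(train$locus_ids[head(zero, 5)], collapse = ", "))
  zs <- scale(g, center = ctr, scale = sds)
  w <- crossprod(zs) / (nrow(g) - 1)
  ed <- eigen(w, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  u <- ed$vectors
  # sign convention: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  cum <- cumsum(vals) / sum(vals)
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(vals)
  structure(list(
    rotation = u,
    values = vals,
    center = ctr,
    scale = sds,
    locus_ids = train$locus_ids,
    retained_k = as.integer(k),
    threshold = threshold,
    n_train = nrow(g)
  ), class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf(
    "<pca_basis> %d markers, %d training individuals; %d PCs retained at %.4g cumulative variance\n",
    length(x$values), x$n_train, x$retained_k, x$threshold))
  invisible(x)
}

#' Project genotypes onto a fitted PC basis
#'
#' Columns are standardised with the *training* means and standard
#' deviations, then multiplied by the first `retained_k` eigenvectors. With
#' `scores = "raw"` the genotype matrix is projected without
#' standardisation, i.e. Z U directly.
#'
#' @param geno a [marker_data()] (or plain genotype matrix) over the same
#'   locus set as the basis.
#' @param basis a [fit_pca()] result.
#' @param k number of components to keep (default: the basis's retained
#'   count).
#' @param scores `"standardized"` (default, consistent with the
#'   correlation-matrix eigensystem) or `"raw"`.
#' @return an n x k matrix of PC scores.
#' @export
project <- function(geno, basis, k = basis$retained_k,
                    scores = c("standardized", "raw")) {
  scores <- match.arg(scores)
  g <- if (inherits(geno, "marker_data")) geno$genotypes else as.matrix(geno)
  if (ncol(g) != length(basis$values))
    stop("locus set does not match the PCA basis")
  if (inherits(geno, "marker_data") &&
      !identical(geno$locus_ids, basis$locus_ids))
    stop("locus ids do not match the PCA basis")
  stopifnot(k >= 1, k <= length(basis$values))
  if (scores == "standardized")
    g <- scale(g, center = basis$center, scale = basis$scale)
  out <- g %*% basis$rotation[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(k))
  out
}

#' Per-component variance profile
#'
#' The fraction of total marker-correlation variance carried by each
#' principal component and its cumulative sum (the data behind the scree and
#' cumulative-variance curves).
#'
#' @param basis a [fit_pca()] result.
#' @return data.frame with columns `pc`, `eigenvalue`, `prop`, `cumprop`.
#' @export
variance_profile <- function(basis) {
  tot <- sum(basis$values)
  data.frame(pc = seq_along(basis$values),
             eigenvalue = basis$values,
             prop = basis$values / tot,
             cumprop = cumsum(basis$values) / tot)
}

#' @rdname variance_profile
#' @param file output path for a TSV of the profile.
#' @export
write_variance_profile <- function(basis, file) {
  data.table::fwrite(variance_profile(basis), file, sep = "\t")
  invisible(file)
}
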