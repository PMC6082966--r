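#' Construct a marker data set
#'
#' Wraps an n x m genotype matrix in the -1/0/1 coding together with locus
#' metadata. Allele frequencies refer to the allele counted positively by
#' the coding.
#'
#' @param genotypes integer/numeric matrix, one row per individual, one
#'   column per marker, values in \{-1, 0, 1\}.
#' @param locus_ids optional character vector of marker names.
#' @return an object of class `marker_data`.
#' @export
marker_data <- function(genotypes, locus_ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(-1L, 0L, 1L)))
    stop("genotypes must be coded -1/0/1")
  if (is.null(locus_ids))
    locus_ids <- sprintf("SNP%04d", seq_len(ncol(genotypes)))
  colnames(genotypes) <- locus_ids
  structure(list(
    genotypes = genotypes,
    locus_ids = locus_ids,
    allele_frequencies = colMeans(genotypes + 1) / 2,
    qc = NULL
  ), class = "marker_data")
}

#' @export
print.marker_data <- function(x, ...) {
  cat(sprintf("<marker_data> %d individuals x %d markers%s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              if (is.null(x$qc)) "" else " (QC applied)"))
  invisible(x)
}

#' @export
dim.marker_data <- function(x) dim(x$genotypes)

# one-locus Hardy-Weinberg goodness-of-fit chi-square (1 df, no continuity
# correction); returns NA p-value for monomorphic loci (handled by MAF rule)
.hwe_test <- function(g) {
  n <- length(g)
  obs <- c(sum(g == -1L), sum(g == 0L), sum(g == 1L))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(c(chisq = 0, p = NA_real_))
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((obs - expd)^2 / expd)
  c(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' SNP quality control
#'
#' Removes markers with minor allele frequency below `maf_min` (strict
#' inequality) or with a Hardy-Weinberg goodness-of-fit p-value below
#' `hwe_p_min` (Pearson chi-square, 1 df). MAF is checked first, so a
#' monomorphic locus is recorded as a MAF removal. The returned object keeps
#' a per-locus report; apply the same mask to other cohorts with
#' [apply_snp_filter()] so that candidate sets see exactly the loci the
#' training set retained.
#'
#' @param geno a [marker_data()] (typically the training population).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum Hardy-Weinberg p-value (default 1e-5).
#' @return a filtered `marker_data` whose `qc` field is a data.frame with
#'   columns locus, maf, hwe_chisq, hwe_p, kept, reason.
#' @export
filter_snps <- function(geno, maf_min = 0.01, hwe_p_min = 1e-5) {
  stopifnot(inherits(geno, "marker_data"))
  g <- geno$genotypes
  if (nrow(g) == 0L) stop("no individuals in marker data")
  p <- colMeans(g + 1) / 2
  maf <- pmin(p, 1 - p)
  hwe <- apply(g, 2, .hwe_test)
  reason <- rep(NA_character_, ncol(g))
  reason[!is.na(hwe["p", ]) & hwe["p", ] < hwe_p_min] <- "hwe"
  reason[maf < maf_min] <- "maf"   # MAF rule takes precedence
  kept <- is.na(reason)
  report <- data.frame(
    locus = geno$locus_ids,
    maf = unname(maf),
    hwe_chisq = unname(hwe["chisq", ]),
    hwe_p = unname(hwe["p", ]),
    kept = kept,
    reason = reason,
    stringsAsFactors = FALSE)
  out <- marker_data(g[, kept, drop = FALSE], geno$locus_ids[kept])
  out$qc <- report
  out
}

#' Apply a previously computed SNP filter
#'
#' @param geno a [marker_data()] covering the same locus set the filter was
#'   computed on.
#' @param qc either the `qc` report of a filtered `marker_data`, or the
#'   filtered `marker_data` itself.
#' @return `geno` restricted to the retained loci.
#' @export
apply_snp_filter <- function(geno, qc) {
  stopifnot(inherits(geno, "marker_data"))
  report <- if (inherits(qc, "marker_data")) qc$qc else qc
  if (is.null(report)) stop("no QC report found; run filter_snps() first")
  if (!all(report$locus %in% geno$locus_ids))
    stop("QC report loci are not a subset of this marker data")
  keep <- report$locus[report$kept]
  out <- marker_data(geno$genotypes[, keep, drop = FALSE], keep)
  out$qc <- report
  out
}

#' Write / read genotypes in a PLINK .raw-style text table
#'
#' Whitespace-delimited with header `FID IID PAT MAT SEX PHENOTYPE` followed
#' by one column per SNP counting reference alleles 0/1/2. `read_plink_raw`
#' converts counts to the internal -1/0/1 coding.
#'
#' @param cohort a `cohort`.
#' @param spec the matching `genome_spec`.
#' @param file output path.
#' @export
write_plink_raw <- function(cohort, spec, file) {
  g <- marker_genotypes(cohort, spec) + 1L
  n <- n_individuals(cohort)
  dt <- data.table::data.table(
    FID = rep(1L, n),
    IID = cohort$id,
    PAT = ifelse(is.na(cohort$sire), 0L, cohort$sire),
    MAT = ifelse(is.na(cohort$dam), 0L, cohort$dam),
    SEX = ifelse(cohort$sex == "M", 1L, 2L),
    PHENOTYPE = if (is.null(cohort$phenotype)) -9 else cohort$phenotype)
  dt <- cbind(dt, data.table::as.data.table(g))
  data.table::fwrite(dt, file, sep = " ")
  invisible(file)
}

#' @rdname write_plink_raw
#' @return `read_plink_raw` returns a list with the `marker_data` and a
#'   data.frame of the leading pedigree/phenotype columns.
#' @export
read_plink_raw <- function(file) {
  dt <- data.table::fread(file)
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta_cols %in% names(dt)))
    stop("not a PLINK .raw-style table: missing header columns")
  snp_cols <- setdiff(names(dt), meta_cols)
  g <- as.matrix(dt[, snp_cols, with = FALSE]) - 1L
  md <- marker_data(g, snp_cols)
  rownames(md$genotypes) <- as.character(dt$IID)
  list(markers = md,
       samples = as.data.frame(dt[, meta_cols, with = FALSE]))
}

#' Write a cohort's individual table
#'
#' TSV of id, generation, sex, TBV and phenotype.
#' @param cohort a `cohort`.
#' @param file output path.
#' @export
write_cohort_info <- function(cohort, file) {
  dt <- data.table::data.table(
    id = cohort$id,
    generation = rep_len(cohort$generation, n_individuals(cohort)),
    sex = cohort$sex,
    tbv = if (is.null(cohort$tbv)) NA_real_ else cohort$tbv,
    phenotype = if (is.null(cohort$phenotype)) NA_real_ else cohort$phenotype)
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}

#' Write the SNP QC report
#' @param geno a filtered `marker_data`.
#' @param file output path.
#' @export
write_qc_report <- function(geno, file) {
  if (is.null(geno$qc)) stop("no QC report attached")
  data.table::fwrite(geno$qc, file, sep = "\t")
  invisible(file)
}
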