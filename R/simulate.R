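#' @useDynLib pcgp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pchisq quantile rbinom rgamma rnorm runif sd var
#' @importFrom utils head tail
NULL

# internal: per-chromosome first/last locus indices (loci are sorted)
.chr_bounds <- function(spec) {
  first <- match(seq_len(spec$n_chromosomes), spec$chr)
  last <- length(spec$chr) - match(seq_len(spec$n_chromosomes), rev(spec$chr)) + 1L
  list(first = first, last = last)
}

.drop_args <- function(spec) {
  b <- .chr_bounds(spec)
  list(pos = spec$pos, chr_first = b$first, chr_last = b$last,
       chr_len = spec$chrom_length,
       marker_idx = marker_loci(spec), qtl_idx = qtl_loci(spec))
}

.new_cohort <- function(generation, haplo, sex, allele_count,
                        id = NULL, sire = NA_integer_, dam = NA_integer_) {
  n <- ncol(haplo) / 2L
  structure(list(
    generation = generation,
    id = if (is.null(id)) seq_len(n) else id,
    sire = rep_len(sire, n), dam = rep_len(dam, n),
    sex = sex,
    haplo = haplo,
    allele_count = allele_count,
    tbv = NULL, phenotype = NULL
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> generation %s: %d individuals (%d M / %d F), %d loci\n",
              x$generation, length(x$id), sum(x$sex == "M"), sum(x$sex == "F"),
              nrow(x$haplo)))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort a `cohort`.
#' @export
n_individuals <- function(cohort) length(cohort$id)

#' Simulate the historical (mutation-drift) population
#'
#' Random mating from unrelated founders: the population grows linearly from
#' the founder count to `hist_size` during the growth phase, then stays
#' constant. Male counts are interpolated linearly up to `hist_final_males`
#' in the final generation. Meiosis follows the Haldane map (Poisson
#' crossovers, mean = chromosome length in Morgans); mutation is recurrent at
#' the genome's stated rates. Only the final generation is returned.
#'
#' @param spec a [genome_spec()].
#' @param cfg a [sim_config()].
#' @return a `cohort` for the last historical generation.
#' @export
simulate_historical <- function(spec, cfg) {
  validate_genome_spec(spec)
  n_f <- cfg$hist_founder_females
  n_m <- cfg$hist_founder_males
  n0 <- n_f + n_m
  L <- length(spec$pos)

  # founder haplotypes: markers at frequency 0.5, QTL uniform over the
  # initial allele set
  haplo <- matrix(0L, L, 2L * n0)
  mi <- marker_loci(spec); qi <- qtl_loci(spec)
  haplo[mi, ] <- matrix(rbinom(length(mi) * 2L * n0, 1L, 0.5),
                        length(mi), 2L * n0)
  if (length(qi))
    haplo[qi, ] <- matrix(sample.int(spec$n_qtl_alleles,
                                     length(qi) * 2L * n0, replace = TRUE),
                          length(qi), 2L * n0)
  allele_count <- integer(L)
  allele_count[qi] <- spec$n_qtl_alleles

  n_gen <- cfg$hist_growth_generations + cfg$hist_constant_generations
  if (n_gen == 0) {
    sex <- rep(c("M", "F"), c(n_m, n_f))
    return(.new_cohort(0L, haplo, sex, allele_count))
  }
  g <- seq_len(n_gen)
  sizes <- ifelse(g <= cfg$hist_growth_generations,
                  round(n0 + (cfg$hist_size - n0) * g /
                          max(cfg$hist_growth_generations, 1)),
                  cfg$hist_size)
  males <- pmax(1L, round(n_m + (cfg$hist_final_males - n_m) * g / n_gen))

  da <- .drop_args(spec)
  res <- cpp_random_mating(haplo, n_m, as.integer(sizes), as.integer(males),
                           da$pos, da$chr_first, da$chr_last, da$chr_len,
                           da$marker_idx, spec$marker_mutation_rate,
                           da$qtl_idx, spec$qtl_mutation_rate,
                           allele_count)
  final_m <- res$n_males
  final_n <- ncol(res$haplo) / 2L
  sex <- rep(c("M", "F"), c(final_m, final_n - final_m))
  cohort <- .new_cohort(as.integer(n_gen), res$haplo, sex, res$allele_count)

  # drift sanity: warn (not fail) if every marker is fixed
  if (length(mi)) {
    seg <- rowSums(res$haplo[mi, , drop = FALSE])
    if (all(seg == 0L | seg == 2L * final_n))
      warning("all marker loci are fixed in the final historical generation")
  }
  cohort
}

#' Assign QTL allele effects and calibrate the additive variance
#'
#' Draws one additive effect per QTL allele from a gamma distribution with
#' shape `arch$qtl_effect_shape` and a random sign, centres effects within
#' each locus, then rescales all effects by a single common factor so that
#' the variance of true breeding values in the supplied reference cohort
#' equals the target additive variance. The calibration is one-time: alleles
#' created later by mutation reuse the stored scale factor and are not
#' re-centred.
#'
#' @param spec a [genome_spec()].
#' @param arch a [trait_architecture()].
#' @param reference a `cohort` used to measure realised genetic variance.
#' @return the `genome_spec` with effect tables attached.
#' @export
assign_qtl_effects <- function(spec, arch, reference) {
  qi <- qtl_loci(spec)
  spec$qtl_effect_shape <- arch$qtl_effect_shape
  eff_env <- new.env(parent = emptyenv())
  eff_env$eff <- vector("list", length(qi))
  if (length(qi) == 0L) {
    spec$qtl_effects <- eff_env
    spec$effect_scale <- 0
    return(spec)
  }
  counts <- reference$allele_count[qi]
  for (k in seq_along(qi)) {
    raw <- rgamma(counts[k], shape = arch$qtl_effect_shape) *
      sample(c(-1, 1), counts[k], replace = TRUE)
    eff_env$eff[[k]] <- raw - mean(raw)
  }
  spec$qtl_effects <- eff_env
  spec$effect_scale <- 1
  tbv <- compute_tbv(reference, spec)
  v <- var(tbv)
  if (!is.finite(v) || v <= 0)
    stop("zero genetic variance in the reference cohort; all QTL fixed?")
  scale_factor <- sqrt(arch$additive_variance / v)
  eff_env$eff <- lapply(eff_env$eff, function(e) e * scale_factor)
  spec$effect_scale <- scale_factor
  spec
}

#' True breeding values from haplotypes
#'
#' Sums the QTL allele effects carried on both haplotypes of each
#' individual. Alleles created by mutation after calibration get a fresh
#' gamma-drawn, sign-randomised effect scaled by the stored calibration
#' factor, drawn on first use.
#'
#' @param cohort a `cohort`.
#' @param spec a `genome_spec` with effects assigned.
#' @return numeric vector of TBVs.
#' @export
compute_tbv <- function(cohort, spec) {
  qi <- qtl_loci(spec)
  n <- n_individuals(cohort)
  if (length(qi) == 0L || is.null(spec$qtl_effects)) return(numeric(n))
  eff_env <- spec$qtl_effects
  pat <- seq(1L, 2L * n, by = 2L)
  tbv <- numeric(n)
  for (k in seq_along(qi)) {
    eff <- eff_env$eff[[k]]
    n_seen <- cohort$allele_count[qi[k]]
    if (n_seen > length(eff)) {
      extra <- rgamma(n_seen - length(eff), shape = spec$qtl_effect_shape) *
        sample(c(-1, 1), n_seen - length(eff), replace = TRUE) *
        spec$effect_scale
      eff <- c(eff, extra)
      eff_env$eff[[k]] <- eff
    }
    h <- cohort$haplo[qi[k], ]
    tbv <- tbv + eff[h[pat]] + eff[h[pat + 1L]]
  }
  tbv
}

#' Add phenotypes to a cohort
#'
#' phenotype = TBV + e with e ~ N(0, residual variance), independent across
#' individuals. No sex effect is simulated.
#'
#' @param cohort a `cohort` with TBVs assigned.
#' @param arch a [trait_architecture()].
#' @return the cohort with a `phenotype` field.
#' @export
generate_phenotypes <- function(cohort, arch) {
  stopifnot(!is.null(cohort$tbv))
  n <- n_individuals(cohort)
  cohort$phenotype <- cohort$tbv + rnorm(n, 0, sqrt(arch$residual_variance))
  cohort
}

#' Simulate the recent (selected) population
#'
#' Generation 0 is sampled at random from the final historical generation.
#' Each subsequent generation is bred from the previous one by truncation
#' selection: the top `recent_males` males and top `recent_females` females
#' of the previous generation become parents, each dam is paired with a
#' randomly drawn selected sire and produces `offspring_per_dam` offspring.
#' Offspring sexes are an exact random half split. TBVs and phenotypes are
#' filled in for every generation.
#'
#' Parents are ranked by own phenotype by default — the estimated breeding
#' value available without a pedigree BLUP, with accuracy h. Ranking on the
#' true breeding value itself (`criterion = "tbv"`) selects with accuracy 1
#' and erodes the additive variance far below the nominal h2 by the time the
#' reference generations are reached; `"random"` disables selection
#' altogether (used to quantify the response to selection).
#'
#' @param hist the final historical `cohort`.
#' @param spec a `genome_spec` with QTL effects assigned.
#' @param arch a [trait_architecture()].
#' @param cfg a [sim_config()].
#' @param criterion parent-ranking criterion: `"phenotype"` (default),
#'   `"tbv"`, or `"random"`.
#' @return list of `cohort`s, one per generation 0..`recent_generations`.
#' @export
simulate_recent <- function(hist, spec, arch, cfg,
                            criterion = c("phenotype", "tbv", "random")) {
  criterion <- match.arg(criterion)
  if (is.null(spec$qtl_effects) && spec$n_qtl > 0)
    stop("assign_qtl_effects() must be called before simulate_recent()")
  m_avail <- which(hist$sex == "M")
  f_avail <- which(hist$sex == "F")
  if (length(m_avail) < cfg$recent_males || length(f_avail) < cfg$recent_females)
    stop("historical generation has fewer animals than the recent founders require")

  take <- c(sample(m_avail, cfg$recent_males),
            sample(f_avail, cfg$recent_females))
  cols <- as.vector(rbind(2L * take - 1L, 2L * take))
  g0 <- .new_cohort(0L, hist$haplo[, cols, drop = FALSE],
                    rep(c("M", "F"), c(cfg$recent_males, cfg$recent_females)),
                    hist$allele_count)
  g0$tbv <- compute_tbv(g0, spec)
  g0 <- generate_phenotypes(g0, arch)

  da <- .drop_args(spec)
  cohorts <- vector("list", cfg$recent_generations + 1L)
  cohorts[[1L]] <- g0
  prev <- g0
  for (g in seq_len(cfg$recent_generations)) {
    males <- which(prev$sex == "M")
    females <- which(prev$sex == "F")
    if (length(males) < cfg$recent_males || length(females) < cfg$recent_females)
      stop(sprintf("generation %d: fewer candidates than required parents", g))
    if (criterion == "random") {
      sires <- sample(males, cfg$recent_males)
      dams <- sample(females, cfg$recent_females)
    } else {
      score <- if (criterion == "phenotype") prev$phenotype else prev$tbv
      sires <- males[order(score[males], decreasing = TRUE)][seq_len(cfg$recent_males)]
      dams <- females[order(score[females], decreasing = TRUE)][seq_len(cfg$recent_females)]
    }
    dam_vec <- rep(dams, each = cfg$offspring_per_dam)
    sire_vec <- rep(sample(sires, length(dams), replace = TRUE),
                    each = cfg$offspring_per_dam)
    n_off <- length(dam_vec)
    res <- cpp_drop_generation(prev$haplo, sire_vec, dam_vec,
                               da$pos, da$chr_first, da$chr_last, da$chr_len,
                               da$marker_idx, spec$marker_mutation_rate,
                               da$qtl_idx, spec$qtl_mutation_rate,
                               prev$allele_count)
    n_m <- n_off %/% 2L
    sex <- sample(rep(c("M", "F"), c(n_m, n_off - n_m)))
    coh <- .new_cohort(as.integer(g), res$haplo, sex, res$allele_count,
                       sire = sire_vec, dam = dam_vec)
    coh$sire <- sire_vec
    coh$dam <- dam_vec
    coh$tbv <- compute_tbv(coh, spec)
    coh <- generate_phenotypes(coh, arch)
    cohorts[[g + 1L]] <- coh
    prev <- coh
  }
  names(cohorts) <- paste0("gen", 0:cfg$recent_generations)
  cohorts
}

#' Pool several cohorts into one
#'
#' Used to build the reference (training) population from generations 8 and
#' 9. Fields are concatenated; the `generation` field becomes a vector.
#'
#' @param cohorts list of `cohort`s sharing a genome.
#' @return a pooled `cohort`.
#' @export
bind_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  haplo <- do.call(cbind, lapply(cohorts, `[[`, "haplo"))
  out <- .new_cohort(
    generation = unlist(lapply(cohorts, function(co)
      rep(co$generation[1L], n_individuals(co)))),
    haplo = haplo,
    sex = unlist(lapply(cohorts, `[[`, "sex"), use.names = FALSE),
    allele_count = cohorts[[length(cohorts)]]$allele_count)
  tbvs <- lapply(cohorts, `[[`, "tbv")
  if (!any(vapply(tbvs, is.null, logical(1))))
    out$tbv <- unlist(tbvs, use.names = FALSE)
  phen <- lapply(cohorts, `[[`, "phenotype")
  if (!any(vapply(phen, is.null, logical(1))))
    out$phenotype <- unlist(phen, use.names = FALSE)
  out
}

#' Marker genotype matrix of a cohort
#'
#' Collapses the two haplotypes at every marker locus into the -1/0/1
#' genotype coding used by all models (count of the "1" allele minus 1).
#'
#' @param cohort a `cohort`.
#' @param spec the matching `genome_spec`.
#' @return an n x m integer matrix with marker ids as column names.
#' @export
marker_genotypes <- function(cohort, spec) {
  mi <- marker_loci(spec)
  n <- n_individuals(cohort)
  pat <- seq(1L, 2L * n, by = 2L)
  h <- cohort$haplo[mi, , drop = FALSE]
  g <- t(h[, pat, drop = FALSE] + h[, pat + 1L, drop = FALSE]) - 1L
  colnames(g) <- sprintf("SNP%04d", seq_along(mi))
  rownames(g) <- as.character(cohort$id)
  g
}
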