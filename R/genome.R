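#' Define a simulated genome
#'
#' Lays out biallelic SNP markers and multi-allelic QTL at random positions on
#' a set of chromosomes. Marker and QTL positions are drawn uniformly inside
#' each chromosome and are mutually disjoint; loci are stored sorted by
#' chromosome then position. Mutation is recurrent: a marker mutation flips
#' the allele state, a QTL mutation creates a brand-new allele.
#'
#' @param n_chromosomes number of chromosomes (default 3).
#' @param chrom_length length of each chromosome in Morgans (default 1).
#' @param n_markers total number of SNP markers across the genome.
#' @param n_qtl total number of QTL across the genome (15, 60 or 105 in the
#'   standard scenarios).
#' @param marker_mutation_rate per-locus, per-meiosis marker mutation rate.
#' @param qtl_mutation_rate per-locus, per-meiosis QTL mutation rate.
#' @param n_qtl_alleles number of QTL alleles segregating at initialisation.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 3, chrom_length = 1.0,
                        n_markers = 3000, n_qtl = 105,
                        marker_mutation_rate = 1e-3,
                        qtl_mutation_rate = 1e-5,
                        n_qtl_alleles = 4) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_markers >= 0, n_qtl >= 0,
            marker_mutation_rate >= 0, qtl_mutation_rate >= 0,
            n_qtl_alleles >= 2)
  chrom_length <- rep_len(chrom_length, n_chromosomes)
  n_loci <- n_markers + n_qtl
  # spread loci over chromosomes proportionally to length
  chr_of <- sort(rep_len(seq_len(n_chromosomes), n_loci))
  pos <- numeric(n_loci)
  type <- logical(n_loci)  # TRUE = marker
  # assign marker/QTL labels at random within the genome-wide locus set
  is_marker <- rep(FALSE, n_loci)
  is_marker[sample.int(n_loci, n_markers)] <- TRUE
  for (c in seq_len(n_chromosomes)) {
    idx <- which(chr_of == c)
    # strictly interior, distinct positions
    repeat {
      p <- sort(stats::runif(length(idx), 0, chrom_length[c]))
      if (!anyDuplicated(p) && all(p > 0) && all(p < chrom_length[c])) break
    }
    pos[idx] <- p
  }
  type <- is_marker
  ord <- order(chr_of, pos)
  spec <- structure(list(
    n_chromosomes = n_chromosomes,
    chrom_length = chrom_length,
    n_markers = n_markers,
    n_qtl = n_qtl,
    chr = chr_of[ord],
    pos = pos[ord],
    is_marker = type[ord],
    marker_mutation_rate = marker_mutation_rate,
    qtl_mutation_rate = qtl_mutation_rate,
    n_qtl_alleles = n_qtl_alleles,
    qtl_effects = NULL,
    effect_scale = NULL,
    qtl_effect_shape = NULL
  ), class = "genome_spec")
  validate_genome_spec(spec)
  spec
}

validate_genome_spec <- function(spec) {
  with(spec, {
    stopifnot(length(pos) == n_markers + n_qtl)
    for (c in seq_len(n_chromosomes)) {
      pc <- pos[chr == c]
      if (length(pc) && (any(pc <= 0) || any(pc >= chrom_length[c])))
        stop("locus positions must lie strictly inside (0, chromosome length)")
      if (anyDuplicated(pc)) stop("marker and QTL positions must be disjoint")
    }
    if (marker_mutation_rate < 0 || qtl_mutation_rate < 0)
      stop("mutation rates must be non-negative")
  })
  invisible(spec)
}

#' @rdname genome_spec
#' @param spec a `genome_spec`.
#' @export
marker_loci <- function(spec) which(spec$is_marker)

#' @rdname genome_spec
#' @export
qtl_loci <- function(spec) which(!spec$is_marker)

#' Trait genetic architecture
#'
#' A single additive trait: phenotypic variance is partitioned into additive
#' genetic variance `h2 * phenotypic_variance` (captured by the QTL) and an
#' independent normal residual. QTL allele substitution effects are drawn
#' from a gamma distribution with the given shape and a random sign.
#'
#' @param h2 narrow-sense heritability (default 0.25).
#' @param phenotypic_variance total phenotypic variance (default 1).
#' @param qtl_effect_shape shape of the gamma distribution of raw QTL allele
#'   effects (default 0.4).
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(h2 = 0.25, phenotypic_variance = 1.0,
                               qtl_effect_shape = 0.4) {
  stopifnot(h2 > 0, h2 < 1, phenotypic_variance > 0, qtl_effect_shape > 0)
  structure(list(
    h2 = h2,
    phenotypic_variance = phenotypic_variance,
    additive_variance = h2 * phenotypic_variance,
    residual_variance = (1 - h2) * phenotypic_variance,
    qtl_effect_shape = qtl_effect_shape
  ), class = "trait_architecture")
}

#' Simulation design of the historical and recent populations
#'
#' The historical phase starts from unrelated founders, grows linearly to
#' `hist_size` over `hist_growth_generations` generations of random mating,
#' then keeps a constant size for `hist_constant_generations` more. Male
#' counts are interpolated linearly from the founder male count to
#' `hist_final_males` in the last historical generation. The recent phase
#' samples founders from the final historical generation and applies
#' truncation selection on true breeding values for `recent_generations`
#' discrete generations.
#'
#' @param hist_founder_females,hist_founder_males founder counts (400 / 20).
#' @param hist_growth_generations generations of linear growth (100).
#' @param hist_size population size after growth (1000).
#' @param hist_constant_generations generations at constant size (400).
#' @param hist_final_males males in the last historical generation (70).
#' @param recent_males,recent_females parents selected each recent generation
#'   (35 / 455).
#' @param recent_generations number of selected generations (15).
#' @param offspring_per_dam litter size (2).
#' @param training_generations generations pooled into the reference
#'   population (8 and 9).
#' @param candidate_generations selection-candidate generations (10 to 15).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(hist_founder_females = 400, hist_founder_males = 20,
                       hist_growth_generations = 100, hist_size = 1000,
                       hist_constant_generations = 400, hist_final_males = 70,
                       recent_males = 35, recent_females = 455,
                       recent_generations = 15, offspring_per_dam = 2,
                       training_generations = c(8, 9),
                       candidate_generations = 10:15) {
  stopifnot(hist_founder_females >= 1, hist_founder_males >= 1,
            hist_growth_generations >= 0, hist_constant_generations >= 0,
            hist_size >= 2, hist_final_males >= 1,
            recent_males >= 1, recent_females >= 1,
            recent_generations >= 1, offspring_per_dam >= 1)
  if (length(intersect(training_generations, candidate_generations)))
    stop("training and candidate generation sets must be disjoint")
  structure(list(
    hist_founder_females = hist_founder_females,
    hist_founder_males = hist_founder_males,
    hist_growth_generations = hist_growth_generations,
    hist_size = hist_size,
    hist_constant_generations = hist_constant_generations,
    hist_final_males = hist_final_males,
    recent_males = recent_males,
    recent_females = recent_females,
    recent_generations = recent_generations,
    offspring_per_dam = offspring_per_dam,
    training_generations = training_generations,
    candidate_generations = candidate_generations
  ), class = "sim_config")
}
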