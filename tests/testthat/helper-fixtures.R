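# Shared fixtures: all data are generated in code at test time.

# small genome/population used by most unit tests (seconds, not minutes)
small_genome <- function(n_markers = 120, n_qtl = 12, ...) {
  genome_spec(n_chromosomes = 2, chrom_length = 1, n_markers = n_markers,
              n_qtl = n_qtl, ...)
}

small_config <- function(...) {
  defaults <- list(hist_founder_females = 40, hist_founder_males = 10,
                   hist_growth_generations = 10, hist_size = 80,
                   hist_constant_generations = 40, hist_final_males = 20,
                   recent_males = 8, recent_females = 40,
                   recent_generations = 15, offspring_per_dam = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# one cached small end-to-end simulation reused across test files
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  set.seed(424)
  spec <- small_genome()
  cfg <- small_config()
  arch <- trait_architecture()
  hist <- simulate_historical(spec, cfg)
  spec <- assign_qtl_effects(spec, arch, hist)
  cohorts <- simulate_recent(hist, spec, arch, cfg)
  train <- bind_cohorts(cohorts[c("gen8", "gen9")])
  .fixture_cache$small <- list(spec = spec, cfg = cfg, arch = arch,
                               hist = hist, cohorts = cohorts, train = train)
  .fixture_cache$small
}

# the full-scale 105-QTL replicate shared by the calibration and
# table-reproduction checks (built once; ~1 minute)
full_replicate <- function() {
  if (!is.null(.fixture_cache$full)) return(.fixture_cache$full)
  set.seed(1)
  spec <- genome_spec()
  cfg <- sim_config()
  arch <- trait_architecture()
  hist <- simulate_historical(spec, cfg)
  spec <- assign_qtl_effects(spec, arch, hist)
  cohorts <- simulate_recent(hist, spec, arch, cfg)
  train <- bind_cohorts(cohorts[c("gen8", "gen9")])
  md <- filter_snps(marker_data(marker_genotypes(train, spec)))
  basis <- fit_pca(md)
  .fixture_cache$full <- list(spec = spec, cfg = cfg, arch = arch,
                              cohorts = cohorts, train = train,
                              md = md, basis = basis)
  .fixture_cache$full
}

# independent single-locus Wright-Fisher oracle: allele-frequency binomial
# sampling with symmetric recurrent (flip) mutation, vectorised over
# replicates; returns expected heterozygosity after n_gen generations
wf_het_oracle <- function(n_diploid, mu, n_gen, n_rep = 2000, p0 = 0.5) {
  p <- rep(p0, n_rep)
  for (g in seq_len(n_gen)) {
    p_mut <- p * (1 - mu) + (1 - p) * mu
    p <- rbinom(n_rep, 2 * n_diploid, p_mut) / (2 * n_diploid)
  }
  het <- 2 * p * (1 - p)
  c(mean = mean(het), se = sd(het) / sqrt(n_rep))
}

# simulated -1/0/1 genotype matrix with independent loci (for model tests)
random_genotypes <- function(n, m, maf_range = c(0.1, 0.5)) {
  p <- runif(m, maf_range[1], maf_range[2])
  g <- vapply(p, function(pp) rbinom(n, 2, pp) - 1L, integer(n))
  # guard against monomorphic columns
  for (j in which(apply(g, 2, sd) == 0)) g[1:2, j] <- c(-1L, 1L)
  colnames(g) <- sprintf("SNP%04d", seq_len(m))
  g
}
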