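test_that("without mutation every allele traces to a declared parent", {
  set.seed(11)
  spec <- small_genome(n_markers = 60, n_qtl = 8,
                       marker_mutation_rate = 0, qtl_mutation_rate = 0)
  cfg <- small_config(hist_growth_generations = 0,
                      hist_constant_generations = 2,
                      hist_size = 50, hist_final_males = 10)
  arch <- trait_architecture()
  hist <- simulate_historical(spec, cfg)
  # no mutation: QTL allele ids never exceed the founder allele set
  expect_true(all(hist$allele_count[qtl_loci(spec)] == spec$n_qtl_alleles))
  spec <- assign_qtl_effects(spec, arch, hist)
  cohorts <- simulate_recent(hist, spec, arch, cfg)
  for (g in 2:4) {
    off <- cohorts[[g]]
    par <- cohorts[[g - 1]]
    for (o in sample(n_individuals(off), 5)) {
      pat <- off$haplo[, 2 * o - 1]
      mat <- off$haplo[, 2 * o]
      s <- off$sire[o]; d <- off$dam[o]
      expect_true(all(pat == par$haplo[, 2 * s - 1] |
                      pat == par$haplo[, 2 * s]))
      expect_true(all(mat == par$haplo[, 2 * d - 1] |
                      mat == par$haplo[, 2 * d]))
    }
  }
})

test_that("cohort sizes follow dams x litter size and training pool is gens 8-9", {
  fx <- small_sim()
  sizes <- vapply(fx$cohorts, n_individuals, integer(1))
  expect_equal(unname(sizes["gen0"]),
               fx$cfg$recent_males + fx$cfg$recent_females)
  expect_true(all(sizes[paste0("gen", 1:15)] ==
                    fx$cfg$recent_females * fx$cfg$offspring_per_dam))
  expect_equal(n_individuals(fx$train), 2 * 40 * 2)
  expect_setequal(unique(fx$train$generation), c(8, 9))
})

test_that("stored TBV equals an independent haplotype walk", {
  fx <- small_sim()
  co <- fx$cohorts$gen5
  qi <- qtl_loci(fx$spec)
  eff <- fx$spec$qtl_effects$eff
  n <- n_individuals(co)
  tbv <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(qi)) {
      a1 <- co$haplo[qi[k], 2 * i - 1]
      a2 <- co$haplo[qi[k], 2 * i]
      s <- s + eff[[k]][a1] + eff[[k]][a2]
    }
    tbv[i] <- s
  }
  expect_equal(tbv, co$tbv, tolerance = 1e-12)
})

test_that("QTL effect calibration hits the target additive variance", {
  fx <- small_sim()
  # exact by construction in the reference cohort
  tbv_ref <- compute_tbv(fx$hist, fx$spec)
  expect_equal(var(tbv_ref), fx$arch$additive_variance, tolerance = 1e-10)
})

test_that("a genome without QTL gives identically zero TBV", {
  set.seed(3)
  spec <- small_genome(n_markers = 40, n_qtl = 0)
  cfg <- small_config(hist_growth_generations = 0,
                      hist_constant_generations = 2,
                      hist_size = 50, hist_final_males = 10)
  hist <- simulate_historical(spec, cfg)
  spec <- assign_qtl_effects(spec, trait_architecture(), hist)
  expect_equal(compute_tbv(hist, spec), rep(0, n_individuals(hist)))
})

test_that("calibration fails when all QTL are fixed", {
  set.seed(4)
  spec <- small_genome(n_markers = 20, n_qtl = 5)
  cfg <- small_config(hist_growth_generations = 0,
                      hist_constant_generations = 1,
                      hist_size = 50, hist_final_males = 10)
  hist <- simulate_historical(spec, cfg)
  hist$haplo[qtl_loci(spec), ] <- 1L  # monomorphic at every QTL
  expect_error(assign_qtl_effects(spec, trait_architecture(), hist),
               "genetic variance")
})

test_that("phenotypes are TBV plus independent residual noise", {
  set.seed(5)
  arch <- trait_architecture()  # sigma2_e = 0.75
  co <- structure(list(generation = 0L, id = 1:10000,
                       sire = NA, dam = NA,
                       sex = rep(c("M", "F"), 5000),
                       haplo = matrix(0L, 1, 20000),
                       allele_count = 0L,
                       tbv = rnorm(10000, 0, 0.5), phenotype = NULL),
                  class = "cohort")
  co <- generate_phenotypes(co, arch)
  resid <- co$phenotype - co$tbv
  expect_equal(var(resid), 0.75, tolerance = 0.05)
  # additive model: unit regression of phenotype on TBV
  b <- cov(co$phenotype, co$tbv) / var(co$tbv)
  expect_equal(b, 1, tolerance = 0.05)
  # degenerate residual variance: phenotype equals TBV exactly
  arch0 <- trait_architecture(h2 = 0.999999)
  co0 <- generate_phenotypes(co, arch0)
  expect_equal(co0$phenotype, co0$tbv, tolerance = 1e-2)
})

test_that("selection on breeding values beats random mating in mean TBV", {
  set.seed(6)
  diffs <- replicate(6, {
    spec <- small_genome()
    cfg <- small_config(recent_generations = 8)
    arch <- trait_architecture()
    hist <- simulate_historical(spec, cfg)
    spec <- assign_qtl_effects(spec, arch, hist)
    sel <- simulate_recent(hist, spec, arch, cfg, criterion = "phenotype")
    rnd <- simulate_recent(hist, spec, arch, cfg, criterion = "random")
    mean(sel$gen8$tbv) - mean(rnd$gen8$tbv)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 2)
})

test_that("equilibrium heterozygosity matches a single-locus Wright-Fisher oracle", {
  set.seed(7)
  # 50 diploids, one marker locus, mu = 1e-3, 200 generations
  n_rep <- 40
  het_sim <- replicate(n_rep, {
    spec <- genome_spec(n_chromosomes = 1, chrom_length = 1, n_markers = 1,
                        n_qtl = 0, marker_mutation_rate = 1e-3)
    cfg <- sim_config(hist_founder_females = 25, hist_founder_males = 25,
                      hist_growth_generations = 0, hist_size = 50,
                      hist_constant_generations = 200, hist_final_males = 25,
                      recent_males = 2, recent_females = 2)
    hist <- simulate_historical(spec, cfg)
    p <- mean(hist$haplo[1, ])
    2 * p * (1 - p)
  })
  oracle <- wf_het_oracle(n_diploid = 50, mu = 1e-3, n_gen = 200)
  se <- sqrt(oracle[["se"]]^2 + var(het_sim) / n_rep)
  expect_lt(abs(mean(het_sim) - oracle[["mean"]]), 3 * se)
})

test_that("identical seeds reproduce identical populations", {
  run <- function() {
    set.seed(99)
    spec <- small_genome(n_markers = 40, n_qtl = 6)
    cfg <- small_config(hist_constant_generations = 5,
                        recent_generations = 3)
    arch <- trait_architecture()
    hist <- simulate_historical(spec, cfg)
    spec <- assign_qtl_effects(spec, arch, hist)
    simulate_recent(hist, spec, arch, cfg)
  }
  a <- run(); b <- run()
  expect_identical(lapply(a, `[[`, "haplo"), lapply(b, `[[`, "haplo"))
  expect_identical(lapply(a, `[[`, "phenotype"), lapply(b, `[[`, "phenotype"))
})

test_that("too few recent-founder candidates is an error naming the generation", {
  fx <- small_sim()
  cfg_big <- small_config(recent_males = 500)
  expect_error(simulate_recent(fx$hist, fx$spec, fx$arch, cfg_big),
               "fewer animals|fewer candidates")
})
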