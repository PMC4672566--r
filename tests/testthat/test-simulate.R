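test_that("scenario validation and defaults match the study design", {
  scen <- sim_scenario()
  expect_equal(scen$n_segments, 3000L)
  expect_equal(scen$segment_length_bp, 500000L)
  # total simulated length is 1.5 Gb
  expect_equal(as.numeric(scen$n_segments) * scen$segment_length_bp, 1.5e9)
  expect_equal(scen$effective_size, 10000L)
  expect_equal(scen$panel_haplotypes, 200L)
  expect_equal(scen$maf_floor, 0.10)
  expect_error(sim_scenario(maf_floor = 0.6))
  expect_error(sim_scenario(n_segments = 0))
})

test_that("mosaic cohorts satisfy panel invariants, the MAF floor and determinism", {
  co <- make_mosaic_cohort(n_segments = 6L, seed = 11L)
  p <- co$panel
  f <- colMeans(p$haplotypes)
  expect_true(all(pmin(f, 1 - f) >= 0.10))
  expect_equal(length(co$individuals), 2L)
  expect_equal(length(co$individuals[[1]]$h1), n_sites(p))
  expect_true(all(unlist(co$individuals[[1]]) %in% 0:1))
  co2 <- make_mosaic_cohort(n_segments = 6L, seed = 11L)
  expect_identical(co2$panel$haplotypes, p$haplotypes)
  expect_identical(co2$individuals, co$individuals)
  expect_error(simulate_cohort(sim_scenario(n_segments = 2,
                                            split_generations = 100),
                               backend = "mosaic"),
               "msprime")
})

test_that("mosaic linkage disequilibrium decays with distance", {
  co <- make_mosaic_cohort(n_segments = 10L, panel_haplotypes = 60L,
                           seed = 21L)
  p <- co$panel
  h <- p$haplotypes
  s <- p$sites
  r2_at <- function(lo, hi) {
    vals <- c()
    for (ch in unique(s$chrom)) {
      idx <- which(s$chrom == ch)
      pos <- s$pos[idx]
      take <- sample(seq_along(idx), min(40, length(idx)))
      for (a in take) for (b in take) {
        d <- pos[b] - pos[a]
        if (d > lo && d <= hi)
          vals <- c(vals, suppressWarnings(
            cor(h[, idx[a]], h[, idx[b]]))^2)
      }
    }
    mean(vals, na.rm = TRUE)
  }
  withr::with_seed(1, {
    near <- r2_at(0, 5000)
    far <- r2_at(100000, 5e5)
  })
  expect_gt(near, far)
})

test_that("the coalescent bridge produces usable split and single-population cohorts", {
  scen <- sim_scenario(n_segments = 4L, panel_haplotypes = 30L, seed = 3L)
  co <- simulate_cohort(scen, n_individuals = 2L, backend = "msprime")
  p <- co$panel
  expect_equal(n_haplotypes(p), 30L)
  f <- colMeans(p$haplotypes)
  expect_true(all(pmin(f, 1 - f) >= 0.10))
  expect_true(length(unique(p$sites$chrom)) <= 4L)
  # determinism of the bridge given the scenario seed
  co2 <- simulate_cohort(scen, n_individuals = 2L, backend = "msprime")
  expect_identical(co2$panel$haplotypes, p$haplotypes)

  split <- sim_scenario(n_segments = 3L, panel_haplotypes = 20L,
                        split_generations = 1000L, seed = 5L)
  cos <- simulate_cohort(split, n_individuals = 1L, backend = "msprime")
  expect_equal(n_haplotypes(cos$panel), 20L)
  expect_equal(cos$provenance$focal_population, "population-1")
})

test_that("mating preserves Mendelian consistency and degenerates without recombination", {
  co <- make_mosaic_cohort(n_segments = 5L, seed = 31L)
  p <- co$panel
  A <- co$individuals[[1]]; B <- co$individuals[[2]]
  child <- mate(A, B, p, recombination_rate = 1e-8, seed = 8L)
  expect_true(all(child$h1 == A$h1 | child$h1 == A$h2))
  expect_true(all(child$h2 == B$h1 | child$h2 == B$h2))
  # zero recombination: each gamete is one unmodified parental haplotype
  # per segment
  child0 <- mate(A, B, p, recombination_rate = 0, seed = 9L)
  for (ch in unique(p$sites$chrom)) {
    idx <- p$sites$chrom == ch
    expect_true(identical(child0$h1[idx], A$h1[idx]) ||
                  identical(child0$h1[idx], A$h2[idx]))
  }
  expect_error(mate(list(h1 = 0L, h2 = 1L), B, p), "sites")
})

test_that("observation sampling applies the double-draw discard rule", {
  co <- make_mosaic_cohort(n_segments = 40L, panel_haplotypes = 18L,
                           seed = 51L, n_individuals = 1L)
  p <- co$panel
  ind <- co$individuals[[1]]
  ns <- n_sites(p)
  expect_gt(ns, 10000)
  obs <- sample_observations(ind, p, rate = 0.01, seed = 1L, "s")
  # P(observe a site) = 2 * 0.01 * 0.99; binomial +/- 4 sd band
  expected <- 2 * 0.01 * 0.99
  tol <- 4 * sqrt(expected * (1 - expected) / ns)
  expect_lt(abs(length(obs) / ns - expected), tol)
  # emitted alleles are the drawn copy's alleles
  het <- which(ind$h1 != ind$h2)
  on_het <- obs$site_index %in% het
  expect_true(all(obs$allele_code[on_het] %in% 0:1))
  hom <- obs$site_index[!on_het]
  expect_identical(obs$allele_code[!on_het], ind$h1[hom])
  # determinism and independence across seeds
  expect_identical(sample_observations(ind, p, 0.01, 1L, "s")$site_index,
                   obs$site_index)
  obs2 <- sample_observations(ind, p, 0.01, 2L, "s")
  expect_false(identical(obs2$site_index, obs$site_index))
  # rate near 1: nearly everything is a double draw and gets discarded
  dense <- sample_observations(ind, p, 0.999, 3L, "s")
  expect_lt(length(dense) / ns, 0.02)
  expect_error(sample_observations(ind, p, 0, 1L), "rate")
})

test_that("replicated study table reproduces the five-panel comparison layout", {
  scen <- sim_scenario(n_segments = 10L, panel_haplotypes = 40L, seed = 71L)
  tab <- run_replicates(scen, n_replicates = 2L, observation_rate = 0.03,
                        config = pairing_config(window_size_bp = 5e5,
                                                n_bootstrap = 15L),
                        backend = "mosaic")
  expect_setequal(unique(tab$comparison),
                  c("within_A1", "within_A2", "within_B1",
                    "same_individual", "different_individuals",
                    "parent_child"))
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$verdict %in% c("SAME", "DIFFERENT", "INCONCLUSIVE")))
  tab2 <- run_replicates(scen, n_replicates = 2L, observation_rate = 0.03,
                         config = pairing_config(window_size_bp = 5e5,
                                                 n_bootstrap = 15L),
                         backend = "mosaic")
  expect_identical(tab, tab2)
})

test_that("simulated pairs respect the gamma lower bound end to end", {
  co <- make_mosaic_cohort(n_segments = 8L, seed = 91L)
  p <- co$panel
  o1 <- sample_observations(co$individuals[[1]], p, 0.04, 1L, "a")
  o2 <- sample_observations(co$individuals[[2]], p, 0.04, 2L, "b")
  pairs <- enumerate_pairs(o1, o2, p, pairing_config())
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$llr >= -1 - 1e-12))
  expect_true(all(pairs$distance_bp >= 1000 & pairs$distance_bp <= 50000))
})
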