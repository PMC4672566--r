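# Panel used by several aggregation tests: three window-separated site
# pairs on one pseudo-chromosome, engineered so the pair in window 1 is in
# perfect LD, window 2 likewise (observed discordantly), window 3 in
# equilibrium. gamma values are then log2(1.5), -1 and 0 exactly.
make_three_window_panel <- function() {
  cols <- list(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L),    # window 1
               c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L),    # window 2
               c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))    # window 3
  make_panel(cols, pos = c(100000L, 110000L,
                           600000L, 610000L,
                           1100000L, 1110000L))
}

test_that("pairing config enforces distance and window ordering", {
  expect_s3_class(pairing_config(), "pairing_config")
  expect_error(pairing_config(min_distance_bp = 0))
  expect_error(pairing_config(min_distance_bp = 6e4, max_distance_bp = 5e4))
  expect_error(pairing_config(max_distance_bp = 6e5, window_size_bp = 5e5))
})

test_that("pair enumeration respects distance bounds, windows and panel identity", {
  panel <- make_random_panel(10, 5, seed = 1)
  # sites at 1000, 11000, 21000, 31000, 41000
  o1 <- obs_set("s1", c(1L, 3L), c(0L, 1L), panel)
  o2 <- obs_set("s2", c(1L, 2L, 5L), c(1L, 0L, 1L), panel)
  cfg <- pairing_config(min_distance_bp = 1000, max_distance_bp = 30000)
  pairs <- enumerate_pairs(o1, o2, panel, cfg)
  # same-site pair (1,1) excluded by the minimum distance; (3,5) spans
  # 20 kb and qualifies; (1,5) spans 40 kb > max
  expect_setequal(paste(pairs$site_i, pairs$site_j),
                  c("1 2", "3 1", "3 2", "3 5"))
  expect_true(all(pairs$distance_bp >= 1000 & pairs$distance_bp <= 30000))
  expect_true(all(pairs$window_start == 1L))

  other <- make_random_panel(10, 5, seed = 2)
  o3 <- obs_set("s3", 1L, 0L, other)
  expect_error(enumerate_pairs(o1, o3, panel, cfg), "panel mismatch")
})

test_that("a 60 kb pair is out of range and a 5 kb pair qualifies with distance 5000", {
  panel <- make_panel(list(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L),
                           c(0L, 0L, 1L, 1L)),
                      pos = c(10000L, 15000L, 75000L))
  o1 <- obs_set("a", 1L, 0L, panel)
  o2 <- obs_set("b", c(2L, 3L), c(0L, 1L), panel)
  pairs <- enumerate_pairs(o1, o2, panel, pairing_config())
  expect_equal(nrow(pairs), 1L)      # 65 kb pair rejected
  expect_equal(pairs$distance_bp, 5000L)
  expect_equal(pairs$site_j, 2L)
})

test_that("within-sample mode enumerates unordered pairs once and skips non-autosomes", {
  panel <- make_random_panel(10, 4, seed = 5)
  obs <- obs_set("s", c(1L, 2L, 3L), c(0L, 1L, 0L), panel)
  pairs <- enumerate_pairs(obs, obs, panel, pairing_config())
  expect_true(all(pairs$site_i < pairs$site_j))
  expect_equal(nrow(pairs), 3L)      # (1,2) (1,3) (2,3) all within 50 kb

  xpanel <- make_random_panel(10, 4, seed = 6, chrom = "chrX")
  xobs <- obs_set("s", c(1L, 2L), c(0L, 1L), xpanel)
  expect_equal(nrow(enumerate_pairs(xobs, xobs, xpanel, pairing_config())),
               0L)
  keepx <- pairing_config(autosomes_only = FALSE)
  expect_equal(nrow(enumerate_pairs(xobs, xobs, xpanel, keepx)), 1L)
})

test_that("pair enumeration is symmetric in sample order", {
  co <- make_mosaic_cohort()
  p <- co$panel
  oA <- sample_observations(co$individuals[[1]], p, 0.03, 1, "A")
  oB <- sample_observations(co$individuals[[2]], p, 0.03, 2, "B")
  cfg <- pairing_config(seed = 4)
  ab <- enumerate_pairs(oA, oB, p, cfg)
  ba <- enumerate_pairs(oB, oA, p, cfg)
  key <- function(d) sort(paste(pmin(d$site_i, d$site_j),
                                pmax(d$site_i, d$site_j), round(d$llr, 9)))
  expect_identical(key(ab), key(ba))
})

test_that("single-candidate windows sum exactly and degenerate inputs behave", {
  panel <- make_three_window_panel()
  o1 <- obs_set("a", c(1L, 3L, 5L), c(0L, 0L, 0L), panel)
  o2 <- obs_set("b", c(2L, 4L, 6L), c(0L, 1L, 0L), panel)
  cfg <- pairing_config(n_bootstrap = 25, seed = 11)
  pairs <- enumerate_pairs(o1, o2, panel, cfg)
  expect_equal(nrow(pairs), 3L)
  expect_equal(sort(pairs$window_start), c(1L, 500001L, 1000001L))
  res <- aggregate_llr(pairs, cfg)
  # gamma = {log2(1.5), -1, 0}: no sampling variance with one candidate
  # per window, every replicate Lambda = log2(1.5) - 1
  expect_equal(res$n_windows_used, 3L)
  expect_true(all(abs(res$bootstrap_llrs - (log2(1.5) - 1)) < 1e-12))
  expect_equal(res$sd_llr, 0)
  expect_equal(res$verdict, "DIFFERENT")

  # all-zero gammas: inconclusive
  oz1 <- obs_set("z1", 5L, 0L, panel)
  oz2 <- obs_set("z2", 6L, 0L, panel)
  zres <- compare_samples(oz1, oz2, panel, cfg)
  expect_equal(zres$mean_llr, 0)
  expect_equal(zres$verdict, "INCONCLUSIVE")

  # no eligible windows at all: explicit low-coverage diagnostic
  expect_error(compare_samples(oz1, NULL, panel, cfg),
               "too few linked observation pairs")
})

test_that("bootstrap is deterministic given the seed and Lambda is additive", {
  co <- make_mosaic_cohort()
  p <- co$panel
  oA <- sample_observations(co$individuals[[1]], p, 0.05, 3, "A")
  oB <- sample_observations(co$individuals[[1]], p, 0.05, 4, "B")
  cfg <- pairing_config(n_bootstrap = 40, seed = 99)
  r1 <- compare_samples(oA, oB, p, cfg)
  r2 <- compare_samples(oA, oB, p, cfg)
  expect_identical(r1$bootstrap_llrs, r2$bootstrap_llrs)
  expect_identical(r1$verdict, r2$verdict)

  pairs <- enumerate_pairs(oA, oB, p, cfg)
  # every pair maps to exactly one window tile and the window count is
  # bounded by the genome tiling
  wid <- paste(pairs$chrom, pairs$window_start)
  expect_true(all((pairs$window_start - 1L) %% cfg$window_size_bp == 0))
  expect_lte(r1$n_windows_used, ceiling(3.1e9 / 5e5))
  expect_lte(r1$n_windows_used, length(unique(wid)))
  # additivity: min/max of the bootstrap distribution are bounded by the
  # per-window extremes summed
  lo <- sum(tapply(pairs$llr, wid, min))
  hi <- sum(tapply(pairs$llr, wid, max))
  expect_true(all(r1$bootstrap_llrs >= lo - 1e-9 &
                    r1$bootstrap_llrs <= hi + 1e-9))
})

test_that("more observations give a larger aggregated llr on average", {
  co <- simulate_cohort(sim_scenario(n_segments = 40L,
                                     panel_haplotypes = 100L, seed = 77L),
                        n_individuals = 1L, backend = "msprime")
  p <- co$panel
  mean_llr_at <- function(rate) {
    vals <- vapply(1:8, function(r) {
      o1 <- sample_observations(co$individuals[[1]], p, rate, 1000 + r, "x")
      o2 <- sample_observations(co$individuals[[1]], p, rate, 2000 + r, "y")
      compare_samples(o1, o2, p,
                      pairing_config(n_bootstrap = 30, seed = r))$mean_llr
    }, numeric(1))
    mean(vals)
  }
  sparse <- mean_llr_at(0.01)
  mid <- mean_llr_at(0.02)
  dense <- mean_llr_at(0.05)
  # same-individual signal grows with observation density (generous slack:
  # monotone in expectation, noisy per cohort)
  expect_gt(mid, sparse * 0.7)
  expect_gt(dense, mid * 0.7)
  expect_gt(dense, sparse)
})

test_that("all-vs-all over n samples yields n(n+1)/2 rows incl. self-comparisons", {
  co <- make_mosaic_cohort(n_segments = 8L, seed = 5L)
  p <- co$panel
  obs_list <- lapply(1:4, function(i)
    sample_observations(co$individuals[[1 + i %% 2]], p, 0.05, i,
                        paste0("s", i)))
  cfg <- pairing_config(n_bootstrap = 10, seed = 2)
  rep <- compare_all_vs_all(obs_list, p, cfg)
  expect_equal(nrow(rep), 4 * 5 / 2)
  expect_equal(sum(rep$sample1 == rep$sample2), 4L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 10L)
  expect_true(all(c("mean_llr", "verdict") %in% names(tab)))
})
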