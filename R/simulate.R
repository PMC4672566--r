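# Synthetic-data generator: haplotype panels with realistic LD, diploid
# individuals from the same or a diverged population, relatives, and sparse
# allele observations. Simulated segments are emitted as independent
# pseudo-chromosomes (named "1", "2", ...) so inter-segment pairs never form
# and each segment is one aggregation window.

#' Simulation scenario
#'
#' Defaults describe the reference simulation study design: 3000 independent
#' 500-kb segments (1.5 Gb total) from a constant-size population of
#' Ne = 10,000, a 200-haplotype reference panel filtered at MAF >= 10%, and
#' human-typical mutation (1.25e-8) and recombination (1e-8) rates per bp
#' per generation. `split_generations > 0` instead draws the sampled
#' individuals and the panel from the two sides of a symmetric population
#' split that long ago (no migration), emulating an imperfectly matched
#' reference population.
#'
#' @param n_segments number of independent segments (default 3000).
#' @param segment_length_bp segment length (default 5e5).
#' @param effective_size diploid effective population size (default 1e4).
#' @param mutation_rate,recombination_rate per-bp per-generation rates.
#' @param panel_haplotypes panel rows to draw (default 200).
#' @param maf_floor minimum minor allele frequency among panel rows for a
#'   site to be kept (default 0.10).
#' @param split_generations generations since the focal/panel population
#'   split; 0 = single population (default).
#' @param seed integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_segments = 3000L, segment_length_bp = 500000L,
                         effective_size = 10000L, mutation_rate = 1.25e-8,
                         recombination_rate = 1e-8,
                         panel_haplotypes = 200L, maf_floor = 0.10,
                         split_generations = 0L, seed = 1L) {
  stopifnot(n_segments >= 1, segment_length_bp >= 1000,
            maf_floor >= 0, maf_floor < 0.5, panel_haplotypes >= 2,
            split_generations >= 0)
  structure(list(n_segments = as.integer(n_segments),
                 segment_length_bp = as.integer(segment_length_bp),
                 effective_size = as.integer(effective_size),
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 panel_haplotypes = as.integer(panel_haplotypes),
                 maf_floor = maf_floor,
                 split_generations = as.integer(split_generations),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

find_python <- function() {
  py <- Sys.getenv("LDIDENT_PYTHON", "")
  if (nzchar(py)) return(py)
  p3 <- unname(Sys.which("python3"))
  if (nzchar(p3)) return(p3)
  unname(Sys.which("python"))
}

has_msprime <- function() {
  py <- find_python()
  if (!nzchar(py)) return(FALSE)
  code <- suppressWarnings(system2(py, c("-c", shQuote("import msprime")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}

# Parse the ms-style segment file written by inst/python/coalsim.py into a
# list of list(pos = integer positions, hap = haplotype x site matrix).
parse_segments <- function(file) {
  lines <- readLines(file)
  starts <- grep("^//", lines)
  lapply(seq_along(starts), function(k) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    pos_line <- sub("^positions: ?", "", lines[from + 1L])
    pos <- if (nzchar(pos_line)) as.integer(strsplit(pos_line, " ")[[1]])
           else integer(0)
    hap_lines <- lines[seq(from + 2L, to)]
    hap_lines <- hap_lines[nzchar(hap_lines)]
    if (!length(pos))
      return(list(pos = integer(0),
                  hap = matrix(integer(0), nrow = length(hap_lines))))
    hap <- matrix(as.integer(unlist(strsplit(hap_lines, "", fixed = TRUE))),
                  nrow = length(hap_lines), byrow = TRUE)
    list(pos = pos, hap = hap)
  })
}

# msprime backend: one subprocess simulates all segments of a cohort.
simulate_segments_msprime <- function(scenario, n_focal) {
  py <- find_python()
  if (!nzchar(py)) stop("no python interpreter found for the msprime backend")
  script <- system.file("python", "coalsim.py", package = "ldident",
                        mustWork = TRUE)
  out <- tempfile(fileext = ".segs")
  on.exit(unlink(out))
  args <- c(script, "--out", out, "--seed", scenario$seed,
            "--segments", scenario$n_segments,
            "--length", scenario$segment_length_bp,
            "--ne", scenario$effective_size,
            "--mu", scenario$mutation_rate,
            "--recomb", scenario$recombination_rate,
            "--focal", n_focal, "--panel", scenario$panel_haplotypes,
            "--split-generations", scenario$split_generations,
            "--maf-floor", scenario$maf_floor)
  code <- system2(py, args, stdout = FALSE, stderr = "")
  if (!identical(code, 0L)) stop("coalescent backend failed (exit ", code, ")")
  parse_segments(out)
}

# Mosaic fallback backend: haplotypes are recombinant mosaics of a small set
# of founder haplotypes, switching founders along the segment at a
# population-scaled rate (a Li-Stephens-flavoured copying model). Produces
# allele-frequency variation and LD that decays with distance without an
# external coalescent engine. Single population only.
simulate_segments_mosaic <- function(scenario, n_focal, n_founders = 12L,
                                     site_density = 8e-4) {
  if (scenario$split_generations > 0)
    stop("the mosaic backend supports split_generations = 0 only; ",
         "use backend = 'msprime' for split scenarios")
  n_hap <- n_focal + scenario$panel_haplotypes
  L <- scenario$segment_length_bp
  jump_rate <- 4 * scenario$effective_size * scenario$recombination_rate /
    n_founders
  withr::with_seed(scenario$seed, lapply(seq_len(scenario$n_segments),
                                         function(seg) {
    n_sites <- max(2L, rpois(1, site_density * L))
    pos <- sort(sample.int(L, n_sites))
    p <- runif(n_sites, 0.05, 0.95)
    founders <- matrix(rbinom(n_founders * n_sites, 1L, rep(p, each = n_founders)),
                       nrow = n_founders)
    gap <- diff(pos)
    switch_p <- 1 - exp(-jump_rate * gap)
    hap <- matrix(0L, nrow = n_hap, ncol = n_sites)
    for (h in seq_len(n_hap)) {
      f <- integer(n_sites)
      f[1] <- sample.int(n_founders, 1)
      sw <- runif(n_sites - 1) < switch_p
      for (s in seq_len(n_sites - 1L))
        f[s + 1L] <- if (sw[s]) sample.int(n_founders, 1) else f[s]
      hap[h, ] <- founders[cbind(f, seq_len(n_sites))]
    }
    pf <- colMeans(hap[(n_focal + 1L):n_hap, , drop = FALSE])
    keep <- pmin(pf, 1 - pf) >= scenario$maf_floor
    list(pos = pos[keep], hap = hap[, keep, drop = FALSE])
  }))
}

#' Simulate a cohort: reference panel plus diploid individuals
#'
#' Simulates `n_segments` independent segments under the scenario's
#' demographic model, filters sites below the panel MAF floor, and
#' partitions the simulated haplotypes — without overlap — into
#' `2 * n_individuals` focal haplotypes (pairs forming the diploid
#' individuals) and `panel_haplotypes` panel rows. Under a split scenario
#' the focal haplotypes come from population 1 and the panel from
#' population 2. Segments become pseudo-chromosomes named "1", "2", ....
#'
#' @param scenario a [sim_scenario()].
#' @param n_individuals diploid individuals to draw (default 2).
#' @param backend `"msprime"` (coalescent with recombination via the bundled
#'   Python bridge; default when available) or `"mosaic"` (pure-R founder
#'   copying approximation, single population only).
#' @return A `sim_cohort`: `panel` (a `ref_panel`), `individuals` (list of
#'   `list(h1, h2)` allele vectors over panel sites), `provenance`.
#' @export
simulate_cohort <- function(scenario, n_individuals = 2L,
                            backend = c("msprime", "mosaic")) {
  backend <- match.arg(backend)
  n_focal <- 2L * n_individuals
  segs <- switch(backend,
                 msprime = simulate_segments_msprime(scenario, n_focal),
                 mosaic = simulate_segments_mosaic(scenario, n_focal))
  # zero-padded pseudo-chromosome names keep lexicographic == numeric order
  chrom_name <- sprintf(paste0("%0", nchar(length(segs)), "d"),
                        seq_along(segs))
  nonempty <- which(vapply(segs, function(sg) length(sg$pos) > 0L,
                           logical(1)))
  if (!length(nonempty))
    stop("simulation produced too few sites; increase segment count/length")
  sites <- do.call(rbind, lapply(nonempty, function(k) {
    data.frame(chrom = chrom_name[k], pos = segs[[k]]$pos,
               stringsAsFactors = FALSE)
  }))
  if (nrow(sites) < 2L)
    stop("simulation produced too few sites; increase segment count/length")
  hap_all <- do.call(cbind, lapply(segs[nonempty], function(sg) sg$hap))
  # arbitrary but fixed transversion alleles; simulated data carries no
  # sequence context
  sites$ref <- "A"; sites$alt <- "C"; sites$id <- NA_character_
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  hap_all <- hap_all[, ord, drop = FALSE]
  panel_rows <- (n_focal + 1L):nrow(hap_all)
  # guaranteed by the MAF floor when panel_haplotypes * maf_floor >= 1
  mac_floor <- max(1L, as.integer(floor(scenario$panel_haplotypes *
                                          scenario$maf_floor)))
  panel <- ref_panel(sites, hap_all[panel_rows, , drop = FALSE],
                     population = if (scenario$split_generations > 0)
                       "panel-split" else "panel-same",
                     min_minor_count = mac_floor)
  individuals <- lapply(seq_len(n_individuals), function(i) {
    list(h1 = hap_all[2L * i - 1L, ], h2 = hap_all[2L * i, ])
  })
  structure(list(panel = panel, individuals = individuals,
                 provenance = list(scenario = scenario, backend = backend,
                                   focal_population =
                                     if (scenario$split_generations > 0)
                                       "population-1" else "single")),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", length(x$individuals), "diploid individual(s), panel of",
      n_haplotypes(x$panel), "haplotypes x", n_sites(x$panel), "sites over",
      x$provenance$scenario$n_segments, "segment(s); backend",
      x$provenance$backend, "\n")
  invisible(x)
}

#' Mate two diploid individuals
#'
#' Produces a child: one recombinant gamete from each parent, with
#' per-segment Poisson crossovers at `recombination_rate` placed uniformly.
#' Every child allele is carried by the contributing parent at that site
#' (Mendelian consistency).
#'
#' @param parent1,parent2 individuals from a [simulate_cohort()] (lists with
#'   `h1`, `h2` allele vectors over the panel's sites).
#' @param panel the cohort's `ref_panel` (supplies site coordinates).
#' @param recombination_rate per-bp per-generation crossover rate.
#' @param seed integer seed.
#' @return A diploid individual `list(h1, h2)` defined on the same sites.
#' @export
mate <- function(parent1, parent2, panel, recombination_rate = 1e-8,
                 seed = 1L) {
  if (length(parent1$h1) != n_sites(panel) ||
      length(parent2$h1) != n_sites(panel))
    stop("parents are not defined on this panel's sites")
  s <- panel$sites
  gamete <- function(parent) {
    out <- integer(n_sites(panel))
    for (ch in unique(s$chrom)) {
      idx <- which(s$chrom == ch)
      pos <- s$pos[idx]
      L <- max(pos)
      k <- rpois(1, recombination_rate * L)
      breaks <- sort(runif(k, 0, L))
      phase <- (findInterval(pos, breaks) + sample(0:1, 1)) %% 2L
      out[idx] <- ifelse(phase == 0L, parent$h1[idx], parent$h2[idx])
    }
    out
  }
  withr::with_seed(as.integer(seed),
                   list(h1 = gamete(parent1), h2 = gamete(parent2)))
}

#' Sample sparse allele observations from a diploid individual
#'
#' Each of the two chromosome copies is drawn independently at every panel
#' site with probability `rate`; sites where both copies are drawn are
#' discarded (on real data a double observation cannot be attributed to a
#' chromosome), so a site yields an observation with probability
#' `2 * rate * (1 - rate)` — about 0.0198, i.e. ~0.02-fold coverage, at the
#' default rate of 0.01.
#'
#' @param individual a diploid `list(h1, h2)` over the panel's sites.
#' @param panel the cohort's `ref_panel`.
#' @param rate per-copy draw probability in (0, 1) (default 0.01).
#' @param seed integer seed; different seeds give independent observation
#'   sets from the same individual.
#' @param sample_id identifier for the resulting set.
#' @return An `obs_set`.
#' @export
sample_observations <- function(individual, panel, rate = 0.01, seed = 1L,
                                sample_id = "sim") {
  if (!(rate > 0 && rate < 1)) stop("rate must be in (0, 1)")
  ns <- n_sites(panel)
  withr::with_seed(as.integer(seed), {
    d1 <- runif(ns) < rate
    d2 <- runif(ns) < rate
  })
  keep <- xor(d1, d2)
  allele <- ifelse(d1[keep], individual$h1[keep], individual$h2[keep])
  obs_set(sample_id, which(keep), allele, panel)
}

#' Replicated simulation study of the identity test
#'
#' Per replicate: simulate a cohort of two individuals (A, B), optionally a
#' child C of A and B, draw observation sets, and run the standard
#' comparison layout — within-sample for each library, across-sets for the
#' same individual, across individuals, and (optionally) parent-child.
#' Returns a tidy table for plotting and power summaries.
#'
#' @param scenario a [sim_scenario()]; replicate `r` uses `seed + r`.
#' @param n_replicates number of independent replicates.
#' @param observation_rate per-copy observation rate (default 0.01).
#' @param config a [pairing_config()] (its `window_size_bp` should match the
#'   scenario's segment length so each segment is one window).
#' @param backend simulation backend, see [simulate_cohort()].
#' @param relatives also simulate a parent-child comparison (default TRUE).
#' @return data.frame: `replicate`, `comparison`, `n_windows_used`,
#'   `mean_llr`, `ci_low`, `ci_high`, `verdict`.
#' @export
run_replicates <- function(scenario, n_replicates = 20L,
                           observation_rate = 0.01,
                           config = pairing_config(
                             window_size_bp = scenario$segment_length_bp,
                             n_bootstrap = 50L),
                           backend = c("msprime", "mosaic"),
                           relatives = TRUE) {
  backend <- match.arg(backend)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    scen_r <- scenario
    scen_r$seed <- scenario$seed + r
    cohort <- simulate_cohort(scen_r, n_individuals = 2L, backend = backend)
    pan <- cohort$panel
    A <- cohort$individuals[[1]]; B <- cohort$individuals[[2]]
    sseed <- (scen_r$seed %% 2147483L) * 13L
    oA1 <- sample_observations(A, pan, observation_rate, sseed + 1L, "A1")
    oA2 <- sample_observations(A, pan, observation_rate, sseed + 2L, "A2")
    oB1 <- sample_observations(B, pan, observation_rate, sseed + 3L, "B1")
    cfg <- config; cfg$seed <- scen_r$seed
    comps <- list(within_A1 = list(oA1, NULL), within_A2 = list(oA2, NULL),
                  within_B1 = list(oB1, NULL),
                  same_individual = list(oA1, oA2),
                  different_individuals = list(oA1, oB1))
    if (relatives) {
      C <- mate(A, B, pan, scenario$recombination_rate, seed = sseed + 7L)
      oC1 <- sample_observations(C, pan, observation_rate, sseed + 4L, "C1")
      comps$parent_child <- list(oA1, oC1)
    }
    for (nm in names(comps)) {
      res <- compare_samples(comps[[nm]][[1]], comps[[nm]][[2]], pan, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, comparison = nm,
        n_windows_used = res$n_windows_used, mean_llr = res$mean_llr,
        ci_low = res$ci_low, ci_high = res$ci_high,
        verdict = res$verdict, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
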