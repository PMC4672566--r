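# Fixtures are built in code at test time; nothing binary is stored.

# Small panel with hand-chosen columns, built through the public constructor.
make_panel <- function(columns, pos = NULL, chrom = "1",
                       ref = "A", alt = "C", min_minor_count = 1L) {
  hap <- do.call(cbind, columns)
  storage.mode(hap) <- "integer"
  ns <- ncol(hap)
  if (is.null(pos)) pos <- seq(1000L, by = 10000L, length.out = ns)
  ref_panel(data.frame(chrom = chrom, pos = as.integer(pos),
                       ref = rep_len(ref, ns), alt = rep_len(alt, ns),
                       stringsAsFactors = FALSE),
            hap, population = "toy", min_minor_count = min_minor_count)
}

# Random polymorphic panel for property tests (monomorphic columns repaired
# by flipping one entry).
make_random_panel <- function(n_hap, n_sites, seed, chrom = "1") {
  withr::with_seed(seed, {
    hap <- matrix(rbinom(n_hap * n_sites, 1L, runif(n_sites, 0.2, 0.8)),
                  nrow = n_hap, byrow = TRUE)
    for (s in seq_len(n_sites)) {
      if (sum(hap[, s]) == 0L) hap[sample.int(n_hap, 1), s] <- 1L
      if (sum(hap[, s]) == n_hap) hap[sample.int(n_hap, 1), s] <- 0L
    }
    make_panel(lapply(seq_len(n_sites), function(s) hap[, s]), chrom = chrom)
  })
}

# Toy phased VCF: 4 samples, 3 clean biallelic SNPs, plus one indel, one
# multi-allelic record and one unphased record that must be filtered out.
# The clean genotype columns are hand-transcribable (see test-panel.R).
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3\tS4",
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0|1\t0|0\t1|1\t0|1",
    "1\t200\trs2\tG\tT\t.\tPASS\t.\tGT\t0|0\t0|1\t0|0\t0|0",
    "1\t250\trsIndel\tGA\tG\t.\tPASS\t.\tGT\t0|1\t0|0\t0|0\t0|0",
    "1\t300\trsMulti\tA\tC,T\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0\t0|0",
    "1\t400\trs3\tC\tG\t.\tPASS\t.\tGT\t1|0\t1|1\t0|0\t0|1",
    "1\t500\trsUnph\tA\tT\t.\tPASS\t.\tGT\t0/1\t0|0\t0|0\t0|1",
    "1\t600\trsMono\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|0\t0|0\t0|0")
  writeLines(lines, path)
  path
}

# Hand transcription of the toy VCF's clean records, rows in sample order
# with haplotype 0 then 1 per sample (S1.0, S1.1, S2.0, ...).
toy_vcf_hap_matrix <- function() {
  matrix(as.integer(c(
    # rs1    rs2    rs3
    0, 0, 1,
    1, 0, 0,
    0, 0, 1,
    0, 1, 1,
    1, 0, 0,
    1, 0, 0,
    0, 0, 0,
    1, 0, 1)), nrow = 8, byrow = TRUE)
}

# VCF with 100 samples (200 haplotypes) holding one site with alt count 9
# and one with alt count 10, for the minor-allele-count floor.
write_mac_vcf <- function(path) {
  gt_row <- function(n_alt) {
    g <- rep("0|0", 100)
    # distribute n_alt alt alleles one per haplotype
    full <- n_alt %/% 2L
    if (full > 0) g[seq_len(full)] <- "1|1"
    if (n_alt %% 2L == 1L) g[full + 1L] <- "0|1"
    paste(g, collapse = "\t")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:100)), collapse = "\t"),
    paste("1\t1000\tmac9\tA\tC\t.\tPASS\t.\tGT", gt_row(9L), sep = "\t"),
    paste("1\t2000\tmac10\tA\tC\t.\tPASS\t.\tGT", gt_row(10L), sep = "\t"))
  writeLines(lines, path)
  path
}

# Panel matching the engineered BAM fixture: five sites on contig "1".
make_bam_panel <- function() {
  ref_panel(
    data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
               ref = c("A", "C", "G", "A", "A"),
               alt = c("C", "T", "T", "T", "G"),
               stringsAsFactors = FALSE),
    matrix(c(0L, 1L, 0L, 1L,
             0L, 1L, 1L, 0L,
             0L, 0L, 1L, 1L,
             1L, 0L, 0L, 1L,
             0L, 1L, 0L, 1L), nrow = 4),
    population = "toy", min_minor_count = 1L)
}

# Engineered BAM exercising every observation filter branch:
#   site 100 (A/C, transversion): one clean read, base C      -> emit alt
#   site 200 (C/T, transition):   one clean read, base T      -> emit alt,
#                                 unless transversions-only
#   site 300 (G/T): two passing reads                         -> omitted
#   site 400 (A/T): one read, base G (neither allele)         -> discarded
#   site 500 (A/G): one low-MAPQ read + one low-BQ read       -> no pileup
make_test_bam <- function(dir = withr::local_tempdir(.local_envir =
                                                       parent.frame())) {
  q_hi <- strrep("I", 10)                       # Q40
  rd <- function(name, pos, seq, mapq = 60L, qual = q_hi) {
    paste(name, 0L, "1", pos, mapq, "10M", "*", 0L, 0L, seq, qual,
          sep = "\t")
  }
  q_low_at6 <- paste0(strrep("I", 5), "&", strrep("I", 4))  # Q5 at offset 6
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:1\tLN:1000",
    rd("r100", 95L, "AAAAACAAAA"),              # base C at pos 100
    rd("r200", 195L, "CCCCCTCCCC"),             # base T at pos 200
    rd("r300a", 295L, "GGGGGTGGGG"),
    rd("r300b", 296L, "GGGGTGGGGG"),            # second passing read
    rd("r400", 395L, "AAAAAGAAAA"),             # G matches neither A/T
    rd("r500a", 495L, "AAAAAGAAAA", mapq = 10L),
    rd("r500b", 495L, "AAAAAGAAAA", qual = q_low_at6))
  sam_file <- file.path(dir, "toy.sam")
  writeLines(sam, sam_file)
  bam <- Rsamtools::asBam(sam_file, file.path(dir, "toy"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

# Tiny simulated cohort shared by aggregate/simulate tests (pure R backend).
make_mosaic_cohort <- function(n_segments = 12L, panel_haplotypes = 40L,
                               seed = 42L, n_individuals = 2L) {
  simulate_cohort(
    sim_scenario(n_segments = n_segments, panel_haplotypes = panel_haplotypes,
                 seed = seed),
    n_individuals = n_individuals, backend = "mosaic")
}
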