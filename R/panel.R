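#' @importFrom stats rbinom rpois runif quantile sd setNames
#' @importFrom utils read.table write.table packageVersion
NULL

PANEL_FORMAT_VERSION <- "ldident_panel_v1"

#' Construct a reference panel object
#'
#' Low-level constructor for a phased reference haplotype panel: an ordered
#' table of biallelic SNP sites plus a 0/1 haplotype matrix (rows =
#' haplotypes, columns = sites; 0 = reference allele, 1 = alternate allele).
#' Most users should build panels from a VCF with [build_panel()] or simulate
#' one with [simulate_cohort()]; this constructor validates the invariants
#' that the likelihood model relies on (every site polymorphic, minor allele
#' count at or above the configured floor).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases), and optionally `id`. Must be sorted by
#'   (chrom, pos) with strictly increasing positions within a chromosome.
#' @param haplotypes integer matrix of 0/1 allele codes, one row per
#'   haplotype, one column per site.
#' @param population population label stored with the panel.
#' @param min_minor_count the minor-allele-count floor the panel was filtered
#'   at (recorded as metadata and validated).
#' @return An object of class `ref_panel`.
#' @export
ref_panel <- function(sites, haplotypes, population = "unknown",
                      min_minor_count = 1L) {
  stopifnot(is.data.frame(sites), is.matrix(haplotypes))
  if (is.null(sites$id)) sites$id <- NA_character_
  sites <- sites[, c("chrom", "pos", "ref", "alt", "id")]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  storage.mode(haplotypes) <- "integer"
  if (ncol(haplotypes) != nrow(sites))
    stop("haplotype matrix has ", ncol(haplotypes), " columns but ",
         nrow(sites), " sites")
  if (nrow(haplotypes) < 2L) stop("a panel needs at least 2 haplotypes")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
    stop("ref/alt must be single bases A/C/G/T")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  if (any(unlist(tapply(sites$pos, sites$chrom, function(p) diff(p) <= 0L))))
    stop("positions must be strictly increasing within a chromosome")
  if (!all(haplotypes %in% c(0L, 1L))) stop("haplotype codes must be 0/1")
  alt_counts <- colSums(haplotypes)
  mac <- pmin(alt_counts, nrow(haplotypes) - alt_counts)
  if (any(mac == 0L)) stop("every panel site must be polymorphic")
  if (any(mac < min_minor_count))
    stop("site(s) violate the minor allele count floor of ", min_minor_count)
  rownames(sites) <- NULL
  obj <- structure(
    list(sites = sites, haplotypes = haplotypes,
         population = as.character(population),
         min_minor_count = as.integer(min_minor_count),
         fingerprint = NA_character_),
    class = "ref_panel")
  obj$fingerprint <- panel_fingerprint(obj)
  obj
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel> population:", x$population, "\n")
  cat("  ", nrow(x$haplotypes), "haplotypes x", nrow(x$sites), "SNP sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  cat("  minor allele count floor:", x$min_minor_count,
      " fingerprint:", substr(x$fingerprint, 1, 12), "\n")
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel a `ref_panel`.
#' @return Number of SNP sites / haplotype rows in the panel.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' @rdname n_sites
#' @export
n_haplotypes <- function(panel) nrow(panel$haplotypes)

# Checksum tying observation sets to the exact panel (sites + matrix).
panel_fingerprint <- function(panel) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeLines(c(
    paste(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
          panel$sites$alt, sep = ":"),
    apply(panel$haplotypes, 1L, paste, collapse = "")), con)
  close(con)
  unname(tools::md5sum(tf))
}

#' Read a mappability mask from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to 1-based closed
#' intervals at ingest. Intervals are merged per chromosome so the stored
#' mask is sorted and non-overlapping. A SNP passes the mask when its single
#' base position is covered by an interval. Typical use: a uniqueness track
#' (e.g. 35-mer mappability) pre-computed for the reference assembly.
#'
#' @param bed_file path to a BED file (3+ columns, no header).
#' @return An object of class `mappability_mask`.
#' @export
read_mask_bed <- function(bed_file) {
  bed <- read.table(bed_file, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = bed[[1]],
    ranges = IRanges::IRanges(start = bed[[2]] + 1L, end = bed[[3]])))
  structure(list(ranges = gr), class = "mappability_mask")
}

mask_covers <- function(mask, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, mask$ranges)
}

#' Build a reference panel from a phased multi-sample VCF
#'
#' Retains only biallelic single-base-substitution records that are phased
#' and complete in the chosen samples, polymorphic within those samples, and
#' at or above the minor-allele-count floor; optionally restricts to sites
#' covered by a mappability mask. The haplotype matrix has two rows per
#' sample, in sample order, haplotype 0 (left of `|`) then haplotype 1.
#'
#' Filter counts (records skipped as non-SNP, unphased/missing, monomorphic,
#' below the MAC floor, or masked out) are reported via `message()` and kept
#' in `attr(panel, "filter_counts")`.
#'
#' @param vcf_file path to a VCF (optionally bgzip-compressed) with phased GT.
#' @param samples character vector of sample names to use; default all.
#' @param min_minor_count minimum minor allele count per retained site
#'   (default 10).
#' @param mask optional `mappability_mask` from [read_mask_bed()].
#' @param population label stored with the panel.
#' @return A `ref_panel`.
#' @export
build_panel <- function(vcf_file, samples = NULL, min_minor_count = 10L,
                        mask = NULL, population = "unknown") {
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  all_samples <- colnames(gt)
  if (is.null(samples)) samples <- all_samples
  missing_s <- setdiff(samples, all_samples)
  if (length(missing_s))
    stop("sample(s) not present in VCF: ", paste(missing_s, collapse = ", "))
  gt <- gt[, samples, drop = FALSE]

  bases <- c("A", "C", "G", "T")
  n_rec <- nrow(fix)
  is_snp <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  counts <- c(records = n_rec, non_biallelic_snp = sum(!is_snp))

  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  phased_ok <- matrix(grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  row_ok <- rowSums(phased_ok) == ncol(gt)
  counts["unphased_or_missing"] <- sum(!row_ok)
  gt <- gt[row_ok, , drop = FALSE]
  fix <- fix[row_ok, , drop = FALSE]

  if (nrow(gt) == 0L) stop("no usable phased biallelic SNP records")

  # haplotype matrix: per sample, left then right allele of the phased GT
  h0 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h1 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  hap <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  for (s in seq_len(ncol(gt))) {
    hap[2L * s - 1L, ] <- h0[, s]
    hap[2L * s, ] <- h1[, s]
  }

  alt_count <- colSums(hap)
  mac <- pmin(alt_count, nrow(hap) - alt_count)
  mono <- mac == 0L
  low_mac <- !mono & mac < min_minor_count
  counts["monomorphic"] <- sum(mono)
  counts["below_mac_floor"] <- sum(low_mac)
  keep <- !mono & !low_mac

  if (!is.null(mask)) {
    covered <- mask_covers(mask, fix[, "CHROM"], as.integer(fix[, "POS"]))
    counts["masked_out"] <- sum(keep & !covered)
    keep <- keep & covered
  }
  counts["retained"] <- sum(keep)
  if (!any(keep)) stop("no sites retained after filtering")

  sites <- data.frame(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
    id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                NA_character_, fix[keep, "ID"]),
    stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  panel <- ref_panel(sites[ord, , drop = FALSE],
                     hap[, keep, drop = FALSE][, ord, drop = FALSE],
                     population = population,
                     min_minor_count = min_minor_count)
  message("build_panel: ", paste(names(counts), counts, sep = "=",
                                 collapse = " "))
  attr(panel, "filter_counts") <- counts
  panel
}

#' Empirical allele frequency at a panel site
#'
#' @param panel a `ref_panel`.
#' @param site_index 1-based site index.
#' @param allele_code 0 (reference allele) or 1 (alternate allele).
#' @return The fraction of panel haplotypes carrying the allele; strictly in
#'   (0, 1) because every panel site is polymorphic.
#' @export
allele_freq <- function(panel, site_index, allele_code) {
  if (site_index < 1L || site_index > n_sites(panel))
    stop("site_index out of range")
  stopifnot(allele_code %in% c(0L, 1L))
  col <- panel$haplotypes[, site_index]
  sum(col == allele_code) / length(col)
}

#' Empirical two-site haplotype frequency
#'
#' Fraction of panel haplotypes carrying `allele_a` at `site_i` and
#' `allele_b` at `site_j`. May be exactly zero: the likelihood model stays
#' finite because the one-individual probability keeps an allele-frequency
#' product term.
#'
#' @inheritParams allele_freq
#' @param site_i,site_j distinct 1-based site indices.
#' @param allele_a,allele_b allele codes (0/1) at the two sites.
#' @return Haplotype frequency in \[0, 1\].
#' @export
haplotype_freq <- function(panel, site_i, allele_a, site_j, allele_b) {
  if (site_i == site_j) stop("site_i and site_j must be distinct")
  if (min(site_i, site_j) < 1L || max(site_i, site_j) > n_sites(panel))
    stop("site index out of range")
  h <- panel$haplotypes
  mean(h[, site_i] == allele_a & h[, site_j] == allele_b)
}

#' Is a SNP a transversion?
#'
#' TRUE unless the ref/alt pair is A/G or C/T (a transition). Restricting to
#' transversions removes the C-to-T and G-to-A substitution classes that
#' post-mortem cytosine deamination inflates in ancient DNA.
#'
#' @param ref,alt single-base alleles (vectorized).
#' @return Logical vector.
#' @export
is_transversion <- function(ref, alt) {
  pair <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  !(pair %in% c("A/G", "C/T"))
}

#' @rdname is_transversion
#' @param panel a `ref_panel`.
#' @export
transversion_sites <- function(panel) {
  is_transversion(panel$sites$ref, panel$sites$alt)
}

#' Save / load a reference panel archive
#'
#' The archive is a single self-describing text file: `#key=value` metadata
#' (format version, population, filter settings, fingerprint), a sites table,
#' and the haplotype matrix packed one haplotype per line as a 0/1 string.
#' `load_panel()` recomputes the fingerprint and refuses archives that are
#' truncated, corrupted, or from an unknown format version.
#'
#' @param panel a `ref_panel`.
#' @param file path to write / read.
#' @return `save_panel()` the path invisibly; `load_panel()` a `ref_panel`.
#' @export
save_panel <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#", PANEL_FORMAT_VERSION),
    paste0("#population=", panel$population),
    paste0("#min_minor_count=", panel$min_minor_count),
    paste0("#n_haplotypes=", n_haplotypes(panel)),
    paste0("#n_sites=", n_sites(panel)),
    paste0("#fingerprint=", panel$fingerprint),
    "#sites chrom pos ref alt id"), con)
  writeLines(paste(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                   panel$sites$alt,
                   ifelse(is.na(panel$sites$id), ".", panel$sites$id),
                   sep = "\t"), con)
  writeLines("#haplotypes", con)
  writeLines(apply(panel$haplotypes, 1L, paste, collapse = ""), con)
  invisible(file)
}

#' @rdname save_panel
#' @export
load_panel <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 8L || lines[1] != paste0("#", PANEL_FORMAT_VERSION))
    stop("not a recognisable panel archive (version header missing): ", file)
  meta <- function(key) {
    ln <- grep(paste0("^#", key, "="), lines[1:6], value = TRUE)
    if (!length(ln)) stop("panel archive missing metadata key: ", key)
    sub(paste0("^#", key, "="), "", ln[1])
  }
  ns <- as.integer(meta("n_sites"))
  nh <- as.integer(meta("n_haplotypes"))
  site_lines <- lines[seq(8L, length.out = ns)]
  hap_start <- 8L + ns + 1L
  hap_lines <- lines[seq(hap_start, length.out = nh)]
  if (length(lines) < hap_start - 1L + nh || anyNA(hap_lines) ||
      lines[8L + ns] != "#haplotypes")
    stop("panel archive truncated or corrupt: ", file)
  parts <- strsplit(site_lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5L)) stop("malformed sites table in ", file)
  sm <- do.call(rbind, parts)
  sites <- data.frame(chrom = sm[, 1], pos = as.integer(sm[, 2]),
                      ref = sm[, 3], alt = sm[, 4],
                      id = ifelse(sm[, 5] == ".", NA_character_, sm[, 5]),
                      stringsAsFactors = FALSE)
  if (any(nchar(hap_lines) != ns)) stop("haplotype rows truncated in ", file)
  hap <- matrix(as.integer(unlist(strsplit(hap_lines, "", fixed = TRUE))),
                nrow = nh, byrow = TRUE)
  panel <- ref_panel(sites, hap, population = meta("population"),
                     min_minor_count = as.integer(meta("min_minor_count")))
  if (!identical(panel$fingerprint, meta("fingerprint")))
    stop("panel archive fingerprint mismatch (corrupt file?): ", file)
  panel
}
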