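# Sparse single-base observations at panel SNP positions. An observation is
# one base call at one panel site from exactly one passing read; sites hit by
# more than max_depth passing reads are omitted (multiple reads at a sparse
# site are as likely to reflect mismapping as true coverage), and bases that
# match neither panel allele are discarded.

#' Construct an observation set
#'
#' @param sample_id sample / library identifier.
#' @param site_index integer indices into the panel's site table, strictly
#'   increasing (at most one observation per site).
#' @param allele_code parallel vector of 0/1 observed allele codes.
#' @param panel the `ref_panel` the indices refer to (its fingerprint is
#'   recorded so downstream comparisons can refuse mismatched panels).
#' @return An object of class `obs_set`.
#' @export
obs_set <- function(sample_id, site_index, allele_code, panel) {
  site_index <- as.integer(site_index)
  allele_code <- as.integer(allele_code)
  stopifnot(length(site_index) == length(allele_code),
            all(allele_code %in% c(0L, 1L)))
  if (length(site_index) &&
      (is.unsorted(site_index, strictly = TRUE)))
    stop("site_index must be strictly increasing (one observation per site)")
  if (length(site_index) &&
      (min(site_index) < 1L || max(site_index) > n_sites(panel)))
    stop("site_index out of panel range")
  structure(list(sample_id = as.character(sample_id),
                 panel_fingerprint = panel$fingerprint,
                 site_index = site_index, allele_code = allele_code),
            class = "obs_set")
}

#' @export
print.obs_set <- function(x, ...) {
  cat("<obs_set>", x$sample_id, "-", length(x$site_index),
      "single-base observations (panel", substr(x$panel_fingerprint, 1, 12),
      ")\n")
  invisible(x)
}

#' @export
length.obs_set <- function(x) length(x$site_index)

check_fingerprint <- function(obs, panel) {
  if (!identical(obs$panel_fingerprint, panel$fingerprint))
    stop("panel mismatch: observation set '", obs$sample_id,
         "' was made against a different panel")
  invisible(TRUE)
}

#' Extract single-base observations from mapped reads
#'
#' Pileup over the panel's SNP positions. At each site, reads must pass
#' `min_map_q`/`min_base_q` (duplicates, secondary alignments, QC failures
#' and unmapped reads are excluded); if more than `max_depth` reads pass the
#' site is omitted; bases matching neither panel allele are discarded; an
#' observation is emitted when the remaining base call is unambiguous (with
#' the default `max_depth = 1`, exactly one passing read). With
#' `transversions_only = TRUE` transition SNPs are skipped before pileup —
#' the ancient-DNA mode that sidesteps deamination-driven C-to-T/G-to-A
#' errors.
#'
#' @param bam_file coordinate-sorted, indexed BAM.
#' @param panel a `ref_panel` on the same reference assembly.
#' @param sample_id identifier for the resulting set (default: BAM basename).
#' @param min_base_q,min_map_q base and mapping quality floors
#'   (defaults 20 / 30).
#' @param max_depth sites with more passing reads than this are omitted
#'   (default 1).
#' @param transversions_only restrict to transversion SNPs (default FALSE).
#' @return An `obs_set`; filter counts in `attr(, "filter_counts")` and via
#'   `message()`.
#' @export
observe_from_alignments <- function(bam_file, panel,
                                    sample_id = sub("\\.bam$", "",
                                                    basename(bam_file)),
                                    min_base_q = 20L, min_map_q = 30L,
                                    max_depth = 1L,
                                    transversions_only = FALSE) {
  bf <- Rsamtools::BamFile(bam_file)
  if (!file.exists(paste0(bam_file, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_file)))
    stop("BAM index (.bai) not found for ", bam_file)
  bam_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  panel_chroms <- unique(panel$sites$chrom)
  absent <- setdiff(panel_chroms, bam_chroms)
  if (length(absent) == length(panel_chroms)) {
    hint <- if (any(sub("^chr", "", panel_chroms) %in% bam_chroms) ||
                any(paste0("chr", panel_chroms) %in% bam_chroms))
      " (contig naming differs, e.g. 'chr1' vs '1'; rename panel or BAM contigs)"
    else ""
    stop("no panel chromosome found in BAM header", hint)
  }

  keep_site <- panel$sites$chrom %in% bam_chroms
  if (transversions_only) keep_site <- keep_site & transversion_sites(panel)
  site_idx <- which(keep_site)
  counts <- c(sites_examined = length(site_idx), omitted_multiread = 0L,
              discarded_mismatch = 0L, ambiguous = 0L, emitted = 0L)
  if (!length(site_idx)) {
    message("observe: ", paste(names(counts), counts, sep = "=", collapse = " "))
    out <- obs_set(sample_id, integer(0), integer(0), panel)
    attr(out, "filter_counts") <- counts
    return(out)
  }

  which_gr <- GenomicRanges::GRanges(
    panel$sites$chrom[site_idx],
    IRanges::IRanges(panel$sites$pos[site_idx], panel$sites$pos[site_idx]))
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isNotPassingQualityControls = FALSE),
    which = which_gr, mapqFilter = min_map_q)
  pp <- Rsamtools::PileupParam(
    max_depth = 10000L, min_base_quality = min_base_q,
    min_mapq = min_map_q, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  pu <- Rsamtools::pileup(bf, scanBamParam = sbp, pileupParam = pp)

  key <- paste(pu$seqnames, pu$pos)
  site_key <- paste(panel$sites$chrom[site_idx], panel$sites$pos[site_idx])
  pu_site <- match(key, site_key)
  ok <- !is.na(pu_site)
  pu <- pu[ok, , drop = FALSE]
  pu_site <- pu_site[ok]

  depth <- tapply(pu$count, pu_site, sum)
  obs_i <- integer(0); obs_a <- integer(0)
  for (k in seq_along(depth)) {
    s_local <- as.integer(names(depth)[k])
    s_global <- site_idx[s_local]
    if (depth[k] > max_depth) {
      counts["omitted_multiread"] <- counts["omitted_multiread"] + 1L
      next
    }
    rows <- pu[pu_site == s_local, , drop = FALSE]
    alle <- c(panel$sites$ref[s_global], panel$sites$alt[s_global])
    match_rows <- rows[as.character(rows$nucleotide) %in% alle, , drop = FALSE]
    n_mismatch <- sum(rows$count) - sum(match_rows$count)
    if (n_mismatch > 0)
      counts["discarded_mismatch"] <- counts["discarded_mismatch"] + 1L
    if (nrow(match_rows) == 1L) {
      obs_i <- c(obs_i, s_global)
      obs_a <- c(obs_a, if (as.character(match_rows$nucleotide[1]) ==
                            alle[1]) 0L else 1L)
      counts["emitted"] <- counts["emitted"] + 1L
    } else if (nrow(match_rows) > 1L) {
      counts["ambiguous"] <- counts["ambiguous"] + 1L   # conflicting bases
    }
  }
  ord <- order(obs_i)
  message("observe: ", paste(names(counts), counts, sep = "=", collapse = " "))
  out <- obs_set(sample_id, obs_i[ord], obs_a[ord], panel)
  attr(out, "filter_counts") <- counts
  out
}

#' Read / write observations as TSV
#'
#' The on-disk format is a tab-separated file with `#`-prefixed header lines
#' (`#sample_id=`, `#panel=` fingerprint, column header) followed by one row
#' per observation: `chrom`, `pos` (1-based), `base`. On read, rows at
#' non-panel positions or with a base matching neither panel allele are
#' rejected (counted); if a position appears more than once, every copy of
#' that site is dropped — the file-level analogue of the multi-read omission
#' rule.
#'
#' @param file path to read / write.
#' @param panel a `ref_panel`.
#' @param obs an `obs_set` to write.
#' @return `read_observations_tsv()` an `obs_set` (rejection counts in
#'   `attr(, "filter_counts")`); `write_observations_tsv()` the path,
#'   invisibly.
#' @export
read_observations_tsv <- function(file, panel) {
  lines <- readLines(file)
  hdr <- grepl("^#", lines)
  sample_id <- sub("^#sample_id=", "",
                   grep("^#sample_id=", lines, value = TRUE)[1])
  if (is.na(sample_id)) sample_id <- sub("\\.tsv$", "", basename(file))
  fp_line <- grep("^#panel=", lines, value = TRUE)
  if (length(fp_line) && sub("^#panel=", "", fp_line[1]) != panel$fingerprint)
    stop("panel mismatch: observations TSV records a different panel fingerprint")
  body <- lines[!hdr & nzchar(lines)]
  counts <- c(rows = length(body), rejected_offpanel = 0L,
              rejected_mismatch = 0L, dropped_duplicate = 0L, emitted = 0L)
  if (!length(body)) {
    out <- obs_set(sample_id, integer(0), integer(0), panel)
    attr(out, "filter_counts") <- counts
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed row at line ", which(!hdr & nzchar(lines))[bad[1]],
         " of ", file)
  m <- do.call(rbind, parts)
  chrom <- m[, 1]; pos <- suppressWarnings(as.integer(m[, 2])); base <- m[, 3]
  if (anyNA(pos) || !all(base %in% c("A", "C", "G", "T")))
    stop("malformed position or base in ", file)
  site <- match(paste(chrom, pos),
                paste(panel$sites$chrom, panel$sites$pos))
  counts["rejected_offpanel"] <- sum(is.na(site))
  keep <- !is.na(site)
  site <- site[keep]; base <- base[keep]
  code <- ifelse(base == panel$sites$ref[site], 0L,
                 ifelse(base == panel$sites$alt[site], 1L, NA_integer_))
  counts["rejected_mismatch"] <- sum(is.na(code))
  site <- site[!is.na(code)]; code <- code[!is.na(code)]
  dup_sites <- unique(site[duplicated(site)])
  counts["dropped_duplicate"] <- sum(site %in% dup_sites)
  keep <- !(site %in% dup_sites)
  site <- site[keep]; code <- code[keep]
  ord <- order(site)
  counts["emitted"] <- length(site)
  out <- obs_set(sample_id, site[ord], code[ord], panel)
  attr(out, "filter_counts") <- counts
  out
}

#' @rdname read_observations_tsv
#' @export
write_observations_tsv <- function(obs, panel, file) {
  check_fingerprint(obs, panel)
  s <- panel$sites[obs$site_index, , drop = FALSE]
  base <- ifelse(obs$allele_code == 0L, s$ref, s$alt)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("#sample_id=", obs$sample_id),
               paste0("#panel=", obs$panel_fingerprint),
               "#chrom\tpos\tbase"), con)
  if (length(obs$site_index))
    writeLines(paste(s$chrom, s$pos, base, sep = "\t"), con)
  invisible(file)
}

#' Randomly thin an observation set
#'
#' Keeps each observation independently with probability `rate`; used to
#' emulate lower sequencing effort from an existing set. Deterministic given
#' `seed`.
#'
#' @param obs an `obs_set`.
#' @param rate keep probability in (0, 1].
#' @param seed integer seed.
#' @param panel the panel the set refers to.
#' @return A thinned `obs_set`.
#' @export
subsample_observations <- function(obs, rate, seed, panel) {
  if (!(rate > 0 && rate <= 1)) stop("rate must be in (0, 1]")
  check_fingerprint(obs, panel)
  keep <- withr::with_seed(as.integer(seed),
                           runif(length(obs$site_index)) < rate)
  obs_set(obs$sample_id, obs$site_index[keep], obs$allele_code[keep], panel)
}
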