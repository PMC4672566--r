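# Core probability model for a pair of single-base observations at two
# linked SNPs. Allele codes a, b are observed at sites i, j; the panel
# supplies the empirical allele frequencies f(A), f(B) and the two-site
# haplotype frequency f(AB).

#' Pair probability under the two-individual model
#'
#' If the two reads come from chromosomes of independent individuals, the
#' observations are independent draws from the population:
#' `P2 = f(A) * f(B)`.
#'
#' @param f_a,f_b allele frequencies, strictly in (0, 1).
#' @return Probability of the observed allele pair.
#' @export
p_two_individuals <- function(f_a, f_b) {
  stopifnot(all(f_a > 0 & f_a < 1), all(f_b > 0 & f_b < 1))
  f_a * f_b
}

#' Pair probability under the one-individual model
#'
#' If both reads come from one diploid individual, each read lands on either
#' of its two chromosomes with equal probability, so with probability 1/2 the
#' two bases sit on the same chromosome (probability = haplotype frequency
#' `f(AB)`) and with probability 1/2 on different chromosomes (independent):
#' `P1 = 1/2 f(AB) + 1/2 f(A) f(B)`. Strictly positive even when
#' `f(AB) = 0`, so the log-likelihood ratio is always finite.
#'
#' @inheritParams p_two_individuals
#' @param f_ab two-site haplotype frequency, in `[0, min(f_a, f_b)]`.
#' @return Probability of the observed allele pair.
#' @export
p_one_individual <- function(f_a, f_b, f_ab) {
  stopifnot(all(f_a > 0 & f_a < 1), all(f_b > 0 & f_b < 1), all(f_ab >= 0))
  if (any(f_ab > pmin(f_a, f_b) + 1e-12))
    stop("inconsistent frequencies: f_ab exceeds min(f_a, f_b)")
  0.5 * f_ab + 0.5 * f_a * f_b
}

#' Per-pair log-likelihood ratio
#'
#' `gamma = log2(P1 / P2)` in bits. Positive values favour the
#' one-individual model, negative values the two-individual model. Bounded
#' below by -1 bit (`P1 >= P2 / 2`) and above by
#' `log2(1/2 + 1/(2 * max(f_a, f_b)))`. Zero exactly when the two panel
#' columns are in empirical linkage equilibrium.
#'
#' @param panel a `ref_panel`.
#' @param site_i,site_j distinct site indices on the same chromosome.
#' @param allele_a,allele_b observed allele codes (0/1) at the two sites.
#' @return A one-row data.frame of class `pair_comparison` with columns
#'   `site_i`, `site_j`, `allele_a`, `allele_b`, `distance_bp`, `llr`.
#' @export
llr_pair <- function(panel, site_i, allele_a, site_j, allele_b) {
  s <- panel$sites
  if (s$chrom[site_i] != s$chrom[site_j])
    stop("pair sites must be on the same chromosome")
  f_a <- allele_freq(panel, site_i, allele_a)
  f_b <- allele_freq(panel, site_j, allele_b)
  f_ab <- haplotype_freq(panel, site_i, allele_a, site_j, allele_b)
  llr <- log2(p_one_individual(f_a, f_b, f_ab) / p_two_individuals(f_a, f_b))
  structure(data.frame(site_i = site_i, site_j = site_j,
                       allele_a = allele_a, allele_b = allele_b,
                       distance_bp = abs(s$pos[site_j] - s$pos[site_i]),
                       llr = llr),
            class = c("pair_comparison", "data.frame"))
}

# Vectorized gamma for many candidate pairs at once; used by the aggregator.
# idx_i/idx_j/a/b are parallel vectors. Frequencies are computed from integer
# counts and divided last, keeping the normalization identities exact.
pair_llrs <- function(panel, idx_i, a, idx_j, b) {
  h <- panel$haplotypes
  nh <- nrow(h)
  alt <- colSums(h)
  c_i <- ifelse(a == 1L, alt[idx_i], nh - alt[idx_i])
  c_j <- ifelse(b == 1L, alt[idx_j], nh - alt[idx_j])
  c_ab <- vapply(seq_along(idx_i), function(k) {
    sum(h[, idx_i[k]] == a[k] & h[, idx_j[k]] == b[k])
  }, integer(1))
  f_a <- c_i / nh; f_b <- c_j / nh; f_ab <- c_ab / nh
  log2((0.5 * f_ab + 0.5 * f_a * f_b) / (f_a * f_b))
}

#' Brute-force enumeration oracle for the one-individual probability
#'
#' Independent check of [p_one_individual()]: enumerates every ordered pair
#' of panel haplotypes (h1, h2) drawn with replacement as the two chromosomes
#' of a hypothetical diploid, and every one of the four read-origin choices
#' (each read independently from h1 or h2), and averages the indicator that
#' the two reads show the queried alleles. Intended for small panels only.
#'
#' @inheritParams llr_pair
#' @return Probability; equal to the closed form to floating precision.
#' @export
enumeration_oracle_p1 <- function(panel, site_i, allele_a, site_j, allele_b) {
  h <- panel$haplotypes
  nh <- nrow(h)
  if (nh > 64L) stop("oracle is meant for small panels (<= 64 haplotypes)")
  total <- 0
  for (h1 in seq_len(nh)) {
    for (h2 in seq_len(nh)) {
      chroms <- c(h1, h2)
      for (c1 in chroms) {
        for (c2 in chroms) {
          total <- total +
            (h[c1, site_i] == allele_a) * (h[c2, site_j] == allele_b)
        }
      }
    }
  }
  total / (nh * nh * 4)
}
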