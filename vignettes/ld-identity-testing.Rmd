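---
title: "Identity testing from extremely low-coverage sequencing via linkage disequilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identity testing from extremely low-coverage sequencing via linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldident)
```

## The problem

Ancient, historical and forensic DNA samples often yield so little
endogenous DNA that each sequencing library covers well under 1% of the
genome. Two such libraries from the same individual typically share few or
no sequenced positions, so direct genotype comparison — the basis of STR
profiling and of standard SNP-matching — is impossible. Worse, at these
depths almost every covered SNP is seen by exactly one read, so even the
sample's own genotypes are unknowable.

`ldident` decides whether two such observation sets derive from the same
diploid individual *without ever comparing alleles at the same site*.
The information source is linkage disequilibrium (LD): if two single-base
observations at nearby SNPs come from one diploid individual, there is a
1-in-2 chance they come from the same chromosome, and chromosomes are
mosaics of population haplotypes. Observations from two unrelated
individuals carry no such association. A phased reference haplotype panel
supplies the allele and two-site haplotype frequencies that quantify this.

## The model

For a pair of observed alleles $A$ (at one SNP) and $B$ (at a nearby SNP),
with panel frequencies $f(A)$, $f(B)$ and haplotype frequency $f(AB)$:

* **Two individuals** — the observations are independent draws from the
  population:
  $$P_2(A \wedge B) = f(A)\,f(B)$$
* **One diploid individual** — each read lands on either of the two
  chromosomes with equal probability, so with probability $\tfrac12$ both
  bases sit on one chromosome (probability $f(AB)$) and with probability
  $\tfrac12$ on different, independent chromosomes:
  $$P_1(A \wedge B) = \tfrac12 f(AB) + \tfrac12 f(A)\,f(B)$$

The models are compared per pair as a log-likelihood ratio in bits,
$$\gamma(A,B) = \log_2 \frac{P_1(A \wedge B)}{P_2(A \wedge B)},$$
and aggregated over a set $S$ of pairs sampled genome-wide,
$$\Lambda(S) = \sum_{(A,B) \in S} \gamma(A,B).$$

Useful analytic facts, all of which are asserted by the test suite:

* $P_1 \ge \tfrac12 P_2 > 0$, so $\gamma \ge -1$ bit: a single discordant
  pair can never be decisive, which gives the statistic its robustness to
  sporadic errors.
* If the panel columns are in empirical equilibrium,
  $f(AB) = f(A)f(B)$, then $\gamma = 0$ exactly: unlinked pairs are
  uninformative, they do not bias the sum.
* Both $P_1$ and $P_2$ sum to 1 over the four allele combinations of a
  pair, and $P_1$ equals the exhaustive average over all ordered haplotype
  pairs and read-origin choices (`enumeration_oracle_p1()` verifies the
  closed form against brute-force enumeration).

Frequencies are empirical panel proportions with **no pseudocounts**. The
panel's minor-allele-count floor (default 10) keeps marginal frequencies
away from 0 and 1, and $f(AB) = 0$ is harmless because the
$\tfrac12 f(A)f(B)$ term keeps $P_1$ positive.

## Aggregation, windows and the verdict

Nearby pairs are correlated — that correlation is the very signal — so
summing every eligible pair would badly overstate confidence. Instead the
genome is tiled into non-overlapping windows (default 500 kb); per
bootstrap replicate, **one** candidate pair is drawn uniformly from every
window that has at least one, and the drawn $\gamma$ values are summed
into $\Lambda$. Windows a human genome provides: about 6000. Repeating the
draw (default 100 replicates) yields an empirical distribution of
$\Lambda$, summarised by its mean, SD and 2.5%/97.5% quantiles.

Design choices made where the design was genuinely open:

* **Tiled, not sliding, windows.** Treating windows as independent
  assessments and counting ~6000 of them in a 3-Gb genome implies
  non-overlapping 500-kb tiles; sliding windows would reuse pairs and
  break the independence the sum relies on.
* **Midpoint assignment.** A pair spans at most 50 kb, a tenth of the
  window, so assigning it to the tile containing the midpoint of its two
  positions is unique and symmetric in the two samples.
* **Pair distance 1–50 kb.** The minimum (1 kb) guarantees that in
  within-sample mode the two bases can never come from one sequenced
  fragment, and incidentally forbids same-site comparison altogether; the
  maximum keeps pairs inside the range where panel LD is informative.
* **Verdict rule.** `SAME` when the bootstrap 95% interval of $\Lambda$
  lies above 0, `DIFFERENT` when below, `INCONCLUSIVE` otherwise. The
  interval rule is an artifact of making the tool decision-capable;
  mixtures and badly matched panels land in `INCONCLUSIVE`, which is the
  correct refusal.
* **Reproducibility.** One top-level seed; bootstrap draws iterate windows
  in sorted (chromosome, start) order so reports are byte-identical across
  runs and machines.
* **Autosomes only by default**: the one-individual model assumes diploidy
  at every site. Chromosome names that are not numeric (with or without a
  `chr` prefix) are skipped unless `autosomes_only = FALSE`.

## Observations and their filters

An observation is one base call at a known panel SNP from exactly one
passing read. `observe_from_alignments()` applies, in order: mapping
quality ≥ 30 and base quality ≥ 20 (defaults; the right values depend on
the platform and damage profile, so both are exposed), duplicate/secondary
read exclusion, omission of any site covered by more than `max_depth = 1`
passing reads (at ~0.01-fold coverage a doubly covered SNP is as likely a
mismapping artifact as real), and discarding of bases that match neither
panel allele. For ancient DNA, `transversions_only = TRUE` removes all
C/T and G/A SNPs before pileup, sidestepping post-mortem deamination
damage at the cost of roughly half the marker catalog.

The same rules govern the TSV interchange format: duplicate rows for one
position drop the site entirely, mirroring the multi-read rule.

## The reference panel

`build_panel()` ingests a phased multi-sample VCF and keeps biallelic
single-base substitutions that are phased and complete in the chosen
samples, polymorphic among them, and at or above the minor-allele-count
floor (default 10, which bounds frequency estimation error at panel sizes
of a few hundred haplotypes). An optional mappability mask (BED, e.g. a
35-mer uniqueness track) restricts sites to uniquely mappable sequence.
Sites with missing or unphased genotypes are dropped rather than imputed:
frequency estimates must come from complete columns.

Coordinates are stored 1-based throughout (the R/Bioconductor convention;
VCF positions pass through unchanged and BED intervals are converted once
at ingest). The panel archive is a single self-describing text file whose
fingerprint ties every observation set to the exact panel it was made
against; comparisons across mismatched panels are refused.

## The simulation module

`simulate_cohort()` emulates the study design used to validate the
method: independent 500-kb segments simulated under a coalescent with
recombination, a 200-haplotype reference panel, two diploid individuals
drawn from the same simulated population without overlap with the panel,
sites filtered at MAF ≥ 10% (computed over the panel rows, since the
filter exists to guarantee panel frequency estimates), and sparse
observation sampling at rate 0.01 per chromosome copy with double-drawn
sites discarded — giving an observed-site fraction of
$2r(1-r) \approx 0.0198$, i.e. ~0.02-fold equivalent coverage.
Mutation and recombination rates default to human-typical
$1.25\times10^{-8}$ and $1\times10^{-8}$ per bp per generation.
`mate()` produces children (one recombinant gamete per parent) for
relatedness layouts; `split_generations` moves the panel to the far side
of a symmetric population split to emulate an imperfectly matched
reference population.

Two backends produce segments:

* **msprime** (default): exact coalescent with recombination, driven
  through a small bundled Python script; this is the backend behind all
  quantitative claims.
* **mosaic**: a pure-R founder-copying approximation (haplotypes switch
  among a small founder set at a population-scaled rate along the
  segment). It produces allele-frequency variation and LD that decays
  with distance and runs with no external process, so fast structural
  tests use it; its LD is weaker than coalescent LD and it supports only
  the single-population model. It is an approximation for convenience,
  not a calibrated population-genetic model.

What the simulations do **not** emulate: sequencing error (observations
are error-free; on real data errors are handled by the quality filters
and the transversion mode), contamination mixtures, variable fragment
length, reference bias, and real human demographic history beyond the
constant-size and two-population-split models. Passing the simulation
checks therefore demonstrates the statistical machinery under idealised
sampling, not robustness to every real-data artifact.

## Problem sizes used by the test suite

The package's replicated checks run a deliberately scaled-down version of
the full design: 300 segments × 500 kb (a tenth of the 3000-segment,
1.5-Gb reference layout) with 20 replicates for sign-recovery and
relatedness ordering, 200 segments × 8 replicates per split time
(100 vs 4000 generations) for the divergence trend, and 100 bootstrap
draws per comparison. At these scales the same-individual and
different-individual $\Lambda$ distributions are already separated by
roughly 20 bits, so sign recovery is comfortably testable; the scales are
the package's choice of a small but decisive experiment.

## Numerical and degenerate-input behaviour

* Frequencies are computed from integer counts and divided last; the
  normalization identities hold to 1e-12 and are asserted at that
  tolerance.
* A comparison with no window containing an eligible pair fails with an
  explicit low-coverage diagnostic ("too few linked observation pairs") —
  at 0.01% coverage this is the expected outcome, not an error in the
  data.
* Windows with a single candidate contribute no bootstrap variance;
  a comparison where every candidate $\gamma = 0$ reports mean 0 and
  `INCONCLUSIVE`.
* Ties in the bootstrap draw are impossible by construction (uniform draw
  over an indexed candidate list).

## Known limitations

* Power depends on how well the panel matches the samples' source
  population; the split-model simulations quantify the decay. Panel
  selection itself (e.g. by principal components on the sparse data) is
  out of scope.
* Relatives produce intermediate $\Lambda$: parent–child and sibling
  pairs sit between the same- and different-individual distributions,
  centred near zero. The tool reports the intermediate value but does not
  classify kinship degree.
* Admixed individuals and multi-way mixtures are not modelled;
  within-sample mode flags them only as `INCONCLUSIVE`/negative.
* The X chromosome, Y and mitochondrion are excluded by default; the
  diploid model does not apply to them.
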