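"""Coalescent-with-recombination segment simulator backing the R package.

Simulates independent segments under either a single constant-size
population or a clean two-population split (no migration), using msprime.
Haplotypes are emitted as ms-style 0/1 strings per segment after filtering
sites on the minor allele frequency computed over the *panel* rows (the
last `panel` haplotypes; the filter exists to guarantee panel frequency
estimates). Output format, per segment:

    //<segment index>
    positions: <1-based integer bp positions, space separated>
    <one 0/1 string per haplotype; first `focal` rows are the focal
     (sample-individual) haplotypes, remaining rows the panel>
"""

import argparse
import sys

import msprime
import numpy as np


def parse_args(argv):
    p = argparse.ArgumentParser()
    p.add_argument("--out", required=True)
    p.add_argument("--seed", type=int, required=True)
    p.add_argument("--segments", type=int, required=True)
    p.add_argument("--length", type=float, required=True)
    p.add_argument("--ne", type=float, required=True)
    p.add_argument("--mu", type=float, required=True)
    p.add_argument("--recomb", type=float, required=True)
    p.add_argument("--focal", type=int, required=True,
                   help="haplotypes for the sampled individuals (pop 1)")
    p.add_argument("--panel", type=int, required=True,
                   help="haplotypes for the reference panel (pop 2 if split)")
    p.add_argument("--split-generations", type=int, default=0)
    p.add_argument("--maf-floor", type=float, default=0.10)
    return p.parse_args(argv)


def main(argv=None):
    a = parse_args(argv)
    rng = np.random.default_rng(a.seed)
    if a.split_generations > 0:
        demography = msprime.Demography()
        demography.add_population(name="focal", initial_size=a.ne)
        demography.add_population(name="panel", initial_size=a.ne)
        demography.add_population(name="anc", initial_size=a.ne)
        demography.add_population_split(time=a.split_generations,
                                        derived=["focal", "panel"],
                                        ancestral="anc")
        samples = [msprime.SampleSet(a.focal, population="focal", ploidy=1),
                   msprime.SampleSet(a.panel, population="panel", ploidy=1)]
        demog_kw = dict(samples=samples, demography=demography)
    else:
        demog_kw = dict(samples=a.focal + a.panel, ploidy=1,
                        population_size=a.ne)

    with open(a.out, "w") as out:
        for seg in range(a.segments):
            seeds = rng.integers(1, 2**31 - 1, size=2)
            ts = msprime.sim_ancestry(sequence_length=a.length,
                                      recombination_rate=a.recomb,
                                      random_seed=int(seeds[0]), **demog_kw)
            ts = msprime.sim_mutations(
                ts, rate=a.mu, model=msprime.BinaryMutationModel(),
                random_seed=int(seeds[1]))
            G = ts.genotype_matrix()          # sites x haplotypes, 0/1
            pos = ts.sites_position.astype(int) + 1   # 1-based
            # one site per discrete position
            _, first = np.unique(pos, return_index=True)
            G = G[first]
            pos = pos[first]
            panel_rows = G[:, a.focal:]
            f = panel_rows.mean(axis=1)
            maf = np.minimum(f, 1 - f)
            keep = maf >= a.maf_floor
            G = G[keep]
            pos = pos[keep]
            out.write("//%d\n" % (seg + 1))
            out.write("positions: %s\n" % " ".join(map(str, pos)))
            for h in range(G.shape[1]):
                out.write("".join(map(str, G[:, h])) + "\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
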