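"""msprime-based oracle for the test suite.

Writes into OUTDIR:
  * aln_XX.fasta -- 50 isochronous alignments (n=10, L=1500, JC69 finite
    sites) used to cross-check the summary statistics implementation.
  * cross.json   -- per-replicate S, mean pairwise differences and TMRCA
    (in generations) for 500 constant-size replicates (n=10, L=15000,
    haploid N=1000, per-generation rate 2.56e-7), computed with
    msprime/tskit/numpy only. Used as the cross-simulator oracle.

Usage: python msprime_oracle.py SEED OUTDIR
"""
import json
import sys

import msprime
import numpy as np


def variable_matrix(ts):
    """Genotype matrix restricted to sites polymorphic among the samples."""
    G = ts.genotype_matrix()
    if G.size == 0:
        return G
    poly = np.array([len(np.unique(row)) > 1 for row in G])
    return G[poly]


def stats_of(ts):
    G = variable_matrix(ts)
    S = G.shape[0]
    n = ts.num_samples
    diffs = 0
    for i in range(n - 1):
        for j in range(i + 1, n):
            if S:
                diffs += int(np.sum(G[:, i] != G[:, j]))
    k_bar = diffs / (n * (n - 1) / 2)
    tree = ts.first()
    tmrca = tree.time(tree.root)
    return S, k_bar, tmrca


def write_fasta(path, ts, length, idx):
    rng = np.random.default_rng(idx + 77)
    bases = np.array(list("ACGT"))
    ref = rng.integers(0, 4, int(length))
    n = ts.num_samples
    mat = np.tile(ref, (n, 1))
    for var in ts.variants():
        pos = int(var.site.position)
        alleles = var.alleles
        code = np.array([list("ACGT").index(a) for a in alleles])
        mat[:, pos] = code[var.genotypes]
    with open(path, "w") as fh:
        for i in range(n):
            fh.write(f">m{i:02d}\n")
            fh.write("".join(bases[mat[i]]) + "\n")


def main():
    seed = int(sys.argv[1])
    outdir = sys.argv[2]

    # 50 small alignments for the statistics oracle
    for r in range(50):
        ts = msprime.sim_ancestry(
            samples=10, ploidy=1, population_size=5000,
            sequence_length=1500, random_seed=seed + r + 1)
        ts = msprime.sim_mutations(
            ts, rate=2e-6, model=msprime.JC69(), random_seed=seed + 1000 + r)
        write_fasta(f"{outdir}/aln_{r:02d}.fasta", ts, 1500, r)

    # cross-simulator replicates: constant N=1000, n=10, L=15000
    out = {"S": [], "k_bar": [], "tmrca": []}
    for r in range(500):
        ts = msprime.sim_ancestry(
            samples=10, ploidy=1, population_size=1000,
            sequence_length=15000, random_seed=seed + 5000 + r)
        ts = msprime.sim_mutations(
            ts, rate=2.56e-7, model=msprime.JC69(),
            random_seed=seed + 9000 + r)
        S, k_bar, tmrca = stats_of(ts)
        out["S"].append(S)
        out["k_bar"].append(k_bar)
        out["tmrca"].append(tmrca)
    with open(f"{outdir}/cross.json", "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
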