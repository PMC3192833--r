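"""Batched coalescent sampler for SweepScan synthetic panels.

Reads a JSON task file and simulates each task with msprime under the
wolf -> domesticated-dog -> simultaneous-breed-split demographic program.
Each task writes <out_dir>/<id>.bin:

    int32 n_sites, int32 n_haps,
    float64 positions[n_sites]  (1-based integer bp),
    uint8  genotypes[n_sites * n_haps]  (site-major)

Only strictly biallelic sites at unique integer positions are emitted.
"""
import json
import struct
import sys

import numpy as np
import msprime


def build_demography(task):
    nb = len(task["pop_f"])
    scale = task.get("size_scale", 1.0)
    d = msprime.Demography()
    for i in range(nb):
        d.add_population(name=f"B{i}",
                         initial_size=task["pop_f"][i] * task["ne_wolf"] * scale)
    d.add_population(name="DOG", initial_size=task["ne_dog"] * scale)
    d.add_population(name="WOLF", initial_size=task["ne_wolf"] * scale)
    d.add_population_split(time=task["t_breed"],
                           derived=[f"B{i}" for i in range(nb)],
                           ancestral="DOG")
    d.add_population_split(time=task["t_dom"], derived=["DOG"],
                           ancestral="WOLF")
    return d


def run_task(task, out_dir):
    demog = build_demography(task)
    samples = {f"B{i}": n for i, n in enumerate(task["n_per_pop"])}
    ts = msprime.sim_ancestry(
        samples=samples, demography=demog,
        sequence_length=task["length"],
        recombination_rate=task["recomb"],
        random_seed=task["seed"])
    ts = msprime.sim_mutations(ts, rate=task["mu"],
                               random_seed=task["seed"] + 1)
    G = ts.genotype_matrix()
    pos = np.floor(ts.tables.sites.position).astype(np.int64) + 1
    biallelic = np.array(
        [len(s.mutations) > 0 and G[k].max() <= 1
         for k, s in enumerate(ts.sites())], dtype=bool)
    uniq = np.ones(len(pos), dtype=bool)
    uniq[1:] = pos[1:] != pos[:-1]
    keep = biallelic & uniq
    G = G[keep].astype(np.uint8)
    pos = pos[keep]
    with open(f"{out_dir}/{task['id']}.bin", "wb") as fh:
        fh.write(struct.pack("<ii", G.shape[0], G.shape[1]))
        fh.write(pos.astype("<f8").tobytes())
        fh.write(G.tobytes(order="C"))


def main(path):
    with open(path) as fh:
        spec = json.load(fh)
    for task in spec["tasks"]:
        run_task(task, spec["out_dir"])


if __name__ == "__main__":
    main(sys.argv[1])
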