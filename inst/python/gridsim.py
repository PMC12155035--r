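"""Deme-grid coalescent simulation driver.

Called by the R package with a JSON config. Two modes:

  simulate  -- grid-of-demes demography (rook migration, single ancestral
               merge, hybrid DTWF + Hudson coalescent), binary mutation
               overlay, seeded site thinning; writes a compact dosage
               matrix, variant/sample metadata and per-chromosome tree
               sequences (kept for later true-IBD extraction).
  ibd       -- true IBD segments (contiguous shared ancestry) from saved
               tree sequences, mapped to diploid individual pairs, with a
               minimum genetic length; writes a six-column segment table
               (id_a id_b chromosome start_bp end_bp length_cM).

Usage: python gridsim.py <mode> <config.json>
"""

import json
import os
import sys

import numpy as np
import msprime
import tskit


def build_demography(cfg):
    n = cfg["grid_n"]
    size = cfg["deme_size"]
    demog = msprime.Demography()
    names = []
    for i in range(n):
        for j in range(n):
            name = f"d{i}_{j}"
            names.append(name)
            demog.add_population(name=name, initial_size=size)
    demog.add_population(name="anc", initial_size=size * n * n)
    m = cfg["migration_rate"]
    if m > 0:
        for i in range(n):
            for j in range(n):
                for di, dj in ((1, 0), (0, 1)):  # rook adjacency
                    ii, jj = i + di, j + dj
                    if ii < n and jj < n:
                        demog.set_symmetric_migration_rate(
                            [f"d{i}_{j}", f"d{ii}_{jj}"], m
                        )
    demog.add_population_split(time=cfg["t_ancestral"], derived=names,
                               ancestral="anc")
    return demog, names


def simulate(cfg):
    out = cfg["out_dir"]
    os.makedirs(out, exist_ok=True)
    demog, names = build_demography(cfg)
    dpd = cfg["diploids_per_deme"]
    seed = int(cfg["seed"])
    model = [
        msprime.DiscreteTimeWrightFisher(duration=cfg["t_dtwf"]),
        msprime.StandardCoalescent(),
    ]

    single_chrom = len(cfg["chromosomes"]) == 1
    trees_meta = []
    mut_paths = []
    mut_cache = {}
    site_counts = []
    for ci, chrom in enumerate(cfg["chromosomes"]):
        ts = msprime.sim_ancestry(
            samples={name: dpd for name in names},
            demography=demog,
            sequence_length=chrom["length_bp"],
            recombination_rate=chrom["recomb_rate"],
            model=model,
            random_seed=seed + 1009 * ci + 1,
        )
        trees_path = os.path.join(out, f"chr{chrom['name']}.trees")
        ts.dump(trees_path)
        trees_meta.append({
            "name": chrom["name"],
            "path": trees_path,
            "recomb_rate": chrom["recomb_rate"],
            "length_bp": chrom["length_bp"],
        })
        mts = msprime.sim_mutations(ts, rate=cfg["mutation_rate"],
                                    random_seed=seed + 1009 * ci + 577,
                                    model=msprime.BinaryMutationModel())
        if single_chrom:
            # keep in memory; the thinning pass below runs immediately
            mut_cache[ci] = mts
            mut_paths.append(None)
        else:
            mpath = trees_path + ".mut"
            mts.dump(mpath)
            mut_paths.append(mpath)
        site_counts.append(mts.num_sites)
        del ts, mts

    total_sites = int(sum(site_counts))
    max_v = cfg.get("max_variants")
    thin = max_v is not None and max_v > 0 and total_sites > max_v
    if thin:
        rng = np.random.default_rng(seed + 99991)
        budgets = np.floor(np.array(site_counts) * max_v / total_sites)
        budgets = budgets.astype(int)
        # distribute the rounding remainder to the largest chromosomes
        rem = int(max_v) - int(budgets.sum())
        for i in np.argsort(site_counts)[::-1][:rem]:
            budgets[i] += 1

    sample_rows = None
    n_kept = 0
    with open(os.path.join(out, "dosages.txt"), "wb") as dos_fh, \
         open(os.path.join(out, "variants.tsv"), "w") as var_fh:
        for ci, chrom in enumerate(cfg["chromosomes"]):
            mts = mut_cache.pop(ci) if single_chrom else tskit.load(mut_paths[ci])
            if thin:
                keep = np.sort(rng.choice(mts.num_sites, size=budgets[ci],
                                          replace=False))
                drop = np.setdiff1d(np.arange(mts.num_sites), keep)
                mts = mts.delete_sites(drop)
            if sample_rows is None:
                pop_name = {p.id: p.metadata.get("name", str(p.id))
                            for p in mts.populations()}
                sample_rows = []
                for ind in mts.individuals():
                    node = mts.node(ind.nodes[0])
                    name = pop_name[node.population]
                    row, col = (int(x) for x in name[1:].split("_"))
                    sample_rows.append((f"S{ind.id + 1:05d}", row, col, name))
            ind_nodes = np.array([ind.nodes for ind in mts.individuals()])
            left, right = ind_nodes[:, 0], ind_nodes[:, 1]
            # stream variant by variant: memory stays O(n) even unthinned
            for var in mts.variants():
                gv = var.genotypes
                dos = (gv[left] + gv[right]).astype(np.uint8)
                dos_fh.write((dos + 48).tobytes())
                dos_fh.write(b"\n")
                pos = int(var.site.position) + 1
                var_fh.write(
                    f"{chrom['name']}\t{pos}\tA\tG\t{chrom['name']}:{pos}\n"
                )
                n_kept += 1
            del mts
            if not single_chrom:
                os.remove(mut_paths[ci])

    with open(os.path.join(out, "samples.tsv"), "w") as fh:
        for sid, row, col, deme in sample_rows:
            fh.write(f"{sid}\t{row}\t{col}\t{deme}\n")
    with open(os.path.join(out, "meta.json"), "w") as fh:
        json.dump({
            "n_samples": len(sample_rows),
            "n_variants": n_kept,
            "n_sites_before_thinning": total_sites,
            "trees": trees_meta,
            "seed": seed,
        }, fh)


def extract_ibd(cfg):
    min_cm = float(cfg["min_cM"])
    if min_cm <= 0:
        raise ValueError("min_cM must be > 0")
    with open(cfg["out_path"], "w") as fh:
        for chrom in cfg["trees"]:
            ts = tskit.load(chrom["path"])
            r = float(chrom["recomb_rate"])
            min_span = min_cm / 100.0 / r
            node_ind = np.full(ts.num_nodes, -1, dtype=np.int64)
            for ind in ts.individuals():
                node_ind[ind.nodes] = ind.id
            res = ts.ibd_segments(min_span=min_span, store_pairs=True,
                                  store_segments=True)
            for (na, nb), segs in res.items():
                ia, ib = node_ind[na], node_ind[nb]
                if ia < 0 or ib < 0 or ia == ib:
                    continue
                sa = f"S{ia + 1:05d}"
                sb = f"S{ib + 1:05d}"
                for seg in segs:
                    span = seg.right - seg.left
                    cm = span * r * 100.0
                    fh.write(
                        f"{sa}\t{sb}\t{chrom['name']}\t"
                        f"{int(seg.left) + 1}\t{int(seg.right)}\t{cm:.6f}\n"
                    )


def main():
    mode, cfg_path = sys.argv[1], sys.argv[2]
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    if mode == "simulate":
        simulate(cfg)
    elif mode == "ibd":
        extract_ibd(cfg)
    else:
        raise SystemExit(f"unknown mode: {mode}")


if __name__ == "__main__":
    main()
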