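# orthotri

Hierarchical ortholog delineation by best-reciprocal-hit triangulation,
with evolutionary annotations and clustering benchmarks — an R
implementation of the classic BRH/in-paralog/triangulation approach to
building orthologous groups at taxonomy-defined levels.

## What it does

Orthologs are genes in different species descended by speciation from a
single gene of their last common ancestor (LCA); duplications after that
speciation produce co-orthologs (in-paralogs). An orthologous group (OG)
is the set of all extant descendants of one LCA gene across the species
considered, and because orthology is relative to an LCA, delineation at
different nodes of the species phylogeny yields nested *levels* of
orthology.

Given per-genome protein FASTA files (longest isoform per gene) and a
Newick species taxonomy with labeled internal nodes, `orthotri`:

1. computes all-vs-all **Smith–Waterman** local alignments (affine gaps,
   BLOSUM62/11/1 defaults; raw score ≥ 50 covering ≥ 50% of the shorter
   sequence);
2. **collapses near-identical gene copies** within each genome (greedy
   longest-first, ≥ 97% identity over ≥ 90% coverage);
3. finds **best reciprocal hits** (BRH) between genome pairs (ties
   kept), detects **in-paralogs** — within-genome pairs scoring strictly
   above the weakest per-genome best-BRH score of either gene — and
   **triangulates** BRHs into groups: three-species BRH triangles seed
   clusters, remaining edges attach or form pairs, in-paralog links
   join their co-ortholog clusters, absorbed copies re-expand. All of
   this is re-run independently at every requested taxonomy level;
4. annotates each group with its **phyletic profile** (universality,
   duplicability, copy-number class), **evolutionary rate** (mean
   inter-species identity normalized by the per-genome-pair BRH
   baseline; 1.0 = lineage average), **gene architecture** (median/SD of
   protein length and exon count, deviant flagging) and **sibling
   groups** (shared domains in ≥ 2 organisms of each group);
5. **benchmarks** a predicted clustering against reference groups:
   per-reference precision/recall/F1, the six-way event classification
   (Exact / Akin / Fused / Split / Missed / Complex with
   85%-precision/recall thresholds) and the Variation of Information
   VI(X,Y) = H(X) + H(Y) − 2 I(X;Y) in bits;
6. ships a **birth–death simulator** that evolves gene families down a
   species tree (Poisson duplication/loss, per-site substitution) and
   emits FASTA + metadata + ground-truth groups at every level, so the
   whole pipeline can be validated against known truth.

## Worked example

Simulate six genomes with known orthology, delineate groups at every
level of the tree, and benchmark the result against the simulator's
ground truth:

```r
library(orthotri)

sim  <- simulate_proteomes(sim_config(n_families = 20, dup_rate = 0,
                                      loss_rate = 0, seed = 42))
hits <- all_vs_all(sim$genes)                    # 618 directed hits
cl   <- cluster_all_levels(hits, sim$genes, sim$taxonomy)

truth <- sim$truth[sim$truth$level_id == "ROOT",
                   c("family_group_id", "gene_id")]
names(truth)[1] <- "refog_id"
benchmark_clustering(cl[cl$level_id == "ROOT", ], truth)
```

```
benchmark: 20 reference groups vs 20 predicted clusters
  events: Exact=20 Akin=0 Fused=0 Split=0 Missed=0 Complex=0
  split events: 0  fuse events: 0  VI: 0.0000
```

Every simulated family (20 reference groups) is recovered exactly —
perfect precision and recall for each group and a Variation of
Information of 0 bits, i.e. the predicted and true partitions are
identical. With duplication and loss switched on (`dup_rate = 0.1`,
`loss_rate = 0.05`) most groups still classify Exact and the remainder
Akin/Split, mirroring how real delineations degrade.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/orthotri.R simulate --families 100 --seed 42 --out data/
Rscript inst/scripts/orthotri.R run --genomes data/ --tax data/tree.nwk --out-dir results/
```

`run` executes align → collapse → cluster → annotate (→ benchmark when
given `--ref`), logs per-stage summaries — including the percentage of
genes clustered per level — to stderr, and skips stages whose inputs and
parameters are unchanged since the last run.

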