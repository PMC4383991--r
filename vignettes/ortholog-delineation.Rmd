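---
title: "Delineating hierarchical orthologous groups with orthotri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating hierarchical orthologous groups with orthotri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotri)
```

## The problem

Orthologs are genes in different species that descend by speciation from
a single gene in those species' last common ancestor (LCA); paralogs
that arose by duplication *after* that speciation (in-paralogs, or
co-orthologs) are jointly orthologous to their counterparts in the other
species. An *orthologous group* (OG) collects all extant descendants of
one LCA gene across a chosen set of species. Because orthology is
relative to an LCA, delineation at different internal nodes of the
species phylogeny yields nested "levels of orthology": older nodes give
broader groups, younger nodes finer ones.

`orthotri` implements a complete delineation suite on this model:

1. all-vs-all protein comparison by full Smith-Waterman local alignment;
2. collapsing of near-identical within-genome gene copies;
3. best-reciprocal-hit (BRH) detection between genome pairs,
   in-paralog identification within genomes, and triangulation
   clustering into orthologous groups, repeated independently at each
   requested taxonomy level;
4. per-group evolutionary annotations (phyletic profiles, normalized
   evolutionary rates, gene architecture statistics, sibling groups);
5. benchmarking of a predicted clustering against a reference
   clustering (precision/recall/F1, a six-way event classification, and
   the Variation of Information);
6. a birth-death gene-family simulator that produces proteomes with
   known ortholog ground truth, used throughout the test suite.

## The delineation procedure

**Pairwise similarity.** Every unordered pair of distinct genes is
aligned with affine-gap Smith-Waterman (Gotoh's algorithm). The defaults
are the standard protein-BLAST setting -- BLOSUM62, gap open 11, gap
extend 1 -- because the delineation literature specifies the algorithm
but not its parameters, and these are the least-surprise choice. A hit
is reported only when the raw score reaches `min_score` (default 50)
and the alignment covers at least `min_overlap` (default 0.5) of the
shorter sequence. The raw alignment score, not a bit score or E-value,
is the ranking statistic throughout: it is symmetric, database-size
independent, and sufficient for best-hit comparisons. The coverage
floor suppresses short domain-only matches that would otherwise seed
spurious reciprocal hits between multidomain proteins. Hits can also be
supplied precomputed through the tab-separated hits format, so any
external aligner emitting the same columns can be plugged in.

**Collapsing similar copies.** Within each genome, genes are visited by
descending length and absorbed by the first already-chosen
representative to which they align with at least 97% identity over at
least 90% of the shorter sequence -- the greedy longest-first strategy
familiar from CD-HIT. Absorbed genes are invisible to clustering and
re-attached to their representative's final group afterwards. The
greedy rule (rather than transitive closure) keeps chains of marginally
similar copies from merging; the thresholds are package conventions.

**BRH detection.** For genomes A and B, gene *a*'s best-hit set in B is
every B gene attaining *a*'s maximal raw score (ties kept). An edge
(a, b) is a BRH iff each is in the other's best-hit set. The edge score
is the minimum of the two directed scores, the edge identity the mean
of the two directed identities.

**In-paralogs.** A within-genome pair more similar than the best
reciprocal matches across the level's deepest radiation represents a
duplication after the level's speciation point. Operationally, T(x) is
the *weakest per-genome best-BRH score* of gene x: for each partner
genome take x's best BRH edge score, then take the minimum over
genomes; T(x) is infinite when x has no BRH edge at all, so unanchored
genes never recruit in-paralogs. A link is emitted for intra-genome
pair (g, h) with score s iff s > min(T(g), T(h)), strictly -- exact
ties are left out because their post-speciation timing is undecidable.
Taking the minimum over genomes (rather than the maximum) is the design
decision that makes the rule level-aware: a duplication that predates a
child level's LCA but postdates an ancestral one scores below the
within-child-clade BRH but above the cross-ancestral-radiation BRH, so
it is linked at the ancestral level only. With the maximum, the
strongest (youngest) BRH would mask every older duplication and the
linked set could never grow when moving to older levels, contradicting
the definition of co-orthology relative to an LCA.

**Triangulation clustering.** The clustering itself runs in four
stages:

1. every BRH triangle -- three genes in three distinct genomes with all
   three pairwise edges -- seeds or merges a cluster; stage-1 clusters
   are the connected components of the triangle-edge subgraph;
2. each remaining BRH edge, visited by descending score (ties broken
   lexicographically), attaches its free endpoint(s) to a touched
   cluster, forms a new two-gene group when it touches none, and is
   recorded as *unverified* -- without merging -- when it bridges two
   existing clusters;
3. in-paralog links, by descending score and transitively to a
   fixpoint, attach their ungrouped endpoint to the grouped endpoint's
   cluster, and merge two clusters when a link bridges them. Unlike
   the unverified edges of stage 2, in-paralog links have passed the
   threshold test against the level's BRH baseline, so they are trusted
   as clustering edges; the merge is what reunites pre-child-LCA
   duplicates at ancestral levels;
4. absorbed near-identical copies re-expand into their representative's
   group.

Requiring a third-species triangle before trusting cluster growth
reduces chaining through promiscuous genes relative to naive connected
components, and degrades gracefully: at a two-genome level no triangle
exists and every BRH edge simply yields a two-gene group. The naive
connected-components closure is available for comparison
(`closure = "naive"`).

Each requested level is computed independently on the hits restricted
to its genomes, because best-hit sets and in-paralog thresholds change
with the species set. Genes with no qualifying edge remain unclustered
singletons -- on real proteomes a ~90% clustered fraction is the
expected regime, and the per-level log line reports it.

Group identifiers are `OG<level>_<ordinal>`, ordinals assigned by
descending group size then lexicographically smallest member, so output
is deterministic and diff-able; every writer sorts its rows for the
same reason.

## Evolutionary annotations

For each group at a level the package computes:

* **Phyletic profile** -- per-genome copy numbers over all genomes of
  the level. *Universality* is the fraction of level genomes with at
  least one member. *Duplicability* is the fraction of *present*
  genomes with at least two members: duplicate retention is conditional
  on presence, so absence does not dilute it. The copy-number class is
  `single_copy_in_all`, `multi_copy_in_all`, `present_in_all` or
  `patchy`, and `query_by_profile()` retrieves groups by class or by a
  per-genome pattern such as `"A=1,B>=2"`.
* **Evolutionary rate** -- the mean over inter-species member pairs of
  the pair's percent identity divided by the mean identity of all BRH
  edges between the same genome pair at the level. A rate of 1.0 is
  lineage-average divergence; lower is faster evolution. Pairs without
  a stored alignment are skipped rather than re-aligned (the hits table
  is the performance contract); the rate is undefined for single-genome
  groups.
* **Gene architecture** -- median and population standard deviation
  (n denominator, so single-member groups are well-defined with sd 0)
  of protein lengths and exon counts. Members deviating from the
  median length by more than k spreads (default k = 3, spread floored
  at 1 aa) are flagged, never removed. The default spread is the plain
  SD; a MAD-based robust mode exists because a single extreme gene
  model inflates the plain SD enough to hide itself -- the
  `{100, 102, 98, 400}` case flags nothing under SD and flags the 400
  under MAD.
* **Sibling groups** -- group pairs sharing a domain identifier carried
  by at least two distinct genomes in each group. Counting organisms
  rather than genes prevents a tandem array in one genome from
  qualifying.

## Benchmarking

A predicted clustering is compared to reference groups after
restriction to the reference universe (predicted clusters are
intersected with it; unassigned reference elements count as
singletons). Each reference group is matched to its best cluster by F1
(ties: larger intersection, then smallest cluster id) and labeled by
the first matching rule of the precedence **Exact** (p = r = 1) >
**Akin** (p, r > 0.85) > **Fused** (two or more reference groups each
recalled > 85% by one shared cluster whose summed precision over them
exceeds 85%) > **Split** (two or more clusters, each > 85% precise for
the group, jointly recalling > 85% of it) > **Missed** (best recall
< 0.5) > **Complex**. Fused and Split are tested before Missed because
a cleanly split group can have per-piece recall below 0.5. Fuse events
are counted once per fusing cluster (co-fused groups beyond the first);
split events count the pieces.

The Variation of Information VI(X, Y) = H(X) + H(Y) - 2 I(X; Y) is
computed from block-overlap counts, in bits by default; the base is an
argument because published VI tables do not always state it. VI is a
metric on partitions -- symmetric, zero iff identical, triangle
inequality -- and the suite property-tests all three on random
partition triples.

## The simulator

`simulate_proteomes()` evolves `n_families` independent gene families
down a species tree with branch lengths in expected substitutions per
site. Per branch and lineage, loss events and duplications are Poisson
in branch length; substitutions hit each site with probability
1 - exp(-t), drawing the replacement uniformly from the 20 residues (so
a small back-substitution floor exists, and chance identity between
unrelated sequences is ~5%). Root sequences are i.i.d. uniform with
Normal(300, 50) lengths floored at 50 aa; exon counts are drawn once
per family (uniform 1..10) and inherited unchanged; each family carries
a private domain identifier and a configurable number of shared domains
link random family pairs so sibling detection has structure. Every
lineage records which gene copy it descends from at each labeled node;
`truth_at_level()` turns that record into the ground-truth partition,
which nests hierarchically by construction.

The default study conditions used by the acceptance checks are a
six-genome, three-radiation tree
`(((A:0.2,B:0.2)AB:0.15,(C:0.2,D:0.2)CD:0.15)ABCD:0.15,(E:0.3,F:0.3)EF:0.2)ROOT;`
with 100 families -- pairwise divergences of roughly 0.4-1.0
substitutions/site, i.e. ~40-70% identity, comfortably above noise but
far from trivial -- with duplication/loss rates of 0 (clean recovery)
or 0.1/0.05 (event classification). Test-suite unit fixtures use 6-30
families so the whole suite stays fast; these sizes are the package's
own choices and are stated here so results are reproducible.

What the simulator deliberately does *not* model: insertions/deletions
within genes (alignments of simulated orthologs are gap-free, keeping
identity interpretable), rate heterogeneity across sites, partial or
domain-level duplications, and horizontal transfer. Passing the
recovery tests therefore shows the BRH/triangulation machinery is
correct under whole-gene birth-death divergence, not that the pipeline
is robust to fragmented gene models or domain shuffling in real
proteomes.

## Numerical and degenerate-case choices

* Isoform length ties resolve to the lexicographically smallest isoform
  id -- deterministic and file-order independent; equal-length,
  same-id, different-sequence records are a hard error.
* Letters outside the 20-residue alphabet are masked to X with a
  warning; BLOSUM X-scores then apply.
* The in-paralog inequality is strict; BRH ties are kept (a gene may
  have several best hits).
* Co-optimal local alignments are resolved deterministically: the
  lexicographically smaller sequence is always the query internally, so
  the reported alignment (identity, coordinates) does not depend on
  argument order; the optimal score is argument-order invariant anyway.
* Unverified cross-cluster edges never merge; their provenance is kept
  in an attribute of the cluster table.
* Levels with fewer than two genomes are an error; empty hit tables are
  valid inputs everywhere and yield empty results.
* VI of identical partitions is clamped to exactly 0 against floating
  point drift.

## Limitations

The stage machine is one concrete realization of "triangulate and
cluster": the published description of the original C++ implementation
does not fix the rules, so equality with it cannot be claimed -- only
fidelity to the published three-step outline, verified here against an
independent brute-force implementation of the same staged semantics.
Very old duplications whose copies survive in all genomes of a level
are delineated as separate groups when no third-genome evidence joins
them; that is inherent to BRH-based methods rather than a bug. The
all-vs-all stage is exact and quadratic: fine for desk-scale studies
(hundreds of genes align in seconds, a 600-gene six-genome study in
under a minute), but thousands of proteomes require an external
prefiltering aligner feeding the hits format.
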