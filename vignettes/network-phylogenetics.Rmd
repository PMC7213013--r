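---
title: "Network phylogenetics with haplonet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network phylogenetics with haplonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplonet)
```

## The problem this package addresses

At shallow evolutionary depths — within a genus, between closely related
species — individual markers carry few consistent mutations. The likelihood
surface over tree space is then nearly flat, and a single bifurcating tree
both overstates and understates the signal: it overstates because arbitrary
resolutions of soft polytomies get drawn, and understates because equally
parsimonious alternatives and ancestor–descendant relationships are
invisible. Parsimony-style *networks* are the standard answer: they show all
equally good connections at once and depict ancestors as interior nodes.
`haplonet` implements that workflow end to end for multi-marker sequence
data:

1. **Alignment diagnostics** — per-region summaries (duplicate sequences,
   gappyness, distinct alignment patterns) that tell you how much signal a
   marker has before you invest in inference.
2. **Recoding** — plastid spacers and introns are length-polymorphic;
   treating every gapped column as an independent character badly inflates
   mutation counts. Four pattern categories (SNP, indel, length-polymorphic
   tract, oligo-nucleotide motif) reduce the alignment to one character per
   mutational *event*.
3. **Median-joining (MJ) networks** on the recoded matrix, with collapsing
   into haplotype groups for readability.
4. **Statistical parsimony (SP) networks** on genotype data under an
   infinite-site model, with ancestral/derived classification.
5. **Bootstrap consensus split systems** from tree sets, including a
   bootstopping criterion that decides how many pseudoreplicates suffice.
6. **Outgroup placement rooting** — maximum-likelihood placement of
   outgroup queries on a fixed ingroup tree, aggregated into per-scenario
   root probabilities `p_R`.

## Models and procedures

### Diagnostics

For an alignment of `n` taxa and `m` columns:

* `nld` = `n` − number of distinct row strings (exact match after
  uppercasing). It counts duplicates *beyond the first occurrence*.
* `puc` = proportion of cells in the undetermined set, by default
  `{-, ?, N}`. IUPAC partial ambiguities (R, Y, W, …) are *determined*:
  they carry information and are not gappyness.
* `dap` = number of distinct column vectors, gap states included, with no
  pattern weighting. This is the simplest reproducible reading of
  "distinct alignment patterns".

### Recoding categories

* **SNP** — any leftover variable column emits one character whose states
  are the bases; gaps and `N`/`?` become a missing state that never enters
  distances.
* **INDEL** — maximal gap runs sharing identical start/end across the taxa
  bearing them are one event, recoded as a binary presence/absence
  character. Taxa gapped over a sub- or super-range get the missing state
  (partial overlap is evidence of a different event, not of this one).
  When candidate runs overlap, the best-supported run is kept and
  overlapping candidates are dropped, so events are pairwise disjoint.
* **LP** — homopolymer (and similar) tracts vary in copy number far faster
  than point mutation; pure length variation is therefore *not* a
  character. An LP event contributes characters only for point mutations
  internal to the tract. Detection flags maximal runs of columns whose
  majority base is constant, at least `min_run = 5` columns wide (a
  typical homopolymer-instability threshold) and containing at least one
  gap.
* **ONM** — short motifs with linked mutations (including inversions, e.g.
  pseudo-hairpin stems) are one multistate character: one state per
  distinct motif variant, either user-annotated via a variant map or by
  automatic distinct-substring labelling. Linked mutations cannot be
  *inferred* reliably without expert judgement, so the detectors assist
  but an expert event table is authoritative; inversions must be
  user-annotated.
* **EXCLUDE** — hypervariable regions that are only alignable among close
  relatives (the "high-div" situation) are dropped outright. Their
  coordinates are data-dependent and are therefore an input, not a
  constant.

### Median-joining networks

`median_joining()` follows the published algorithm: (i) build the minimum
spanning network (MSN) — all links `(u,v)` with `d(u,v)` at most the
bottleneck connection cost plus `epsilon`; (ii) for every node triplet with
at least two links, compute the majority-state median vector and add it if
new; (iii) iterate to closure; (iv) delete obsolete medians (degree ≤ 2 and
on no shortest path between observed haplotypes) to a fixed point after
each round.

Numerical/design choices:

* `epsilon = 0` by default. The tolerance is exposed but the published
  networks this workflow reproduces use program defaults, which correspond
  to 0.
* For multistate characters, a 3-way tie has no majority; the quasi-median
  convention keeps each parental state. The expansion is capped
  (`quasi_cap = 1000` vectors per triplet, generated in deterministic
  lexicographic order) because full quasi-median closure can explode.
* A `max_nodes` guard (default 5000) truncates pathological inputs with a
  warning; data divergent enough to hit it has no meaningful MJ network.
* **What the network guarantees.** Every MST edge of the final node set is
  present (the MSN is the union of all MSTs). An MST edge of the
  *observed* matrix survives as a connection whose every link costs at
  most that edge's weight — but after medians are inserted, link
  recomputation can replace the direct link by a bottleneck-smaller path
  whose *additive* length exceeds the Hamming distance. This is a property
  of the algorithm itself, reproducible by hand on 5-haplotype binary
  matrices, and is why the test suite asserts additive realization only on
  exhaustively verified small families and bottleneck realization in
  general.

Collapsing (`collapse_groups()`) reports, per group, the maximum
within-group path cost ("dimension") and, per adjacent group pair, the
minimum direct link cost — the circle-size/edge-length semantics of
collapsed MJ figures. Median nodes without a user assignment go to the
nearest group by weighted graph distance, ties to the alphabetically first
group; the assignment rule for connective medians in published figures is
not documented anywhere, so this convention is ours and is deterministic.

### Statistical parsimony networks

`sp_network()` connects genotypes by a Kruskal MST on substitution Hamming
distances with a fully deterministic tie order (weight, then genotype id
pair); every tree edge of length `d` is subdivided by `d − 1` missing
intermediates so each drawn link is one mutational step. When two
components merge at weight `w`, every other cross-component pair at
distance exactly `w` is emitted as a dashed *alternative link* — the
deterministic reconstruction of "equally parsimonious connections". No
connection (parsimony) limit is applied: the network is connected in full,
and indel variation is excluded from distances (it remains available as
subtype metadata on the genotypes).

`classify_centrality()` reports two readings of "ancestral": distance to
the unweighted majority consensus (0 = consensus-identical) and graph
eccentricity in steps (centre vs periphery).

### Consensus split systems and bootstopping

Splits are canonical bitmasks over the sorted taxon universe (smaller side;
ties broken toward the side holding the first taxon). `split_frequencies()`
counts each split once per tree. `consensus_network()` keeps splits at or
above a frequency threshold (default 0.1 — consensus networks exist to
display minority signal; above 0.5 the retained set is provably a tree).
`bootstop()` implements the extended majority-rule convergence criterion:
at checkpoints every `step` trees, random half-splits of the first `n`
trees are summarized by greedy majority-rule-extended consensus (splits by
descending frequency, accepted when compatible with all accepted; ties
broken lexicographically) and compared by Robinson–Foulds distance
normalized by `2(n_taxa − 3)`. Defaults — step 50, 100 permutations,
cutoff 0.03, quorum 0.99 — are the a-posteriori convention associated with
the criterion; the constants are exposed because the criterion's name does
not pin them down.

### Placement rooting

The likelihood engine is standard Felsenstein pruning over JC/HKY/GTR with
an optional discrete-Gamma mixture (4 categories, mean-per-quantile
discretization). Site-rate heterogeneity approximations that exist for
runtime reasons elsewhere are represented here by discrete-Gamma, which is
reproducible to machine precision. `place_query()` attaches the query at
the midpoint of each reference edge and optimizes only the pendant branch
(bounded 1-D maximization, tolerance 1e-4, bounds [1e-8, 2]) — the fast
placement heuristic; per-edge log-likelihoods are normalized into
likelihood weight ratios via log-sum-exp, so `sum(lwr) = 1` by
construction. Ties for the best edge break toward the lexicographically
smallest canonical edge id (the sorted smaller-side tip labels), which
makes placement reproducible across tip orderings and rerootings.

`aggregate_root()` averages, over queries, the LWR mass falling on each
rooting scenario's edge set: `p_R(s) = (1/n_q) Σ_q Σ_{e∈s} lwr_q(e)`.
Scenario edge sets must be disjoint; uncovered edges are binned as
`other`, so the reported vector is a probability distribution. All
placements are averaged (no LWR cutoff) — whether published analyses
truncated small weights is generally unstated, so the transparent default
is no truncation. Model parameters are estimated once on the reference
alignment (`estimate_model()`, direct numerical maximization, relative
tolerance 1e-6) and then held fixed during placement.

## The synthetic-data generator

`sim_config()` / `simulate_tree()` / `evolve_alignment()` emulate the
mutation classes seen in length-polymorphic plastid spacers: point
substitutions on a Yule or coalescent tree; indel events (deletions and,
with probability 0.2, duplications — duplications and deletions dominate
over novel insertions in such data) with geometric lengths (mean 4);
conserved homopolymer tracts drifting by ±1 copy; three-variant
oligo-nucleotide motif switches; and reverse-complement window inversions.
Branch lengths are scaled by `branch_scale = 0.1` by default, putting
pairwise divergence in the few-percent range typical of intrageneric
plastid data. Event intervals are kept disjoint with a one-column buffer
so the recorded truth identifies each event unambiguously — real spacers
do have overlapping events, which is precisely the situation the detectors
do *not* claim to resolve and where the expert event table takes over.
Everything is deterministic given the configuration seed (tree:
`seed`; sequences: `seed + 1`; planted queries: `seed + 2`).

The infinite-sites generator (`simulate_infinite_sites()`) uses a
sampled-ancestor birth model: each new genotype copies an existing one and
adds one mutation at a fresh character. Under it, the true genealogy is
exactly recoverable — the unique MST — and total steps equal the number of
variable characters. This is deliberate: with *unsampled* internal
genotypes the step count exceeds the character count and no method could
tell recovery failure from sampling artefact. Passing those tests
therefore shows algorithmic correctness under the model's assumptions, not
performance on data with unsampled ancestors, homoplasy or recombination.

Placement-recovery fixtures plant queries on edges in the upper half of
the reference edge-length distribution: a query planted on a near-zero
edge is unidentifiable in principle, and a recovery rate over such edges
would measure tree shape, not the placement engine.

## Problem sizes

The test suite runs at desk scale by design: diagnostics oracles on 200
random alignments up to 50×200; MJ checks exhaustively over all
3-haplotype subsets of the 4-character binary hypercube and all
4-haplotype subsets of the 3-character one, plus seeded 5×8 cases; 50
infinite-sites replicates of 10 genotypes; 600-tree topology mixtures;
likelihood exhaustion over all one-site patterns for 2–4 leaves; 20
placement replicates at 10 taxa × 1500 sites. The acceptance script
recomputes the same pipeline quantities on a 60-taxon, ~800-column
synthetic region and reports them as JSON.

## Known limitations

* The recoding detectors handle clean, disjoint events; staggered or
  overlapping gap runs are resolved greedily by support and everything
  else belongs in the expert event table. Inversions and linked motifs are
  never auto-discovered.
* MJ networks are meaningful for low-homoplasy, intra-clade matrices; on
  divergent inputs the quasi-median landscape grows quickly (hence the
  node cap) and the result, while well-defined, is not interpretable.
* SP networks apply no statistical connection limit; for very divergent
  genotype pairs the single-step chain is a parsimony statement, not a
  probability statement.
* The placement engine optimizes the pendant branch only. This is the
  standard fast heuristic and what keeps 20-replicate recovery experiments
  in seconds; it slightly underestimates likelihoods on edges adjacent to
  the true attachment when the reference branch lengths are badly wrong.
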