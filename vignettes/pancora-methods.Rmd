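---
title: "Methods: pan/core-genome partitioning, clade structure and gene-level screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan/core-genome partitioning, clade structure and gene-level screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pancora analyzes collections of bacterial genomes through their
orthologous gene families: which families are shared by all genomes, how
the gene repertoire grows as genomes are added, how genomes group into
clades, and which individual genes tell a different evolutionary story
than the genome-wide signal. This vignette documents the models and
numerical choices behind each stage, what the synthetic-data generator
does and does not emulate, and the design decisions that were genuinely
open.

## The pipeline at a glance

1. **Quality filter.** Genomes whose gene count falls outside
   mean ± 2σ are dropped. σ is the population (divide-by-*n*) standard
   deviation, computed once over all input genomes; the filter is not
   iterated. Poorly assembled genomes otherwise deflate the core genome
   drastically — restoring three deliberately broken genomes is known to
   cut a species core by more than half.
2. **Similarity graph.** Every candidate gene pair is aligned with
   Smith–Waterman (BLOSUM62, affine gaps 11/1 — the customary protein
   defaults). Significance is estimated with the Karlin–Altschul formula
   `E = K·m·N·exp(−λS)` with published gapped-BLOSUM62 constants
   `K = 0.041`, `λ = 0.267`, with `N` the total residue count of the
   dataset. An undirected edge requires `E < 1e-5` **and** coverage
   ≥ 75% *of both sequences*. The classic tool's coverage flag is
   directional; demanding both sides is stricter and symmetric, which the
   graph requires anyway.
3. **Markov clustering.** Edges are weighted `−log10(max(E, 1e-200))`.
   Self-loops are set to each column's maximum before normalization;
   expansion/inflation alternate with entries `< 1e-6` pruned, until the
   maximum entry change is `< 1e-6` (cap 200 iterations, error on
   non-convergence). Inflation defaults to 1.5, the wrapped OMCL default —
   the primary literature rarely reports this value. There is no
   best-bidirectional-hit seeding: plain MCL runs over the full inter- and
   intra-genome graph, so paralogs may co-cluster; per-genome copy counts
   are kept so family expansions remain visible.
4. **Partitioning.** Occupancy counts each genome once regardless of
   paralogs. Core = all genomes; softcore = at least `ceiling(0.95·n)`
   genomes (core ⊆ softcore); cloud = at most 2; shell = the rest, so
   `|softcore| + |shell| + |cloud| = |pan|` always. The rounding rule for
   "95% of genomes" is not standardized; the ceiling was chosen so the
   softcore never dips below 95%. Consequence: for 19 genomes
   `ceiling(0.95·19) = 19`, so no family can be softcore-but-not-core at
   that size — sizes just below n·0.95 land in the shell.
5. **Rarefaction.** Genome orderings are permuted (by default as many
   times as there are genomes); pan/core sizes are tracked cumulatively.
   The pan-genome is called *closed* when the mean marginal gain over the
   last `max(5, n/5)` steps is ≤ 5 genes/genome, *open* otherwise —
   thresholds configurable; the published criteria are verbal ("~50
   genes" vs "4–5 genes" per added genome).
6. **Identity clustering.** Genome-pair identity is the mean percent
   protein identity over all co-clustered gene pairs spanning the two
   genomes (protein, not nucleotide, because the similarity stage is
   protein-based). Pairs sharing no cluster are imputed with the matrix
   minimum, preserving least-similar semantics, with a warning. Rows are
   compared with the Gower distance (mean of range-normalized absolute
   differences; zero-range columns contribute 0), then agglomerated under
   average linkage (single/complete available). Merge ties are broken by
   the lexicographically smallest pair of cluster representative names, so
   dendrograms are reproducible. Clades come from cutting the dendrogram
   into `k` groups.
7. **Gene-tree screen.** Each single-copy core family is aligned
   (center-star: the sequence with minimal summed pairwise distance is the
   center; others merge against it under "once a gap, always a gap"),
   distances follow Jukes–Cantor `d = −(3/4)·ln(1 − 4p/3)` with pairwise
   deletion of gapped sites, and trees are built by neighbor joining
   (Q-ties broken lexicographically, negative branch estimates clamped to
   0). Saturated pairs (`p ≥ 0.75`, where the model diverges) are capped
   at `d = 5` and flagged rather than erroring, as distance software
   conventionally does. Each gene tree is compared to the reference
   topology (by default the identity dendrogram) with the *nodal
   distance*: the RMSD between leaf-pair path-length matrices, path
   lengths in edge counts on the unrooted topologies. Each gene also gets
   a baseline of 10 random topologies (mean ± sd), and both the raw and
   baseline-normalized scores are reported — whether the classic
   implementation normalizes before ranking is unclear, so neither is
   hidden. Genes below the 5% and above the 95% percentile (linear
   interpolation between order statistics) form the tails.
8. **SNPs and ecoSNPs.** The consensus takes the per-column majority base
   (ties alphabetically, all-gap columns become `N`). Two gene-level SNP
   totals are reported side by side — the per-strain mismatch sum
   ("sum SNP") and the variable-column count — because published totals
   are often ambiguous between the two; neither is privileged. Columns
   with ≥ 3 bases are *polyvariable*. An *ecoSNP* is a gap-free, exactly
   dimorphic column in which no clade is split across the two states. For
   two clades this is precisely "state partition = clade partition"; for
   more clades the definition above is the coherent generalization of a
   dimorphic clade-diagnostic site (a strict two-state column cannot
   partition three clades singly). Columns with any gap are excluded —
   conservative by design.
9. **HGT screen.** A family is a transfer candidate when its presence
   fraction lies in [0.30, 0.70] (inclusive — the published rule states no
   strictness) in *every* clade: genes carried by only a subset of strains
   of each clade are the expected footprint of genes moving between
   clades.
10. **Enrichment.** Per functional category (user-supplied gene→category
    table, many-to-many allowed), the fold increase core→pan and
    softcore→pan is computed on unrounded counts and displayed rounded
    half-up to one decimal. Significance uses a two-sided Fisher's exact
    test on `[[category in core, other core], [category in pan, other
    pan]]` — the category-against-pooled-remainder design; the original
    table's orientation is not printed anywhere, but the p-value is
    invariant under transposition. The flag threshold is p < 0.01 and no
    multiple-testing correction is applied, matching the source analysis.

## The synthetic world

`simulation_config()` describes the world the test suite runs on; its
defaults are the acceptance conditions: 2 clades × 10 genomes, 400
families (150 core, 50 softcore, 110 shell, 80 cloud, 10 HGT), 3 planted
ecoSNP columns in each of 5 flagged core families, 2 outlier genomes,
CDS lengths ~ N(450, 120²) truncated at 300 nt and rounded to codons,
5% between-clade and **zero** within-clade divergence. Zero within-clade
noise is the stated recovery condition, not a convenience: recovery under
noise is exercised separately as a property (ecoSNP recall must fall
monotonically as within-clade mutation rises).

Generation is hierarchical: family ancestor → one mutated copy per clade
(between rate) → one mutated copy per genome (within rate). There are no
indels by default, which keeps the alignment stage exact and lets each
downstream stage be tested in isolation. Occupancy classes are planted
inside the partition bands; shell families fill whole clades in random
order and cloud families stay within one clade, which guarantees that no
background family can sit inside the 30–70% band in *every* clade — so
the HGT screen's planted precision/recall of 1 is a property of the
stated world, not luck.

Two subtleties deserve emphasis:

* **Emergent ecoSNPs.** With two clades and nonzero between-clade
  divergence, *every* between-clade substitution column in a core family
  is a genuine clade-diagnostic dimorphic site — indistinguishable from a
  planted one. The generator therefore records all such columns into the
  truth (planted ones flagged), scanning final sequences with its own
  family bookkeeping rather than the pipeline's clustering/MSA machinery.
  Flagged families additionally skip between-clade background mutation, so
  their only diagnostic columns are the planted ones. Detection is scored
  against the complete diagnostic set.
* **Outliers.** Outlier genomes are copies of real genomes inflated by
  whole-family duplications until they exceed the non-outlier mean by
  `max(4σ, 30%)`. The margin is deliberately larger than the 2σ filter
  band because the outliers themselves inflate the pooled mean and σ the
  filter is computed from.

What the generator does **not** emulate: realistic codon usage and GC
content, indels and assembly fragmentation, recombination tracts,
phage/transposon sequence models, and rate heterogeneity across sites. A
green truth-recovery test therefore establishes that the machinery is
correct on clean, clade-structured input — not that the thresholds are
robust to real-data artifacts.

## Numerical and engineering choices

* **Candidate pairing.** All-vs-all Smith–Waterman is quadratic in gene
  count, so pairs are prefiltered by shared amino-acid 5-mers (≥ 3
  shared, k-mers seen in > 200 genes ignored). For families at ≥ 95%
  identity the filter is lossless; truly remote homologs (< ~40%
  identity) could be missed — acceptable here because the E-value gate
  would discard them anyway at these sequence lengths.
* **Alignment engine.** Pairwise alignment is delegated to
  Biostrings' Smith–Waterman/Needleman–Wunsch implementation behind the
  package's own hit contract; E-values, gates, MCL, NJ, Gower, the
  agglomerator, center-star merging, consensus/SNP logic and Fisher's
  test are implemented in the package and cross-checked against
  independent oracles in the test suite (exhaustive clique-graph
  components, `stats::hclust`, additive-matrix recovery over all small
  topologies, `stats::fisher.test`).
* **Determinism.** Every stochastic stage takes a seed; sub-seeds are
  derived arithmetically from the one pipeline seed. `mutate_sequence`
  and friends restore the caller's RNG state. Identical configuration and
  seed give byte-identical artifacts (the manifest's checksums are
  compared in the tests).
* **Degenerate inputs.** Fewer than 3 genomes: partitioning errors, the
  quality filter warns and keeps everything. A gene-tree screen in which
  the 5% and 95% cutoffs coincide (e.g. all distances equal) warns and
  returns empty tails instead of arbitrary ones. Zero-range Gower columns
  contribute zero. All-gap consensus columns become `N`. Fisher tables
  use a `1e-7` relative tolerance when summing probabilities "at most as
  likely as observed", the standard guard against floating-point ties.

## Known limitations

* Identity is protein identity from the similarity stage; "average
  nucleotide identity" in the strict genomic sense (nucleotide-level,
  fragment-based) would differ in absolute value, though not in the
  induced clustering on these data.
* The center-star alignment is exact for the no-indel world it serves; it
  is not a replacement for a progressive aligner on indel-rich input.
* E-values use fixed Karlin–Altschul constants rather than per-search
  fitting; scores are blastp-*scale*, not blastp-identical.
* The pipeline is single-process by contract; at the scale of hundreds of
  genomes the alignment stage is the bottleneck and would need a
  parallel map over candidate pairs.
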