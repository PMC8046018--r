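---
title: "screp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screp: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screp)
```

`screp` analyzes paired-chain single-cell immune repertoires (BCR heavy +
light, TCR beta + alpha) and integrates them with the same cells'
transcriptomes. This vignette explains the models and procedures behind each
stage, the tunable parameters with their defaults and rationale, the
numerical conventions, what the bundled simulators do and do not emulate,
and the design choices we made where the field's practice is genuinely open.

## 1. From contigs to cells

The input unit is a cellranger-style contig table: one row per assembled
receptor chain per cell barcode, with gene calls, CDR3 nucleotide and
amino-acid sequences, UMI and read support, and quality flags. We retain
contigs that are productive, high-confidence, called as cells, and carry a
non-empty CDR3 (`filter_contigs()`), then assemble one cell record per
barcode (`assemble_cells()`):

* Chains are classed *heavy-like* (IGH, TRB) or *light-like* (IGK, IGL,
  TRA); a cell is *paired* when it has exactly one of each after
  resolution.
* Within a class, the highest-UMI contig wins; ties break by read count,
  then lexicographic contig id. This makes assembly deterministic and
  invariant to input order — a property the tests assert.
* Barcodes mixing B and T chains are always dropped as suspected doublets.
  Barcodes with two or more same-class chains are dropped under the default
  `doublet_policy = "drop"` (conservative: we never fabricate a pairing) or
  resolved to the top-UMI contig under `"keep_top_umi"`. Upstream pipelines
  do not document their own resolution, so both policies are exposed rather
  than guessed at.
* Unpaired barcodes are kept in a side table and excluded from clonotyping,
  because every clone definition below concatenates both CDR3s.

Isotype derives only from the heavy constant gene, by prefix:
`IGHA*`→IgA, `IGHG*`→IgG, `IGHM`→IgM, `IGHD`→IgD, `IGHE`→IgE, `TR*C*`→TR,
anything else→unknown.

## 2. Clonotyping strategies

A clone approximates a set of cells descending from one V(D)J
recombination event. `clone_strategy()` implements five operationalizations,
ordered here from fragmenting to merging:

| strategy | cells grouped when | behavior |
|---|---|---|
| `cdr3.nt` | identical CDRH3+CDRL3 nucleotides | splits somatic variants |
| `cdr3.aa` | identical CDRH3+CDRL3 amino acids | merges synonymous variants |
| `hvj.lvj.cdr3length.cdr3homology` | genes + lengths + CDR3 homology ≥ t | merges SHM variants |
| `hvj.lvj.cdr3lengths` | V/J genes + CDR3 lengths | ignores CDR3 content |
| `hvj.lvj` | heavy/light V and J genes only | over-merges |

Formally, the homology strategy first gates cells on identical
(heavy V, heavy J, light V, light J) gene names — allele suffixes such as
`*01` are stripped, since upstream tools emit them inconsistently — and
identical CDRH3/CDRL3 amino-acid lengths. Within a gate all concatenated
CDR3 strings have one length $L$, so similarity is well defined without
alignment:

$$\mathrm{sim}(a,b) = 1 - \frac{\mathrm{Hamming}(a, b)}{L},$$

and cells are merged by **single linkage** at
$\mathrm{sim} \ge t$ (default $t = 0.70$). Two choices here were open:

* *Concatenation vs per-chain homology.* We threshold the concatenated
  CDRH3+CDRL3 string. This matches the length-gated group structure, is
  $O(L)$ per pair, and weighs each chain by its length.
* *Single linkage.* Standard for clonal-lineage grouping (a lineage is a
  chain of mutational neighbors, not a ball around a centroid); it also
  gives clean limiting behavior, which the tests pin down: at $t = 1$ the
  strategy reduces to genes + identical CDR3 amino acids, at $t = 0$ to
  `hvj.lvj.cdr3lengths`, and counts are monotone along the refinement chain
  `hvj.lvj` ≤ `hvj.lvj.cdr3lengths` ≤ homology.

Clonotype ids are `<strategy>_<rank>` with rank by decreasing size, ties by
the lexicographic representative CDR3 nucleotide concatenation, so the
partition and its labels are reproducible regardless of input order.
Representatives are the modal (then lexicographically smallest) member
sequences.

## 3. Repertoire statistics

All statistics make the **cell-level vs clone-level** distinction explicit,
because published figures mix both:

* `isotype_per_clone()` counts *cells* per isotype inside each top clone
  (default top 30); row sums equal clone sizes exactly.
* `cdr3_length_distribution()` histograms combined CDRH3+CDRL3 amino-acid
  length over *clones*.
* `position_probability_matrix()` computes per-position residue
  frequencies of equal-length sequences — the matrix a probability-scaled
  sequence logo renders. Columns sum to 1 within 1e-9; rendering itself is
  out of scope.
* `vj_pairing_counts()` tabulates V–J gene pairs among the top clones
  (default 10) at cell level (default) or clone level, drops pairs below
  `count_threshold` (default 1) and flags pairs at `label_threshold`
  (default 50) — the counts behind a circos-style plot, which we do not
  draw.
* `diversity()` offers Shannon (natural log), Simpson and Gini–Simpson over
  clone sizes. The indices are not enumerated by our sources; this trio is
  the standard minimal set and the nats convention is stated rather than
  assumed.

## 4. Somatic hypermutation

SHM is quantified as substitution columns in an **end-to-end global
alignment** of a cell's full-length V(D)J nucleotide sequence against its
clone's germline reference, summed over heavy and light chains. The scoring
is match $+1$, mismatch $-1$, and an affine gap of length $k$ costs
$4 + k$ (open 4, extend 1 per base — the same convention as
Biostrings/EMBOSS). The aligner is a three-state Gotoh dynamic program in
C++ with a deterministic traceback (diagonal preferred over gap states), so
repeated runs give identical alignments.

Two reporting conventions were open and are resolved explicitly:

* **Gap columns are not mismatches.** Whether indel columns count toward
  "mismatch" totals is unstated upstream; we exclude them from the
  substitution count and report them separately (`gap_columns` attribute),
  so either convention can be reconstructed.
* **Alignment region.** We align over the full attached contig sequence as
  emitted by the FASTA, not a re-derived FR1–FR4 window; the germline
  reference is expected to cover the same region, which the simulator
  guarantees and real inputs approximate.

On indel-free pairs the substitution count equals the Hamming distance
exactly — the property the planted-truth tests use. Germline references are
looked up per clone from a FASTA keyed
`<raw_clonotype_id>_germline_heavy` / `..._germline_light` (the
per-clonotype reference analogue of cellranger's `concat_ref.fasta`); a
clone merged from several upstream clonotypes resolves to the modal id of
its members.

## 5. Clone lineage trees

`build_clone_tree()` concatenates heavy+light sequences per cell, collapses
identical concatenations into a single tip whose label carries the cell
count (`variant<i>_n<cells>`), prepends the germline as its own taxon,
computes all pairwise alignment distances (substitutions + gap columns),
infers a neighbor-joining topology (`ape::nj`) and roots it at the germline
tip. NJ was chosen because no inference method is prescribed, it is exact
on additive matrices (a property the tests verify on a constructed 4-taxon
case), and it needs no model fitting at repertoire scale. Degenerate cases
are explicit: one variant plus germline yields a two-taxon tree, and a
clone identical to its germline warns. Tip cell counts always sum to the
clone size, and the Newick text re-parses to the same topology.

On additive inputs the least-mutated variant is the tip closest to the
root by patristic distance (`root_to_tip_distances()`) — the package-level
analogue of spotting a near-germline expanded antibody.

## 6. Similarity networks

Clone–clone distance is the **sum of per-chain Levenshtein distances** on
amino-acid CDR3 representatives:
$d(a,b) = \mathrm{lev}(\mathrm{CDRH3}_a, \mathrm{CDRH3}_b) +
\mathrm{lev}(\mathrm{CDRL3}_a, \mathrm{CDRL3}_b)$.
Our sources describe the distance both as summed matrices and as "either
chain"; we follow the summed form (the more precise, procedural statement)
and keep the per-chain variant reconstructible from the two addends.
`build_network()` takes the top `top_n_per_sample` expanded clones of each
sample (default 60) and draws an undirected edge when $d <$ `threshold`
(**strictly** below, matching the "separated by less than" phrasing; the
tests pin the boundary at threshold 1 ⇒ only distance-0 edges). Vertices
carry sample and clone size; `cross_sample_components()` flags connected
components spanning two or more samples — the clonal-convergence readout.
Edit distances come from `utils::adist` (full DP) and are verified against
an independent DP oracle in the tests; the summed distance is a metric,
which the tests check on random triples.

## 7. GEX processing and integration

The transcriptome side is a deliberately minimal contract over standard
scRNA-seq machinery; correctness is asserted on planted-structure recovery,
not bit-level agreement with any one toolkit.

* `filter_cells_by_mito()` removes cells whose mitochondrial UMI fraction
  (genes prefixed `MT-`) is **strictly greater** than `max_fraction`
  (default 0.20); a cell exactly at 20% is retained.
* `remove_vdj_genes()` drops receptor segment genes
  (`IG[HKL][VDJ]*`, `IGH[ADEGM]*`, `TR[ABGD][VDJC]*`) before clustering so
  clonotype identity cannot drive the embedding; lookalikes such as `IGF1`
  or `TRIM28` survive the pattern.
* `cluster_cells()` log-normalizes to 10,000 counts per cell (`log1p`),
  takes the `n_hvg = 2000` most variable genes, reduces to `n_pcs = 10`
  principal components, builds a Jaccard-weighted shared-nearest-neighbor
  graph (k = 10) and clusters it with multilevel modularity (Louvain) at
  `resolution = 0.5` — the parameter set mirrors common practice for
  droplet data. Clustering is deterministic under a fixed seed, and the
  planted-cluster fixtures must be recovered at adjusted Rand index ≥ 0.9
  (they come back at 1.0). The upstream normalization used for publication
  figures (SCTransform) is *not* re-implemented; normalization is a
  pluggable contract here.
* `match_barcodes()` intersects VDJ and GEX barcodes after stripping a
  trailing `-<digit>` lane suffix; zero overlap is an error (almost always
  a suffix mismatch, so the message says so).
* `cluster_membership_per_clone()` gives, per expanded clone, the fraction
  of its GEX-matched cells in each transcriptional cluster (rows sum to 1;
  only cells present in both assays count). `sample_cluster_membership()`
  is the whole-sample analogue.
* `assign_phenotype()` labels cells from ordered marker definitions. A
  gene is "detected" when its **raw count exceeds 0** — with droplet RNA
  counts as sparse as these, any detection is the only threshold that does
  not silently drop most cells; the cutoff is exposed
  (`positive_threshold`) for deeper data. The default pair is memory-like
  (CD8A+, CD44+, SELL+, IL7R+, CCL5−) and effector-like (CD8A+, CD44+,
  CCL5+, SELL−, IL7R−); the SELL/IL7R/CCL5 constraints make the pair
  mutually exclusive, which a 2^5 enumeration test proves rather than
  assumes.
* `de_expanded_vs_unexpanded()` compares cells of clones with size > 1
  against singletons: per gene a Wilcoxon rank-sum test on log-normalized
  expression, average logFC as the difference of group means of `log1p`
  CP10K, BH adjustment across genes. This replaces the edgeR/limma path
  used upstream — Wilcoxon is the standard self-contained choice for
  scRNA-seq group comparisons and is documented as a substitution. Under a
  permuted-label null the p-value distribution is uniform (KS-tested in
  acceptance).
* `go_enrichment()` is the upper-tail hypergeometric test
  $P(X \ge k)$ for a hit list of size $n$ against sets of size $K$ in a
  universe of size $N$, with `ratio` $= k/K$ and BH across sets — verified
  against exhaustive enumeration of all $\binom{N}{n}$ draws for small
  universes.
* `gsea_preranked()` is the classic weighted Kolmogorov–Smirnov running
  sum: walking down the score-ranked list, hits add
  $|s_i| / \sum_{\mathrm{hits}} |s|$, misses subtract $1/(N-K)$, and the
  enrichment score is the signed maximum deviation. Significance permutes
  gene labels (`n_perm`, default 1000) with the +1 pseudocount, so $p > 0$
  always, and is reproducible at a fixed seed. Gene sets load from GMT via
  `read_gmt()`.

## 8. The simulators: what a green test establishes

`simulate_repertoire()` plants a stated world, not a tuned one: `n_cells`
paired cells (default 200) in `n_clones` lineages (default 40) with
power-law expansion (exponent 1.5 — a handful of large clones over a
singleton tail, the shape single-cell repertoires of a few thousand cells
actually show); each clone is a germline V/J pick from a fixed 12-sequence
300-nt mini-pool (`inst/extdata/germline_pool.fasta`) with a planted CDR3
pair (heavy 13–17 aa, light 9–11 aa, stop-free codons) spliced in after
nucleotide 150; member cells carry Poisson(`shm_rate`) substitutions per
chain (default 3; no indels by default, so alignment mismatches equal the
planted counts exactly); isotypes draw from IgA 0.45 / IgG 0.30 / IgM 0.25,
an IgA-leaning mix matching the convalescent-donor setting that motivated
the package. Everything is deterministic per seed, byte-identical across
runs.

`simulate_gex()` plants NB background counts (mu 0.3, size 2), disjoint
20-gene marker blocks per cluster (mu 5), six phenotype marker genes wired
to clusters 0 (memory-like) and 1 (effector-like), ten `MT-` genes scaled
so a planted 10% of cells exceed the 20% filter boundary while the rest sit
at 1–10%, and a configurable fraction of barcodes shared with a repertoire
(sampled across clones, so expanded and unexpanded clones both appear in
the GEX assay).

What the simulators do **not** emulate — and therefore what a green test
does not establish: real V(D)J junctional biology (no D-segment model, no
indels in junctions), SHM hot/cold spots and transition bias, isotype-
lineage coupling (isotypes draw independently per cell), ambient RNA,
doublets in the expression matrix, batch effects, or realistic gene–gene
correlation. Tests against this world establish *algorithmic* correctness
(exact recovery of planted quantities, invariants, oracle agreement), not
biological validity on real data.

## 9. Numerical conventions and degenerate inputs

* Hamming/Levenshtein and alignment scores are exact integer/rational
  arithmetic; the only tolerances in the package are 1e-9 on probability
  row/column sums.
* Tie-breaks are total orders everywhere (UMIs → reads → contig id; size →
  representative CDR3 → clonotype id), so every output is reproducible.
* Empty contig files warn and return empty tables; empty repertoires
  clonotype to zero clones; a clone identical to its germline warns and
  yields a two-taxon tree; missing phenotype genes warn and count as
  undetected; missing germline references skip the clone with a warning in
  aggregate SHM and error in single-clone calls.
* Seeds: every stochastic routine takes an explicit seed argument; nothing
  reads global RNG state implicitly except via those seeds.

## 10. Known limitations

* CDR3 homology is Hamming-based within length gates; lineages that
  acquired junction indels will split. A per-chain or alignment-based
  homology mode would relax this.
* SHM alignment scoring is fixed to one parameter set (exposed as
  arguments) and aligns full attached sequences, not MiXCR-exact VDJRegion
  coordinates.
* The clustering contract is a reference implementation (PCA + SNN +
  Louvain); it is not a drop-in reproduction of Seurat or scran output and
  is validated only on planted structure.
* GSEA permutes gene labels, not phenotypes; with few samples that is the
  only option, but it tests a weaker null than phenotype permutation.
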