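---
title: "Delineating prokaryotic species from gene-level genome comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating prokaryotic species from gene-level genome comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ganiclust)
```

## The model

`ganiclust` measures the genomic relatedness of two prokaryotic genomes
from their protein-coding gene sequences alone.  For a genome pair (A, B)
it computes two complementary directional statistics over the set of
bidirectional best hits (BBHs) between their genes:

* **Alignment fraction.**
  AF(A→B) = Σ len(A-side BBH genes) / Σ len(all genes of A).
  AF is a gene-content statistic: 0 means no orthologs were retained, 1
  means every coding base of A sits in a retained ortholog pair.
* **Genome-wide average nucleotide identity.**
  gANI(A→B) = Σ (identity_i × aln_length_i) / D, summed over BBHs.
  With the default denominator D = Σ len(A-side BBH genes)
  (`bbh_gene_lengths`), short alignments are penalised relative to their
  genes; with D = Σ aln_length_i (`alignment_lengths`), gANI is the
  length-weighted mean percent identity of the BBH alignments and is the
  same in both directions.  Both readings of the definition appear in the
  method's literature; the package implements both and defaults to the
  gene-length denominator, read direction-wise for consistency with AF's
  explicit source-genome denominator.

A BBH is a gene pair that is mutually the best-scoring hit between the
two genomes, retained only if it shows **at least 70% identity over at
least 70% of the shorter gene** (both bounds inclusive).  Undefined gANI
(no retained BBHs) is propagated as `NA` and fails every downstream
threshold.

Two genomes are called conspecific when **min(AF(A→B), AF(B→A)) ≥ 0.6**
and **min(gANI(A→B), gANI(B→A)) ≥ 96.5**.  On the graph with these edges,
`enumerate_maximal_cliques()` (Bron–Kerbosch with pivoting) lists all
maximal cliques — complete-linkage clusters in which every genome pair is
species-level linked.  Cliques sharing genomes are consolidated into
*clique-groups* (connected components of the clique-overlap meta-graph,
membership = union of the constituent cliques), which flag species whose
members form a genetic continuum with some below-threshold pairs, e.g.
through genome reduction in one lineage.  Genomes with no qualifying edge
are *singletons*.  Clusters always partition the input collection.

Named species are then audited against the clusters: a species is
*single* or *multiple* according to whether it occupies one or several
clusters/singletons, and *homogeneous* or *heterogeneous* according to
whether any occupied non-singleton cluster also holds a different named
species.  Unlabeled genomes (`NA`, empty, `unclassified`, genus-only
`sp.`) never make a cluster heterogeneous; they are retained solely to
receive assignment proposals when their cluster's labeled members agree
on one species, and entirely unlabeled clusters are reported as candidate
novel species.  Clusters holding type strains of two or more species are
flagged as naming conflicts.

Finally, the empirical intra-species probability model estimates, from
labeled pair results,

P[AF = a, ANI = b] = P[AF = a] · P[ANI = b | AF = a]

by binned histograms over intra-species pairs (each pair symmetrized by
the minimum over its two directions, matching the minimum-pairwise edge
rule; a mean option is provided).  `intra_species_probability()` looks up
the joint probability of a new (AF, gANI) observation, and
`probability_cutoff()` converts labeled intra- plus inter-species pairs
into a probability threshold at a chosen inter-species false-positive
rate (the 1 − FPR quantile of the inter-species pairs' probabilities).

## The aligner

Gene-versus-gene search uses k-mer seeding followed by exact affine-gap
local dynamic programming, emulating the dictionary-lookup design of
BLAST-like tools while keeping the reported alignment exactly optimal:

* candidate pairs must share at least one exact `word_size` (default 11)
  nucleotide word; pairs sharing none report no hit;
* scores: match +1, mismatch −1, gap of length L costs −5 − 2L;
* identity = 100 × matches / alignment columns (gap columns included);
  `N` never matches, including against another `N`;
* problems up to 300,000 matrix cells run the full exact DP; larger
  problems restrict the DP to the diagonal band spanned by all shared
  seed words plus a 32 bp margin.  Near-identical orthologs seed their
  own diagonals, so the banded optimum coincides with the full optimum
  in practice, and every oracle-equivalence test in the suite runs below
  the threshold where the two are identical by construction;
* determinism: the end cell is the maximal-score cell earliest in
  row-major order; traceback prefers diagonal, then vertical, then
  horizontal moves and closes gap runs as early as possible; best hits
  break ties by score, identity, alignment length, then lexicographic
  subject id.  BBH statistics are always taken from the direction whose
  query genome id sorts first, so both argument orders report identical
  tables.

CDS sequences are conventionally stored 5′→3′ on the coding strand, so
only the forward strand is searched by default; `both_strands = TRUE`
additionally tries the reverse complement of the query and keeps the
better alignment, for collections whose upstream annotation occasionally
emits the wrong strand.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `word_size` | 11 | bp | seed word; smaller finds weaker similarity, slower |
| `min_identity` | 70 | % | BBH retention, inclusive |
| `min_cov` | 0.7 | fraction of shorter gene | BBH retention, inclusive |
| `af_min` | 0.6 | fraction | species edge rule, inclusive |
| `gani_min` | 96.5 | % | species edge rule, inclusive |
| `denominator_mode` | `bbh_gene_lengths` | — | see above |
| `af_bin_width` | 0.01 | AF units | probability model |
| `gani_bin_width` | 0.1 | % | probability model |
| quality filter | 700–1200 genes/Mb, < 2500 scaffolds | — | advisory |

Coding-density bounds are treated as inclusive and the scaffold bound as
strict; the published wording fixes only the scaffold reading, so the
density reading is this package's choice and both are configurable.  The
quality filter is advisory: it reports, and the caller (or the CLI's
`--drop-failing`) decides whether failing genomes are excluded.

## The synthetic-data generator

`generate_ancestor()` draws i.i.d. uniform-base genes; at the sizes used
(tens to hundreds of genes of several hundred bp) distinct genes share no
11-mer with overwhelming probability, so each gene's only credible
ortholog in a derived genome is its own descendant.  `evolve_genome()`
applies, deterministically given a seed:

* **substitutions** — exactly `floor(d·L)` distinct positions per gene,
  each to a different base.  Exact counts (rather than per-site Bernoulli
  draws) make analytic identities exact: a gene of length L diverged at
  d = 0.02 has identity exactly 98%.  Gene lengths are drawn from the
  multiples of 100 bp spanning `mean_len` ± 50%, so `d·L` is integral
  for percent-scale divergence values;
* **gene loss** — `ceiling(g·n)` whole genes chosen uniformly at random.
  Loss is uniform over genes, not length-stratified, so the *length*
  fraction removed fluctuates around `g` with a standard deviation of
  about 0.01 at 200 genes; count-based quantities are exact while
  length-based AF is exact only for equal-length genes;
* **indels** — `floor(rate·L)` single-base insertions or deletions;
* **truncation** — `floor(t·L)` bases clipped per gene, split randomly
  between the 5′ and 3′ ends, emulating genes broken at contig
  boundaries in draft assemblies.

`plant_collection()` builds three reusable scenarios with recorded truth:
`fig2d` (seven species realizing all four audit categories),
`clique_group` (four full genomes plus two complementarily gene-reduced
ones, forcing two overlapping cliques that consolidate into one
clique-group), and `bacillus_like` (three clusters with inter-cluster
gANI inside (92, 96.5), i.e. related above background but below the
species threshold).

What the generator does *not* emulate: codon structure, rate
heterogeneity, horizontal transfer, paralogy, rearrangement, and real
base composition.  Passing tests therefore demonstrate the correctness of
the computations and the internal consistency of the thresholds, not the
biological adequacy of those thresholds for real collections — the
latter rests on the published large-scale evidence for this family of
methods.

## Numerical choices and degenerate inputs

* Threshold comparisons on derived floating-point quantities use a 1e-9
  slack so that, e.g., an alignment of exactly 0.7 × 100 columns passes
  the coverage bound despite `0.7 * 100` exceeding 70 in double
  arithmetic; histogram binning adds the same guard before `floor()`.
* Probability bins are left-closed right-open with the last bin closed;
  symmetrized gANI below the 70 support edge (possible only in
  `bbh_gene_lengths` mode) is clamped into the first bin, counted and
  warned about.
* Genomes appearing in no pair row become isolated nodes, so clustering
  output always covers the collection; `NA` gANI always fails the edge
  rule; duplicated conflicting pair rows are an error, exact duplicates
  are tolerated.
* A genome compared with itself pairs every gene with its own copy
  (AF = 1, gANI = 100); same-id hits are not suppressed.
* Genes shorter than `word_size` can never seed and thus never hit.

## Design decisions on genuinely open points

* **gANI denominator.** Both published wordings are implemented; the
  gene-length reading is the default because it comes from the
  operational description of the algorithm.  The modes agree exactly
  whenever alignments are full-length.
* **Draft robustness is a statement about identity, not gene lengths.**
  Clipping intact genes cannot change which bases agree, and
  `alignment_lengths`-mode gANI (≈ 99% for a pair diverged at 1%)
  and AF (still 1.0 in both directions: AF counts whole BBH gene
  lengths) are insensitive to 25% end-truncation.  The gene-length
  denominator instead charges clipped bases to the intact parent genes
  — 25% truncation drags gANI(parent→draft) to roughly 0.75 × 99 ≈ 74
  — so it conflates assembly draftiness with sequence divergence.  The
  package's draft-robustness checks therefore run the pipeline in
  `alignment_lengths` mode; real draft assemblies, where only the
  minority of genes abutting contig breaks are truncated, sit between
  the two extremes.
* **Clique-group membership** is the union of the constituent cliques,
  and transitively overlapping cliques merge into one group.
* **Category counting** uses occupied units: singletons count, and a
  species occupying two or more units (even one singleton plus one mixed
  clique) is "multiple".
* **Probability bin widths** (0.01 AF / 0.1 gANI) are package defaults
  chosen to resolve the thresholds' granularity; the published lookup
  table's granularity is not documented.
* **Edge thresholds** default to AF ≥ 0.6 / gANI ≥ 96.5 from the
  method's operational description (a figure caption in the source
  literature shows AF ≥ 0.5 for display); both are configurable.

## Problem sizes used by the tests

The suite works at desk scale, chosen so the full run stays interactive
on one CPU: self- and divergence checks use 20–200 genes of mean
300–900 bp; the aligner is validated against an independent exact
dynamic-programming oracle on 100 random pairs up to 500 bp plus exact
affine-gap cases up to 60 bp; clique enumeration is validated against
brute-force enumeration of all 4096 vertex subsets on 50 random
12-vertex graphs; scenario pipelines use 6–15 genomes.  The published
corpus-scale numbers (tens of millions of pairs, thousands of species)
are outside this package's test scope by design.

## Known limitations

* The banded aligner can, in principle, miss an optimum that wanders
  more than 32 bp off every seeded diagonal; this matters only for long,
  highly indel-divergent gene pairs that the 70/70 filter would discard
  anyway.
* One best alignment per gene pair: multi-HSP chaining, translated
  search and E-value statistics are out of scope.
* The probability model is a raw histogram — no smoothing — so lookups
  in unpopulated bins return 0 even between populated neighbours.
* Species labels are taken at face value; nomenclatural priority and
  taxonomy-database reconciliation are out of scope.

## A minimal run

```{r example, eval = FALSE}
coll <- plant_collection("fig2d", seed = 1)
pairs <- all_vs_all(coll$genomes)
clustering <- cluster_genomes(pairs, genome_ids = names(coll$genomes))
categorize_species(clustering$clusters, coll$labels)
```
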