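---
title: "Comparative genomics and phyletic profiling of giant viruses with ncldvtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics and phyletic profiling of giant viruses with ncldvtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncldvtools)
```

## The analysis

Nucleo-cytoplasmic large DNA viruses (NCLDVs) — mimiviruses, marseilleviruses,
phycodnaviruses, poxviruses and relatives — have genomes large enough to ask
questions normally reserved for cellular organisms: which genes are shared
with which lineages, how the gene repertoire is organised along the
chromosome, and whether repertoires cluster the viruses as a coherent group
apart from *Bacteria*, *Archaea* and *Eukarya*. `ncldvtools` implements that
comparative workflow as composable, deterministic operations:

1. **Ortholog pairing** between two proteomes by reciprocal best hits (RBH)
   on tabular similarity-search results.
2. **Gene-complement classification**: ORFans (no detectable homolog in a
   reference protein database), meta-ORFans (homologs only in environmental
   metagenomic databases), duplicated genes (connected components of strong
   self-comparison hits), and COG/NCVOG family assignment.
3. **Genome architecture**: are genes of a category (say, RBH partners of
   another virus, or duplicated genes) over- or under-represented in the
   terminal regions of the chromosome? Tested with an exact conditional
   2×2 test.
4. **Synteny**: runs of at least two consecutive orthologous ORFs in
   collinear or inverted order.
5. **Codon usage**: relative synonymous codon usage (RSCU), per gene and
   pooled per genome.
6. **Phyletic profiling**: a binary taxa × family presence/absence matrix,
   Euclidean distances between profiles, agglomerative clustering with
   Newick export, and extraction of the families that discriminate a focal
   taxon from a group.

Because the real inputs (proteomes, BLASTP runs against large databases) are
heavyweight and version-sensitive, the package ships a synthetic-data module
that generates every input with known planted truth, so each stage — and the
pipeline end to end — is testable on a desk.

## Models and procedures

### Reciprocal best hits

For each query, the *best hit* is the subject with the smallest e-value among
hits at or below the cutoff. (a, b) is an ortholog pair iff a's best hit in
the A-vs-B table is b and b's best hit in B-vs-A is a. Whether "best" should
be judged primarily by e-value or by bit score is genuinely open in this kind
of analysis; we fix **e-value as primary**, with bit score and then the
lexicographically smallest subject id as tie-breakers. The tie-breaks make
the result invariant to input row order — without them, binary ties (which
tabular search output produces routinely) would make the pair set depend on
file ordering. Multiple HSPs between the same query and subject are handled
implicitly: the best-per-query selection always keeps the lowest-e-value
record.

### ORFan classification

Labels partition the proteome: HOMOLOG if any reference-database hit meets
the cutoff; else META_ORFAN if any environmental-database hit does; else
ORFAN. The cutoff is the same 1e-5 used for RBH detection.

### Terminal-region enrichment

Genes are assigned to the **terminal** region iff their midpoint
`floor((start + end)/2)` lies within `window` nucleotides of either end of
the sequenced fragment (boundary inclusive on the terminal side), otherwise
**central**. The midpoint rule gives a boundary-spanning gene a single
unambiguous region. The default window is 50,000 nt; the window is anchored
to the coordinates of the sequenced fragment, since only the fragment has
coordinates. Counts of category × region form a 2×2 table, and association
is tested with an exact conditional test: conditional on both margins the
top-left count is hypergeometric, and the two-sided p-value sums the
probabilities of all tables no more probable than the observed one (the
minimum-likelihood rule, the standard two-sided convention for exact 2×2
tests). A relative tolerance of 1e-12 guards floating-point ties in the
comparison of probabilities; probabilities are computed from log-binomial
coefficients, so the test is exact at any desk-scale count. The exact
conditional test is the natural choice here because the interesting counts
are small (a handful of category genes in a 100-kb window); the package
reports raw p-values and leaves multiple-testing control to the caller.

Both region rates are always reported with explicit labels
(`rate_terminal`, `rate_central`) rather than relying on any printing order.

### Synteny

Synteny is defined on gene **ranks** (position in genome order), not
nucleotide coordinates — "consecutive ORFs" is a statement about gene order,
and rank-based runs are robust to intergenic-length variation. Pairs are
first graded by their worse-direction e-value (default cutoff 1e-100, so
only unambiguous orthologs seed blocks), sorted by rank in genome A, and
scanned left to right: a block grows while the next pair advances rank A by
at most `gap + 1` and moves rank B by a step of consistent sign (positive =
collinear, negative = inverted) and magnitude at most `gap + 1`. The default
`gap = 0` demands strictly consecutive ORFs on both sides; the flag exists
because dot-plot-based synteny calls effectively tolerate small gaps.
Blocks need at least two pairs; orientation is reported explicitly because a
dot plot cannot distinguish a short inverted run from scattered points.

### Phyletic profiling and clustering

The presence/absence matrix codes 1 iff a taxon has **at least one** protein
assigned to the family — deliberately ignoring copy number, which keeps the
profile a statement about repertoire rather than amplification. Distances
between taxa are Euclidean; on binary rows this is the square root of the
Hamming distance, so `phyletic_differences()` (the set of differing
families) always has cardinality equal to the squared distance — an identity
the tests exploit.

Clustering is standard agglomerative (single/complete/average linkage via
the Lance–Williams recurrences) with one addition that matters on binary
data: **deterministic tie-breaking**. Exact distance ties are the rule, not
the exception, and a tie broken by memory layout would make the dendrogram
depend on input order. Among tied cluster pairs we merge the pair whose
smallest member labels sort first lexicographically. The default linkage is
**complete**, the common default of base hierarchical-clustering tools; any
reproduction of a published dendrogram should state its linkage, and all
three are selectable. Heights are merge distances; Newick branch lengths are
parent height minus child height, so the tree is ultrametric and the leaf-to-
leaf path length is twice the merge height. `cut_clusters(tree, k)` removes
the k−1 highest merges (ties resolved by the same deterministic merge
order).

For discriminant families, two definitions are provided and documented as
this package's own operationalisation (published analyses of this kind
rarely state theirs precisely): `restrict_to_group()` keeps families present
in at least one member of a group, and `focal_discriminant()` then reports
families where the focal taxon differs from the value held by a strict
majority (> 0.5 by default) of the group; families split with no strict
majority are excluded. Heatmap export orders rows by the taxon dendrogram
and columns by clustering the transposed matrix — both axes clustered.

### RSCU

For codon *j* in a synonymous family of size *n* with counts *x*,
RSCU<sub>j</sub> = x<sub>j</sub> / ((1/n) Σ x). Defined values therefore sum
to the family size, and uniform usage gives 1.0 everywhere. Genome-level
RSCU **pools** codon counts across genes before applying the formula once —
the standard convention — rather than averaging per-gene RSCU, which would
weight short genes equally with long ones. Unused families are reported as
undefined (`NA`), not 0, distinguishing an absent amino acid from an avoided
codon. Triplets containing `N` are skipped and tallied. The genetic code is
fixed to the standard table; the viruses this package targets use it.

## Thresholds

All cutoffs live in one place, `threshold_config()`, with these defaults:

| parameter | default | role |
|---|---|---|
| `e_rbh` | 1e-5 | RBH detection and ORFan calls |
| `e_dup` | 1e-10 | duplicated genes from self-comparison |
| `e_family` | 1e-3 | COG/NCVOG family assignment |
| `e_synteny_grade` | 1e-100 | pairs eligible to seed synteny blocks |
| `min_aln_len` | 70 residues | homolog acceptance (strict >) |
| `min_pid` | 20 % | homolog acceptance (strict >) |

All e-value comparisons elsewhere use ≤ the cutoff; the homolog acceptance
filter is strictly greater-than on both criteria.

## What the synthetic generators emulate — and what they do not

`gen_phyletic_profiles()` plants disjoint per-group core blocks of
⌈`core_frac`·`n_families`⌉ families on an otherwise absent background, then
flips every cell independently with probability `flip_rate`. The flip noise
emulates lineage-specific gene gain/loss and annotation error as independent
events; real gain/loss is phylogenetically correlated within groups, so
recovery rates measured here are optimistic for deep, uneven clades.

`gen_annotated_genome()` draws gene lengths uniformly on 300–1200 nt (a
realistic span for compact viral ORFs) and places them by allocating the
free space over inter-gene gaps via spacings of sorted uniform variates.
This samples uniformly over non-overlapping left-to-right arrangements in
O(n log n) and cannot fail when the packing is feasible, which matters at
the density this analysis works at (500 genes on 618 kb is ~60 % occupancy
— per-gene rejection sampling at that density thrashes). Category labels
are then independent Bernoulli draws with region-dependent probability, so
the planted truth exactly matches the null (equal probabilities) or a
known alternative.

`gen_hit_table()` gives planted pairs mutual e-values log-uniform on
[1e-150, 1e-20] and decoys weak hits on [1e-4, 1], plus (with probability
`fp_rate`) spurious sub-cutoff hits on [1e-30, 1e-6]. The ranges
deliberately straddle the 1e-5 cutoff so threshold logic is exercised, and
the wide true-pair range means only a fraction of true pairs pass the
1e-100 synteny grade — again deliberate, since the grade exists to select a
high-confidence subset. The generator does not emulate alignment-level
phenomena (domain shuffling, low-complexity artefacts, asymmetric database
sizes), so false-positive structure in real searches is richer than here.

`gen_coding_sequences()` draws codons i.i.d. with user weights over the 61
sense codons. There is no amino-acid-level constraint or gene-to-gene
heterogeneity; the generator exists to verify the RSCU estimator against
closed forms, not to imitate real coding statistics.

Passing tests on these generators demonstrate correctness of the
*computations* under the planted models; they do not certify biological
conclusions drawn from real proteomes, where database composition and
annotation quality dominate.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; conversion happens once at
  the I/O boundary. Strand is parsed and carried but positional statistics
  ignore it (genome maps plot both strands together).
* Every generator takes an explicit integer seed, uses one seeded stream,
  and restores the caller's RNG state; identical seeds give byte-identical
  outputs, which the pipeline manifest checksums verify end to end.
* Distance matrices written to TSV round-trip to ≥ 12 significant digits;
  binary matrices round-trip exactly.
* An all-zero 2×2 table is an error; a table with an empty margin row or
  column has a single-point support and p = 1. Enrichment on a genome with
  an empty region errors, naming the region.
* Degenerate clustering inputs (< 2 taxa), empty taxon sets, empty groups,
  and category sets referencing unknown genes all error early with the
  offending identifier in the message.

## Problem sizes used by the test-suite simulations

The statistical checks run at sizes chosen to make their Monte-Carlo bands
tight while keeping the suite quick on a laptop: the exact test is swept
against full hypergeometric enumeration for every 2×2 table with total ≤ 40;
the null calibration of the enrichment test uses 1000 genome draws of 500
genes; power uses 200 draws; RBH recovery uses 100–200 noisy table pairs of
up to 50 proteins a side; clustering recovery uses 100 matrices of 40 taxa ×
200 families; the codon-bias check pools 40,000 codons, at which the ±0.05
acceptance band on RSCU is a ≈3σ bound.

## Known limitations

* The package consumes similarity-search output; it never runs the search
  engine, builds profile databases, or aligns sequences.
* Phylogenetic inference (trees from alignments, bootstrap support on the
  dendrogram) is out of scope; the dendrogram is a repertoire-clustering
  summary, not a phylogeny.
* The exact test reproduces published p-values only insofar as the original
  analysis used the same two-sided convention; "two-sided" for exact 2×2
  tests has several conventions, and results can differ in the last digits.
* GenBank flat files are not parsed; use GFF3 or the 4-column TSV dialect.
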