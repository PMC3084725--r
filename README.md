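# ncldvtools

Comparative genomics and phyletic profiling of giant viruses (nucleo-
cytoplasmic large DNA viruses, NCLDVs) in R.

Giant-virus genomes are large enough to analyse like cellular ones: which
ORFs have orthologs in other viruses or hosts, how gene categories are laid
out along the chromosome, whether gene order is conserved, and whether gene
*repertoires* cluster the viruses as a group of their own next to
*Bacteria*, *Archaea* and *Eukarya*. `ncldvtools` packages that workflow as
small, deterministic, individually tested operations:

- **Orthologs** — reciprocal best hits (RBH) from 12-column tabular
  similarity-search output, with deterministic tie-breaking
  (`read_hits()`, `best_hits()`, `rbh_pairs()`).
- **Gene complement** — ORFans / meta-ORFans (`classify_orfans()`),
  duplicated genes as connected components of strong self-hits
  (`find_duplicates()`), COG/NCVOG family assignment (`assign_families()`),
  homolog acceptance filtering (`filter_homolog_candidates()`).
- **Genome architecture** — terminal-window classification of genes by
  midpoint and an exact conditional 2×2 test for positional enrichment
  (`classify_region()`, `contingency()`, `fisher_exact_two_sided()`,
  `enrichment()`, `genome_tracks()`).
- **Synteny** — maximal runs of ≥ 2 consecutive orthologous ORFs on gene
  ranks, collinear or inverted (`synteny_blocks()`, `dotplot_points()`).
- **Phyletic profiling** — binary presence/absence matrices
  (`build_matrix()`), Euclidean distances, deterministic agglomerative
  clustering with Newick export (`hierarchical_cluster()`, `to_newick()`,
  `cut_clusters()`), and discriminant-family extraction
  (`restrict_to_group()`, `focal_discriminant()`).
- **Codon usage** — RSCU per gene and pooled per genome (`codon_counts()`,
  `rscu()`, `genome_rscu()`).
- **Synthetic data** — generators with known planted truth for every input
  (`gen_phyletic_profiles()`, `gen_annotated_genome()`, `gen_hit_table()`,
  `gen_coding_sequences()`), so the whole pipeline is verifiable offline.
- **Pipeline** — `run_pipeline()` orchestrates the stages from one YAML/JSON
  config and writes a manifest with seeds, thresholds and output checksums;
  `inst/cli/run_pipeline.R` is a thin shell wrapper.

The central statistic: for a 2×2 table of gene category × genome region,
conditional on the margins the top-left count *a* is hypergeometric, and the
two-sided p-value is

&nbsp;&nbsp;&nbsp;&nbsp;p = Σ<sub>k</sub> P(k) over all k in the support with P(k) ≤ P(a),

computed with log-binomial coefficients (minimum-likelihood rule, 1e-12
relative tie guard). For phyletic profiles, the distance between taxa s, t
is d(s,t) = √Σ<sub>f</sub> (x<sub>sf</sub> − x<sub>tf</sub>)², i.e. the
square root of the number of differing families; RSCU of codon j in a
family of size n is x<sub>j</sub>/((1/n)Σx).

## Worked example

Plant a positional bias — a gene category hit with probability 0.5 in the
two terminal 50-kb windows of a 618-kb fragment but 0.1 centrally — and
test for it; then cluster noisy four-group phyletic profiles; then recover
a planted 3:1 lysine codon bias:

```r
library(ncldvtools)

sim  <- gen_annotated_genome(618000, 500, 50000, 0.5, 0.1, seed = 42)
spec <- region_spec(618000, window = 50000)
enrichment(sim$genome, sim$truth$in_category, spec)
#> terminal 48.2% vs central 11.8% (odds ratio 6.96, p = 5.7e-13)

prof <- gen_phyletic_profiles(4, 10, 200, core_frac = 0.15,
                              flip_rate = 0.02, seed = 42)
tree <- hierarchical_cluster(euclidean_distances(prof$matrix), "complete")
lengths(cut_clusters(tree, 4))
#> [1] 10 10 10 10     # the four planted clades, recovered exactly

seqs <- gen_coding_sequences(10, c(AAA = 3, AAG = 1), 4000, seed = 42)
r <- genome_rscu(seqs)
round(c(r[["AAA"]], r[["AAG"]]), 3)
#> [1] 1.537 0.463     # closed form: 1.5 and 0.5
```

The enrichment line reads: 48.2 % of terminal genes carry the category
versus 11.8 % of central genes; the exact test puts the association at
p ≈ 6e-13. `to_newick(tree)` serialises the dendrogram for any tree viewer,
and `write_matrix()` exports matrices as labelled TSV.

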