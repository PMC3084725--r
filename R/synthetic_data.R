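## Truth-known synthetic inputs with the statistical structure the analysis
## assumes: clade-structured presence/absence profiles, genomes with a
## planted positional bias of a gene category, reciprocal hit tables
## consistent with a planted orthology, and coding sequences with specified
## codon frequencies. Every generator takes an explicit seed and is
## deterministic given it; the caller's RNG state is left untouched.

#' Generate clade-structured phyletic profiles
#'
#' Builds a binary taxa-by-family presence/absence matrix with a planted
#' group structure: each of `n_groups` groups of `taxa_per_group` taxa
#' receives a distinct "core" block of `ceiling(core_frac * n_families)`
#' families set to present; all other cells are absent. Every cell is then
#' flipped independently with probability `flip_rate`, emulating gene gain
#' and loss noise on top of the clade signal.
#'
#' @param n_groups Number of planted groups (clades).
#' @param taxa_per_group Taxa per group.
#' @param n_families Total number of gene families (columns).
#' @param core_frac Fraction of families forming each group's core block.
#' @param flip_rate Per-cell flip probability, in \[0, 0.5\].
#' @param seed Integer seed; required.
#' @return A list with `matrix` (the noisy [phyletic_matrix]) and `truth`
#'   (list with `group_of`, a named vector taxon -> group label, and
#'   `planted_matrix`, the matrix before noise).
#' @export
gen_phyletic_profiles <- function(n_groups, taxa_per_group, n_families,
                                  core_frac, flip_rate, seed) {
  stopifnot(n_groups >= 1L, taxa_per_group >= 1L, n_families >= 1L)
  if (flip_rate < 0 || flip_rate > 0.5) abort("flip_rate must be in [0, 0.5]")
  core_size <- ceiling(core_frac * n_families)
  if (n_groups * core_size > n_families) {
    abort("core blocks exceed the family universe: ", n_groups, " x ",
          core_size, " > ", n_families)
  }
  taxa <- paste0("G", rep(seq_len(n_groups), each = taxa_per_group), "_T",
                 sprintf("%02d", rep(seq_len(taxa_per_group), n_groups)))
  groups <- paste0("G", rep(seq_len(n_groups), each = taxa_per_group))
  families <- sprintf("FAM%04d", seq_len(n_families))
  planted <- matrix(0L, nrow = length(taxa), ncol = n_families,
                    dimnames = list(taxa, families))
  for (g in seq_len(n_groups)) {
    rows <- which(groups == paste0("G", g))
    cols <- ((g - 1L) * core_size + 1L):(g * core_size)
    planted[rows, cols] <- 1L
  }
  noisy <- with_seed(seed, {
    flips <- matrix(runif(length(planted)) < flip_rate, nrow = nrow(planted))
    m <- planted
    m[flips] <- 1L - m[flips]
    m
  })
  dimnames(noisy) <- dimnames(planted)
  list(
    matrix = phyletic_matrix(noisy),
    truth = list(group_of = setNames(groups, taxa),
                 planted_matrix = phyletic_matrix(planted))
  )
}

#' Generate a genome with a planted positional category bias
#'
#' Places `n_genes` non-overlapping genes on a linear fragment of the given
#' length, sampling uniformly over non-overlapping arrangements, then labels
#' each gene as belonging to a category of interest with probability
#' `p_cat_terminal` if its midpoint falls within `window` nucleotides of
#' either fragment end, and `p_cat_central` otherwise. Equal probabilities
#' plant no bias (the null); unequal probabilities plant a positional
#' enrichment of known direction and size.
#'
#' @param length Fragment length in nucleotides.
#' @param n_genes Number of genes to place.
#' @param window Terminal window size in nucleotides.
#' @param p_cat_terminal,p_cat_central Category probabilities by region.
#' @param seed Integer seed; required.
#' @param gene_length_range Integer range genes' lengths are drawn from
#'   (uniform), in nucleotides.
#' @return A list with `genome` (a [genome]) and `truth` (list with
#'   `in_category`, the gene ids planted in the category, and `region`,
#'   a named vector gene id -> `"TERMINAL"`/`"CENTRAL"`).
#' @export
gen_annotated_genome <- function(length, n_genes, window, p_cat_terminal,
                                 p_cat_central, seed,
                                 gene_length_range = c(300L, 1200L)) {
  stopifnot(p_cat_terminal >= 0, p_cat_terminal <= 1,
            p_cat_central >= 0, p_cat_central <= 1)
  if (2 * window >= length) abort("2*window must be smaller than genome length")
  if (n_genes == 0L) {
    g <- genome("synthetic", length,
                data.frame(gene_id = character(0), start = numeric(0),
                           end = numeric(0), strand = character(0)))
    return(list(genome = g,
                truth = list(in_category = character(0),
                             region = setNames(character(0), character(0)))))
  }
  if (n_genes * (min(gene_length_range) + 1) > length) {
    abort("infeasible packing: ", n_genes, " genes of >= ",
          min(gene_length_range), " nt do not fit in ", length, " nt")
  }
  with_seed(seed, {
    lens <- sample(seq(gene_length_range[1L], gene_length_range[2L]),
                   n_genes, replace = TRUE)
    free <- length - sum(lens) - (n_genes - 1L)
    if (free < 0) {
      abort("infeasible packing: total gene length ", sum(lens),
            " plus spacers exceeds fragment length ", length)
    }
    # distribute the free space over the n_genes + 1 inter-gene gaps
    # uniformly (spacings of sorted uniforms), giving a uniform draw over
    # non-overlapping arrangements in left-to-right order
    cuts <- sort(runif(n_genes))
    gaps <- floor(diff(c(0, cuts, 1)) * free)
    starts <- cumsum(c(1, head(lens, -1L) + 1L)) + cumsum(gaps)[seq_len(n_genes)]
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    ids <- sprintf("gene_%04d", seq_len(n_genes))
    mid <- floor((starts + ends) / 2)
    terminal <- mid <= window | mid > length - window
    p <- ifelse(terminal, p_cat_terminal, p_cat_central)
    in_cat <- runif(n_genes) < p
    g <- genome("synthetic", length,
                data.frame(gene_id = ids, start = starts, end = ends,
                           strand = strands, stringsAsFactors = FALSE))
    list(
      genome = g,
      truth = list(
        in_category = ids[in_cat],
        region = setNames(ifelse(terminal, "TERMINAL", "CENTRAL"), ids)
      )
    )
  })
}

#' Generate reciprocal hit tables consistent with a planted orthology
#'
#' Emits a pair of hit tables (proteome A vs B and B vs A). Each planted
#' ortholog pair produces mutual hits with e-values drawn log-uniformly from
#' \[1e-150, 1e-20\] (well below the usual 1e-5 cutoff) unless the pair is
#' dropped with probability `fn_rate`. Each decoy protein produces a hit to
#' a random partner with an e-value in \[1e-4, 1\] (above the cutoff), and,
#' with probability `fp_rate`, an additional spurious sub-cutoff hit with an
#' e-value in \[1e-30, 1e-6\]. True and decoy e-value ranges deliberately
#' straddle the 1e-5 threshold so that cutoff logic downstream is exercised.
#'
#' @param planted_pairs Data frame with columns `a_id`, `b_id`: the true
#'   ortholog pairs (one-to-one).
#' @param decoy_a,decoy_b Character vectors of unpaired protein ids on each
#'   side.
#' @param fp_rate Probability a decoy emits a spurious sub-cutoff hit.
#' @param fn_rate Probability a planted pair is dropped from both tables.
#' @param seed Integer seed; required.
#' @return A list with `ab` and `ba`, each a [hit_table].
#' @export
gen_hit_table <- function(planted_pairs, decoy_a = character(0),
                          decoy_b = character(0), fp_rate = 0, fn_rate = 0,
                          seed) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  pp <- data.frame(a_id = as.character(planted_pairs$a_id),
                   b_id = as.character(planted_pairs$b_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pp$a_id) || anyDuplicated(pp$b_id)) {
    abort("planted pairs must be one-to-one")
  }
  all_a <- c(pp$a_id, decoy_a)
  all_b <- c(pp$b_id, decoy_b)
  mk_row <- function(q, s, e) {
    n <- base::length(q)
    if (n == 0L) return(empty_hit_table())
    len <- sample(80:500, n, replace = TRUE)
    pid <- runif(n, 22, 90)
    hit_table(data.frame(
      query_id = q, subject_id = s,
      pct_identity = round(pid, 1), aln_length = len,
      mismatches = round(len * (1 - pid / 100)), gap_opens = sample(0:5, n, TRUE),
      q_start = 1, q_end = len, s_start = 1, s_end = len,
      evalue = e, bitscore = round(pmax(-2 * log10(pmax(e, 1e-180)), 0) + runif(n, 20, 30), 1),
      stringsAsFactors = FALSE
    ))
  }
  with_seed(seed, {
    keep <- runif(nrow(pp)) >= fn_rate
    kept <- pp[keep, , drop = FALSE]
    n_true <- nrow(kept)
    ab_true <- mk_row(kept$a_id, kept$b_id, rloguniform(n_true, 1e-150, 1e-20))
    ba_true <- mk_row(kept$b_id, kept$a_id, rloguniform(n_true, 1e-150, 1e-20))
    decoy_hits <- function(queries, subjects_pool) {
      n <- base::length(queries)
      if (n == 0L || base::length(subjects_pool) == 0L) return(empty_hit_table())
      weak <- mk_row(queries, sample(subjects_pool, n, replace = TRUE),
                     rloguniform(n, 1e-4, 1))
      spurious <- runif(n) < fp_rate
      if (any(spurious)) {
        sp <- mk_row(queries[spurious],
                     sample(subjects_pool, sum(spurious), replace = TRUE),
                     rloguniform(sum(spurious), 1e-30, 1e-6))
        hit_table(rbind(weak, sp))
      } else weak
    }
    ab <- hit_table(rbind(ab_true, decoy_hits(decoy_a, all_b)))
    ba <- hit_table(rbind(ba_true, decoy_hits(decoy_b, all_a)))
    list(ab = ab, ba = ba)
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Generate coding sequences with specified codon frequencies
#'
#' Each gene is a concatenation of `gene_length_codons` codons drawn
#' independently with the given weights over the 61 sense codons of the
#' standard genetic code. Codons not named in `codon_weights` get weight 1,
#' so e.g. `c(AAA = 3, AAG = 1)` biases lysine usage 3:1 while leaving all
#' other synonymous families uniform.
#'
#' @param n_genes Number of genes.
#' @param codon_weights Named non-negative weights for a subset of sense
#'   codons; `NULL` for uniform usage.
#' @param gene_length_codons Codons per gene (sequence length is three times
#'   this).
#' @param seed Integer seed; required.
#' @return A named `DNAStringSet`.
#' @export
gen_coding_sequences <- function(n_genes, codon_weights = NULL,
                                 gene_length_codons, seed) {
  stopifnot(n_genes >= 1L, gene_length_codons >= 1L)
  codons <- sense_codons()
  w <- setNames(rep(1, base::length(codons)), codons)
  if (!is.null(codon_weights)) {
    bad <- intersect(names(codon_weights), STOP_CODONS)
    if (base::length(bad) > 0L) {
      abort("weight given for stop codon(s): ", paste(bad, collapse = ", "))
    }
    unknown <- setdiff(names(codon_weights), codons)
    if (base::length(unknown) > 0L) {
      abort("unknown codon(s) in weights: ", paste(unknown, collapse = ", "))
    }
    if (any(codon_weights < 0)) abort("codon weights must be non-negative")
    w[names(codon_weights)] <- codon_weights
  }
  # every amino acid must stay drawable
  code <- Biostrings::GENETIC_CODE
  fam <- split(names(w), code[names(w)])
  dead <- vapply(fam, function(f) sum(w[f]) == 0, logical(1L))
  if (any(dead)) {
    abort("all codons of amino acid(s) ", paste(names(fam)[dead], collapse = ", "),
          " have zero weight")
  }
  seqs <- with_seed(seed, {
    vapply(seq_len(n_genes), function(i) {
      paste0(sample(codons, gene_length_codons, replace = TRUE, prob = w),
             collapse = "")
    }, character(1L))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("gene_%04d", seq_len(n_genes))
  out
}
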