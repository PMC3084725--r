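## Codon counting and Relative Synonymous Codon Usage (RSCU).
## RSCU of codon j in synonymous family i of size n_i with counts x is
##   RSCU_j = x_j / ((1/n_i) * sum_{j' in i} x_{j'}),
## i.e. the observed count divided by the mean count of the family; 1.0
## means unbiased usage. The genetic code is fixed to the standard table.

#' Count in-frame codons of a coding sequence
#'
#' @param cds A nucleotide sequence: character string or `DNAString`
#'   (alphabet `ACGTN`, case-insensitive), length divisible by 3.
#' @return A list of class `codon_counts` with `counts` (named integer
#'   vector over the 64 ACGT codons) and `n_skipped` (number of in-frame
#'   triplets containing `N`, which are excluded from the counts).
#' @export
codon_counts <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) == 0L) abort("codon_counts: empty sequence")
  if (nchar(s) %% 3 != 0L) {
    abort("codon_counts: sequence length ", nchar(s), " is not divisible by 3")
  }
  bad <- setdiff(strsplit(s, "")[[1L]], c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    abort("codon_counts: unexpected letter(s): ", paste(unique(bad), collapse = ", "))
  }
  x <- Biostrings::DNAString(s)
  counts <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L)
  counts <- counts[!grepl("[^ACGT]", names(counts))]
  structure(list(counts = counts,
                 n_skipped = nchar(s) / 3L - sum(counts)),
            class = "codon_counts")
}

# synonymous families of the standard genetic code, stops excluded
synonymous_families <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  split(names(code), unname(code))
}

#' Relative synonymous codon usage from codon counts
#'
#' Within each synonymous family with a positive total count, each codon's
#' RSCU is its count divided by the family's mean count, so defined values
#' sum to the family size. Families entirely unused yield `NA` (undefined)
#' rather than 0, distinguishing "amino acid absent" from "codon avoided".
#' Single-codon families (Met, Trp) are always 1 when used. Stop codons are
#' excluded.
#'
#' @param counts A [codon_counts] object, or a named numeric vector of
#'   codon counts.
#' @return Named numeric vector of class `rscu_table` over the 61 sense
#'   codons; `NA` for undefined values.
#' @export
rscu <- function(counts) {
  if (inherits(counts, "codon_counts")) counts <- counts$counts
  fams <- synonymous_families()
  out <- setNames(rep(NA_real_, length(unlist(fams))), unlist(fams))
  for (fam in fams) {
    x <- counts[fam]
    x[is.na(x)] <- 0
    tot <- sum(x)
    if (tot > 0) out[fam] <- unname(x) * length(fam) / tot
  }
  out <- out[order(names(out))]
  class(out) <- c("rscu_table", "numeric")
  out
}

#' Genome-level RSCU from pooled codon counts
#'
#' Codon counts are summed over all genes and RSCU computed once on the
#' pooled counts (not averaged over per-gene RSCU values).
#'
#' @param genes A list of coding sequences (character or `DNAString`) or a
#'   `DNAStringSet`.
#' @return An `rscu_table` (see [rscu()]).
#' @export
genome_rscu <- function(genes) {
  if (length(genes) == 0L) abort("genome_rscu: no genes")
  total <- NULL
  for (i in seq_along(genes)) {
    cc <- tryCatch(codon_counts(genes[[i]]), error = function(e) {
      abort("gene ", i, ": ", conditionMessage(e))
    })
    total <- if (is.null(total)) cc$counts else total + cc$counts
  }
  rscu(total)
}

#' Write an RSCU table as TSV
#'
#' One row per sense codon: codon, encoded amino acid, RSCU value (empty
#' for undefined).
#'
#' @param values An `rscu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rscu <- function(values, path) {
  code <- Biostrings::GENETIC_CODE
  df <- data.frame(
    codon = names(values),
    amino_acid = unname(code[names(values)]),
    rscu = as.numeric(values),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}
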