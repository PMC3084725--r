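## Readers and writers for the external formats the pipeline touches.
## Every other module consumes and produces only the in-memory types built
## here: hit tables (data frames), genomes (S3 lists), labelled matrices.

HIT_COLUMNS <- c(
  "query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore"
)

#' Construct a hit table
#'
#' A hit table is a data frame with the twelve standard columns of tabular
#' pairwise similarity-search output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' e-value, bit score). The constructor validates the column set and the
#' basic invariants (e-values non-negative, identities in \[0, 100\],
#' alignment lengths at least 1).
#'
#' @param df A data frame with (at least) the twelve standard columns.
#' @return A `data.frame` of class `hit_table`.
#' @export
hit_table <- function(df) {
  missing_cols <- setdiff(HIT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort("hit table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[HIT_COLUMNS]
  df$query_id <- as.character(df$query_id)
  df$subject_id <- as.character(df$subject_id)
  num_cols <- setdiff(HIT_COLUMNS, c("query_id", "subject_id"))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (nrow(df) > 0L) {
    if (any(df$evalue < 0)) abort("hit table: negative e-value")
    if (any(df$pct_identity < 0 | df$pct_identity > 100)) {
      abort("hit table: percent identity outside [0, 100]")
    }
    if (any(df$aln_length < 1)) abort("hit table: alignment length < 1")
  }
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

empty_hit_table <- function() {
  hit_table(as.data.frame(
    setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10L)),
      HIT_COLUMNS
    )
  ))
}

#' Read a tabular similarity-search hit file
#'
#' Parses the de-facto 12-column tab-separated hit format (the "outfmt 6"
#' dialect): query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score. Lines starting with `#` and blank lines are skipped; extra
#' trailing columns are ignored; input order is preserved.
#'
#' @param path Path to the hit file.
#' @return A [hit_table] with one row per data line.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) abort("hit file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_hit_table())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- idx[which(nf < 12L)[1L]]
    abort("malformed hit line ", bad, ": expected >= 12 tab-separated fields, got ",
          nf[which(nf < 12L)[1L]])
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12L)))
  num <- suppressWarnings(apply(mat[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad_row <- which(rowSums(is.na(num)) > 0L)[1L]
    abort("malformed hit line ", idx[bad_row], ": non-numeric value in a numeric field")
  }
  df <- data.frame(
    query_id = mat[, 1L], subject_id = mat[, 2L], num,
    stringsAsFactors = FALSE
  )
  names(df) <- HIT_COLUMNS
  hit_table(df)
}

#' Write a hit table
#'
#' Writes the 12-column tab-separated dialect read by [read_hits()], without
#' a header so the file round-trips.
#'
#' @param hits A [hit_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- as.data.frame(hits)
  out$evalue <- format(out$evalue, digits = 15, scientific = TRUE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genome
#'
#' A genome is an ordered set of non-nested gene features on one linear
#' sequenced fragment, with 1-based inclusive nucleotide coordinates.
#' Features are sorted by start and assigned a 0-based `rank` in genome
#' order; synteny is later defined on these ranks.
#'
#' @param genome_id Identifier for the sequenced fragment.
#' @param length Fragment length in nucleotides.
#' @param features Data frame with columns `gene_id`, `start`, `end`,
#'   `strand` (`+`/`-`) and optionally `product`.
#' @return An object of class `genome`: a list with elements `genome_id`,
#'   `length` and `features` (with added `rank` column).
#' @export
genome <- function(genome_id, length, features) {
  stopifnot(is.character(genome_id), base::length(genome_id) == 1L)
  length <- as.numeric(length)
  req <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(req, names(features))
  if (base::length(missing_cols) > 0L) {
    abort("genome features missing columns: ", paste(missing_cols, collapse = ", "))
  }
  features$gene_id <- as.character(features$gene_id)
  features$start <- as.numeric(features$start)
  features$end <- as.numeric(features$end)
  features$strand <- as.character(features$strand)
  if (is.null(features$product)) {
    features$product <- rep(NA_character_, nrow(features))
  }
  if (nrow(features) > 0L) {
    if (anyDuplicated(features$gene_id)) abort("duplicate gene_id in genome")
    if (any(features$start < 1)) abort("gene start < 1")
    bad <- features$end < features$start
    if (any(bad)) {
      abort("gene '", features$gene_id[which(bad)[1L]], "': end < start")
    }
    if (any(features$end > length)) {
      bad <- which(features$end > length)[1L]
      abort("gene '", features$gene_id[bad], "' extends beyond genome length ", length)
    }
    if (!all(features$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
    features <- features[order(features$start, features$end, features$gene_id), ,
                         drop = FALSE]
  }
  features$rank <- seq_len(nrow(features)) - 1L
  rownames(features) <- NULL
  structure(
    list(genome_id = genome_id, length = length,
         features = features[c("gene_id", "start", "end", "strand", "rank", "product")]),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, ": ", nrow(x$features), " genes on ",
      format(x$length, big.mark = ","), " nt\n", sep = "")
  invisible(x)
}

#' Read gene coordinates into a genome
#'
#' Two dialects are supported. `"tsv"`: a 4-column table
#' `gene_id, start, end, strand` (tab- or comma-separated, optional header).
#' `"gff3"`: a GFF3 file, from which only rows of type `CDS` or `gene` are
#' used; the fragment length is taken from the `##sequence-region` pragma
#' when present. Coordinates are 1-based inclusive in both dialects.
#'
#' @param path Input file.
#' @param fmt `"tsv"` or `"gff3"`.
#' @param genome_id Fragment identifier; defaults to the file base name
#'   (TSV) or the GFF3 seqid.
#' @param length Fragment length in nucleotides; defaults to the
#'   `##sequence-region` length (GFF3) or the maximum feature end.
#' @return A [genome].
#' @export
read_genome <- function(path, fmt = c("tsv", "gff3"), genome_id = NULL,
                        length = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort("genome file does not exist: ", path)
  if (fmt == "tsv") {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
    has_header <- grepl("gene_id", first, fixed = TRUE)
    df <- read.table(path, sep = sep, header = has_header,
                     stringsAsFactors = FALSE, comment.char = "#")
    if (!has_header) {
      if (ncol(df) < 4L) abort("TSV genome table needs 4 columns: gene_id,start,end,strand")
      names(df)[1:4] <- c("gene_id", "start", "end", "strand")
    }
    gid <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
    len <- length %||% max(as.numeric(df$end))
    genome(gid, len, df)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
    if (base::length(gr) == 0L) abort("no CDS/gene features in GFF3 file: ", path)
    ids <- as.character(gr$ID %||% rep(NA_character_, base::length(gr)))
    if (anyNA(ids) && !is.null(gr$Name)) {
      ids[is.na(ids)] <- as.character(gr$Name)[is.na(ids)]
    }
    if (anyNA(ids)) ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
    seqid <- as.character(GenomicRanges::seqnames(gr))[1L]
    # fragment length: ##sequence-region pragma if present
    len <- length
    if (is.null(len)) {
      pragma <- grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)
      if (base::length(pragma) > 0L) {
        parts <- strsplit(pragma[1L], "\\s+")[[1L]]
        len <- as.numeric(parts[4L])
      } else {
        len <- max(BiocGenerics::end(gr))
      }
    }
    df <- data.frame(
      gene_id = ids,
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      stringsAsFactors = FALSE
    )
    df$strand[!df$strand %in% c("+", "-")] <- "+"
    genome(genome_id %||% seqid, len, df)
  }
}

#' Write a genome's gene table
#'
#' Writes the 4-column TSV dialect (`gene_id`, `start`, `end`, `strand`)
#' read back by [read_genome()].
#'
#' @param g A [genome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  write.table(g$features[c("gene_id", "start", "end", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a 2-column family-membership table
#'
#' Rows map a protein id to a family id (COG/NCVOG), with an optional third
#' e-value column recording the supporting hit.
#'
#' @param path Input TSV (optional header `protein_id  family_id  evalue`).
#' @return A data frame with columns `protein_id`, `family_id`, `evalue`.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) abort("family table does not exist: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("protein_id", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!has_header) names(df)[1:min(3L, ncol(df))] <-
      c("protein_id", "family_id", "evalue")[1:min(3L, ncol(df))]
  if (is.null(df$evalue)) df$evalue <- NA_real_
  df$protein_id <- as.character(df$protein_id)
  df$family_id <- as.character(df$family_id)
  if (any(!nzchar(df$family_id))) abort("empty family_id in family table")
  df[c("protein_id", "family_id", "evalue")]
}

#' Write a family-membership table
#' @param fam Data frame with `protein_id`, `family_id` and optional `evalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(fam, path) {
  if (is.null(fam$evalue)) fam$evalue <- NA_real_
  write.table(fam[c("protein_id", "family_id", "evalue")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a labelled matrix as TSV
#'
#' Writes a phyletic (0/1) or distance matrix with row and column labels.
#' Binary matrices round-trip bit-exactly; numeric matrices round-trip to at
#' least 12 significant digits.
#'
#' @param m A matrix with unique, non-empty `dimnames`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L) {
    abort("write_matrix: matrix is empty")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("write_matrix: matrix must have row and column labels")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("write_matrix: duplicate row or column labels")
  }
  df <- as.data.frame(m, check.names = FALSE)
  vals <- if (all(m %in% c(0, 1))) {
    as.data.frame(lapply(df, function(x) format(as.integer(x))), check.names = FALSE)
  } else {
    as.data.frame(lapply(df, function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE)),
                  check.names = FALSE)
  }
  out <- cbind(data.frame(label = rownames(m), stringsAsFactors = FALSE), vals)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix()]
#' @param path Input TSV.
#' @return A numeric matrix with dimnames restored.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort("matrix file does not exist: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  m
}

#' Write protein or nucleotide sequences to FASTA
#' @param seqs A named `XStringSet` (e.g. from [gen_coding_sequences()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read nucleotide sequences from FASTA
#' @param path Input FASTA.
#' @return A `DNAStringSet`.
#' @export
read_fasta_dna <- function(path) {
  if (!file.exists(path)) abort("FASTA file does not exist: ", path)
  Biostrings::readDNAStringSet(path)
}
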