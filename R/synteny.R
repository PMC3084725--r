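## Synteny: runs of consecutive orthologous genes in collinear or inverted
## order between two genomes. Synteny is defined on gene RANKS (position in
## genome order), not nucleotide coordinates, so it is robust to intergenic
## length variation.

#' Detect synteny blocks between two genomes
#'
#' Ortholog pairs are first filtered to those whose worse e-value
#' (`max(evalue_ab, evalue_ba)`) is at most `e_max` (default 1e-100, keeping
#' only high-grade pairs), then mapped to `(rank_a, rank_b)` using each
#' genome's gene order. Scanning pairs in increasing `rank_a`, a block grows
#' while the next pair advances `rank_a` by at most `gap + 1` and moves
#' `rank_b` by a step of the block's orientation sign (positive for
#' collinear, negative for inverted) with magnitude at most `gap + 1`.
#' With the default `gap = 0` blocks are strictly consecutive ORFs in both
#' genomes. Maximal runs of length at least two are returned; isolated pairs
#' are not blocks.
#'
#' @param pairs An `ortholog_pairs` data frame (see [rbh_pairs()]), or any
#'   data frame with `a_id`, `b_id`, `evalue_ab`, `evalue_ba`.
#' @param genome_a,genome_b The two [genome]s.
#' @param e_max E-value cutoff on the worse direction (default 1e-100).
#' @param gap Allowed rank slack (default 0: strictly consecutive).
#' @return List of blocks; each block is a list with `ranks` (two-column
#'   matrix `rank_a`, `rank_b`), `genes` (data frame `a_id`, `b_id`) and
#'   `orientation` (`"collinear"` or `"inverted"`). Blocks are sorted by
#'   their first `rank_a`.
#' @export
synteny_blocks <- function(pairs, genome_a, genome_b, e_max = 1e-100, gap = 0) {
  stopifnot(gap >= 0)
  rk <- pair_ranks(pairs, genome_a, genome_b, e_max)
  n <- nrow(rk)
  if (n == 0L) return(list())
  rk <- rk[order(rk$rank_a), , drop = FALSE]
  blocks <- list()
  cur <- 1L           # index of first pair of current run
  orient <- 0L        # 0 unknown, +1 collinear, -1 inverted
  close_run <- function(from, to, orient) {
    if (to - from + 1L < 2L) return(NULL)
    idx <- from:to
    list(
      ranks = cbind(rank_a = rk$rank_a[idx], rank_b = rk$rank_b[idx]),
      genes = data.frame(a_id = rk$a_id[idx], b_id = rk$b_id[idx],
                         stringsAsFactors = FALSE),
      orientation = if (orient >= 0L) "collinear" else "inverted"
    )
  }
  last <- 1L
  i <- 2L
  while (i <= n) {
    da <- rk$rank_a[i] - rk$rank_a[last]
    db <- rk$rank_b[i] - rk$rank_b[last]
    step_ok <- da >= 1L && da <= gap + 1L && abs(db) >= 1L && abs(db) <= gap + 1L
    dir_ok <- step_ok && (orient == 0L || sign(db) == orient)
    if (dir_ok) {
      if (orient == 0L) orient <- sign(db)
      last <- i
    } else {
      blk <- close_run(cur, last, orient)
      if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
      cur <- i
      last <- i
      orient <- 0L
    }
    i <- i + 1L
  }
  blk <- close_run(cur, last, orient)
  if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
  blocks
}

# filter pairs by worse-direction e-value, map to ranks; errors on genes
# absent from either genome
pair_ranks <- function(pairs, genome_a, genome_b, e_max = Inf) {
  pr <- as.data.frame(pairs)
  if (nrow(pr) == 0L) {
    return(data.frame(a_id = character(0), b_id = character(0),
                      rank_a = integer(0), rank_b = integer(0)))
  }
  if (!is.null(pr$evalue_ab)) {
    keep <- pmax(pr$evalue_ab, pr$evalue_ba) <= e_max
    pr <- pr[keep, , drop = FALSE]
  }
  rank_a <- setNames(genome_a$features$rank, genome_a$features$gene_id)
  rank_b <- setNames(genome_b$features$rank, genome_b$features$gene_id)
  unknown <- c(setdiff(pr$a_id, names(rank_a)), setdiff(pr$b_id, names(rank_b)))
  if (length(unknown) > 0L) {
    abort("pair references gene(s) absent from the genomes: ",
          paste(head(unknown, 5L), collapse = ", "))
  }
  data.frame(a_id = pr$a_id, b_id = pr$b_id,
             rank_a = unname(rank_a[pr$a_id]),
             rank_b = unname(rank_b[pr$b_id]),
             stringsAsFactors = FALSE)
}

#' Dot-plot points for ortholog pairs
#'
#' One point per ortholog pair: the nucleotide midpoints of the two genes
#' and a score (the worse-direction e-value or the minimum bit score),
#' ready for plotting a genome-vs-genome dot plot.
#'
#' @inheritParams synteny_blocks
#' @param score `"evalue"` (max of the two directions) or `"bitscore"`
#'   (`min_bitscore` when present).
#' @param e_max Optional e-value cutoff on the worse direction; default
#'   `Inf` (no filtering beyond what the caller asks for).
#' @return Data frame with columns `a_id`, `b_id`, `midpoint_a`,
#'   `midpoint_b`, `score`.
#' @export
dotplot_points <- function(pairs, genome_a, genome_b,
                           score = c("evalue", "bitscore"), e_max = Inf) {
  score <- match.arg(score)
  pr <- as.data.frame(pairs)
  rk <- pair_ranks(pairs, genome_a, genome_b, e_max)
  pr <- pr[match(rk$a_id, pr$a_id), , drop = FALSE]
  mid <- function(g) setNames(floor((g$features$start + g$features$end) / 2),
                              g$features$gene_id)
  mid_a <- mid(genome_a); mid_b <- mid(genome_b)
  sc <- if (nrow(pr) == 0L) numeric(0)
        else if (score == "evalue") pmax(pr$evalue_ab, pr$evalue_ba)
        else pr$min_bitscore
  data.frame(
    a_id = rk$a_id, b_id = rk$b_id,
    midpoint_a = unname(mid_a[rk$a_id]),
    midpoint_b = unname(mid_b[rk$b_id]),
    score = sc,
    stringsAsFactors = FALSE
  )
}
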