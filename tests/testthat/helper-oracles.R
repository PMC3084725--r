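## Independent oracles used to cross-check the implementation. Each is
## deliberately written by a different route than the function it checks.

# Two-sided exact p for a 2x2 table by direct hypergeometric enumeration
# with stats::dhyper (the implementation uses log-binomial coefficients).
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  sum(probs[probs <= probs[kk == a] * (1 + 1e-12)])
}

# Best subject per query by an explicit per-query scan over all rows.
oracle_best <- function(hits, e_max) {
  out <- character(0)
  for (q in unique(hits$query_id)) {
    rows <- hits[hits$query_id == q & hits$evalue <= e_max, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$subject_id), ,
                 drop = FALSE]
    out[q] <- rows$subject_id[1L]
  }
  out
}

# Reciprocal best hits by brute-force enumeration of every (a, b) pair.
oracle_rbh <- function(hits_ab, hits_ba, e_max) {
  fwd <- oracle_best(hits_ab, e_max)
  rev <- oracle_best(hits_ba, e_max)
  pairs <- character(0)
  for (a in unique(hits_ab$query_id)) {
    for (b in unique(hits_ba$query_id)) {
      if (!is.na(fwd[a]) && !is.na(rev[b]) && fwd[a] == b && rev[b] == a) {
        pairs <- c(pairs, paste(a, b))
      }
    }
  }
  sort(pairs)
}

# Synteny runs by exhaustive window enumeration: list every window [i, j]
# of the rank_a-sorted pairs that satisfies the run condition, then select
# greedily from the left, longest first, discarding overlaps.
oracle_synteny <- function(rank_a, rank_b, gap = 0) {
  o <- order(rank_a)
  ra <- rank_a[o]; rb <- rank_b[o]
  n <- length(ra)
  window_ok <- function(i, j) {
    da <- diff(ra[i:j]); db <- diff(rb[i:j])
    if (any(da < 1 | da > gap + 1)) return(NA_character_)
    s <- sign(db[1L])
    if (any(sign(db) != s | abs(db) < 1 | abs(db) > gap + 1)) return(NA_character_)
    if (s > 0) "collinear" else "inverted"
  }
  cands <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    ori <- window_ok(i, j)
    if (!is.na(ori)) cands[[length(cands) + 1L]] <- list(i = i, j = j, ori = ori)
  }
  blocks <- list()
  used_until <- 0L
  while (length(cands) > 0L) {
    starts <- vapply(cands, `[[`, 0L, "i")
    lens <- vapply(cands, function(x) x$j - x$i, 0L)
    ok <- starts > used_until
    if (!any(ok)) break
    pick <- which(ok)[order(starts[ok], -lens[ok])][1L]
    blk <- cands[[pick]]
    blocks[[length(blocks) + 1L]] <-
      list(rank_a = ra[blk$i:blk$j], rank_b = rb[blk$i:blk$j],
           orientation = blk$ori)
    used_until <- blk$j
  }
  blocks
}

# Cophenetic (merge) height of every leaf pair, by recursion over the tree.
tree_cophenetic <- function(tree) {
  leaves <- sort(leaf_order(tree))
  m <- matrix(0, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  walk <- function(node) {
    if (!is.null(node$label)) return(node$label)
    kids <- lapply(node$children, walk)
    for (a in kids[[1L]]) for (b in kids[[2L]]) {
      m[a, b] <<- m[b, a] <<- node$height
    }
    unlist(kids)
  }
  walk(tree)
  m
}

# Heights of all internal nodes, paired with whether each child's height
# exceeds its parent's (for monotonicity checks).
tree_monotone <- function(tree) {
  ok <- TRUE
  walk <- function(node) {
    if (is.null(node$label)) {
      for (ch in node$children) {
        if (is.null(ch$label) && ch$height > node$height + 1e-9) ok <<- FALSE
        walk(ch)
      }
    }
  }
  walk(tree)
  ok
}

# All internal-node merge heights of a dendro_node tree.
collect_heights <- function(tree) {
  if (!is.null(tree$label)) return(numeric(0))
  c(tree$height, unlist(lapply(tree$children, collect_heights)))
}

# A toy genome with n unit-spaced genes, used by synteny tests.
mk_toy_genome <- function(prefix, n, gene_len = 500L, spacing = 1000L) {
  starts <- seq(1L, by = spacing, length.out = n)
  genome(prefix, starts[n] + gene_len + 10L,
         data.frame(gene_id = paste0(prefix, seq_len(n)), start = starts,
                    end = starts + gene_len - 1L, strand = "+",
                    stringsAsFactors = FALSE))
}

# Minimal 12-column hit rows for hand-built cases.
mk_hits <- function(query, subject, evalue, bitscore = 100,
                    pid = 50, len = 100) {
  n <- length(query)
  hit_table(data.frame(
    query_id = query, subject_id = subject,
    pct_identity = rep_len(pid, n), aln_length = rep_len(len, n),
    mismatches = 0, gap_opens = 0, q_start = 1, q_end = rep_len(len, n),
    s_start = 1, s_end = rep_len(len, n),
    evalue = evalue, bitscore = rep_len(bitscore, n),
    stringsAsFactors = FALSE
  ))
}
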