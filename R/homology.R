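## Hit-table-derived classifications: best hits and reciprocal best hits
## (the standard ortholog proxy), ORFan / meta-ORFan labels, duplicated
## genes from self-comparison, family (COG/NCVOG) assignment, and the
## homolog acceptance filter on alignment length and identity.

#' Threshold configuration
#'
#' Bundles every cutoff used by the hit-derived classifications, with the
#' defaults the analysis is designed around: 1e-5 for reciprocal best hits
#' and ORFan calls, 1e-10 for duplicated-gene detection, 1e-3 for COG/NCVOG
#' family assignment, 1e-100 for high-grade synteny pairs, and the homolog
#' acceptance filter of alignment length strictly greater than 70 residues
#' and identity strictly greater than 20 percent.
#'
#' @param e_rbh,e_dup,e_family,e_synteny_grade E-value cutoffs.
#' @param min_aln_len Minimum alignment length (residues, strict).
#' @param min_pid Minimum percent identity (strict).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(e_rbh = 1e-5, e_dup = 1e-10, e_family = 1e-3,
                             e_synteny_grade = 1e-100, min_aln_len = 70,
                             min_pid = 20) {
  ev <- c(e_rbh = e_rbh, e_dup = e_dup, e_family = e_family,
          e_synteny_grade = e_synteny_grade)
  if (any(ev <= 0 | ev > 1)) abort("e-value cutoffs must lie in (0, 1]")
  structure(list(e_rbh = e_rbh, e_dup = e_dup, e_family = e_family,
                 e_synteny_grade = e_synteny_grade, min_aln_len = min_aln_len,
                 min_pid = min_pid),
            class = "threshold_config")
}

# order hits by the deterministic "best" rule: smallest e-value, then larger
# bitscore, then lexicographic subject id
order_best <- function(hits) {
  order(hits$evalue, -hits$bitscore, hits$subject_id)
}

#' Best hit per query
#'
#' For each query with at least one hit at `evalue <= e_max`, returns the
#' subject of its best hit: smallest e-value, ties broken by larger bit
#' score, then by lexicographically smallest subject id. Queries with no
#' qualifying hit are absent from the result.
#'
#' @param hits A [hit_table].
#' @param e_max E-value cutoff.
#' @return Named character vector, query id -> subject id.
#' @export
best_hits <- function(hits, e_max) {
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(setNames(character(0), character(0)))
  hits <- hits[order_best(hits), , drop = FALSE]
  first <- !duplicated(hits$query_id)
  setNames(hits$subject_id[first], hits$query_id[first])
}

# best hit rows (not just subjects), used to carry e-values/bitscores
best_hit_rows <- function(hits, e_max) {
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order_best(hits), , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Reciprocal best hit pairs between two proteomes
#'
#' A pair (a, b) is reported iff a's best qualifying hit in the A-vs-B table
#' is b and b's best qualifying hit in the B-vs-A table is a. The result is
#' symmetric in the two input tables.
#'
#' @param hits_ab Hit table, proteome A queried against proteome B.
#' @param hits_ba Hit table, proteome B queried against proteome A.
#' @param e_max E-value cutoff (both directions must qualify).
#' @return Data frame of class `ortholog_pairs` with columns `a_id`, `b_id`,
#'   `evalue_ab`, `evalue_ba`, `min_bitscore`, sorted by `a_id`.
#' @export
rbh_pairs <- function(hits_ab, hits_ba, e_max) {
  best_ab <- best_hit_rows(hits_ab, e_max)
  best_ba <- best_hit_rows(hits_ba, e_max)
  fwd <- setNames(best_ab$subject_id, best_ab$query_id)
  rev <- setNames(best_ba$subject_id, best_ba$query_id)
  a_ids <- names(fwd)
  mutual <- !is.na(rev[fwd[a_ids]]) & rev[fwd[a_ids]] == a_ids
  mutual[is.na(mutual)] <- FALSE
  a_keep <- a_ids[mutual]
  b_keep <- unname(fwd[a_keep])
  ab_rows <- best_ab[match(a_keep, best_ab$query_id), , drop = FALSE]
  ba_rows <- best_ba[match(b_keep, best_ba$query_id), , drop = FALSE]
  out <- data.frame(
    a_id = a_keep, b_id = b_keep,
    evalue_ab = ab_rows$evalue, evalue_ba = ba_rows$evalue,
    min_bitscore = pmin(ab_rows$bitscore, ba_rows$bitscore),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$a_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Classify proteins as homolog, ORFan or meta-ORFan
#'
#' A protein is a HOMOLOG if it has any hit at `evalue <= e_max` against the
#' reference protein database; otherwise a META_ORFAN if it has such a hit
#' against the environmental (metagenomic) database; otherwise an ORFAN.
#' The three labels partition the protein set.
#'
#' @param protein_ids Character vector of all protein ids to label.
#' @param hits_vs_refdb Hit table against the reference database.
#' @param hits_vs_envdb Hit table against the environmental database.
#' @param e_max E-value cutoff.
#' @return A list with `labels` (data frame `protein_id`, `label`) and
#'   `fractions` (named vector of the three label proportions).
#' @export
classify_orfans <- function(protein_ids, hits_vs_refdb, hits_vs_envdb, e_max) {
  protein_ids <- as.character(protein_ids)
  for (h in list(hits_vs_refdb, hits_vs_envdb)) {
    stray <- setdiff(unique(h$query_id), protein_ids)
    if (length(stray) > 0L) {
      abort("hits reference unknown protein id(s): ", paste(head(stray, 5L), collapse = ", "))
    }
  }
  ref_pos <- unique(hits_vs_refdb$query_id[hits_vs_refdb$evalue <= e_max])
  env_pos <- unique(hits_vs_envdb$query_id[hits_vs_envdb$evalue <= e_max])
  label <- ifelse(protein_ids %in% ref_pos, "HOMOLOG",
                  ifelse(protein_ids %in% env_pos, "META_ORFAN", "ORFAN"))
  labels <- data.frame(protein_id = protein_ids, label = label,
                       stringsAsFactors = FALSE)
  counts <- table(factor(label, levels = c("HOMOLOG", "META_ORFAN", "ORFAN")))
  list(labels = labels,
       fractions = setNames(as.numeric(counts) / length(protein_ids),
                            names(counts)))
}

#' Duplicated-gene clusters from a self-comparison hit table
#'
#' Builds a graph whose edges are self-comparison hits between distinct
#' proteins at `evalue <= e_max`; duplicated-gene clusters are its connected
#' components of size at least two. A protein is "duplicated" iff it belongs
#' to some cluster.
#'
#' @param self_hits Hit table of a proteome queried against itself.
#' @param e_max E-value cutoff.
#' @return List of character vectors (clusters, each sorted; list sorted by
#'   first member).
#' @export
find_duplicates <- function(self_hits, e_max) {
  edges <- self_hits[self_hits$query_id != self_hits$subject_id &
                       self_hits$evalue <= e_max, c("query_id", "subject_id")]
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  clusters <- Filter(function(m) length(m) >= 2L, members)
  clusters <- lapply(clusters, sort)
  clusters <- unname(clusters[order(vapply(clusters, `[`, character(1L), 1L))])
  clusters
}

#' Assign proteins to families from hits against a family database
#'
#' Each protein is assigned the family of its best qualifying hit (same
#' deterministic tie rules as [best_hits()]: e-value, then bit score, then
#' lexicographic id). Proteins with no hit at `evalue <= e_max` are omitted.
#'
#' @param hits_vs_family_db Hit table against the family database.
#' @param family_map Data frame with columns `subject_id`, `family_id`
#'   mapping database sequences to their families.
#' @param e_max E-value cutoff.
#' @return Data frame with columns `protein_id`, `family_id`, `evalue`.
#' @export
assign_families <- function(hits_vs_family_db, family_map, e_max) {
  hits <- hits_vs_family_db[hits_vs_family_db$evalue <= e_max, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(protein_id = character(0), family_id = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  fam_of <- setNames(as.character(family_map$family_id),
                     as.character(family_map$subject_id))
  unmapped <- setdiff(unique(hits$subject_id), names(fam_of))
  if (length(unmapped) > 0L) {
    abort("subject(s) with no family mapping: ", paste(unmapped, collapse = ", "))
  }
  hits$family_id <- unname(fam_of[hits$subject_id])
  # best per protein: e-value, then bitscore, then family id, then subject id
  hits <- hits[order(hits$evalue, -hits$bitscore, hits$family_id,
                     hits$subject_id), , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  out <- data.frame(protein_id = best$query_id, family_id = best$family_id,
                    evalue = best$evalue, stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter hits by the homolog acceptance rule
#'
#' Keeps hits whose alignment length is strictly greater than `min_len`
#' residues AND whose percent identity is strictly greater than `min_pid` —
#' the acceptance rule used when deciding whether a best hit counts as a
#' genuine homolog.
#'
#' @param hits A [hit_table].
#' @param min_len Minimum alignment length (strict), default 70.
#' @param min_pid Minimum percent identity (strict), default 20.
#' @return The filtered [hit_table].
#' @export
filter_homolog_candidates <- function(hits, min_len = 70, min_pid = 20) {
  out <- hits[hits$aln_length > min_len & hits$pct_identity > min_pid, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
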