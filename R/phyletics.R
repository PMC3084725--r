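## Phyletic profiling: binary taxa-by-family presence/absence matrices,
## Euclidean distances between profiles, deterministic agglomerative
## clustering with Newick export, cluster cutting, and extraction of the
## families that discriminate a focal taxon from a group.

#' Construct a phyletic (presence/absence) matrix
#'
#' @param m An integer/numeric matrix of 0s and 1s with unique row (taxon)
#'   and column (family) labels.
#' @return The matrix with class `phyletic_matrix`.
#' @export
phyletic_matrix <- function(m) {
  if (!is.matrix(m)) abort("phyletic_matrix: not a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("phyletic_matrix: taxa and family labels required")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("phyletic_matrix: duplicate labels")
  }
  if (!all(m %in% c(0, 1))) abort("phyletic_matrix: cells must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("phyletic_matrix", class(matrix()))
  m
}

#' Build a phyletic matrix from per-taxon family assignments
#'
#' Cell (taxon, family) is 1 iff the taxon has at least one protein assigned
#' to the family — presence, not copy number. Families in the universe that
#' are absent everywhere are retained as all-zero columns.
#'
#' @param assignments Named list, taxon -> family table (data frame with a
#'   `family_id` column, e.g. from [assign_families()]).
#' @param universe Character vector of families to use as columns, or `NULL`
#'   (default) for the union of observed families.
#' @return A [phyletic_matrix] with taxa in the order given and families
#'   sorted.
#' @export
build_matrix <- function(assignments, universe = NULL) {
  if (length(assignments) == 0L) abort("build_matrix: empty taxon set")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    abort("build_matrix: assignments must be named by taxon")
  }
  observed <- unique(unlist(lapply(assignments, function(tab) {
    as.character(tab$family_id)
  }), use.names = FALSE))
  families <- if (is.null(universe)) sort(observed) else as.character(universe)
  m <- matrix(0L, nrow = length(assignments), ncol = length(families),
              dimnames = list(names(assignments), families))
  for (taxon in names(assignments)) {
    present <- intersect(unique(as.character(assignments[[taxon]]$family_id)),
                         families)
    m[taxon, present] <- 1L
  }
  phyletic_matrix(m)
}

#' Euclidean distances between phyletic profiles
#'
#' For binary rows the Euclidean distance is the square root of the Hamming
#' distance (the number of differing families).
#'
#' @param matrix A [phyletic_matrix] with at least two taxa.
#' @return A symmetric numeric matrix of distances with taxon labels, class
#'   `dist_matrix`.
#' @export
euclidean_distances <- function(matrix) {
  if (nrow(matrix) < 2L) abort("euclidean_distances: need at least 2 taxa")
  d <- as.matrix(dist(matrix, method = "euclidean"))
  class(d) <- c("dist_matrix", class(base::matrix()))
  d
}

#' Deterministic agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering: repeatedly merge the two clusters at
#' minimal linkage distance; the merge height is that distance. Binary data
#' produce exact distance ties routinely, so ties are broken
#' deterministically: among tied cluster pairs, the pair whose smallest
#' member labels sort first lexicographically is merged. Linkage updates
#' follow the Lance-Williams recurrences for single, complete and average
#' linkage, under all of which merge heights are monotone non-decreasing.
#'
#' @param dist A symmetric distance matrix with taxon labels (e.g. from
#'   [euclidean_distances()]).
#' @param linkage `"complete"` (default), `"single"` or `"average"`.
#' @return The root `dendro_node`: a nested list; leaves have `label`,
#'   internal nodes have `height`, `children` (list of two nodes), `members`
#'   (sorted leaf labels) and `step` (merge order).
#' @export
hierarchical_cluster <- function(dist, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(unclass(dist))
  n <- nrow(d)
  if (n < 2L) abort("hierarchical_cluster: need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) abort("hierarchical_cluster: distance matrix must be labelled")
  nodes <- lapply(labels, function(l) {
    structure(list(label = l, height = 0, members = l), class = "dendro_node")
  })
  reps <- labels              # smallest member label per active cluster
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  diag(d) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    mn <- min(sub)
    ties <- which(sub <= mn & upper.tri(sub), arr.ind = TRUE)
    # order candidate pairs by the sorted pair of representative labels
    r1 <- reps[idx[ties[, 1L]]]; r2 <- reps[idx[ties[, 2L]]]
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    pick <- order(lo, hi)[1L]
    i <- idx[ties[pick, 1L]]; j <- idx[ties[pick, 2L]]
    # put the lexicographically smaller representative first
    if (reps[j] < reps[i]) { tmp <- i; i <- j; j <- tmp }
    node <- structure(list(
      height = mn,
      children = list(nodes[[i]], nodes[[j]]),
      members = sort(c(nodes[[i]]$members, nodes[[j]]$members)),
      step = step
    ), class = "dendro_node")
    # Lance-Williams update into slot i
    others <- setdiff(which(active), c(i, j))
    if (length(others) > 0L) {
      dik <- d[i, others]; djk <- d[j, others]
      d[i, others] <- switch(linkage,
        single   = pmin(dik, djk),
        complete = pmax(dik, djk),
        average  = (sizes[i] * dik + sizes[j] * djk) / (sizes[i] + sizes[j])
      )
      d[others, i] <- d[i, others]
    }
    nodes[[i]] <- node
    sizes[i] <- sizes[i] + sizes[j]
    reps[i] <- min(reps[i], reps[j])
    active[j] <- FALSE
  }
  nodes[[which(active)]]
}

is_leaf <- function(node) !is.null(node$label)

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are parent height minus child height (leaves have height
#' 0), so the tree is ultrametric: the path from any leaf up to an internal
#' node has total length equal to that node's merge height.
#'
#' @param tree A `dendro_node` from [hierarchical_cluster()].
#' @return A Newick string, terminated with `;`.
#' @export
to_newick <- function(tree) {
  fmt_h <- function(h) format(h, digits = 12, trim = TRUE, scientific = FALSE)
  rec <- function(node, parent_height) {
    if (is_leaf(node)) {
      paste0(node$label, ":", fmt_h(parent_height))
    } else {
      inner <- paste(vapply(node$children, rec, character(1L),
                            parent_height = node$height), collapse = ",")
      paste0("(", inner, "):", fmt_h(parent_height - node$height))
    }
  }
  if (is_leaf(tree)) return(paste0(tree$label, ";"))
  inner <- paste(vapply(tree$children, rec, character(1L),
                        parent_height = tree$height), collapse = ",")
  paste0("(", inner, ");")
}

#' Dendrogram leaf order
#'
#' Left-to-right leaf labels, the order used for heatmap rows/columns.
#'
#' @param tree A `dendro_node`.
#' @return Character vector of leaf labels.
#' @export
leaf_order <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, leaf_order), use.names = FALSE)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges (ties resolved by the deterministic
#' merge order, which is height- then label-ordered) and returns the leaf
#' sets of the remaining subtrees.
#'
#' @param tree A `dendro_node` from [hierarchical_cluster()].
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return List of sorted character vectors (one per cluster), sorted by
#'   first member.
#' @export
cut_clusters <- function(tree, k) {
  leaves <- leaf_order(tree)
  n <- length(leaves)
  if (k < 1L || k > n) abort("cut_clusters: k must be in [1, n_leaves]")
  keep_max <- n - k  # merges retained
  out <- list()
  collect <- function(node) {
    if (!is_leaf(node) && node$step > keep_max) {
      for (ch in node$children) collect(ch)
    } else {
      out[[length(out) + 1L]] <<- sort(if (is_leaf(node)) node$label else node$members)
    }
  }
  collect(tree)
  out[order(vapply(out, `[`, character(1L), 1L))]
}

#' Restrict a phyletic matrix to families present in a group
#'
#' Keeps only families with at least one presence among the given taxa
#' (e.g. "families present in at least one NCLDV genome"); all taxa are
#' retained as rows.
#'
#' @param matrix A [phyletic_matrix].
#' @param group Character vector of taxa (subset of the matrix's taxa).
#' @return The column-restricted [phyletic_matrix].
#' @export
restrict_to_group <- function(matrix, group) {
  if (length(group) == 0L) abort("restrict_to_group: empty group")
  unknown <- setdiff(group, rownames(matrix))
  if (length(unknown) > 0L) {
    abort("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  keep <- colSums(matrix[group, , drop = FALSE]) >= 1L
  phyletic_matrix(unclass(matrix)[, keep, drop = FALSE])
}

#' Families differing between two taxa
#'
#' @param matrix A [phyletic_matrix].
#' @param taxon_a,taxon_b Taxa to compare.
#' @param family_subset Families to consider (default: all).
#' @return Character vector of families where the two presence values
#'   differ. Its length equals the squared Euclidean distance between the
#'   two profiles restricted to the subset.
#' @export
phyletic_differences <- function(matrix, taxon_a, taxon_b,
                                 family_subset = colnames(matrix)) {
  unknown <- setdiff(c(taxon_a, taxon_b), rownames(matrix))
  if (length(unknown) > 0L) abort("unknown taxa: ", paste(unknown, collapse = ", "))
  fams <- intersect(family_subset, colnames(matrix))
  diff <- matrix[taxon_a, fams] != matrix[taxon_b, fams]
  fams[diff]
}

#' Families discriminating a focal taxon from a group
#'
#' After restricting to families present in the group or the focal taxon,
#' returns the families where the focal taxon's presence value differs from
#' the value shared by a strict majority (> `majority`) of the group. Split
#' families with no strict majority are excluded.
#'
#' @param matrix A [phyletic_matrix].
#' @param focal The focal taxon.
#' @param group Character vector of comparison taxa (must exclude the
#'   focal taxon).
#' @param majority Majority fraction threshold (strict; default 0.5).
#' @return Character vector of discriminant families.
#' @export
focal_discriminant <- function(matrix, focal, group, majority = 0.5) {
  if (length(group) == 0L) abort("focal_discriminant: empty group")
  if (focal %in% group) abort("focal_discriminant: group must exclude the focal taxon")
  m <- restrict_to_group(matrix, c(focal, group))
  frac1 <- colMeans(m[group, , drop = FALSE])
  consensus <- ifelse(frac1 > majority, 1L,
                      ifelse(1 - frac1 > majority, 0L, NA_integer_))
  focal_vals <- m[focal, ]
  keep <- !is.na(consensus) & focal_vals != consensus
  colnames(m)[keep]
}
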