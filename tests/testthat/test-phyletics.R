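fam_tab <- function(...) data.frame(family_id = c(...), stringsAsFactors = FALSE)

test_that("build_matrix records presence, not copy number", {
  m <- build_matrix(list(
    t1 = fam_tab("F1", "F1", "F1"),   # three proteins in one family
    t2 = fam_tab("F2")
  ))
  expect_equal(unname(m["t1", "F1"]), 1L)
  expect_equal(unname(m["t1", "F2"]), 0L)
  expect_equal(unname(m["t2", "F2"]), 1L)
  # all-zero column retained when the universe says so
  m2 <- build_matrix(list(t1 = fam_tab("F1")), universe = c("F1", "F9"))
  expect_equal(unname(m2[1, "F9"]), 0L)
  expect_error(build_matrix(list()), "empty taxon set")
})

test_that("Euclidean distances equal the brute-force double loop", {
  m <- phyletic_matrix(matrix(c(1, 0, 1, 1, 1, 1, 0, 1), 2, 4, byrow = TRUE,
                              dimnames = list(c("s", "t"), paste0("f", 1:4))))
  d <- euclidean_distances(m)
  expect_equal(unname(d["s", "t"]), sqrt(2))
  expect_equal(unname(d["s", "s"]), 0)
  set.seed(5)
  r <- matrix(rbinom(120, 1, 0.4), 6, 20,
              dimnames = list(paste0("t", 1:6), paste0("f", 1:20)))
  d2 <- euclidean_distances(phyletic_matrix(r))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(unname(d2[i, j]), sqrt(sum((r[i, ] - r[j, ])^2)))
  }
  # metric axioms
  expect_true(all(d2 >= 0))
  expect_equal(unclass(d2), t(unclass(d2)))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(d2[i, k], d2[i, j] + d2[j, k] + 1e-12)
  }
})

test_that("the 4-point worked example clusters as expected", {
  d <- matrix(10, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 1
  tree <- hierarchical_cluster(d, "complete")
  expect_equal(tree$height, 10)
  expect_equal(sort(vapply(tree$children, `[[`, 0, "height")), c(1, 1))
  expect_equal(cut_clusters(tree, 2), list(c("A", "B"), c("C", "D")))
  expect_equal(to_newick(tree), "((A:1,B:1):9,(C:1,D:1):9);")
})

test_that("identical taxa merge first at height zero", {
  m <- phyletic_matrix(matrix(c(1, 0, 1, 1, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE,
                              dimnames = list(c("x", "y", "z"), paste0("f", 1:3))))
  m[2, ] <- m[1, ]
  tree <- hierarchical_cluster(euclidean_distances(m), "single")
  first <- tree$children[[which(vapply(tree$children, function(n) is.null(n$label),
                                       logical(1)))[1]]]
  expect_equal(first$height, 0)
  expect_setequal(first$members, c("x", "y"))
})

test_that("merge heights are monotone along every root path", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rbinom(8 * 30, 1, runif(1, 0.2, 0.8)), 8, 30,
                dimnames = list(paste0("t", 1:8), paste0("f", 1:30)))
    d <- euclidean_distances(phyletic_matrix(m))
    for (lk in c("single", "complete", "average")) {
      expect_true(tree_monotone(hierarchical_cluster(d, lk)),
                  info = paste(lk, i))
    }
  }
})

test_that("clustering agrees with the reference implementation on tie-free data", {
  set.seed(77)
  for (lk in c("single", "complete", "average")) {
    x <- matrix(rnorm(9 * 5), 9, 5, dimnames = list(letters[1:9], NULL))
    d <- as.matrix(dist(x))
    tree <- hierarchical_cluster(d, lk)
    hc <- stats::hclust(stats::as.dist(d), method = lk)
    expect_equal(sort(collect_heights(tree)), sort(hc$height), tolerance = 1e-12)
    coph_ref <- as.matrix(stats::cophenetic(hc))
    coph_got <- tree_cophenetic(tree)
    ord <- rownames(coph_got)
    expect_equal(coph_got, coph_ref[ord, ord], tolerance = 1e-12)
  }
})

test_that("clustering is invariant under taxon permutation", {
  set.seed(13)
  m <- matrix(rbinom(6 * 25, 1, 0.4), 6, 25,
              dimnames = list(paste0("t", 1:6), paste0("f", 1:25)))
  d <- euclidean_distances(phyletic_matrix(m))
  t1 <- hierarchical_cluster(d, "complete")
  perm <- sample(1:6)
  t2 <- hierarchical_cluster(d[perm, perm], "complete")
  expect_equal(tree_cophenetic(t1), tree_cophenetic(t2))
})

test_that("newick output round-trips through an independent parser", {
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- hierarchical_cluster(d, "complete")
  expect_equal(to_newick(tree), "(A:2,B:2);")
  set.seed(21)
  m <- matrix(rbinom(7 * 40, 1, 0.35), 7, 40,
              dimnames = list(paste0("t", 1:7), paste0("f", 1:40)))
  tr <- hierarchical_cluster(euclidean_distances(phyletic_matrix(m)), "average")
  phy <- ape::read.tree(text = to_newick(tr))
  # ultrametric trees: patristic distance between leaves = 2 * merge height
  pat <- ape::cophenetic.phylo(phy)
  coph <- tree_cophenetic(tr)
  ord <- rownames(coph)
  expect_equal(pat[ord, ord] / 2, coph, tolerance = 1e-9)
})

test_that("cut_clusters spans the k range and recovers planted groups", {
  res <- gen_phyletic_profiles(4, 10, 200, 0.15, 0.02, seed = 19)
  tree <- hierarchical_cluster(euclidean_distances(res$matrix), "complete")
  expect_length(cut_clusters(tree, 1), 1L)
  expect_length(cut_clusters(tree, 40), 40L)
  got <- cut_clusters(tree, 4)
  want <- unname(lapply(split(names(res$truth$group_of), res$truth$group_of),
                        sort))
  expect_equal(got[order(vapply(got, `[`, "", 1))],
               want[order(vapply(want, `[`, "", 1))])
  expect_error(cut_clusters(tree, 0), "k must be")
})

test_that("restrict_to_group keeps families present in the group", {
  m <- phyletic_matrix(matrix(c(1, 0, 0,
                                0, 1, 0,
                                0, 1, 1), 3, 3, byrow = TRUE,
                              dimnames = list(c("t1", "t2", "t3"),
                                              c("f1", "f2", "f3"))))
  r <- restrict_to_group(m, c("t2", "t3"))
  expect_equal(colnames(r), c("f2", "f3"))   # f1 present only outside group
  expect_equal(rownames(r), rownames(m))     # all taxa retained
  r2 <- restrict_to_group(m, rownames(m))
  expect_equal(colnames(r2), c("f1", "f2", "f3"))
  expect_error(restrict_to_group(m, character(0)), "empty group")
})

test_that("phyletic differences equal the squared Euclidean distance", {
  m <- phyletic_matrix(matrix(c(1, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("f1", "f2", "f3"))))
  expect_equal(phyletic_differences(m, "a", "b"), "f1")
  expect_equal(phyletic_differences(m, "a", "a"), character(0))
  expect_error(phyletic_differences(m, "a", "zz"), "unknown taxa")
  set.seed(8)
  for (i in 1:10) {
    r <- matrix(rbinom(2 * 30, 1, 0.5), 2, 30,
                dimnames = list(c("a", "b"), paste0("f", 1:30)))
    pm <- phyletic_matrix(r)
    sub <- sample(colnames(r), 12)
    nd <- length(phyletic_differences(pm, "a", "b", sub))
    expect_equal(nd, sum((r["a", sub] - r["b", sub])^2))
  }
})

test_that("focal discriminant families follow the strict-majority rule", {
  m <- phyletic_matrix(matrix(c(
    0, 1, 1, 0,    # focal
    1, 1, 0, 0,
    1, 1, 0, 0,
    1, 0, 1, 0,
    1, 0, 0, 0
  ), 5, 4, byrow = TRUE,
  dimnames = list(c("focal", paste0("g", 1:4)), paste0("f", 1:4))))
  group <- paste0("g", 1:4)
  # f1: group all 1, focal 0 -> discriminant. f2: group split 2/2 -> excluded.
  # f3: group 1/4 -> consensus 0, focal 1 -> discriminant.
  # f4: absent everywhere -> dropped by the restriction.
  expect_equal(focal_discriminant(m, "focal", group), c("f1", "f3"))
  # focal identical to the whole group: nothing discriminates
  m2 <- phyletic_matrix(matrix(1L, 3, 2,
                               dimnames = list(c("focal", "g1", "g2"),
                                               c("f1", "f2"))))
  expect_equal(focal_discriminant(m2, "focal", c("g1", "g2")), character(0))
  expect_error(focal_discriminant(m, "focal", character(0)), "empty group")
  expect_error(focal_discriminant(m, "focal", c("focal", "g1")),
               "exclude the focal")
})
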