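test_that("best_hits picks the smallest e-value under the cutoff", {
  hits <- mk_hits(c("a1", "a1"), c("b1", "b2"), c(1e-50, 1e-10))
  expect_equal(best_hits(hits, 1e-5), c(a1 = "b1"))
  # a single hit above the cutoff leaves the query unmapped
  weak <- mk_hits("a1", "b1", 1e-4)
  expect_length(best_hits(weak, 1e-5), 0L)
  # the cutoff is inclusive
  at <- mk_hits("a1", "b1", 1e-5)
  expect_equal(best_hits(at, 1e-5), c(a1 = "b1"))
})

test_that("best_hits ties break by bitscore then lexicographic subject", {
  tied <- mk_hits(c("a1", "a1"), c("b2", "b1"), c(1e-30, 1e-30),
                  bitscore = c(200, 150))
  expect_equal(best_hits(tied, 1e-5), c(a1 = "b2"))
  tied2 <- mk_hits(c("a1", "a1"), c("b2", "b1"), c(1e-30, 1e-30),
                   bitscore = c(200, 200))
  expect_equal(best_hits(tied2, 1e-5), c(a1 = "b1"))
  # result independent of input row order
  expect_equal(best_hits(tied2[2:1, ], 1e-5), c(a1 = "b1"))
})

test_that("rbh_pairs requires mutual best hits", {
  ab <- mk_hits(c("a1", "a2"), c("b1", "b1"), c(1e-50, 1e-20))
  ba <- mk_hits("b1", "a1", 1e-40)
  got <- rbh_pairs(ab, ba, 1e-5)
  expect_equal(got$a_id, "a1")
  expect_equal(got$b_id, "b1")
  expect_equal(got$evalue_ab, 1e-50)
  expect_equal(got$evalue_ba, 1e-40)
  # asymmetric bests yield nothing: a1's best is b1 but b1's best is a2
  ba2 <- mk_hits("b1", "a2", 1e-40)
  ab2 <- mk_hits("a1", "b1", 1e-50)
  expect_equal(nrow(rbh_pairs(ab2, ba2, 1e-5)), 0L)
})

test_that("rbh_pairs is symmetric in its two inputs", {
  for (s in 1:20) {
    tabs <- gen_hit_table(
      data.frame(a_id = sprintf("a%02d", 1:15), b_id = sprintf("b%02d", 1:15)),
      decoy_a = sprintf("a%02d", 16:25), decoy_b = sprintf("b%02d", 16:25),
      fp_rate = 0.3, fn_rate = 0.2, seed = 300 + s)
    fwd <- rbh_pairs(tabs$ab, tabs$ba, 1e-5)
    mirror <- rbh_pairs(tabs$ba, tabs$ab, 1e-5)
    expect_setequal(paste(fwd$a_id, fwd$b_id),
                    paste(mirror$b_id, mirror$a_id))
  }
})

test_that("raising the cutoff never removes an RBH pair's qualifying hits", {
  tabs <- gen_hit_table(
    data.frame(a_id = sprintf("a%02d", 1:20), b_id = sprintf("b%02d", 1:20)),
    decoy_a = sprintf("a%02d", 21:30), decoy_b = sprintf("b%02d", 21:30),
    fp_rate = 0.3, fn_rate = 0, seed = 17)
  strict <- rbh_pairs(tabs$ab, tabs$ba, 1e-50)
  # every strict pair's hits still qualify at the looser cutoff
  loose_ab <- best_hits(tabs$ab, 1e-5)
  for (i in seq_len(nrow(strict))) {
    expect_true(strict$a_id[i] %in% names(loose_ab))
  }
})

test_that("orfan classification follows the reference-then-environmental rule", {
  ids <- c("p1", "p2", "p3", "p4")
  ref <- mk_hits(c("p1", "p2"), c("nr1", "nr2"), c(1e-30, 1e-4))
  env <- mk_hits(c("p2", "p3"), c("env1", "env2"), c(1e-20, 1e-3))
  res <- classify_orfans(ids, ref, env, 1e-5)
  lab <- setNames(res$labels$label, res$labels$protein_id)
  expect_equal(lab[["p1"]], "HOMOLOG")     # reference hit below cutoff
  expect_equal(lab[["p2"]], "META_ORFAN")  # ref hit too weak, env hit strong
  expect_equal(lab[["p3"]], "ORFAN")       # env hit above cutoff
  expect_equal(lab[["p4"]], "ORFAN")       # no hits at all
  # labels partition the protein set and fractions sum to one
  expect_equal(nrow(res$labels), length(ids))
  expect_equal(sum(res$fractions), 1)
  expect_equal(unname(res$fractions), c(1, 1, 2) / 4)
  expect_error(classify_orfans(c("p1"), ref, env, 1e-5), "unknown protein")
})

test_that("duplicated genes are connected components of strong self-hits", {
  # self-matches alone never create duplicates
  self_only <- mk_hits(c("a1", "a2"), c("a1", "a2"), c(0, 0))
  expect_length(find_duplicates(self_only, 1e-10), 0L)
  # one mutual pair
  pair <- mk_hits(c("a1", "a2"), c("a2", "a1"), c(1e-50, 1e-50))
  expect_equal(find_duplicates(pair, 1e-10), list(c("a1", "a2")))
  # the cutoff is respected: 1e-8 does not qualify at 1e-10
  weak <- mk_hits("a1", "a2", 1e-8)
  expect_length(find_duplicates(weak, 1e-10), 0L)
  # transitivity: a-b and b-c hits give one 3-member cluster
  chain <- mk_hits(c("a1", "a2"), c("a2", "a3"), c(1e-40, 1e-40))
  expect_equal(find_duplicates(chain, 1e-10), list(c("a1", "a2", "a3")))
})

test_that("family assignment uses the best qualifying hit with stable ties", {
  fmap <- data.frame(subject_id = c("s1", "s2", "s3"),
                     family_id = c("COG2", "COG1", "COG3"))
  ok <- mk_hits("p1", "s1", 1e-6)
  got <- assign_families(ok, fmap, 1e-3)
  expect_equal(got$family_id, "COG2")
  # above the cutoff: unassigned (omitted)
  weak <- mk_hits("p1", "s1", 1e-2)
  expect_equal(nrow(assign_families(weak, fmap, 1e-3)), 0L)
  # e-value tie: higher bitscore wins
  tie <- mk_hits(c("p1", "p1"), c("s1", "s2"), c(1e-6, 1e-6),
                 bitscore = c(100, 200))
  expect_equal(assign_families(tie, fmap, 1e-3)$family_id, "COG1")
  # full tie: lexicographically smaller family
  tie2 <- mk_hits(c("p1", "p1"), c("s1", "s2"), c(1e-6, 1e-6),
                  bitscore = c(100, 100))
  expect_equal(assign_families(tie2, fmap, 1e-3)$family_id, "COG1")
  # unmapped subject is an error naming the subject
  expect_error(assign_families(mk_hits("p1", "sX", 1e-6), fmap, 1e-3), "sX")
})

test_that("the homolog acceptance filter uses strict inequalities", {
  hits <- mk_hits(c("p1", "p2", "p3"), c("s1", "s2", "s3"),
                  rep(1e-20, 3), len = c(100, 70, 100), pid = c(25, 25, 20))
  kept <- filter_homolog_candidates(hits, 70, 20)
  expect_equal(kept$query_id, "p1")  # len 70 and pid 20 both fail strict >
})

test_that("threshold_config carries the documented defaults", {
  thr <- threshold_config()
  expect_equal(thr$e_rbh, 1e-5)
  expect_equal(thr$e_dup, 1e-10)
  expect_equal(thr$e_family, 1e-3)
  expect_equal(thr$e_synteny_grade, 1e-100)
  expect_equal(thr$min_aln_len, 70)
  expect_equal(thr$min_pid, 20)
  expect_error(threshold_config(e_rbh = 0), "\\(0, 1\\]")
})
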