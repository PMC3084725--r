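test_that("genes are classified terminal/central by midpoint", {
  spec <- region_spec(618000, 50000)
  f <- data.frame(start = c(10000, 300000, 570000),
                  end = c(11000, 301500, 572000))
  expect_equal(classify_region(f, spec), c("TERMINAL", "CENTRAL", "TERMINAL"))
  # boundary: midpoint exactly at the window edge is terminal (inclusive),
  # one past the symmetric edge is terminal on the right
  edge <- data.frame(start = c(49999, 50001, 567999, 568001),
                     end = c(50001, 50003, 568001, 568003))
  expect_equal(classify_region(edge, spec),
               c("TERMINAL", "CENTRAL", "CENTRAL", "TERMINAL"))
  expect_error(classify_region(data.frame(start = 1, end = 700000), spec),
               "beyond genome length")
})

test_that("every gene falls in exactly one region", {
  res <- gen_annotated_genome(618000, 300, 50000, 0.3, 0.3, seed = 4)
  spec <- region_spec(618000, 50000)
  region <- classify_region(res$genome, spec)
  expect_equal(sum(region == "TERMINAL") + sum(region == "CENTRAL"), 300L)
  # exactly the genes with midpoint in [1, W] or (L - W, L] are terminal
  f <- res$genome$features
  mid <- floor((f$start + f$end) / 2)
  expect_equal(region == "TERMINAL", mid <= 50000 | mid > 568000)
})

test_that("contingency tables equal a hand count", {
  # 10 genes at controlled positions: 4 terminal, 6 central
  starts <- c(1000, 20000, 40000, 95001, 60000, 70000, 80000, 85000, 90000, 92000)
  g <- genome("toy", 100000,
              data.frame(gene_id = paste0("g", 1:10), start = starts,
                         end = starts + 100, strand = "+"))
  spec <- region_spec(100000, 5000)
  # terminal: midpoints <= 5000 or > 95000 -> g1 (1050) and g4 (95051)
  ct <- contingency(g, c("g1", "g5"), spec)
  expect_equal(ct$a, 1L)  # g1: category, terminal
  expect_equal(ct$b, 1L)  # g5: category, central
  expect_equal(ct$c, 1L)  # g4: other, terminal
  expect_equal(ct$d, 7L)
  # empty category
  ct0 <- contingency(g, character(0), spec)
  expect_equal(c(ct0$a, ct0$b), c(0L, 0L))
  expect_equal(ct0$c + ct0$d, 10L)
  # all genes in category
  ct1 <- contingency(g, paste0("g", 1:10), spec)
  expect_equal(c(ct1$c, ct1$d), c(0L, 0L))
  expect_error(contingency(g, "nope", spec), "unknown gene id")
})

test_that("the exact test reproduces its worked values", {
  expect_equal(fisher_exact_two_sided(c(1, 9, 1, 9)), 1.0)
  expect_equal(fisher_exact_two_sided(c(3, 1, 1, 3)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(c(0, 10, 10, 0)), 2 / 184756,
               tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(c(0, 0, 0, 0)), "all-zero")
})

test_that("the exact test matches enumeration and R's reference test", {
  set.seed(42)
  for (i in 1:50) {
    x <- as.vector(stats::rmultinom(1, sample(5:60, 1), runif(4, 0.05, 1)))
    p <- fisher_exact_two_sided(x)
    expect_equal(p, oracle_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(x, 2, 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
    # invariance under swapping rows and under swapping columns
    expect_equal(p, fisher_exact_two_sided(c(x[3], x[4], x[1], x[2])),
                 tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_sided(c(x[2], x[1], x[4], x[3])),
                 tolerance = 1e-12)
  }
})

test_that("enrichment reports rates, odds ratio and p on a flat table", {
  # 100 terminal genes (5 in category) and 100 central genes (5 in category)
  starts_t <- seq(1, by = 40, length.out = 100)          # midpoints < 5000
  starts_c <- seq(40000, by = 40, length.out = 100)      # central
  g <- genome("toy", 100000, data.frame(
    gene_id = paste0("g", 1:200), start = c(starts_t, starts_c),
    end = c(starts_t, starts_c) + 20, strand = "+"))
  spec <- region_spec(100000, 5000)
  cat_ids <- paste0("g", c(1:5, 101:105))
  enr <- enrichment(g, cat_ids, spec)
  expect_equal(enr$rate_terminal, 5)
  expect_equal(enr$rate_central, 5)
  expect_equal(enr$odds_ratio, 1)
  expect_equal(enr$p_two_sided, 1)
})

test_that("enrichment errors when a region holds no genes", {
  starts <- seq(40000, by = 100, length.out = 20)
  g <- genome("toy", 100000, data.frame(
    gene_id = paste0("g", 1:20), start = starts, end = starts + 50,
    strand = "+"))
  spec <- region_spec(100000, 5000)
  expect_error(enrichment(g, "g1", spec), "terminal")
})

test_that("planted positional bias is detected", {
  res <- gen_annotated_genome(618000, 500, 50000, 0.5, 0.1, seed = 11)
  enr <- enrichment(res$genome, res$truth$in_category,
                    region_spec(618000, 50000))
  expect_lt(enr$p_two_sided, 0.01)
  expect_gt(enr$rate_terminal, enr$rate_central)
})

test_that("genome tracks carry one row per gene with joined labels", {
  g <- mk_toy_genome("g", 3)
  tr <- genome_tracks(g, list(g1 = c("DUPLICATED", "RBH:Mimivirus"),
                              g3 = "ORFAN"))
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$labels, c("DUPLICATED;RBH:Mimivirus", "", "ORFAN"))
  expect_error(genome_tracks(g, list(gX = "ORFAN")), "unknown gene")
  # round-trip through TSV preserves the labels
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = NULL,
                            colClasses = "character")
  expect_equal(back$labels, tr$labels)
})
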