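## Orchestration: run the full analysis (simulate -> homology ->
## architecture -> synteny -> phyletics -> rscu) from one configuration,
## writing every stage's outputs plus a reproducibility manifest with seeds,
## thresholds and output checksums. Re-running an identical configuration
## reproduces identical checksums.

ALL_STAGES <- c("simulate", "rbh", "orfans", "duplicates", "families",
                "architecture", "synteny", "phyletics", "rscu")

#' Build a pipeline configuration
#'
#' Defaults equal the thresholds the analysis is designed around (see
#' [threshold_config()]) and a 50,000-nt terminal window. A configuration
#' either names existing input files in `inputs` or includes the
#' `"simulate"` stage, which generates truth-known synthetic inputs for all
#' later stages.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `"simulate"`, `"rbh"`, `"orfans"`, `"duplicates"`, `"families"`,
#'   `"architecture"`, `"synteny"`, `"phyletics"`, `"rscu"`; or `"all"`.
#' @param thresholds A [threshold_config()].
#' @param window Terminal window size in nucleotides.
#' @param linkage Clustering linkage: `"complete"`, `"single"` or
#'   `"average"`.
#' @param inputs Named list of input paths (`genome_a`, `genome_b`,
#'   `hits_ab`, `hits_ba`, `hits_ref`, `hits_env`, `self_hits`,
#'   `hits_family`, `family_map`, `category_file`, `phyletic_matrix`,
#'   `cds`). Filled in by the simulate stage when present.
#' @param simulate Named list of generator sizes used by the simulate stage:
#'   `genome_length`, `n_genes`, `p_cat_terminal`, `p_cat_central`,
#'   `ortholog_frac`, `n_groups`, `taxa_per_group`, `n_families`,
#'   `core_frac`, `flip_rate`, `n_cds`, `cds_length_codons`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, stages = "all",
                            thresholds = threshold_config(), window = 50000,
                            linkage = "complete", inputs = list(),
                            simulate = list()) {
  if (identical(stages, "all")) stages <- ALL_STAGES
  sim_defaults <- list(
    genome_length = 618000, n_genes = 500, p_cat_terminal = 0.5,
    p_cat_central = 0.1, ortholog_frac = 0.6, n_groups = 4L,
    taxa_per_group = 10L, n_families = 200L, core_frac = 0.15,
    flip_rate = 0.02, n_cds = 40L, cds_length_codons = 300L
  )
  sim <- utils::modifyList(sim_defaults, simulate)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    thresholds = thresholds, window = window, linkage = linkage,
    inputs = inputs, simulate = sim
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file does not exist: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  thr <- do.call(threshold_config, as.list(raw$thresholds %||% list()))
  pipeline_config(
    out_dir = raw$out_dir %||% ".",
    seed = raw$seed %||% 1L,
    stages = unlist(raw$stages %||% "all"),
    thresholds = thr,
    window = raw$window %||% 50000,
    linkage = raw$linkage %||% "complete",
    inputs = as.list(raw$inputs %||% list()),
    simulate = as.list(raw$simulate %||% list())
  )
}

#' Validate a pipeline configuration
#'
#' Checks thresholds, window geometry, stage spelling and the presence of
#' every input file the requested stages need (inputs the simulate stage
#' will generate are exempt). Returns the violations rather than erroring,
#' so callers can report all problems at once; an empty result means the
#' configuration is runnable.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of violations; empty if valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  bad_stage <- setdiff(config$stages, ALL_STAGES)
  if (length(bad_stage) > 0L) {
    v <- c(v, paste0("stages: unknown stage(s) ", paste(bad_stage, collapse = ", ")))
  }
  thr <- config$thresholds
  ev <- c(e_rbh = thr$e_rbh, e_dup = thr$e_dup, e_family = thr$e_family,
          e_synteny_grade = thr$e_synteny_grade)
  for (nm in names(ev)) {
    if (!is.numeric(ev[[nm]]) || ev[[nm]] <= 0 || ev[[nm]] > 1) {
      v <- c(v, paste0("thresholds.", nm, ": e-value must lie in (0, 1]"))
    }
  }
  glen <- config$simulate$genome_length
  if (2 * config$window >= glen) {
    v <- c(v, paste0("window: 2*window (", 2 * config$window,
                     ") must be smaller than the genome length (", glen, ")"))
  }
  if (!config$linkage %in% c("complete", "single", "average")) {
    v <- c(v, "linkage: must be one of complete, single, average")
  }
  simulated <- "simulate" %in% config$stages
  need <- list(
    rbh = c("hits_ab", "hits_ba"),
    orfans = c("genome_a", "hits_ref", "hits_env"),
    duplicates = "self_hits",
    families = c("hits_family", "family_map"),
    architecture = c("genome_a", "category_file"),
    synteny = c("genome_a", "genome_b", "hits_ab", "hits_ba"),
    phyletics = "phyletic_matrix",
    rscu = "cds"
  )
  if (!simulated) {
    for (stage in intersect(config$stages, names(need))) {
      for (inp in need[[stage]]) {
        path <- config$inputs[[inp]]
        if (is.null(path)) {
          v <- c(v, paste0("inputs.", inp, ": required by stage '", stage,
                           "' but not set"))
        } else if (!file.exists(path)) {
          v <- c(v, paste0("inputs.", inp, ": file does not exist: ", path))
        }
      }
    }
  }
  v
}

# sub-seed derivation: distinct, reproducible, below 2^31
sub_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

simulate_stage <- function(config) {
  dir <- file.path(config$out_dir, "inputs")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate
  seed <- config$seed
  p <- function(name) file.path(dir, name)

  ga <- gen_annotated_genome(sim$genome_length, sim$n_genes, config$window,
                             sim$p_cat_terminal, sim$p_cat_central,
                             seed = sub_seed(seed, 1L))
  gb <- gen_annotated_genome(sim$genome_length, sim$n_genes, config$window,
                             sim$p_cat_terminal, sim$p_cat_central,
                             seed = sub_seed(seed, 2L))
  ids_a <- ga$genome$features$gene_id
  ids_b <- paste0("B_", gb$genome$features$gene_id)
  gb$genome$features$gene_id <- ids_b
  write_genome(ga$genome, p("genome_a.tsv"))
  write_genome(gb$genome, p("genome_b.tsv"))
  writeLines(ga$truth$in_category, p("category.tsv"))

  # orthologs on matching ranks for a contiguous run of the genome, so the
  # planted pairs carry collinear synteny
  n_orth <- floor(sim$ortholog_frac * sim$n_genes)
  planted <- data.frame(a_id = ids_a[seq_len(n_orth)],
                        b_id = ids_b[seq_len(n_orth)],
                        stringsAsFactors = FALSE)
  tabs <- gen_hit_table(planted, decoy_a = ids_a[-seq_len(n_orth)],
                        decoy_b = ids_b[-seq_len(n_orth)],
                        fp_rate = 0.05, fn_rate = 0.05,
                        seed = sub_seed(seed, 3L))
  write_hits(tabs$ab, p("hits_ab.tsv"))
  write_hits(tabs$ba, p("hits_ba.tsv"))

  # reference / environmental database hits: ~52% of proteins get a
  # sub-cutoff reference hit, a further ~9% only an environmental one,
  # mirroring the ORFan / meta-ORFan proportions seen in giant-virus
  # proteomes
  with_seed(sub_seed(seed, 4L), {
    n <- length(ids_a)
    r <- runif(n)
    ref_ids <- ids_a[r < 0.52]
    env_ids <- ids_a[r >= 0.52 & r < 0.61]
    simple_hits <- function(q, subj_prefix, lo, hi) {
      if (length(q) == 0L) return(empty_hit_table())
      len <- sample(80:400, length(q), replace = TRUE)
      e <- rloguniform(length(q), lo, hi)
      hit_table(data.frame(
        query_id = q, subject_id = paste0(subj_prefix, seq_along(q)),
        pct_identity = round(runif(length(q), 25, 80), 1), aln_length = len,
        mismatches = 10, gap_opens = 1, q_start = 1, q_end = len,
        s_start = 1, s_end = len, evalue = e,
        bitscore = round(-2 * log10(e) + 25, 1), stringsAsFactors = FALSE
      ))
    }
    write_hits(simple_hits(ref_ids, "ref", 1e-60, 1e-6), p("hits_ref.tsv"))
    write_hits(simple_hits(env_ids, "env", 1e-40, 1e-6), p("hits_env.tsv"))

    # self-comparison: plant duplicate pairs among ~20% of proteins
    dup_ids <- sample(ids_a, 2L * floor(0.1 * n))
    half <- length(dup_ids) / 2L
    e_dup <- rloguniform(half, 1e-50, 1e-12)
    self <- hit_table(data.frame(
      query_id = dup_ids[seq_len(half)],
      subject_id = dup_ids[half + seq_len(half)],
      pct_identity = round(runif(half, 30, 95), 1), aln_length = 200,
      mismatches = 20, gap_opens = 1, q_start = 1, q_end = 200,
      s_start = 1, s_end = 200, evalue = e_dup,
      bitscore = round(-2 * log10(e_dup) + 25, 1), stringsAsFactors = FALSE
    ))
    write_hits(self, p("self_hits.tsv"))

    # family-database hits for ~70% of proteins, over 40 families
    fam_prot <- ids_a[runif(n) < 0.7]
    fam_subj <- paste0("FAM", sprintf("%03d", sample.int(40L, length(fam_prot),
                                                         replace = TRUE)), "_rep")
    e_fam <- rloguniform(length(fam_prot), 1e-30, 1e-4)
    lenf <- sample(80:400, length(fam_prot), replace = TRUE)
    famhits <- hit_table(data.frame(
      query_id = fam_prot, subject_id = fam_subj,
      pct_identity = round(runif(length(fam_prot), 25, 80), 1),
      aln_length = lenf, mismatches = 10, gap_opens = 1,
      q_start = 1, q_end = lenf, s_start = 1, s_end = lenf, evalue = e_fam,
      bitscore = round(-2 * log10(e_fam) + 25, 1), stringsAsFactors = FALSE
    ))
    write_hits(famhits, p("hits_family.tsv"))
    fmap <- data.frame(
      subject_id = paste0("FAM", sprintf("%03d", 1:40), "_rep"),
      family_id = paste0("FAM", sprintf("%03d", 1:40)),
      stringsAsFactors = FALSE
    )
    write.table(fmap, p("family_map.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  prof <- gen_phyletic_profiles(sim$n_groups, sim$taxa_per_group,
                                sim$n_families, sim$core_frac, sim$flip_rate,
                                seed = sub_seed(seed, 5L))
  write_matrix(unclass(prof$matrix), p("phyletic_matrix.tsv"))

  cds <- gen_coding_sequences(sim$n_cds, c(AAA = 3, AAG = 1),
                              sim$cds_length_codons, seed = sub_seed(seed, 6L))
  write_fasta(cds, p("cds.fasta"))

  list(genome_a = p("genome_a.tsv"), genome_b = p("genome_b.tsv"),
       category_file = p("category.tsv"), hits_ab = p("hits_ab.tsv"),
       hits_ba = p("hits_ba.tsv"), hits_ref = p("hits_ref.tsv"),
       hits_env = p("hits_env.tsv"), self_hits = p("self_hits.tsv"),
       hits_family = p("hits_family.tsv"), family_map = p("family_map.tsv"),
       phyletic_matrix = p("phyletic_matrix.tsv"), cds = p("cds.fasta"))
}

#' Run the analysis pipeline
#'
#' Runs the requested stages in dependency order, writing every stage's
#' outputs under `config$out_dir` and a `manifest.json` recording the
#' package version, seed, thresholds and an MD5 checksum of every output.
#' Re-running with the same configuration reproduces identical checksums.
#'
#' @param config A `pipeline_config` (see [pipeline_config()] and
#'   [read_config()]).
#' @param quiet Suppress the per-stage log lines on standard error.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  violations <- validate_config(config)
  if (length(violations) > 0L) {
    abort("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  }
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message("[ncldvtools] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config$inputs
  thr <- config$thresholds
  outputs <- character(0)
  out <- function(name) {
    path <- file.path(config$out_dir, name)
    outputs <<- c(outputs, path)
    path
  }
  stages <- intersect(ALL_STAGES, config$stages)  # dependency order

  if ("simulate" %in% stages) {
    log_line("simulate: generating synthetic inputs (seed ", config$seed, ")")
    inputs <- utils::modifyList(inputs, simulate_stage(config))
  }

  pairs <- NULL
  if ("rbh" %in% stages) {
    log_line("rbh: reciprocal best hits at e <= ", thr$e_rbh)
    pairs <- rbh_pairs(read_hits(inputs$hits_ab), read_hits(inputs$hits_ba),
                       thr$e_rbh)
    write.table(as.data.frame(pairs), out("rbh_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if ("orfans" %in% stages) {
    log_line("orfans: classifying against reference and environmental hits")
    g <- read_genome(inputs$genome_a, "tsv")
    cls <- classify_orfans(g$features$gene_id, read_hits(inputs$hits_ref),
                           read_hits(inputs$hits_env), thr$e_rbh)
    write.table(cls$labels, out("orfan_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(label = names(cls$fractions),
                           fraction = as.numeric(cls$fractions)),
                out("orfan_fractions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if ("duplicates" %in% stages) {
    log_line("duplicates: clusters from self-comparison at e <= ", thr$e_dup)
    clusters <- find_duplicates(read_hits(inputs$self_hits), thr$e_dup)
    df <- if (length(clusters) == 0L) {
      data.frame(gene_id = character(0), cluster = integer(0))
    } else {
      data.frame(gene_id = unlist(clusters),
                 cluster = rep(seq_along(clusters), lengths(clusters)))
    }
    write.table(df, out("duplicate_clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if ("families" %in% stages) {
    log_line("families: assignment at e <= ", thr$e_family)
    fmap <- read.table(inputs$family_map, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    fam <- assign_families(read_hits(inputs$hits_family), fmap, thr$e_family)
    write_family_table(fam, out("families.tsv"))
  }

  if ("architecture" %in% stages) {
    log_line("architecture: terminal-window enrichment, window ", config$window)
    g <- read_genome(inputs$genome_a, "tsv")
    category <- readLines(inputs$category_file, warn = FALSE)
    spec <- region_spec(g$length, config$window)
    enr <- enrichment(g, category, spec)
    write.table(data.frame(
      rate_terminal = enr$rate_terminal, rate_central = enr$rate_central,
      odds_ratio = enr$odds_ratio, p_two_sided = enr$p_two_sided,
      a = enr$table$a, b = enr$table$b, c = enr$table$c, d = enr$table$d
    ), out("enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- setNames(lapply(category, function(id) "CATEGORY"), category)
    write.table(genome_tracks(g, ann), out("genome_tracks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if ("synteny" %in% stages) {
    log_line("synteny: blocks at e <= ", thr$e_synteny_grade)
    if (is.null(pairs)) {
      pairs <- rbh_pairs(read_hits(inputs$hits_ab), read_hits(inputs$hits_ba),
                         thr$e_rbh)
    }
    ga <- read_genome(inputs$genome_a, "tsv")
    gb <- read_genome(inputs$genome_b, "tsv")
    blocks <- synteny_blocks(pairs, ga, gb, e_max = thr$e_synteny_grade)
    bdf <- if (length(blocks) == 0L) {
      data.frame(block = integer(0), a_id = character(0), b_id = character(0),
                 rank_a = integer(0), rank_b = integer(0),
                 orientation = character(0))
    } else {
      do.call(rbind, lapply(seq_along(blocks), function(i) {
        b <- blocks[[i]]
        data.frame(block = i, a_id = b$genes$a_id, b_id = b$genes$b_id,
                   rank_a = b$ranks[, "rank_a"], rank_b = b$ranks[, "rank_b"],
                   orientation = b$orientation, stringsAsFactors = FALSE)
      }))
    }
    write.table(bdf, out("synteny_blocks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(dotplot_points(pairs, ga, gb, score = "evalue"),
                out("dotplot.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if ("phyletics" %in% stages) {
    log_line("phyletics: distances, ", config$linkage, "-linkage clustering")
    pm <- phyletic_matrix(read_matrix(inputs$phyletic_matrix))
    d <- euclidean_distances(pm)
    write_matrix(unclass(d), out("distances.tsv"))
    tree <- hierarchical_cluster(d, config$linkage)
    writeLines(to_newick(tree), out("tree.nwk"))
    # heatmap matrix: rows in dendrogram leaf order, columns ordered by
    # clustering the transposed matrix
    col_tree <- hierarchical_cluster(
      euclidean_distances(phyletic_matrix(t(unclass(pm)))), config$linkage)
    hm <- unclass(pm)[leaf_order(tree), leaf_order(col_tree), drop = FALSE]
    write_matrix(hm, out("heatmap_matrix.tsv"))
  }

  if ("rscu" %in% stages) {
    log_line("rscu: pooled genome-level codon usage")
    write_rscu(genome_rscu(read_fasta_dna(inputs$cds)), out("rscu.tsv"))
  }

  manifest <- list(
    package = "ncldvtools",
    version = as.character(utils::packageVersion("ncldvtools")),
    seed = config$seed,
    window = config$window,
    linkage = config$linkage,
    thresholds = unclass(config$thresholds),
    stages = stages,
    inputs = inputs,
    outputs = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("done in ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
  invisible(manifest)
}
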