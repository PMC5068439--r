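test_that("back-translation maps residues to codons and gaps to ---", {
  aa <- alignment(c("t1", "t2"), c("M-K", "MAK"), "amino_acid")
  cds <- c(t1 = "ATGAAA", t2 = "ATGGCTAAA")
  nt <- back_translate(aa, cds)
  expect_equal(nt$sequences, c("ATG---AAA", "ATGGCTAAA"))
  expect_equal(nt$codon_positions, rep(1:3, 3))
  # ambiguity passes through
  ax <- alignment("t1", "X", "amino_acid")
  expect_equal(back_translate(ax, c(t1 = "NNN"))$sequences, "NNN")
  # translation mismatch and internal stops are caught with positions
  expect_error(back_translate(aa, c(t1 = "ATGCCC", t2 = "ATGGCTAAA")),
               "mismatch for t1")
  expect_error(back_translate(alignment("t1", "MK", "amino_acid"),
                              c(t1 = "ATGTAAAAA")),
               "ATGTAA|residue|stop")
})

test_that("simulated codon alignments round-trip translate/back-translate", {
  set.seed(41)
  sp <- scenario_spec(n_genes = 2, length_median = 40, seed = 41,
                      discordant_fraction = 0)
  gs <- simulate_gene_set(sp, default_sim_model())
  for (g in gs$genes) {
    cds <- stats::setNames(gsub("-", "", g$nt$sequences), g$nt$taxa)
    back <- back_translate(g$aa, cds)
    expect_equal(back$sequences, g$nt$sequences)
  }
})

test_that("concatenation preserves columns, charsets and taxa", {
  a1 <- alignment(c("x", "y"), c("ACGTACGTAC", "ACGTACGTAC"))
  a2 <- alignment(c("y", "x"), c(strrep("GT", 10), strrep("AC", 10)))
  sm <- concatenate(list(g1 = a1, g2 = a2))
  expect_equal(n_columns(sm$alignment), 30)
  expect_equal(sm$charsets$g1, c(1, 10))
  expect_equal(sm$charsets$g2, c(11, 30))
  # rows follow the first gene's taxon order
  expect_equal(substring(sm$alignment$sequences[1], 11, 30),
               strrep("AC", 10))
  # single gene is the identity
  sm1 <- concatenate(list(solo = a1))
  expect_equal(sm1$alignment$sequences, a1$sequences)
  # taxon mismatch is an error (no missing-data padding)
  a3 <- alignment(c("x", "z"), c("ACGT", "ACGT"))
  expect_error(concatenate(list(a1, a3)), "taxon sets")
})

test_that("partition schemes cover the supermatrix disjointly", {
  set.seed(42)
  lens <- sample(5:30, 8)
  genes <- lapply(lens, function(L) {
    nt <- replicate(2, paste(sample(c("A", "C", "G", "T"), 3 * L, TRUE),
                             collapse = ""))
    alignment(c("x", "y"), nt, "nucleotide",
              codon_positions = rep(1:3, L))
  })
  names(genes) <- sprintf("g%d", seq_along(genes))
  sm <- concatenate(genes)
  for (sch in c("unpartitioned", "by_gene", "by_codon")) {
    ps <- build_partitions(sm, sch)
    cols <- unlist(lapply(ps$subsets, `[[`, "columns"))
    expect_equal(sort(cols), seq_len(n_columns(sm$alignment)), info = sch)
    expect_equal(anyDuplicated(cols), 0L, info = sch)
  }
  expect_length(build_partitions(sm, "by_gene")$subsets, 8)
  expect_length(build_partitions(sm, "by_codon")$subsets, 24)
  aa <- concatenate(list(alignment(c("x", "y"), c("MK", "MK"),
                                   "amino_acid")))
  expect_error(build_partitions(aa, "by_codon"), "codon")
})

test_that("partitioned likelihood reduces to the unpartitioned engine", {
  set.seed(43)
  st <- make_scenario_tree(scenario_spec(seed = 43))
  m <- default_sim_model()
  genes <- lapply(1:3, function(i) {
    g <- simulate_alignment(st$tree, m, 300)
    g$source_name <- sprintf("g%d", i)
    g
  })
  sm <- concatenate(genes)
  ps <- build_partitions(sm, "by_gene")
  joint <- partitioned_log_likelihood(sm, ps, st$tree, m)
  expect_equal(joint, log_likelihood(sm$alignment, st$tree, m),
               tolerance = 1e-8)
  # doubling one subset's multiplier = doubling branch lengths for its term
  ps2 <- ps
  ps2$subsets[[2]]$rate_multiplier <- 2
  tr2 <- st$tree
  tr2$edge.length <- tr2$edge.length * 2
  delta <- partitioned_log_likelihood(sm, ps2, st$tree, m) - joint
  sub2 <- subset_columns(sm$alignment, ps$subsets[[2]]$columns)
  expect_equal(delta,
               log_likelihood(sub2, tr2, m) -
                 log_likelihood(sub2, st$tree, m), tolerance = 1e-8)
  expect_error({
    ps3 <- ps
    ps3$subsets[[1]]$rate_multiplier <- -1
    partitioned_log_likelihood(sm, ps3, st$tree, m)
  }, "positive")
})

test_that("per-subset rate multipliers recover simulated rate variation", {
  set.seed(44)
  st <- make_scenario_tree(scenario_spec(seed = 44))
  m <- default_sim_model()
  slow_tree <- st$tree
  slow_tree$edge.length <- st$tree$edge.length * 0.5
  fast_tree <- st$tree
  fast_tree$edge.length <- st$tree$edge.length * 2
  g1 <- simulate_alignment(slow_tree, m, 3000)
  g1$source_name <- "slow"
  g2 <- simulate_alignment(fast_tree, m, 3000)
  g2$source_name <- "fast"
  sm <- concatenate(list(slow = g1, fast = g2))
  ps <- build_partitions(sm, "by_gene")
  fit <- fit_partition_models(sm, ps, st$tree, m, free = character(0))
  mult <- vapply(fit$scheme$subsets, `[[`, 0, "rate_multiplier")
  expect_equal(unname(mult[2] / mult[1]), 4, tolerance = 0.15 * 4)
  lens <- vapply(fit$scheme$subsets, function(s) length(s$columns), 0)
  expect_equal(sum(mult * lens) / sum(lens), 1, tolerance = 1e-6)
})

test_that("partition files are emitted in both dialects", {
  a <- alignment(c("x", "y"), c(strrep("ACG", 4), strrep("ACG", 4)),
                 codon_positions = rep(1:3, 4))
  sm <- concatenate(list(gene27 = a))
  ps <- build_partitions(sm, "by_codon")
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_partitions(ps, f1, "nexus")
  write_partitions(ps, f2, "raxml", "DNA")
  nx <- readLines(f1)
  expect_true(any(grepl("charset gene27_pos1 = 1-12\\\\3;", nx)))
  rx <- readLines(f2)
  expect_true(any(grepl("^DNA, gene27_pos2 = 2-12\\\\3$", rx)))
})
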