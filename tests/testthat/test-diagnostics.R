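test_that("composition profiles report the documented fractions", {
  groups <- taxon_groups(c(a = "complexa", b = "robusta"))
  nt <- alignment(c("a", "b"), c("AATT", "GGCC"))
  prof <- composition_profile(nt, groups)
  expect_equal(prof$per_taxon$AT_content, c(1, 0))
  aa <- alignment(c("a", "b"), c("FYMINKGARP", "FYMINKGARP"),
                  "amino_acid")
  paa <- composition_profile(aa, groups)
  expect_equal(paa$per_taxon$FYMINK, c(0.6, 0.6))
  expect_equal(paa$per_taxon$GARP, c(0.4, 0.4))
  # FYMINK + GARP + remainder = 1 exactly on unambiguous data
  set.seed(51)
  aa2 <- alignment("a", paste(sample(coralphy:::AA_STATES, 200, TRUE),
                              collapse = ""), "amino_acid")
  p2 <- composition_profile(aa2)
  rest <- 1 - p2$per_taxon$FYMINK - p2$per_taxon$GARP
  other <- setdiff(coralphy:::AA_STATES,
                   c(coralphy:::FYMINK_SET, coralphy:::GARP_SET))
  expect_equal(rest, sum(p2$per_taxon[, other]), tolerance = 1e-12)
})

test_that("gaps and ambiguities are excluded from denominators", {
  nt <- alignment(c("a", "b"), c("AA--NN", "AATTGG"))
  prof <- composition_profile(nt)
  expect_equal(prof$per_taxon$AT_content[1], 1)
  expect_error(composition_profile(alignment(c("a", "b"), c("--", "AC"))),
               "countable")
})

test_that("per-taxon frequencies track the generating composition", {
  set.seed(52)
  m <- substitution_model("nucleotide", "GTR",
                          freqs = c(0.3, 0.2, 0.2, 0.3))
  tr <- ape::rtree(5)
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  aln <- simulate_alignment(tr, m, 4000)
  prof <- composition_profile(aln)
  se3 <- 3 * sqrt(0.3 * 0.7 / 4000)
  expect_true(all(abs(prof$per_taxon[["A"]] - 0.3) < se3 + 0.02))
})

test_that("profiles are invariant to taxon order and column permutation", {
  set.seed(53)
  aln <- simulate_alignment(ape::rtree(4),
                            substitution_model("nucleotide", "JC"), 200)
  prof <- composition_profile(aln)
  perm <- sample(4)
  aln2 <- alignment(aln$taxa[perm], aln$sequences[perm])
  prof2 <- composition_profile(aln2)
  expect_equal(prof$per_taxon[perm, -1], prof2$per_taxon[, -1],
               ignore_attr = TRUE)
  cols <- sample(n_columns(aln))
  prof3 <- composition_profile(subset_columns(aln, cols))
  expect_equal(prof$per_taxon[, -1], prof3$per_taxon[, -1])
})

test_that("homogeneity test matches hand-computed chi-square", {
  ident <- alignment(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  h0 <- composition_homogeneity_test(ident)
  expect_equal(h0$statistic, 0, tolerance = 1e-12)
  expect_equal(h0$p_value, 1)
  # printed 2 x 4 count table, oracle arithmetic
  tab <- rbind(c(10, 5, 3, 2), c(4, 6, 8, 2))
  seqs <- apply(tab, 1, function(r)
    paste(rep(c("A", "C", "G", "T"), r), collapse = ""))
  h <- composition_homogeneity_test(alignment(c("a", "b"), seqs))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(h$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(h$df, 3)
  expect_error(composition_homogeneity_test(alignment("a", "ACGT")),
               "2 taxa")
})

test_that("saturation index hits its analytic endpoints", {
  ident <- alignment(sprintf("t%d", 1:6), rep(strrep("ACGT", 50), 6))
  states <- coralphy:::NT_STATES
  expect_equal(coralphy:::iss_index(alignment_matrix(ident), states), 0)
  # iid uniform sequences approach full saturation
  set.seed(54)
  m <- matrix(sample(states, 12 * 4000, TRUE), nrow = 12)
  rownames(m) <- sprintf("t%d", 1:12)
  expect_lt(abs(coralphy:::iss_index(m, states) - 1), 0.02)
})

test_that("Iss grows with tree depth and the test calibrates sensibly", {
  set.seed(55)
  tr <- ape::rtree(8)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  m <- substitution_model("nucleotide", "JC")
  iss <- vapply(c(0.05, 0.5, 4), function(d) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * d
    aln <- simulate_alignment(tr2, m, 1500)
    coralphy:::iss_index(alignment_matrix(aln), coralphy:::NT_STATES)
  }, 0)
  expect_true(all(diff(iss) > 0))
  # shallow alignments are not flagged as saturated
  flags <- vapply(1:4, function(i) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * 0.05
    aln <- simulate_alignment(tr2, m, 800)
    rep <- saturation_test(aln, n_sim = 48, seed = i)
    rep$significant_saturation
  }, TRUE)
  expect_true(sum(flags) <= 1)
  expect_error(saturation_test(alignment(c("a", "b"), c("AC", "AC")),
                               seed = 1), "4 taxa")
})
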