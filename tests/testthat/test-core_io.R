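test_that("FASTA parsing preserves order, labels and length", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tax2", "ACGT", "AC", ">tax1", "ACGTAC"), f)
  aln <- read_alignment(f)
  expect_equal(aln$taxa, c("tax2", "tax1"))
  expect_equal(nchar(aln$sequences), c(6L, 6L))
  expect_equal(aln$alphabet, "nucleotide")
})

test_that("alphabet is auto-detected at the 50% ACGTN- rule", {
  expect_equal(alignment(c("a", "b"), c("ACGT", "ACGT"))$alphabet,
               "nucleotide")
  expect_equal(alignment(c("a", "b"), c("MKLF", "MKLF"))$alphabet,
               "amino_acid")
})

test_that("malformed alignments are rejected", {
  expect_error(alignment(c("a", "b"), c("ACGT", "ACG")), "length mismatch")
  expect_error(alignment(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(alignment("a", "AC!T"), "characters")
})

test_that("PHYLIP relaxed dialect round-trips, incl. interleaved reads", {
  taxa <- sprintf("longtaxonname%02d", 1:15)
  set.seed(1)
  seqs <- replicate(15, paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                              collapse = ""))
  aln <- alignment(taxa, seqs)
  f <- withr::local_tempfile(fileext = ".phy")
  write_alignment(aln, f, "phylip")
  expect_match(readLines(f, n = 1), "^15 40$")
  back <- read_alignment(f, "phylip")
  expect_equal(back$taxa, aln$taxa)
  expect_equal(back$sequences, aln$sequences)
  # interleaved continuation blocks cycle taxa in header order
  f2 <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 8", "t1 ACGT", "t2 TTTT", "AAAA", "CCCC"), f2)
  il <- read_alignment(f2, "phylip")
  expect_equal(il$sequences, c("ACGTAAAA", "TTTTCCCC"))
})

test_that("interleaved NEXUS equals its hand-assembled sequential form", {
  taxa <- c("alpha", "beta", "gamma")
  seqs <- c("ACGTACGTAC", "TTGTACGAAC", "ACGAACGTGG")
  aln <- alignment(taxa, seqs)
  fseq <- withr::local_tempfile(fileext = ".nex")
  fint <- withr::local_tempfile(fileext = ".nex")
  write_alignment(aln, fseq, "nexus")
  write_alignment(aln, fint, "nexus", interleave = 4)
  a1 <- read_alignment(fseq, "nexus")
  a2 <- read_alignment(fint, "nexus")
  expect_equal(a1$sequences, seqs)
  expect_equal(a2$sequences, seqs)
  expect_equal(a1$taxa, a2$taxa)
})

test_that("round-trip identity holds across all alignment formats", {
  set.seed(2)
  aln <- alignment(c("s1", "s2", "s3"),
                   c("MK-LX", "MKALF", "MK?LF"), "amino_acid")
  for (fmt in c("fasta", "phylip", "nexus")) {
    f <- withr::local_tempfile()
    write_alignment(aln, f, fmt)
    back <- read_alignment(f, fmt, alphabet = "amino_acid")
    expect_equal(back$taxa, aln$taxa, info = fmt)
    expect_equal(back$sequences, aln$sequences, info = fmt)
  }
})

test_that("Newick reading handles supports, polytomies and errors", {
  tr <- read_trees("((A:1,B:1):0.5,C:1);", text = TRUE)
  expect_length(tr, 1)
  expect_equal(sort(tr[[1]]$tip.label), c("A", "B", "C"))
  tr2 <- read_trees("((A,B)95,C,D);", text = TRUE)[[1]]
  expect_true("95" %in% tr2$node.label)
  expect_true(attr(tr2, "binary"))  # a quartet: unrooted binary
  poly <- read_trees("((A,B,C)80,D,E);", text = TRUE)[[1]]
  expect_false(attr(poly, "binary"))
  expect_error(read_trees("((A:1,B:-0.5):1,C:1);", text = TRUE),
               "negative")
})

test_that("a 1,000-tree Newick file is read back in order", {
  f <- withr::local_tempfile(fileext = ".nwk")
  labs <- LETTERS[1:5]
  set.seed(3)
  txt <- vapply(1:1000, function(i)
    ape::write.tree(ape::rtree(5, tip.label = sample(labs))), "")
  writeLines(txt, f)
  trees <- read_trees(f)
  expect_length(trees, 1000)
  expect_equal(ape::write.tree(trees[[17]]), txt[17])
})

test_that("write_tree round-trips topology, lengths and supports", {
  set.seed(4)
  tr <- ape::rtree(15)
  txt <- write_tree(tr)
  back <- read_trees(txt, text = TRUE)[[1]]
  expect_setequal(tree_splits(back), tree_splits(tr))
  expect_lt(max(abs(back$edge.length - tr$edge.length)), 1e-6)
  # probability supports survive a round trip
  tr$node.label <- c("", rep("0.9975", tr$Nnode - 1))
  back2 <- read_trees(write_tree(tr, support_as = "probability"),
                      text = TRUE)[[1]]
  expect_equal(suppressWarnings(as.numeric(back2$node.label[2])), 0.9975,
               tolerance = 1e-6)
  # trees without supports carry no internal labels
  tr$node.label <- NULL
  expect_false(grepl("\\)[0-9]", write_tree(tr)))
})

test_that("bipartitions are invariant under leaf reordering", {
  set.seed(5)
  tr <- ape::rtree(10)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_setequal(tree_splits(tr), tree_splits(tr2))
})
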