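# Group-labeled example trees: the two drawn hypotheses plus an "other"
# arrangement. The classifier's two clade conditions cannot both hold on a
# binary tree containing a complexan: a Scleractinia clade contains every
# robust taxon together with a complexan, while a Robusta+Corallimorpharia
# clade contains every robust taxon with a corallimorpharian and no
# complexan; two clades of a tree must be nested or disjoint, and neither
# containment is possible here, so monophyly-then-naked-coral precedence
# never decides a call.

tree_of <- function(txt) ape::read.tree(text = txt)

mono_tree <- function()
  tree_of(paste0("(Out01,(((Comp01,(Comp02,Comp03)),(Rob01,((Rob02,Rob03),",
                 "(Rob04,(Rob05,Rob06))))),(Cor01,(Cor02,Cor03)),",
                 "(Act01,Act02)));"))

naked_tree <- function()
  tree_of(paste0("(Out01,(((Cor01,(Cor02,Cor03)),(Rob01,((Rob02,Rob03),",
                 "(Rob04,(Rob05,Rob06))))),(Comp01,(Comp02,Comp03)),",
                 "(Act01,Act02)));"))

other_tree <- function()
  tree_of(paste0("(Out01,(((Comp01,(Comp02,Comp03)),(Cor01,(Cor02,Cor03))),",
                 "(Rob01,((Rob02,Rob03),(Rob04,(Rob05,Rob06)))),",
                 "(Act01,Act02)));"))

test_that("outgroup rooting places the root on the outgroup edge", {
  g <- demo_groups()
  un <- tree_of("((Comp01,Rob01),(Cor01,Out01));")
  rt <- root_on_outgroup(un, g)
  expect_true(ape::is.rooted(rt))
  ch <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1, 2]
  expect_true(match("Out01", rt$tip.label) %in% ch)
  # rooting then unrooting preserves bipartitions; leaf order irrelevant
  expect_setequal(tree_splits(ape::unroot(rt)), tree_splits(un))
  un2 <- tree_of("((Out01,Cor01),(Rob01,Comp01));")
  expect_setequal(tree_splits(root_on_outgroup(un2, g)),
                  tree_splits(rt))
  # non-monophyletic multi-taxon outgroups are refused
  g2 <- taxon_groups(c(A = "outgroup", B = "outgroup", C = "complexa",
                       D = "robusta", E = "corallimorpharia"))
  bad <- tree_of("((A,C),(B,(D,E)));")
  expect_error(root_on_outgroup(bad, g2), "monophyletic")
})

test_that("the classifier names the two drawn hypotheses and the rest", {
  g <- demo_groups()
  expect_equal(classify_topology(mono_tree(), g), "monophyly")
  expect_equal(classify_topology(naked_tree(), g), "naked_coral")
  expect_equal(classify_topology(other_tree(), g), "other")
  expect_error(classify_topology(tree_of("(Comp01,(Rob01,Cor01));"), g),
               "outgroup")
})

test_that("classification ignores branch lengths and leaf order", {
  g <- demo_groups()
  tr <- mono_tree()
  tr$edge.length <- runif(nrow(tr$edge))
  expect_equal(classify_topology(tr, g), "monophyly")
  rot <- ape::rotateConstr(tr, rev(sort(tr$tip.label)))
  expect_equal(classify_topology(rot, g), "monophyly")
})

test_that("calls are exhaustive over many random trees", {
  g <- demo_groups()
  set.seed(61)
  calls <- vapply(1:40, function(i) {
    tr <- ape::rtree(15, tip.label = sample(names(g)))
    classify_topology(tr, g)
  }, "")
  expect_true(all(calls %in% c("monophyly", "naked_coral", "other")))
})

test_that("pattern tables group, rank and flag concordant genes", {
  calls <- rbind(gene1 = rep("monophyly", 4),
                 gene2 = rep("monophyly", 4),
                 gene3 = rep("naked_coral", 4))
  tab <- pattern_table(calls, c(900, 905, 300))
  expect_equal(attr(tab, "patterns")$count, c(2, 1))
  expect_equal(tab$pattern_rank[tab$gene == "gene3"], 2)
  expect_true(all(tab$concordant_monophyly[tab$gene != "gene3"]))
  expect_true(tab$concordant_naked_coral[tab$gene == "gene3"])
  # conservation: group sizes sum to the gene count, on random matrices
  set.seed(62)
  for (i in 1:5) {
    cm <- matrix(sample(c("monophyly", "naked_coral", "other"), 40, TRUE),
                 ncol = 4)
    tt <- pattern_table(cm, rep(100, 10))
    expect_equal(sum(attr(tt, "patterns")$count), 10)
  }
  expect_error(pattern_table(matrix(c("monophyly", NA), 1), 100),
               "incomplete")
})

test_that("Mann-Whitney U matches the enumeration oracle on examples", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r1$U, 0)
  expect_equal(r1$p_value, 1 / 3)
  r2 <- mann_whitney_u(1:5, 6:10, mode = "exact")
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 2 / 252)
  expect_equal(mann_whitney_u(c(2, 2, 3), c(2, 2, 3))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact and normal p-values agree for moderate samples", {
  set.seed(63)
  for (i in 1:3) {
    x <- sample(1:50, 20, TRUE)
    y <- sample(5:55, 20, TRUE)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pn <- mann_whitney_u(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("tie-free exact p-values match wilcox.test", {
  set.seed(64)
  for (i in 1:5) {
    x <- runif(5)
    y <- runif(4)
    ours <- mann_whitney_u(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("length comparison contrasts the concordant gene classes", {
  calls <- rbind(matrix("monophyly", 5, 2), matrix("naked_coral", 2, 2))
  rownames(calls) <- sprintf("g%d", 1:7)
  tab <- pattern_table(calls, c(rep(900, 5), rep(300, 2)))
  res <- length_comparison(tab)
  expect_true(res$testable)
  expect_gt(res$median_monophyly, res$median_naked_coral)
  expect_equal(res$U, 10)  # complete separation: 5 x 2 pairs
  expect_equal(res$p_value, 2 / choose(7, 2))
  # identical length sets
  tab2 <- pattern_table(calls, rep(500, 7))
  expect_equal(length_comparison(tab2)$p_value, 1)
  # an empty class is reported as not testable
  calls3 <- matrix("monophyly", 3, 2)
  tab3 <- pattern_table(calls3, rep(100, 3))
  res3 <- length_comparison(tab3)
  expect_false(res3$testable)
  expect_null(res3$p_value)
})
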