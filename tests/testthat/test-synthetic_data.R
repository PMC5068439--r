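test_that("scenario trees encode their own hypothesis", {
  sp_m <- scenario_spec("monophyly", seed = 71)
  st_m <- make_scenario_tree(sp_m)
  expect_length(st_m$tree$tip.label, 15)
  expect_equal(classify_topology(st_m$tree, st_m$groups), "monophyly")
  expect_equal(classify_topology(st_m$alternative, st_m$groups),
               "naked_coral")
  sp_n <- scenario_spec("naked_coral", seed = 71)
  st_n <- make_scenario_tree(sp_n)
  expect_equal(classify_topology(st_n$tree, st_n$groups), "naked_coral")
  # requested depth is the root-to-tip path length
  d <- ape::node.depth.edgelength(st_m$tree)
  tipd <- d[seq_len(15)]
  expect_equal(max(tipd), 0.3, tolerance = 1e-6)
  expect_equal(min(tipd), 0.3, tolerance = 1e-6)
})

test_that("sequence simulation matches closed-form expectations", {
  m <- substitution_model("nucleotide", "JC")
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  aln <- simulate_alignment(tr, m, 100000, seed = 72)
  mm <- alignment_matrix(aln)
  p <- mean(mm[1, ] != mm[2, ])
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 100000))
  # zero lengths give identical rows
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  aln0 <- simulate_alignment(tr0, m, 500, seed = 73)
  expect_equal(aln0$sequences[1], aln0$sequences[2])
})

test_that("simulation and refitting recover the gamma shape", {
  set.seed(74)
  st <- make_scenario_tree(scenario_spec(seed = 74))
  m <- substitution_model("nucleotide", "GTR", rates = c(1, 2, 1, 1, 4, 1),
                          freqs = c(0.28, 0.22, 0.22, 0.28),
                          gamma_shape = 0.8, p_inv = 0)
  aln <- simulate_alignment(st$tree, m, 20000)
  fit <- optimize_model(aln, st$tree, m, free = "alpha")
  expect_lt(abs(fit$model$gamma_shape - 0.8) / 0.8, 0.2)
})

test_that("simulation is deterministic under seed control", {
  m <- default_sim_model()
  tr <- make_scenario_tree(scenario_spec(seed = 75))$tree
  a1 <- simulate_alignment(tr, m, 300, seed = 9)
  a2 <- simulate_alignment(tr, m, 300, seed = 9)
  a3 <- simulate_alignment(tr, m, 300, seed = 10)
  expect_identical(a1$sequences, a2$sequences)
  expect_false(identical(a1$sequences, a3$sequences))
})

test_that("gene sets honour the discordance and length design", {
  m <- default_sim_model()
  gs0 <- simulate_gene_set(scenario_spec(n_genes = 6, length_median = 35,
                                         discordant_fraction = 0,
                                         seed = 76), m)
  expect_true(all(gs0$manifest$label == "monophyly"))
  # floor arithmetic at the study scale: 291 genes, 10% discordant -> 29
  sp <- scenario_spec(n_genes = 291, discordant_fraction = 0.1, seed = 77)
  n_disc <- floor(sp$discordant_fraction * sp$n_genes)
  expect_equal(n_disc, 29)
  # length scaling: discordant genes at ~1/3 the concordant median
  set.seed(78)
  sp2 <- scenario_spec(n_genes = 200, discordant_fraction = 0.5,
                       discordant_length_factor = 1 / 3, seed = 78)
  lens <- round(exp(log(sp2$length_median) +
                      sp2$length_sigma * rnorm(200)))
  gs_lens <- local({
    n_disc <- floor(0.5 * 200)
    labels <- rep(c("monophyly", "naked_coral"), c(100, 100))
    list(conc = lens[labels == "monophyly"],
         disc = pmax(round(lens[labels == "naked_coral"] / 3), 30))
  })
  expect_equal(median(gs_lens$disc) / median(gs_lens$conc), 1 / 3,
               tolerance = 0.15)
  # simulated gene sets carry stop-free coding sequences and aa companions
  gs <- simulate_gene_set(scenario_spec(n_genes = 3, length_median = 40,
                                        discordant_fraction = 0.34,
                                        seed = 79), m)
  expect_equal(sum(gs$manifest$label == "naked_coral"), 1)
  for (g in gs$genes) {
    expect_equal(n_columns(g$nt), 3 * g$n_codons)
    expect_false(any(vapply(g$aa$sequences, grepl, TRUE,
                            pattern = "\\*")))
  }
})

test_that("composition bias injection shifts only the target group", {
  set.seed(80)
  st <- make_scenario_tree(scenario_spec(seed = 80))
  m <- default_sim_model()
  aln <- simulate_alignment(st$tree, m, 10000)
  shift <- c(A = 0.05, T = 0.05, C = -0.05, G = -0.05)
  expect_identical(inject_composition_bias(aln, st$groups, "robusta",
                                           shift * 0)$sequences,
                   aln$sequences)
  biased <- inject_composition_bias(aln, st$groups, "robusta", shift)
  prof0 <- composition_profile(aln, st$groups)
  prof1 <- composition_profile(biased, st$groups)
  rob <- prof1$per_taxon$group == "robusta"
  d_at <- mean(prof1$per_taxon$AT_content[rob]) -
    mean(prof0$per_taxon$AT_content[rob])
  expect_lt(abs(d_at - 0.1), 3 * sqrt(0.5 / (6 * 10000)) + 0.01)
  expect_identical(prof1$per_taxon$AT_content[!rob],
                   prof0$per_taxon$AT_content[!rob])
  expect_error(inject_composition_bias(aln, st$groups, "robusta",
                                       c(A = 0.9, C = -0.9)),
               "simplex|zero")
})
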