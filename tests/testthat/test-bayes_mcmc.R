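test_that("settings are validated", {
  expect_error(mcmc_settings(n_generations = 10, sample_every = 100),
               ">= sample_every")
  expect_error(mcmc_settings(burnin_fraction = 1), "burnin")
  expect_error(mcmc_settings(proposal_weights = c(1, 1, 0)), "positive")
})

test_that("prior-only runs recover the branch-length prior mean", {
  aln <- simulate_alignment(ape::rtree(6),
                            substitution_model("nucleotide", "JC"), 10,
                            seed = 1)
  res <- mcmc_run(aln, substitution_model("nucleotide", "JC"),
                  mcmc_settings(n_generations = 60000, sample_every = 60,
                                n_runs = 1, seed = 7),
                  prior_only = TRUE)
  bl <- vapply(res$runs[[1]]$sample$topologies,
               function(t) mean(t$edge.length), 0)
  mcse <- sd(bl) / sqrt(coralphy:::ess_ips(bl))
  expect_lt(abs(mean(bl) - 0.1), 3 * mcse + 0.005)
})

test_that("a 2-taxon posterior matches direct numerical integration", {
  aln <- alignment(c("a", "b"),
                   c(strrep("A", 100),
                     paste0(strrep("A", 90), strrep("C", 10))))
  m <- substitution_model("nucleotide", "JC")
  res <- mcmc_run(aln, m, mcmc_settings(n_generations = 200000,
                                        sample_every = 100, n_runs = 1,
                                        seed = 3))
  ts <- vapply(res$runs[[1]]$sample$topologies,
               function(t) sum(t$edge.length), 0)
  # oracle: total length T has prior Gamma(2, rate 10); L(T) closed-form JC
  gr <- seq(1e-4, 2, length.out = 20000)
  lnL <- 90 * log((1 / 4 + 3 / 4 * exp(-4 * gr / 3)) / 4) +
    10 * log((1 - (1 / 4 + 3 / 4 * exp(-4 * gr / 3))) / 12)
  post <- dgamma(gr, 2, rate = 10) * exp(lnL - max(lnL))
  post <- post / sum(post)
  expect_equal(mean(ts), sum(gr * post), tolerance = 0.02)
  expect_equal(sd(ts), sqrt(sum(gr^2 * post) - sum(gr * post)^2),
               tolerance = 0.15)
})

test_that("4-taxon topology posterior matches exhaustive computation", {
  # weak data so prior Monte-Carlo integration of the marginal likelihood
  # per topology is accurate; posterior frequencies compared within 0.03
  set.seed(31)
  gen <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  m <- substitution_model("nucleotide", "JC")
  aln <- simulate_alignment(gen, m, 40, seed = 5)
  res <- mcmc_run(aln, m, mcmc_settings(n_generations = 150000,
                                        sample_every = 50, n_runs = 1,
                                        seed = 11))
  samp <- res$runs[[1]]$sample
  keys <- vapply(samp$topologies, function(t) tree_splits(t)[1], "")
  obs <- table(factor(keys, levels = c("c|d", "b|d", "b|c")))
  obs <- as.numeric(obs) / length(keys)
  # prior Monte-Carlo marginal likelihood per topology
  topos <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  pd <- coralphy:::pattern_data(aln)
  marg <- vapply(topos, function(tx) {
    tr <- ape::read.tree(text = tx)
    eng <- coralphy:::new_engine(pd, m)
    pt <- coralphy:::phylo_to_parent(tr, pd$taxa)
    lls <- vapply(1:30000, function(i) {
      bl <- rexp(length(pt$blen), rate = 10)
      coralphy:::cpp_engine_set_tree(eng$ptr, pt$parent, bl)
      coralphy:::cpp_engine_loglik(eng$ptr)
    }, 0)
    mx <- max(lls)
    mx + log(mean(exp(lls - mx)))
  }, 0)
  pexp <- exp(marg - max(marg))
  pexp <- pexp / sum(pexp)
  expect_true(all(abs(obs - pexp) < 0.03))
})

test_that("consensus trees report bipartition frequencies", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  same <- tree_sample(rep(list(t1), 5))
  cons <- consensus_tree(same)
  expect_setequal(tree_splits(cons), tree_splits(t1))
  expect_true(all(as.numeric(cons$node.label[nzchar(cons$node.label)]) ==
                    1))
  mix <- tree_sample(c(rep(list(t1), 6), rep(list(t2), 4)))
  cons2 <- consensus_tree(mix)
  expect_true(has_clade(cons2, c("a", "b")))
  lab <- as.numeric(cons2$node.label[nzchar(cons2$node.label)])
  expect_true(any(abs(lab - 0.6) < 1e-9))
  # order invariance
  mix2 <- tree_sample(c(rep(list(t2), 4), rep(list(t1), 6)))
  expect_setequal(tree_splits(consensus_tree(mix2)), tree_splits(cons2))
  expect_error(consensus_tree(tree_sample(list())), "empty")
})

test_that("convergence diagnostics behave at their reference points", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  s1 <- tree_sample(rep(list(t1), 10))
  d0 <- convergence_diagnostics(list(s1, s1))
  expect_equal(d0$maxdiff, 0)
  d1 <- convergence_diagnostics(list(s1, tree_sample(rep(list(t2), 10))))
  expect_equal(d1$maxdiff, 1)
  expect_true(is.na(convergence_diagnostics(list(s1))$maxdiff))
  # iid trace: ESS within 20% of n
  set.seed(33)
  x <- rnorm(2000)
  expect_lt(abs(coralphy:::ess_ips(x) - 2000) / 2000, 0.2)
})

test_that("sampler output is reproducible under seed reuse", {
  aln <- simulate_alignment(ape::rtree(5),
                            substitution_model("nucleotide", "JC"), 200,
                            seed = 2)
  m <- substitution_model("nucleotide", "JC")
  st <- mcmc_settings(n_generations = 2000, sample_every = 100, n_runs = 2,
                      seed = 5)
  r1 <- mcmc_run(aln, m, st)
  r2 <- mcmc_run(aln, m, st)
  expect_identical(r1$runs[[1]]$trace, r2$runs[[1]]$trace)
  expect_identical(lapply(r1$runs[[2]]$sample$topologies, write_tree),
                   lapply(r2$runs[[2]]$sample$topologies, write_tree))
})
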