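test_that("discrete-gamma rates are quantile-bin means averaging to one", {
  expect_equal(discretize_gamma(0.73, 1), 1)
  expect_true(all(abs(discretize_gamma(1e6, 4) - 1) < 1e-2))
  r <- discretize_gamma(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-9)
  # adaptive quadrature oracle for the bin means
  a <- 0.5
  q <- qgamma((0:4) / 4, a, rate = a)
  num <- vapply(1:4, function(i)
    4 * integrate(function(x) x * dgamma(x, a, rate = a),
                  q[i], q[i + 1])$value, 0)
  expect_equal(r, num, tolerance = 1e-6)
  expect_error(discretize_gamma(-1, 4), "positive")
})

test_that("transition matrices satisfy limits, closed forms and balance", {
  jc <- substitution_model("nucleotide", "JC")
  expect_equal(transition_matrix(jc, 0), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_matrix(jc, 0.1)
  expect_equal(P[1, 1], 1 / 4 + 3 / 4 * exp(-4 * 0.1 / 3),
               tolerance = 1e-12)
  Pinf <- transition_matrix(jc, 60)
  expect_true(max(abs(Pinf - 0.25)) < 1e-6)
  set.seed(10)
  m <- random_gtr_gi()
  P <- transition_matrix(m, 0.37)
  expect_true(max(abs(rowSums(P) - 1)) < 1e-10)
  # detailed balance pi_i P_ij = pi_j P_ji
  B <- m$freqs * P
  expect_true(max(abs(B - t(B))) < 1e-10)
  expect_error(transition_matrix(m, -0.1), ">= 0")
})

test_that("two-taxon likelihoods match their closed forms", {
  jc <- substitution_model("nucleotide", "JC")
  a1 <- alignment(c("x", "y"), c("A", "A"))
  t0 <- read_trees("(x:0,y:0);", text = TRUE)[[1]]
  expect_equal(log_likelihood(a1, t0, jc), log(0.25), tolerance = 1e-12)
  a2 <- alignment(c("x", "y"),
                  c(strrep("A", 100),
                    paste0(strrep("A", 90), strrep("C", 10))))
  tr <- read_trees("(x:0.05,y:0.05);", text = TRUE)[[1]]
  ps <- 1 / 4 + 3 / 4 * exp(-4 * 0.1 / 3)
  pd <- (1 - ps) / 3
  expect_equal(log_likelihood(a2, tr, jc),
               90 * log(ps / 4) + 10 * log(pd / 4), tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on small instances", {
  set.seed(11)
  for (i in 1:6) {
    tr <- random_tree(sample(4:6, 1))
    m <- random_gtr_gi()
    aln <- simulate_alignment(tr, m, 30)
    expect_equal(log_likelihood(aln, tr, m),
                 brute_force_loglik(aln, tr, m), tolerance = 1e-10)
  }
  tr <- random_tree(4)
  m <- random_jtt_gi()
  aln <- simulate_alignment(tr, m, 20)
  expect_equal(log_likelihood(aln, tr, m),
               brute_force_loglik(aln, tr, m), tolerance = 1e-10)
})

test_that("lnL is invariant under re-rooting and leaf reordering", {
  set.seed(12)
  tr <- random_tree(8)
  m <- random_gtr_gi()
  aln <- simulate_alignment(tr, m, 200)
  base <- log_likelihood(aln, tr, m)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                        resolve.root = TRUE)
  expect_equal(log_likelihood(aln, rerooted, m), base, tolerance = 1e-8)
  perm <- sample(length(aln$taxa))
  aln2 <- alignment(aln$taxa[perm], aln$sequences[perm], aln$alphabet)
  expect_equal(log_likelihood(aln2, tr, m), base, tolerance = 1e-8)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  tr <- random_tree(6)
  m <- substitution_model("nucleotide", "GTR", rates = c(1, 2, 1, 1, 4, 1),
                          freqs = c(0.3, 0.2, 0.2, 0.3),
                          gamma_shape = 0.6, p_inv = 0.2)
  aln <- simulate_alignment(tr, m, 1500)
  fitp <- phangorn::pml(tr, phangorn::phyDat(alignment_matrix(aln),
                                             type = "DNA"),
                        bf = c(0.3, 0.2, 0.2, 0.3),
                        Q = c(1, 2, 1, 1, 4, 1), k = 4, shape = 0.6,
                        inv = 0.2)
  expect_equal(log_likelihood(aln, tr, m), fitp$logLik, tolerance = 1e-6)
})

test_that("an all-gap column leaves the likelihood unchanged", {
  set.seed(14)
  tr <- random_tree(5)
  m <- random_gtr_gi()
  aln <- simulate_alignment(tr, m, 50)
  base <- log_likelihood(aln, tr, m)
  aln2 <- alignment(aln$taxa, paste0(aln$sequences, "-"), aln$alphabet)
  expect_equal(log_likelihood(aln2, tr, m), base, tolerance = 1e-10)
})

test_that("pattern compression: duplicated columns scale site terms", {
  set.seed(15)
  tr <- random_tree(5)
  m <- random_gtr_gi()
  aln <- simulate_alignment(tr, m, 40)
  doubled <- alignment(aln$taxa, paste0(aln$sequences, aln$sequences),
                       aln$alphabet)
  expect_equal(log_likelihood(doubled, tr, m),
               2 * log_likelihood(aln, tr, m), tolerance = 1e-8)
})

test_that("branch-length optimization hits the JC closed form", {
  jc <- substitution_model("nucleotide", "JC")
  aln <- alignment(c("x", "y"),
                   c(strrep("A", 100),
                     paste0(strrep("A", 90), strrep("C", 10))))
  tr <- read_trees("(x:0.3,y:0.3);", text = TRUE)[[1]]
  fit <- optimize_branch_lengths(aln, tr, jc)
  t_hat <- sum(fit$tree$edge.length)
  expect_equal(t_hat, -3 / 4 * log(1 - 4 * 0.1 / 3), tolerance = 1e-4)
  # a branch with no supporting signal collapses to the lower bound:
  # only constant columns and single-taxon autapomorphies
  tr4 <- read_trees("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);",
                    text = TRUE)[[1]]
  m <- substitution_model("nucleotide", "JC")
  cols <- c(rep("AAAA", 60), rep("CAAA", 10), rep("ACAA", 10),
            rep("AACA", 10), rep("AAAC", 10))
  mat <- do.call(cbind, strsplit(cols, ""))
  rownames(mat) <- c("a", "b", "c", "d")
  aln4 <- coralphy:::matrix_alignment(mat, "nucleotide")
  fit4 <- optimize_branch_lengths(aln4, tr4, m)
  internal <- fit4$tree$edge[, 2] > 4
  expect_lt(min(fit4$tree$edge.length[internal]), 1e-4)
})

test_that("branch lengths are consistently recovered on long alignments", {
  set.seed(17)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  m <- substitution_model("nucleotide", "JC")
  aln <- simulate_alignment(tr, m, 10000)
  start <- tr
  start$edge.length <- rep(0.3, nrow(tr$edge))
  fit <- optimize_branch_lengths(aln, start, m)
  expect_true(all(abs(fit$tree$edge.length - 0.1) < 0.02))
})

test_that("optimize_model with no free blocks only refits branch lengths", {
  set.seed(18)
  tr <- random_tree(5)
  m <- default_sim_model()
  aln <- simulate_alignment(tr, m, 300)
  fit <- optimize_model(aln, tr, m, free = character(0))
  expect_equal(fit$model$gamma_shape, m$gamma_shape)
  expect_equal(fit$model$p_inv, m$p_inv)
  expect_equal(fit$model$rates, m$rates)
  bl_only <- optimize_branch_lengths(aln, tr, m)
  expect_equal(fit$log_likelihood, bl_only$log_likelihood,
               tolerance = 1e-3)
})

test_that("gamma shape and p_inv are recovered from simulated data", {
  set.seed(19)
  st <- make_scenario_tree(scenario_spec(seed = 19))
  m <- substitution_model("nucleotide", "GTR", rates = c(1, 2, 1, 1, 4, 1),
                          freqs = c(0.28, 0.22, 0.22, 0.28),
                          gamma_shape = 0.5, p_inv = 0)
  aln <- simulate_alignment(st$tree, m, 20000)
  fit <- optimize_model(aln, st$tree, m, free = c("alpha", "p_inv"))
  expect_gt(fit$model$gamma_shape, 0.4)
  expect_lt(fit$model$gamma_shape, 0.6)
  expect_lte(fit$model$p_inv, 0.05)
})

test_that("tree search recovers generating topologies", {
  set.seed(20)
  # 3 taxa: the unique unrooted topology, with a warning
  m <- substitution_model("nucleotide", "JC")
  tr3 <- read_trees("(a:0.1,b:0.1,c:0.1);", text = TRUE)[[1]]
  aln3 <- simulate_alignment(tr3, m, 300)
  expect_warning(fit3 <- search_ml_tree(aln3, m), "one unrooted topology")
  expect_equal(length(fit3$tree$tip.label), 3L)
  expect_error(search_ml_tree(alignment(c("a", "b"), c("AC", "AC")), m),
               "at least 3")
  # 6-taxon recovery
  hits <- 0
  for (i in 1:10) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.25)
    gm <- substitution_model("nucleotide", "GTR",
                             rates = c(1, 2, 1, 1, 4, 1),
                             freqs = c(0.3, 0.2, 0.2, 0.3),
                             gamma_shape = 1)
    aln <- simulate_alignment(tr, gm, 5000)
    fit <- search_ml_tree(aln, gm, seed = i)
    if (setequal(tree_splits(fit$tree), tree_splits(tr))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(21)
  tr <- random_tree(6, 0.1, 0.3)
  m <- substitution_model("nucleotide", "JC")
  aln <- simulate_alignment(tr, m, 800)
  b1 <- bootstrap_support(aln, m, n_reps = 5, seed = 99)
  b2 <- bootstrap_support(aln, m, n_reps = 5, seed = 99)
  expect_identical(write_tree(b1), write_tree(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_support(aln, m, n_reps = 0), "n_reps")
})

test_that("model selection ranks by AIC with parameter tie-breaks", {
  set.seed(22)
  st <- make_scenario_tree(scenario_spec(seed = 22, depth = 0.4))
  gen <- substitution_model("nucleotide", "GTR",
                            rates = c(1, 3, 1, 1, 6, 1),
                            freqs = c(0.35, 0.15, 0.15, 0.35),
                            gamma_shape = 0.3, p_inv = 0)
  aln <- simulate_alignment(st$tree, gen, 8000)
  cands <- list(substitution_model("nucleotide", "JC"),
                substitution_model("nucleotide", "GTR", gamma_shape = 1),
                substitution_model("nucleotide", "GTR", gamma_shape = 1,
                                   p_inv = 0.1))
  tab <- select_model(aln, st$tree, cands)
  expect_match(tab$model[1], "^GTR\\+G")
  expect_equal(tab$model[nrow(tab)], "JC")
  # single candidate returned as best
  tab1 <- select_model(aln, st$tree, cands[1])
  expect_equal(nrow(tab1), 1L)
  # equal lnL ties break toward fewer parameters
  fake <- tab
  expect_true(all(diff(tab$AIC) >= 0))
})

test_that("fitted models round-trip through their text serialization", {
  set.seed(23)
  m <- random_gtr_gi()
  back <- read_model(write_model(m), text = TRUE)
  expect_equal(back$freqs, m$freqs, tolerance = 1e-9)
  expect_equal(back$rates, m$rates, tolerance = 1e-9)
  expect_equal(back$gamma_shape, m$gamma_shape, tolerance = 1e-9)
  expect_equal(back$p_inv, m$p_inv, tolerance = 1e-9)
  jt <- substitution_model("amino_acid", "JTT", gamma_shape = 0.7)
  f <- withr::local_tempfile()
  write_model(jt, f)
  back2 <- read_model(f)
  expect_equal(back2$rates, jt$rates, tolerance = 1e-6)
  expect_equal(back2$states, coralphy:::AA_STATES)
})
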