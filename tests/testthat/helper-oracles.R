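# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: matrix exponentials come from eigen() on the
# raw generator, likelihoods from exhaustive summation over ancestral-state
# assignments, and Mann-Whitney p-values from direct pair counting over all
# group assignments.

# generator matrix built from first principles (no shared code with pmat)
oracle_Q <- function(rates, freqs) {
  ns <- length(freqs)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns))
    if (i != j) Q[i, j] <- rates[i, j] * freqs[j]
  diag(Q) <- -rowSums(Q)
  Q / sum(-freqs * diag(Q))
}

oracle_pmat <- function(rates, freqs, t, rate = 1) {
  Q <- oracle_Q(rates, freqs)
  e <- eigen(Q * rate * t)
  P <- Re(e$vectors %*% diag(exp(e$values), nrow(Q)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P
}

# exhaustive-enumeration log-likelihood: sums over every assignment of
# states to internal nodes, per site, mixing gamma categories and the
# invariant class exactly as the model defines them
brute_force_loglik <- function(aln, tree, model) {
  model <- coralphy:::resolve_model(model, aln)
  states <- model$states
  ns <- length(states)
  mix <- coralphy:::model_mixture(model)
  rates <- if (mix$ncat == 1) 1 else discretize_gamma(mix$alpha, mix$ncat)
  rates <- rates / (1 - mix$p_inv)
  amb <- coralphy:::ambiguity_of(aln$alphabet)
  m <- alignment_matrix(aln)
  nsite <- ncol(m)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  m <- m[tree$tip.label, , drop = FALSE]
  nn <- ntip + tree$Nnode
  root <- tree$edge[1, 1]
  internals <- sort(unique(tree$edge[, 1]))
  nint <- length(internals)
  A <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  colnames(A) <- internals
  # tip partial vectors (ns x nsite) per tip
  tip_p <- lapply(seq_len(ntip), function(i) {
    sapply(seq_len(nsite), function(s) {
      v <- numeric(ns)
      v[match(amb[[m[i, s]]], states)] <- 1
      v
    })
  })
  site_L_cat <- matrix(0, mix$ncat, nsite)
  for (cc in seq_len(mix$ncat)) {
    contrib <- matrix(model$freqs[A[, as.character(root)]],
                      nrow(A), nsite)
    for (k in seq_len(nrow(tree$edge))) {
      u <- tree$edge[k, 1]
      ch <- tree$edge[k, 2]
      P <- oracle_pmat(model$rates, model$freqs, tree$edge.length[k],
                       rates[cc])
      if (ch > ntip) {
        contrib <- contrib * P[cbind(A[, as.character(u)],
                                     A[, as.character(ch)])]
      } else {
        contrib <- contrib * (P[A[, as.character(u)], , drop = FALSE] %*%
                                tip_p[[ch]])
      }
    }
    site_L_cat[cc, ] <- colSums(contrib)
  }
  # invariant-class contribution at constant-compatible sites
  constC <- sapply(seq_len(nsite), function(s) {
    ok <- Reduce(intersect, lapply(seq_len(ntip),
                                   function(i) amb[[m[i, s]]]))
    sum(model$freqs[match(ok, states)])
  })
  siteL <- (1 - mix$p_inv) * colMeans(site_L_cat) + mix$p_inv * constC
  sum(log(siteL))
}

# Mann-Whitney oracle: direct pair counting over all C(nx+ny, nx)
# assignments of the pooled values
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  U_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U <- U_of(x, y)
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(ix)
    U_of(pooled[ix], pooled[-ix]))
  p_lo <- mean(us <= U + 1e-9)
  p_hi <- mean(us >= U - 1e-9)
  list(U = U, p_value = min(1, 2 * min(p_lo, p_hi)))
}

# random alignment/tree/model generators for property suites
random_gtr_gi <- function() {
  substitution_model("nucleotide", "GTR",
                     rates = stats::runif(6, 0.5, 3),
                     freqs = {
                       f <- stats::runif(4, 0.5, 2)
                       f / sum(f)
                     },
                     gamma_shape = stats::runif(1, 0.3, 2),
                     p_inv = stats::runif(1, 0, 0.4))
}

random_jtt_gi <- function() {
  substitution_model("amino_acid", "JTT",
                     gamma_shape = stats::runif(1, 0.3, 2),
                     p_inv = stats::runif(1, 0, 0.4))
}

random_tree <- function(ntip, min_bl = 0.02, max_bl = 0.5) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# standard 15-taxon group map used in classification tests
demo_groups <- function() {
  taxon_groups(c(
    Comp01 = "complexa", Comp02 = "complexa", Comp03 = "complexa",
    Rob01 = "robusta", Rob02 = "robusta", Rob03 = "robusta",
    Rob04 = "robusta", Rob05 = "robusta", Rob06 = "robusta",
    Cor01 = "corallimorpharia", Cor02 = "corallimorpharia",
    Cor03 = "corallimorpharia",
    Act01 = "actiniaria", Act02 = "actiniaria",
    Out01 = "outgroup"))
}

default_sim_model <- function() {
  substitution_model("nucleotide", "GTR", rates = c(1, 2, 1, 1, 4, 1),
                     freqs = c(0.28, 0.22, 0.22, 0.28),
                     gamma_shape = 0.6, p_inv = 0.25)
}
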