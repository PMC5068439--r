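# Branch-length and model-parameter optimization, ML tree search (NJ start +
# NNI hill climbing) and the nonparametric bootstrap.

fit_result <- function(tree, model, loglik, ntip) {
  structure(list(tree = tree, model = model, log_likelihood = loglik,
                 n_free_parameters = count_free_parameters(model, ntip)),
            class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL %.4f, %d free parameters, %d taxa\n",
              model_tag(x$model), x$log_likelihood, x$n_free_parameters,
              length(x$tree$tip.label)))
  invisible(x)
}

# write engine branch lengths back onto the original tree object
blen_to_tree <- function(tree, taxa, blen) {
  ntip <- length(tree$tip.label)
  remap <- c(match(tree$tip.label, taxa), (ntip + 1):(ntip + tree$Nnode))
  tree$edge.length <- blen[remap[tree$edge[, 2]]]
  tree
}

#' Optimize branch lengths by iterated one-dimensional search
#'
#' Each branch is optimized in turn (bounded Brent search on the log scale,
#' bounds `[1e-8, 10]`) along a tree traversal; sweeps repeat until the
#' log-likelihood improves by less than `tol` per sweep or `max_sweeps` is
#' reached. The log-likelihood never decreases across sweeps.
#'
#' @param aln a [alignment()].
#' @param tree a `"phylo"` tree over the alignment's taxa; missing branch
#'   lengths start at 0.1.
#' @param model a [substitution_model()].
#' @param tol per-sweep log-likelihood tolerance.
#' @param max_sweeps maximum number of sweeps.
#' @return a `"phylo_fit"` with the re-lengthed tree and log-likelihood.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-4,
                                    max_sweeps = 20) {
  model <- resolve_model(model, aln)
  pd <- pattern_data(aln)
  eng <- new_engine(pd, model)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  engine_set_tree(eng, tree)
  if (!is.finite(cpp_engine_loglik(eng$ptr))) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
    engine_set_tree(eng, tree)
    if (!is.finite(cpp_engine_loglik(eng$ptr)))
      stop("non-finite likelihood even after branch-length reset")
  }
  res <- cpp_engine_optimize_edges(eng$ptr, tol, max_sweeps, integer(0))
  fit_result(blen_to_tree(tree, eng$taxa, res$blen), model, res$loglik,
             length(aln$taxa))
}

# ---------------------------------------------------------------------------
# model-parameter optimization

model_eigen <- function(model) {
  pi <- pmax(model$freqs, 1e-10)
  pi <- pi / sum(pi)
  Q <- sweep(model$rates, 2, pi, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  S <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = diag(1 / sqrt(pi)) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(sqrt(pi)),
       lam = e$values, pi = pi)
}

pmat_eigen <- function(me, t, rate = 1) {
  P <- me$U %*% (exp(me$lam * rate * t) * me$Uinv)
  P[P < 0] <- 0
  P
}

# mixture rates of the variable classes (already scaled by 1/(1 - p_inv))
variable_rates <- function(model) {
  mix <- model_mixture(model)
  r <- if (mix$ncat == 1) 1 else discretize_gamma(mix$alpha, mix$ncat)
  r / (1 - mix$p_inv)
}

#' Optimize substitution-model parameters
#'
#' Coordinate-wise bounded optimization cycling over the requested parameter
#' blocks and the branch lengths until the joint improvement per cycle drops
#' below `tol`. Frequencies are taken as observed counts in empirical mode
#' (GTR default, `+F`) or optimized on the simplex when the `"frequencies"`
#' block is requested.
#'
#' @param aln a [alignment()].
#' @param tree a `"phylo"` tree with (possibly rough) branch lengths.
#' @param model starting [substitution_model()].
#' @param free character subset of
#'   `c("alpha", "p_inv", "exchangeabilities", "frequencies")`; empty means
#'   branch lengths only.
#' @param tol per-cycle log-likelihood tolerance.
#' @param max_cycles cap on the number of cycles.
#' @return a `"phylo_fit"`; `$model` carries the fitted values.
#' @export
optimize_model <- function(aln, tree, model,
                           free = c("alpha", "p_inv"),
                           tol = 1e-3, max_cycles = 8) {
  if (length(free))
    free <- match.arg(free, c("alpha", "p_inv", "exchangeabilities",
                              "frequencies"), several.ok = TRUE)
  model <- resolve_model(model, aln)
  pd <- pattern_data(aln)
  eng <- new_engine(pd, model)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  engine_set_tree(eng, tree)
  ll <- cpp_engine_optimize_edges(eng$ptr, 1e-4, 20, integer(0))$loglik

  set_ll <- function(m) {
    engine_set_model(eng, m)
    cpp_engine_loglik(eng$ptr)
  }
  for (cycle in seq_len(max_cycles)) {
    ll0 <- ll
    if ("alpha" %in% free && !is.null(model$gamma_shape)) {
      o <- stats::optimize(function(x) {
        m <- model; m$gamma_shape <- exp(x); set_ll(m)
      }, c(log(0.02), log(100)), maximum = TRUE, tol = 1e-3)
      model$gamma_shape <- exp(o$maximum)
    }
    if ("p_inv" %in% free) {
      o <- stats::optimize(function(p) {
        m <- model; m$p_inv <- p; set_ll(m)
      }, c(0, 0.9), maximum = TRUE, tol = 1e-4)
      model$p_inv <- o$maximum
    }
    if ("exchangeabilities" %in% free && model$type == "GTR") {
      r0 <- model$rates[lower.tri(model$rates)]
      r0 <- r0 / r0[6]
      fn <- function(lx) {
        m <- model
        r <- exp(c(lx, 0))
        mm <- matrix(0, 4, 4)
        mm[lower.tri(mm)] <- r
        m$rates <- mm + t(mm)
        -set_ll(m)
      }
      o <- stats::optim(log(r0[1:5]), fn, method = "L-BFGS-B",
                        lower = -7, upper = 7,
                        control = list(maxit = 25, factr = 1e10))
      r <- exp(c(o$par, 0))
      mm <- matrix(0, 4, 4, dimnames = list(model$states, model$states))
      mm[lower.tri(mm)] <- r
      model$rates <- mm + t(mm)
    }
    if ("frequencies" %in% free) {
      ns <- length(model$states)
      f0 <- pmax(model$freqs, 1e-6)
      fn <- function(lx) {
        m <- model
        f <- exp(c(lx, 0))
        m$freqs <- f / sum(f)
        -set_ll(m)
      }
      o <- stats::optim(log(f0[-ns] / f0[ns]), fn, method = "Nelder-Mead",
                        control = list(maxit = 100))
      f <- exp(c(o$par, 0))
      model$freqs <- f / sum(f)
      names(model$freqs) <- model$states
    }
    engine_set_model(eng, model)
    res <- cpp_engine_optimize_edges(eng$ptr, 1e-4, 20, integer(0))
    ll <- res$loglik
    if (length(free) == 0 || ll - ll0 < tol) break
  }
  res <- cpp_engine_optimize_edges(eng$ptr, 1e-4, 5, integer(0))
  fit_result(blen_to_tree(tree, eng$taxa, res$blen), model, res$loglik,
             length(aln$taxa))
}

# ---------------------------------------------------------------------------
# ML pairwise distances and tree search

# pairwise count tables (rows: i-state x j-state, row-major), one row per
# taxon pair in (1,2), (1,3), ..., (n-1,n) order; ambiguous columns skipped
pair_count_tables <- function(pd) {
  states <- states_of(pd$alphabet)
  ns <- length(states)
  code <- matrix(match(pd$chars, states), nrow = nrow(pd$chars))
  n <- nrow(code)
  tabs <- matrix(0, n * (n - 1) / 2, ns * ns)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    ok <- which(!is.na(code[i, ]) & !is.na(code[j, ]))
    idx <- (code[i, ok] - 1) * ns + code[j, ok]
    tabs[k, ] <- tabulate_weighted(idx, ns * ns, pd$weights[ok])
  }
  tabs
}

tabulate_weighted <- function(idx, nbins, w) {
  out <- numeric(nbins)
  rs <- rowsum(w, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

ml_distance_matrix <- function(pd, model) {
  n <- length(pd$taxa)
  mix <- model_mixture(model)
  tabs <- pair_count_tables(pd)
  d <- cpp_pair_ml_distances(tabs, model$rates, pmax(model$freqs, 1e-10),
                             mix$alpha, mix$ncat, mix$p_inv)
  D <- matrix(0, n, n, dimnames = list(pd$taxa, pd$taxa))
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    D[i, j] <- D[j, i] <- d[k]
  }
  D
}

children_of <- function(parent) {
  nnode <- length(parent)
  split(seq_len(nnode) - 1L, factor(parent, levels = seq_len(nnode) - 1L))
}

# core search on pattern data: NJ start, then NNI hill climbing in which each
# candidate is scored with its central branch re-optimized and the accepted
# best neighbor gets a full branch-length re-optimization
search_core <- function(pd, model, nni_tol = 1e-3, bl_tol = 1e-4,
                        max_rounds = 50, max_sweeps = 20) {
  ntip <- length(pd$taxa)
  eng <- new_engine(pd, model)
  D <- ml_distance_matrix(pd, model)
  if (ntip == 3) {
    parent <- c(3L, 3L, 3L, -1L)
    blen <- c(rep(0.1, 3), 0)
  } else {
    nj <- ape::unroot(ape::nj(D))
    if (!ape::is.binary(nj)) nj <- ape::multi2di(nj)
    nj$edge.length <- pmax(nj$edge.length, 1e-6)
    pt <- phylo_to_parent(nj, pd$taxa)
    parent <- pt$parent
    blen <- pt$blen
  }
  cpp_engine_set_tree(eng$ptr, parent, blen)
  res <- cpp_engine_optimize_edges(eng$ptr, bl_tol, max_sweeps, integer(0))
  ll <- res$loglik
  blen <- res$blen
  nnode <- length(parent)
  root <- which(parent == -1L) - 1L

  if (ntip > 3) {
    for (round in seq_len(max_rounds)) {
      kids <- children_of(parent)
      best <- NULL
      for (v in setdiff(ntip:(nnode - 1), root)) {
        u <- parent[v + 1]
        vkids <- kids[[as.character(v)]]
        b <- setdiff(kids[[as.character(u)]], v)[1]
        for (a in vkids) {
          cand <- parent
          cand[a + 1] <- u
          cand[b + 1] <- v
          cpp_engine_set_tree(eng$ptr, cand, blen)
          sc <- cpp_engine_optimize_edges(eng$ptr, bl_tol, 1,
                                          as.integer(v))$loglik
          if (is.null(best) || sc > best$ll)
            best <- list(ll = sc, parent = cand)
        }
      }
      if (is.null(best)) break
      cpp_engine_set_tree(eng$ptr, best$parent, blen)
      res <- cpp_engine_optimize_edges(eng$ptr, bl_tol, max_sweeps,
                                       integer(0))
      if (res$loglik > ll + nni_tol) {
        parent <- best$parent
        blen <- res$blen
        ll <- res$loglik
      } else break
    }
  }
  list(parent = parent, blen = blen, loglik = ll, taxa = pd$taxa)
}

#' Maximum-likelihood tree search
#'
#' Builds a neighbor-joining start tree from maximum-likelihood pairwise
#' distances, then hill-climbs over nearest-neighbor-interchange
#' rearrangements, accepting the best improving neighbor (with re-optimized
#' branch lengths) until no rearrangement improves the log-likelihood by more
#' than `1e-3`. Deterministic given `seed`.
#'
#' @param aln a [alignment()] with at least 3 taxa.
#' @param model a [substitution_model()].
#' @param seed integer seed (tree search itself is deterministic; the seed
#'   fixes tie-breaking in degenerate starting trees).
#' @return a `"phylo_fit"`.
#' @export
search_ml_tree <- function(aln, model, seed = NULL) {
  if (length(aln$taxa) < 3) stop("need at least 3 taxa")
  if (length(aln$taxa) == 3)
    warning("3 taxa: only one unrooted topology exists")
  if (!is.null(seed)) set.seed(seed)
  model <- resolve_model(model, aln)
  pd <- pattern_data(aln)
  res <- search_core(pd, model)
  fit_result(parent_to_phylo(res$parent, res$blen, res$taxa), model,
             res$loglik, length(aln$taxa))
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement (within partitions when a
#' scheme is given), reruns the ML tree search on every replicate, and maps
#' bipartition frequencies (as percentages) onto the ML tree from the
#' original data.
#'
#' @param aln a [alignment()].
#' @param model a [substitution_model()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; supports are reproducible under seed reuse.
#' @param partition optional [build_partitions()] scheme; columns are then
#'   resampled within subsets.
#' @param keep_trees keep the replicate trees as an attribute.
#' @return the ML tree with integer percent supports in `node.label`.
#' @export
bootstrap_support <- function(aln, model, n_reps = 100, seed = 1,
                              partition = NULL, keep_trees = FALSE) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1) stop("n_reps must be >= 1")
  model <- resolve_model(model, aln)
  pd <- pattern_data(aln)
  best <- search_core(pd, model)
  best_tree <- parent_to_phylo(best$parent, best$blen, best$taxa)

  groups <- if (is.null(partition)) list(seq_len(n_columns(aln)))
            else lapply(partition$subsets, `[[`, "columns")
  set.seed(seed)
  npat <- length(pd$weights)
  rep_splits <- vector("list", n_reps)
  rep_trees <- if (keep_trees) vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- unlist(lapply(groups, function(g) g[sample.int(length(g),
                                                          length(g),
                                                          replace = TRUE)]))
    wp <- tabulate(pd$col_pattern[idx], nbins = npat)
    keep <- wp > 0
    sub <- list(chars = pd$chars[, keep, drop = FALSE],
                weights = as.numeric(wp[keep]),
                taxa = pd$taxa, alphabet = pd$alphabet)
    fitr <- search_core(sub, model, bl_tol = 0.1, max_sweeps = 4)
    tr <- parent_to_phylo(fitr$parent, fitr$blen, fitr$taxa)
    rep_splits[[r]] <- tree_splits(tr)
    if (keep_trees) rep_trees[[r]] <- tr
  }
  # map split frequencies onto the internal nodes of the best tree
  labs <- best_tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(best_tree)
  node_lab <- character(best_tree$Nnode)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1 || length(side) >= length(labs) - 1) {
      node_lab[i] <- ""
      next
    }
    key <- paste(sort(side), collapse = "|")
    node_lab[i] <- as.character(round(100 * mean(vapply(
      rep_splits, function(s) key %in% s, TRUE))))
  }
  best_tree$node.label <- node_lab
  attr(best_tree, "log_likelihood") <- best$loglik
  if (keep_trees) attr(best_tree, "replicate_trees") <- rep_trees
  best_tree
}

#' Rank candidate models by AIC
#'
#' Fits every candidate with [optimize_model()] (free blocks inferred from
#' the candidate's structure) and ranks by `AIC = 2k - 2 lnL`, ties broken
#' by fewer parameters.
#'
#' @param aln a [alignment()].
#' @param tree a `"phylo"` tree used (with re-optimized branch lengths) for
#'   all candidates.
#' @param candidates non-empty list of [substitution_model()] skeletons.
#' @return data.frame with columns model, log_likelihood, k, AIC, ranked
#'   best-first; the fitted objects are in `attr(, "fits")`.
#' @export
select_model <- function(aln, tree, candidates) {
  if (!length(candidates)) stop("no candidate models")
  fits <- lapply(candidates, function(m) {
    free <- character(0)
    if (!is.null(m$gamma_shape)) free <- c(free, "alpha")
    if (m$p_inv > 0) free <- c(free, "p_inv")
    if (m$type == "GTR") free <- c(free, "exchangeabilities")
    optimize_model(aln, tree, m, free = free)
  })
  tab <- data.frame(
    model = vapply(fits, function(f) model_tag(f$model), ""),
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    k = vapply(fits, function(f) as.numeric(f$n_free_parameters), 0))
  tab$AIC <- 2 * tab$k - 2 * tab$log_likelihood
  o <- order(tab$AIC, tab$k)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[o]
  tab
}
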