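# Pattern compression, tip partial vectors, and the bridge between R-side
# alignments/trees and the compiled pruning engine.

# compress an alignment into unique site patterns
# returns: chars (taxa x npat matrix), weights, col_pattern (column -> pattern)
pattern_data <- function(aln) {
  m <- alignment_matrix(aln)
  keys <- apply(m, 2, paste, collapse = "")
  u <- !duplicated(keys)
  idx <- match(keys, keys[u])
  w <- tabulate(idx, nbins = sum(u))
  list(chars = m[, u, drop = FALSE], weights = as.numeric(w),
       col_pattern = idx, taxa = aln$taxa, alphabet = aln$alphabet)
}

# tip partial-likelihood vectors: ambiguity codes are indicator vectors over
# compatible states; a fully ambiguous code equals a gap
tip_partial_list <- function(pd) {
  states <- states_of(pd$alphabet)
  amb <- ambiguity_of(pd$alphabet)
  ns <- length(states)
  lookup <- matrix(0, ns, length(amb),
                   dimnames = list(states, names(amb)))
  for (a in names(amb)) lookup[amb[[a]], a] <- 1
  lapply(seq_len(nrow(pd$chars)), function(i) {
    ch <- pd$chars[i, ]
    bad <- setdiff(unique(ch), colnames(lookup))
    if (length(bad))
      stop("unknown characters for ", pd$taxa[i], ": ",
           paste(bad, collapse = " "))
    lookup[, ch, drop = FALSE]
  })
}

# states compatible with every taxon at each pattern (invariant-class mask)
const_ok_matrix <- function(tip_parts) {
  ok <- tip_parts[[1]] > 0
  for (i in seq_along(tip_parts)[-1]) ok <- ok & (tip_parts[[i]] > 0)
  storage.mode(ok) <- "integer"
  ok
}

# a live engine: compiled state + bookkeeping needed to talk to it
new_engine <- function(pd, model) {
  mix <- model_mixture(model)
  tp <- tip_partial_list(pd)
  ptr <- cpp_engine_new(tp, pd$weights, const_ok_matrix(tp), mix$ncat)
  eng <- new.env(parent = emptyenv())
  eng$ptr <- ptr
  eng$taxa <- pd$taxa
  eng$model <- model
  engine_set_model(eng, model)
  eng
}

engine_set_model <- function(eng, model) {
  if (is.null(model$freqs)) stop("model frequencies unset")
  mix <- model_mixture(model)
  cpp_engine_set_model(eng$ptr, model$rates, pmax(model$freqs, 1e-10),
                       mix$alpha, mix$p_inv, mix$ncat)
  eng$model <- model
  invisible(eng)
}

# ape phylo -> 0-based parent/branch-length arrays in engine node order
# (tips first, matched to `taxa`, then internal nodes)
phylo_to_parent <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  if (!setequal(tree$tip.label, taxa) || ntip != length(taxa))
    stop("tree leaves do not match alignment taxa")
  nnode <- ntip + tree$Nnode
  # engine tip index for each ape node id
  remap <- integer(nnode)
  remap[seq_len(ntip)] <- match(tree$tip.label, taxa)
  remap[(ntip + 1):nnode] <- (ntip + 1):nnode
  parent <- rep(-1L, nnode)
  blen <- rep(0.1, nnode)
  el <- tree$edge.length
  for (k in seq_len(nrow(tree$edge))) {
    p <- remap[tree$edge[k, 1]]
    ch <- remap[tree$edge[k, 2]]
    parent[ch] <- p - 1L
    if (!is.null(el)) blen[ch] <- el[k]
  }
  list(parent = parent, blen = blen, ntip = ntip)
}

engine_set_tree <- function(eng, tree) {
  pt <- phylo_to_parent(tree, eng$taxa)
  cpp_engine_set_tree(eng$ptr, pt$parent, pt$blen)
  eng$ntip <- pt$ntip
  eng$nnode <- length(pt$parent)
  invisible(eng)
}

engine_set_parent <- function(eng, parent, blen) {
  cpp_engine_set_tree(eng$ptr, parent, blen)
  eng$ntip <- length(eng$taxa)
  eng$nnode <- length(parent)
  invisible(eng)
}

# 0-based parent/blen arrays -> ape phylo (tip labels = taxa order)
parent_to_phylo <- function(parent, blen, taxa) {
  ntip <- length(taxa)
  nnode <- length(parent)
  root <- which(parent < 0)
  ints <- setdiff(seq_len(nnode), seq_len(ntip))
  # ape wants root first among internals (preorder is safest)
  ord <- integer(0)
  kids <- split(seq_len(nnode), factor(parent + 1L, levels = seq_len(nnode)))
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > ntip) ord <- c(ord, v)
    stack <- c(stack, kids[[v]])
  }
  newid <- integer(nnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  newid[ord] <- ntip + seq_along(ord)
  child <- setdiff(seq_len(nnode), root)
  edge <- cbind(newid[parent[child] + 1L], newid[child])
  o <- order(edge[, 1], edge[, 2])
  tr <- list(edge = edge[o, , drop = FALSE],
             edge.length = blen[child][o],
             tip.label = taxa, Nnode = length(ord))
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

# re-root an (unrooted) tree at the internal node with minimal eccentricity
# so incremental updates walk short paths to the virtual root
root_at_center <- function(tree) {
  if (length(tree$tip.label) < 4) return(tree)
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]
    b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ecc <- function(v) {
    d <- rep(NA_integer_, nn)
    d[v] <- 0L
    q <- v
    while (length(q)) {
      x <- q[1]
      q <- q[-1]
      for (y in adj[[x]]) if (is.na(d[y])) {
        d[y] <- d[x] + 1L
        q <- c(q, y)
      }
    }
    max(d)
  }
  internals <- (ntip + 1):nn
  best <- internals[which.min(vapply(internals, ecc, 0L))]
  out <- tryCatch(ape::root(tree, node = best, resolve.root = FALSE),
                  error = function(e) tree)
  if (!is.null(out$edge.length) && anyNA(out$edge.length))
    out$edge.length[is.na(out$edge.length)] <- 0
  out
}

#' Phylogenetic log-likelihood (Felsenstein pruning)
#'
#' Computes the log-likelihood of an alignment on a tree under a reversible
#' substitution model, using pruning over compressed site patterns with
#' per-pattern numerical rescaling. Site likelihoods mix the discrete-gamma
#' categories (weight `(1 - p_inv) / k` each) with the invariant class
#' (weight `p_inv`, contributing only at sites compatible with a constant
#' column). Gaps and ambiguity codes enter as partial-state indicator
#' vectors.
#'
#' @param aln a [alignment()] object.
#' @param tree a `"phylo"` tree with branch lengths; its leaves must match
#'   the alignment's taxa.
#' @param model a [substitution_model()].
#' @return the log-likelihood (finite for valid inputs).
#' @export
log_likelihood <- function(aln, tree, model) {
  if (length(aln$taxa) == 0 || n_columns(aln) == 0) stop("empty alignment")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  model <- resolve_model(model, aln)
  pd <- pattern_data(aln)
  eng <- new_engine(pd, model)
  engine_set_tree(eng, tree)
  cpp_engine_loglik(eng$ptr)
}
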