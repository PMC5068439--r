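# Sample-wise concordance factors across per-gene posterior tree samples,
# in the gene-independence limit.

# weighted frequency of samples containing the clade (unrooted test)
gene_clade_probability <- function(sample, clade) {
  hits <- vapply(sample$topologies, function(t) has_clade(t, clade), TRUE)
  sum(sample$weights[hits]) / sum(sample$weights)
}

#' Sample-wise concordance factor of a clade
#'
#' The per-gene clade probability is the weighted frequency of that gene's
#' sampled topologies containing the clade; the sample-wide concordance
#' factor is the mean over genes. The 95% credibility interval is Monte
#' Carlo: per replicate, one topology is drawn per gene (per its weights)
#' and the concordant-gene fraction recorded; the 2.5/97.5 percentiles over
#' `n_draws` replicates form the interval.
#'
#' @param samples list of [tree_sample()]s (one per gene), all over the
#'   same leaf set.
#' @param clade character vector of taxon labels; must be a non-trivial
#'   subset of the leaves.
#' @param n_draws Monte-Carlo replicates for the interval.
#' @param seed integer seed.
#' @return list of class `"clade_cf"`: `clade`, `cf`, `ci`, `per_gene`.
#' @export
sample_wide_cf <- function(samples, clade, n_draws = 1000, seed = 1) {
  if (inherits(samples, "tree_sample")) samples <- list(samples)
  if (!length(samples)) stop("need at least one gene sample")
  leaves <- sort(samples[[1]]$topologies[[1]]$tip.label)
  for (s in samples)
    if (!identical(sort(s$topologies[[1]]$tip.label), leaves))
      stop("gene samples have mismatched leaf sets")
  clade <- unique(clade)
  if (!all(clade %in% leaves)) stop("clade taxa absent from the trees")
  if (length(clade) < 1 || length(clade) >= length(leaves))
    stop("clade must be a non-trivial subset of the taxa")
  pg <- vapply(samples, gene_clade_probability, 0, clade = clade)
  cf <- mean(pg)
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i)
    mean(stats::rbinom(length(pg), 1, pg)), 0)
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(list(clade = sort(clade), cf = cf, ci = ci, per_gene = pg),
            class = "clade_cf")
}

#' @export
print.clade_cf <- function(x, ...) {
  cat(sprintf("CF{%s} = %.3f (95%% CI %.3f-%.3f, %d genes)\n",
              paste(x$clade, collapse = ","), x$cf, x$ci[1], x$ci[2],
              length(x$per_gene)))
  invisible(x)
}

#' Primary concordance tree
#'
#' Collects every clade seen in the per-gene samples with its sample-wide
#' concordance factor, then greedily assembles mutually compatible clades in
#' descending CF order; each edge is annotated with its CF.
#'
#' @param samples list of per-gene [tree_sample()]s.
#' @param n_draws,seed passed to [sample_wide_cf()] for the per-edge
#'   intervals.
#' @return a `"phylo"` tree with CFs in `node.label`; per-edge `"clade_cf"`
#'   objects in `attr(, "clade_cfs")`.
#' @export
primary_concordance_tree <- function(samples, n_draws = 1000, seed = 1) {
  if (inherits(samples, "tree_sample")) samples <- list(samples)
  if (!length(samples)) stop("need at least one gene sample")
  leaves <- sort(samples[[1]]$topologies[[1]]$tip.label)
  # mean (over genes) within-gene frequency of every observed split
  freqs <- lapply(samples, split_frequencies)
  keys <- unique(unlist(lapply(freqs, names)))
  cf <- vapply(keys, function(k)
    mean(vapply(freqs, function(f) if (k %in% names(f)) f[[k]] else 0, 0)),
    0)
  ord <- order(-cf)
  keys <- keys[ord]
  cf <- cf[ord]
  chosen <- list()
  chosen_cf <- numeric(0)
  chosen_key <- character(0)
  for (i in seq_along(keys)) {
    s <- strsplit(keys[i], "|", fixed = TRUE)[[1]]
    if (all(vapply(chosen, function(cs) compatible_splits(cs, s), TRUE))) {
      chosen <- c(chosen, list(s))
      chosen_cf <- c(chosen_cf, cf[i])
      chosen_key <- c(chosen_key, keys[i])
    }
  }
  tr <- splits_to_tree(chosen, chosen_cf, leaves)
  attr(tr, "clade_cfs") <- lapply(seq_along(chosen), function(i)
    sample_wide_cf(samples, chosen[[i]], n_draws = n_draws, seed = seed))
  tr
}
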