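# Bayesian MCMC over (topology, branch lengths, model parameters), tree
# samples, consensus trees and convergence diagnostics.

#' MCMC sampler settings
#'
#' Defaults mirror the study design: 2,000,000 generations, sampling every
#' 1,000, 25% burn-in, 4 independent runs. Tests and desk-scale analyses
#' pass smaller values.
#'
#' @param n_generations total generations per run.
#' @param sample_every thinning interval.
#' @param burnin_fraction fraction of samples discarded as burn-in.
#' @param n_runs number of independent runs.
#' @param proposal_weights positive weights for the `nni`,
#'   `branch_multiplier` and `model_param` proposals (normalized to sum 1).
#' @param seed integer seed controlling every run.
#' @return an object of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_generations = 2e6, sample_every = 1000,
                          burnin_fraction = 0.25, n_runs = 4,
                          proposal_weights = c(nni = 0.45,
                                               branch_multiplier = 0.45,
                                               model_param = 0.10),
                          seed = 1) {
  n_generations <- as.integer(n_generations)
  sample_every <- as.integer(sample_every)
  if (n_generations < sample_every)
    stop("n_generations must be >= sample_every")
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must be in [0, 1)")
  if (length(proposal_weights) != 3 || any(proposal_weights <= 0))
    stop("three positive proposal weights required")
  proposal_weights <- proposal_weights / sum(proposal_weights)
  structure(list(n_generations = n_generations,
                 sample_every = sample_every,
                 burnin_fraction = burnin_fraction,
                 n_runs = as.integer(n_runs),
                 proposal_weights = proposal_weights,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' A weighted sample of tree topologies
#'
#' Post-burn-in, thinned topologies from one gene's posterior; the input to
#' concordance-factor estimation.
#'
#' @param topologies list of `"phylo"` trees over a common leaf set.
#' @param weights positive per-tree multiplicities (default 1 each).
#' @param gene_name label.
#' @return an object of class `"tree_sample"`.
#' @export
tree_sample <- function(topologies, weights = NULL, gene_name = "") {
  if (inherits(topologies, "phylo")) topologies <- list(topologies)
  if (!length(topologies)) stop("empty tree sample")
  if (is.null(weights)) weights <- rep(1, length(topologies))
  if (length(weights) != length(topologies) || any(weights <= 0))
    stop("weights must be positive, one per topology")
  leaves <- sort(topologies[[1]]$tip.label)
  same <- vapply(topologies, function(t) identical(sort(t$tip.label), leaves),
                 TRUE)
  if (!all(same)) stop("all sampled trees must share one leaf set")
  structure(list(topologies = topologies, weights = weights,
                 gene_name = gene_name),
            class = "tree_sample")
}

#' Metropolis-Hastings MCMC over phylogenies
#'
#' Samples (topology, branch lengths, model parameters) under the priors:
#' uniform over unrooted topologies, exponential (mean 0.1) branch lengths,
#' exponential (mean 1) gamma shape, uniform proportion of invariant sites,
#' flat Dirichlet frequencies and exchangeabilities. Proposals are NNI,
#' single-branch multipliers (log-uniform factor in `[1/e, e]`) and
#' sliding-window / Dirichlet parameter moves, with exact Hastings
#' corrections. Runs are independent and fully reproducible from
#' `settings$seed`.
#'
#' @param aln a [alignment()] with >= 4 taxa (fewer are allowed with the
#'   topology then fixed).
#' @param model a [substitution_model()]; which parameters are sampled
#'   follows its structure (gamma shape when `+G`, p_inv when `+I`,
#'   frequencies/exchangeabilities for nucleotide GTR).
#' @param settings an [mcmc_settings()].
#' @param prior_only force the likelihood to a constant (sampler-correctness
#'   checks).
#' @param start_tree optional `"phylo"` start tree; default is a
#'   neighbor-joining tree on ML distances (a random tree when
#'   `prior_only`).
#' @return an object of class `"mcmc_result"`: per-run [tree_sample()]s
#'   (post-burn-in), traces (generation, lnL, alpha, p_inv) and acceptance
#'   rates per proposal type.
#' @export
mcmc_run <- function(aln, model, settings = mcmc_settings(),
                     prior_only = FALSE, start_tree = NULL) {
  stopifnot(inherits(settings, "mcmc_settings"))
  model <- resolve_model(model, aln)
  pd <- pattern_data(aln)
  ntip <- length(pd$taxa)
  if (ntip < 2) stop("need at least 2 taxa")
  set.seed(settings$seed)

  ctrl <- list(prior_only = prior_only,
               sample_alpha = !is.null(model$gamma_shape),
               sample_pinv = model$p_inv > 0,
               sample_freqs = !prior_only && model$alphabet == "nucleotide" &&
                 model$type == "GTR",
               sample_exch = !prior_only && model$alphabet == "nucleotide" &&
                 model$type == "GTR",
               branch_prior_mean = 0.1,
               dirichlet_conc = 500, debug_check = FALSE)

  nsamp <- settings$n_generations %/% settings$sample_every
  burn <- floor(settings$burnin_fraction * nsamp)
  runs <- vector("list", settings$n_runs)
  for (run in seq_len(settings$n_runs)) {
    eng <- new_engine(pd, model)
    tr0 <- start_tree
    if (is.null(tr0)) {
      if (prior_only || ntip < 4) {
        tr0 <- ape::rtree(ntip, tip.label = sample(pd$taxa))
        if (ntip >= 4) tr0 <- ape::unroot(tr0)
        tr0$edge.length <- stats::rexp(nrow(tr0$edge), rate = 10)
      } else {
        tr0 <- ape::unroot(ape::nj(ml_distance_matrix(pd, model)))
        if (!ape::is.binary(tr0)) tr0 <- ape::multi2di(tr0)
        tr0$edge.length <- pmax(tr0$edge.length, 1e-6)
      }
    }
    engine_set_tree(eng, root_at_center(tr0))
    out <- cpp_engine_mcmc(eng$ptr, settings$n_generations,
                           settings$sample_every,
                           settings$proposal_weights, ctrl)
    keep <- seq_len(nrow(out$parent)) > burn
    topo <- lapply(which(keep), function(i)
      parent_to_phylo(out$parent[i, ], out$blen[i, ], pd$taxa))
    trace <- data.frame(
      generation = seq_len(nsamp) * settings$sample_every,
      loglik = out$loglik, alpha = out$alpha, p_inv = out$p_inv)
    acc <- data.frame(proposal = c("nni", "branch_multiplier", "model_param"),
                      proposed = out$proposed, accepted = out$accepted,
                      rate = ifelse(out$proposed > 0,
                                    out$accepted / out$proposed, NA))
    runs[[run]] <- list(
      sample = tree_sample(topo, gene_name = aln$source_name),
      trace = trace, acceptance = acc)
  }
  structure(list(runs = runs, settings = settings,
                 burnin_samples = burn), class = "mcmc_result")
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat(sprintf("MCMC: %d runs x %d generations (%d post-burn-in samples/run)\n",
              length(x$runs), x$settings$n_generations,
              length(x$runs[[1]]$sample$topologies)))
  invisible(x)
}

# pool the post-burn-in samples of all runs
pooled_sample <- function(result) {
  ts <- do.call(c, lapply(result$runs, function(r) r$sample$topologies))
  ws <- do.call(c, lapply(result$runs, function(r) r$sample$weights))
  tree_sample(ts, ws)
}

# weighted split frequencies of a tree sample
split_frequencies <- function(sample) {
  W <- sum(sample$weights)
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(sample$topologies)) {
    for (key in tree_splits(sample$topologies[[i]])) {
      tab[[key]] <- (if (is.null(tab[[key]])) 0 else tab[[key]]) +
        sample$weights[i]
    }
  }
  keys <- ls(tab)
  stats::setNames(vapply(keys, function(k) tab[[k]] / W, 0), keys)
}

#' Majority-rule consensus tree with posterior probabilities
#'
#' Bipartitions at frequency > 0.5 form the consensus; compatible extra
#' bipartitions are added greedily in order of descending frequency. Node
#' labels carry the bipartition frequency among samples.
#'
#' @param samples a [tree_sample()] (or an [mcmc_run()] result, whose runs
#'   are then pooled).
#' @return a `"phylo"` tree with posterior probabilities in `node.label`.
#' @export
consensus_tree <- function(samples) {
  if (inherits(samples, "mcmc_result")) samples <- pooled_sample(samples)
  stopifnot(inherits(samples, "tree_sample"))
  freq <- split_frequencies(samples)
  ord <- order(-freq)
  freq <- freq[ord]
  labs <- sort(samples$topologies[[1]]$tip.label)
  chosen <- list()
  chosen_freq <- numeric(0)
  for (i in seq_along(freq)) {
    s <- strsplit(names(freq)[i], "|", fixed = TRUE)[[1]]
    if (all(vapply(chosen, function(cs) compatible_splits(cs, s), TRUE))) {
      chosen <- c(chosen, list(s))
      chosen_freq <- c(chosen_freq, freq[i])
    }
  }
  splits_to_tree(chosen, chosen_freq, labs)
}

# ---------------------------------------------------------------------------
# convergence diagnostics

# integrated-autocorrelation-time ESS (initial positive sequence estimator)
ess_ips <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 2000), type = "covariance",
                   plot = FALSE)$acf[, 1, 1]
  g0 <- ac[1]
  sigma2 <- -g0
  m <- 0
  while (2 * m + 2 <= length(ac)) {
    gam <- ac[2 * m + 1] + ac[2 * m + 2]
    if (gam <= 0) break
    sigma2 <- sigma2 + 2 * gam
    m <- m + 1
  }
  if (sigma2 <= 0) return(n)
  n * g0 / sigma2
}

#' Convergence diagnostics across MCMC runs
#'
#' `maxdiff` is the maximum over bipartitions of the absolute between-run
#' difference in sampled frequency; the effective sample size of the lnL
#' trace uses the initial-positive-sequence estimator of the integrated
#' autocorrelation time. Convergence is flagged when `maxdiff < 0.1` and
#' `ESS > 300`.
#'
#' @param result an [mcmc_run()] result, or a list of [tree_sample()]s
#'   together with `traces` (list of numeric lnL traces).
#' @param traces optional list of numeric lnL traces matching the samples.
#' @return list with `maxdiff`, `ess` (per run and minimum), and `converged`.
#' @export
convergence_diagnostics <- function(result, traces = NULL) {
  if (inherits(result, "mcmc_result")) {
    samples <- lapply(result$runs, `[[`, "sample")
    traces <- lapply(result$runs, function(r) r$trace$loglik)
  } else samples <- result
  freqs <- lapply(samples, split_frequencies)
  if (length(samples) < 2) {
    maxdiff <- NA_real_
  } else {
    keys <- unique(unlist(lapply(freqs, names)))
    maxdiff <- 0
    for (i in seq_along(freqs)) for (j in seq_along(freqs)) {
      if (j <= i) next
      fi <- freqs[[i]][keys]
      fj <- freqs[[j]][keys]
      fi[is.na(fi)] <- 0
      fj[is.na(fj)] <- 0
      d <- if (length(keys)) max(abs(fi - fj)) else 0
      maxdiff <- max(maxdiff, d)
    }
  }
  ess <- if (is.null(traces)) NA_real_ else vapply(traces, ess_ips, 0)
  list(maxdiff = maxdiff, ess = ess,
       converged = !is.na(maxdiff) && maxdiff < 0.1 &&
         all(!is.na(ess)) && min(ess) > 300)
}
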