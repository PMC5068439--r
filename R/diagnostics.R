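# Composition-bias and substitution-saturation screens.

#' Taxon groups
#'
#' Maps each taxon to one of the five groups used throughout:
#' complexa, robusta, corallimorpharia, actiniaria, outgroup
#' (Scleractinia = complexa + robusta).
#'
#' @param x named character vector (names = taxa, values = groups).
#' @return validated named character vector of class `"taxon_groups"`.
#' @export
taxon_groups <- function(x) {
  groups <- c("complexa", "robusta", "corallimorpharia", "actiniaria",
              "outgroup")
  x <- vapply(x, match.arg, "", choices = groups)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("every taxon must be named")
  if (anyDuplicated(names(x))) stop("duplicate taxa in group map")
  structure(x, class = "taxon_groups")
}

group_taxa <- function(groups, which) names(groups)[groups %in% which]

scleractinia_taxa <- function(groups)
  group_taxa(groups, c("complexa", "robusta"))

#' Per-taxon sequence composition profile
#'
#' State frequencies per taxon (overall, and per codon position for coding
#' nucleotide alignments), A+T content, the fractions of amino acids encoded
#' by A+T-rich codons (FYMINK) and by G+C-rich codons (GARP), and unweighted
#' group means. Gaps and ambiguity codes are excluded from all denominators.
#'
#' @param aln a [alignment()].
#' @param groups optional [taxon_groups()] for group means.
#' @param codon_positions optional integer vector of per-column codon
#'   positions (defaults to the alignment's own, if any).
#' @return list of class `"composition_profile"` with data.frames
#'   `per_taxon`, `per_position` (nucleotide with codon bookkeeping only)
#'   and `group_means`.
#' @export
composition_profile <- function(aln, groups = NULL, codon_positions = NULL) {
  states <- states_of(aln$alphabet)
  m <- alignment_matrix(aln)
  if (is.null(codon_positions)) codon_positions <- aln$codon_positions
  count_row <- function(ch) {
    cnt <- table(factor(ch, levels = states))
    tot <- sum(cnt)
    if (tot == 0) stop("taxon with no countable residues")
    as.numeric(cnt) / tot
  }
  freq <- t(apply(m, 1, count_row))
  colnames(freq) <- states
  per_taxon <- data.frame(taxon = aln$taxa, freq, check.names = FALSE)
  if (!is.null(groups))
    per_taxon$group <- unname(unclass(groups)[aln$taxa])
  if (aln$alphabet == "nucleotide") {
    per_taxon$AT_content <- freq[, "A"] + freq[, "T"]
  } else {
    per_taxon$FYMINK <- rowSums(freq[, FYMINK_SET, drop = FALSE])
    per_taxon$GARP <- rowSums(freq[, GARP_SET, drop = FALSE])
  }
  per_position <- NULL
  if (aln$alphabet == "nucleotide" && !is.null(codon_positions)) {
    per_position <- do.call(rbind, lapply(1:3, function(pos) {
      sel <- codon_positions == pos
      f <- t(apply(m[, sel, drop = FALSE], 1, count_row))
      colnames(f) <- states
      data.frame(taxon = aln$taxa, codon_position = pos, f,
                 AT_content = f[, "A"] + f[, "T"], check.names = FALSE)
    }))
  }
  group_means <- NULL
  if (!is.null(groups)) {
    gm <- stats::aggregate(per_taxon[, !(names(per_taxon) %in%
                                           c("taxon", "group"))],
                           by = list(group = per_taxon$group), FUN = mean)
    group_means <- gm
  }
  structure(list(per_taxon = per_taxon, per_position = per_position,
                 group_means = group_means, alphabet = aln$alphabet),
            class = "composition_profile")
}

#' Chi-square test of compositional homogeneity across taxa
#'
#' Pearson chi-square on the taxa-by-states contingency table of ungapped,
#' unambiguous residue counts, with `df = (n_taxa - 1)(n_states - 1)` and an
#' upper-tail p-value.
#'
#' @param aln a [alignment()] with at least 2 taxa.
#' @return list with `statistic`, `df`, `p_value` and the count `table`.
#' @export
composition_homogeneity_test <- function(aln) {
  if (length(aln$taxa) < 2) stop("need at least 2 taxa")
  states <- states_of(aln$alphabet)
  m <- alignment_matrix(aln)
  tab <- t(apply(m, 1, function(ch)
    as.numeric(table(factor(ch, levels = states)))))
  colnames(tab) <- states
  rownames(tab) <- aln$taxa
  if (any(rowSums(tab) == 0))
    stop("taxon without countable residues: ",
         paste(aln$taxa[rowSums(tab) == 0], collapse = ", "))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), table = tab)
}

# ---------------------------------------------------------------------------
# substitution saturation

# mean per-site Shannon entropy of the observed states across taxa
mean_site_entropy <- function(m, states) {
  apply_entropy <- function(col) {
    cnt <- table(factor(col, levels = states))
    tot <- sum(cnt)
    if (tot == 0) return(NA_real_)
    p <- cnt[cnt > 0] / tot
    -sum(p * log(p))
  }
  h <- apply(m, 2, apply_entropy)
  mean(h, na.rm = TRUE)
}

# exact expected entropy of n iid draws from frequency vector f
expected_entropy_iid <- function(n, f) {
  ns <- length(f)
  lf <- log(ifelse(f > 0, f, 1))
  comp <- function(rest, left) {
    if (length(rest) == 1) return(matrix(left, ncol = 1))
    out <- do.call(rbind, lapply(0:left, function(k)
      cbind(k, comp(rest[-1], left - k))))
    out
  }
  cc <- comp(seq_len(ns), n)
  lp <- lgamma(n + 1) - rowSums(lgamma(cc + 1)) + as.vector(cc %*% lf)
  p <- cc / n
  H <- -rowSums(ifelse(p > 0, p * log(p), 0))
  sum(exp(lp) * H)
}

# entropy-based saturation index of an alignment matrix
iss_index <- function(m, states) {
  freqs <- {
    cnt <- table(factor(m, levels = states))
    as.numeric(cnt) / sum(cnt)
  }
  hsat <- expected_entropy_iid(nrow(m), freqs)
  if (hsat <= 0) return(0)
  mean_site_entropy(m, states) / hsat
}

#' Entropy-based test of substitution saturation
#'
#' The saturation index `Iss` is the mean per-site entropy of the observed
#' states divided by the expected per-site entropy at full saturation
#' (iid draws from the observed base frequencies). The critical value
#' `Iss_critical` is estimated by simulation: alignments of matched
#' dimensions are generated on a reference tree over a ladder of tree
#' depths, and a logistic fit locates the `Iss` level at which
#' neighbor-joining recovery of the reference topology drops to 50%. The
#' observed `Iss` is then tested (two-tailed, normal approximation using the
#' simulation spread) against the critical value.
#'
#' @param aln nucleotide [alignment()] with >= 4 taxa.
#' @param n_sim total number of simulated alignments across the depth
#'   ladder.
#' @param seed integer seed.
#' @return list of class `"saturation_report"`: `Iss`, `Iss_critical`,
#'   `p_value`, `Pinv` (fraction of constant-compatible columns) and
#'   `significant_saturation`.
#' @export
saturation_test <- function(aln, n_sim = 160, seed = 1) {
  if (aln$alphabet != "nucleotide") stop("saturation test needs nucleotides")
  ntax <- length(aln$taxa)
  if (ntax < 4) stop("need at least 4 taxa")
  set.seed(seed)
  states <- NT_STATES
  m <- alignment_matrix(aln)
  iss_obs <- iss_index(m, states)
  nsite <- min(n_columns(aln), 2000)
  freqs <- observed_frequencies(aln)

  # constant-compatible columns
  amb <- ambiguity_of("nucleotide")
  pinv_obs <- mean(apply(m, 2, function(col) {
    sets <- amb[col]
    length(Reduce(intersect, sets)) > 0
  }))

  ref <- ape::rtree(ntax, tip.label = aln$taxa)
  depths <- exp(seq(log(0.03), log(8), length.out = 8))
  per <- max(2, ceiling(n_sim / length(depths)))
  model <- substitution_model("nucleotide", "GTR", rates = rep(1, 6),
                              freqs = freqs)
  sims <- do.call(rbind, lapply(depths, function(d) {
    do.call(rbind, lapply(seq_len(per), function(i) {
      tr <- ref
      tr$edge.length <- ref$edge.length * d / max(ape::node.depth.edgelength(ref))
      sim <- simulate_alignment(tr, model, nsite)
      sm <- alignment_matrix(sim)
      iss <- iss_index(sm, states)
      rec <- nj_recovers(sm, ref)
      c(depth = d, iss = iss, recovered = rec)
    }))
  }))
  sims <- as.data.frame(sims)
  fit <- tryCatch(
    suppressWarnings(stats::glm(recovered ~ iss, binomial, data = sims)),
    error = function(e) NULL)
  iss_crit <- if (!is.null(fit) && is.finite(coef(fit)[2]) &&
                  coef(fit)[2] != 0) {
    unname(-coef(fit)[1] / coef(fit)[2])
  } else {
    # complete separation: midpoint between recovered and lost regimes
    mean(c(max(sims$iss[sims$recovered == 1], -Inf),
           min(sims$iss[sims$recovered == 0], Inf)))
  }
  iss_crit <- min(max(iss_crit, 0), 1.2)
  near <- sims[order(abs(sims$iss - iss_crit)), ][seq_len(per), ]
  spread <- max(stats::sd(near$iss), 1e-6)
  z <- (iss_obs - iss_crit) / spread
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(Iss = iss_obs, Iss_critical = iss_crit, p_value = p,
                 Pinv = pinv_obs,
                 significant_saturation = iss_obs >= iss_crit && p < 0.05,
                 simulations = sims),
            class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf("Iss = %.3f vs Iss.c = %.3f (p = %.3g): %s\n", x$Iss,
              x$Iss_critical, x$p_value,
              if (x$significant_saturation) "significant saturation"
              else "no significant saturation"))
  invisible(x)
}

# does NJ on JC distances recover the reference topology?
nj_recovers <- function(m, ref) {
  states <- NT_STATES
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(m[i, ] != m[j, ])
    d <- if (p >= 0.74) 5 else -0.75 * log(1 - 4 * p / 3)
    D[i, j] <- D[j, i] <- d
  }
  rownames(D) <- colnames(D) <- rownames(m)
  tr <- tryCatch(ape::nj(D), error = function(e) NULL)
  if (is.null(tr)) return(0)
  as.numeric(setequal(tree_splits(tr), tree_splits(ref)))
}
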