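# Topology-hypothesis machinery: outgroup rooting, classification of gene
# trees against scleractinian monophyly vs the naked-coral topology,
# cross-method pattern concordance, and the gene-length comparison.

#' Root a tree on its outgroup
#'
#' Places the root on the edge separating the outgroup taxa from the rest.
#' The outgroup must be monophyletic on the unrooted tree (a single-taxon
#' outgroup always qualifies).
#'
#' @param tree a `"phylo"` tree.
#' @param groups a [taxon_groups()] map containing the tree's outgroup
#'   taxa.
#' @return a rooted `"phylo"` tree.
#' @export
root_on_outgroup <- function(tree, groups) {
  og <- intersect(group_taxa(groups, "outgroup"), tree$tip.label)
  if (!length(og)) stop("no outgroup taxon present in the tree")
  if (length(og) > 1 && !has_clade(tree, og))
    stop("outgroup is not monophyletic on the unrooted tree; offending ",
         "bipartition side: {", paste(sort(og), collapse = ", "), "}")
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

#' Classify a gene tree against the two competing hypotheses
#'
#' After rooting on the outgroup: `monophyly` if Scleractinia
#' (complexa + robusta) forms a clade; otherwise `naked_coral` if
#' robusta + corallimorpharia forms a clade (corallimorpharians nested
#' within a paraphyletic Scleractinia); otherwise `other`. On a binary tree
#' containing at least one complexan the two clade conditions are mutually
#' exclusive. Actiniarian placement is ignored; branch lengths and leaf
#' order are irrelevant.
#'
#' @param tree a `"phylo"` tree containing at least one taxon from each of
#'   complexa, robusta, corallimorpharia and the outgroup.
#' @param groups a [taxon_groups()] map.
#' @return one of `"monophyly"`, `"naked_coral"`, `"other"`.
#' @export
classify_topology <- function(tree, groups) {
  labs <- tree$tip.label
  need <- c("complexa", "robusta", "corallimorpharia", "outgroup")
  for (g in need)
    if (!length(intersect(group_taxa(groups, g), labs)))
      stop("no taxon of group '", g, "' in the tree")
  scler <- intersect(scleractinia_taxa(groups), labs)
  if (has_clade(tree, scler)) return("monophyly")
  naked <- intersect(group_taxa(groups, c("robusta", "corallimorpharia")),
                     labs)
  if (has_clade(tree, naked)) return("naked_coral")
  "other"
}

#' The four critical clades of the monophyly topology
#'
#' @param groups a [taxon_groups()] map.
#' @return named list of taxon sets: node1 = Corallimorpharia+Scleractinia,
#'   node2 = Corallimorpharia, node3 = Robusta, node4 = Complexa.
#' @export
critical_nodes <- function(groups) {
  list(node1 = group_taxa(groups, c("corallimorpharia", "complexa",
                                    "robusta")),
       node2 = group_taxa(groups, "corallimorpharia"),
       node3 = group_taxa(groups, "robusta"),
       node4 = group_taxa(groups, "complexa"))
}

#' Cross-method concordance pattern table
#'
#' Groups genes by their tuple of topology calls across inference
#' configurations, orders the patterns by descending abundance (ties by
#' first occurrence) and flags the fully concordant monophyly and
#' naked-coral patterns.
#'
#' @param calls character matrix (genes x configurations) of
#'   `"monophyly"`/`"naked_coral"`/`"other"` calls; rownames are gene names.
#' @param lengths numeric vector of aligned gene lengths (columns).
#' @return a data.frame of class `"gene_pattern_table"`: one row per gene
#'   with its calls, pattern string, pattern rank and count, and concordance
#'   flags; the per-pattern summary is in `attr(, "patterns")`.
#' @export
pattern_table <- function(calls, lengths) {
  calls <- as.matrix(calls)
  if (any(is.na(calls))) stop("incomplete call matrix")
  ok <- calls %in% c("monophyly", "naked_coral", "other")
  if (!all(ok)) stop("invalid topology calls: ",
                     paste(unique(calls[!ok]), collapse = ", "))
  if (length(lengths) != nrow(calls))
    stop("need one length per gene")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("gene%03d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("config%d", seq_len(ncol(calls)))
  pattern <- apply(calls, 1, paste, collapse = "|")
  counts <- table(pattern)[unique(pattern)]  # first-occurrence order
  ord <- order(-as.numeric(counts))
  ranks <- stats::setNames(seq_along(ord), names(counts)[ord])
  df <- data.frame(gene = rownames(calls), length = lengths, calls,
                   pattern = pattern,
                   pattern_count = as.numeric(counts[pattern]),
                   pattern_rank = as.numeric(ranks[pattern]),
                   concordant_monophyly =
                     apply(calls == "monophyly", 1, all),
                   concordant_naked_coral =
                     apply(calls == "naked_coral", 1, all),
                   row.names = NULL, check.names = FALSE)
  df <- df[order(df$pattern_rank), ]
  rownames(df) <- NULL
  pat <- data.frame(pattern = names(counts)[ord],
                    count = as.numeric(counts)[ord],
                    rank = seq_along(ord))
  structure(df, patterns = pat, class = c("gene_pattern_table",
                                          "data.frame"))
}

#' Mann-Whitney U test
#'
#' `U` counts pairs with `x_i > y_j` plus half the ties. Exact mode
#' enumerates all assignments of the pooled values to the two groups
#' (handling ties exactly); normal mode uses the tie-corrected normal
#' approximation with continuity correction. Two-sided p-values are
#' `2 * min(lower tail, upper tail, 0.5)`.
#'
#' @param x,y non-empty numeric samples.
#' @param mode `"auto"` (exact when `n_x + n_y <= 20`), `"exact"` or
#'   `"normal"`.
#' @return list with `U`, `p_value`, `mode`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x)
  ny <- length(y)
  if (mode == "auto") mode <- if (nx + ny <= 40) "exact" else "normal"
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (mode == "exact") {
    # exact null distribution of the rank sum over all C(N, nx) group
    # assignments (ties included), by dynamic programming over doubled
    # midranks; counts stay below 2^53 for any practical layout
    N <- nx + ny
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
    dp <- matrix(0, nx + 1, smax + 1)  # dp[k+1, s+1]
    dp[1, 1] <- 1
    for (it in seq_len(N)) {
      kmax <- min(it, nx)
      for (k in kmax:1) {
        src <- dp[k, seq_len(smax + 1 - r2[it])]
        idx <- (r2[it] + 1):(smax + 1)
        dp[k + 1, idx] <- dp[k + 1, idx] + src
      }
    }
    cnt <- dp[nx + 1, ]
    s_obs <- as.integer(round(2 * (U + nx * (nx + 1) / 2)))
    total <- sum(cnt)
    p_lo <- sum(cnt[seq_len(min(s_obs + 1, length(cnt)))]) / total
    p_hi <- sum(cnt[min(s_obs + 1, length(cnt)):length(cnt)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    N <- nx + ny
    ties <- table(pooled)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z_hi <- (U - mu - 0.5) / sqrt(sig2)
      z_lo <- (U - mu + 0.5) / sqrt(sig2)
      p <- min(1, 2 * min(stats::pnorm(z_lo), stats::pnorm(z_hi,
                                                           lower.tail = FALSE),
                          0.5))
    }
  }
  list(U = unname(U), p_value = p, mode = mode, n_x = nx, n_y = ny)
}

#' Compare aligned lengths of the two fully concordant gene classes
#'
#' Mann-Whitney U test of the aligned lengths of genes fully concordant
#' with scleractinian monophyly against those fully concordant with the
#' naked-coral topology.
#'
#' @param table a [pattern_table()].
#' @param mode passed to [mann_whitney_u()].
#' @return list with group sizes, medians, `U` and `p_value` (`NULL` and
#'   `testable = FALSE` when a class is empty).
#' @export
length_comparison <- function(table, mode = "auto") {
  stopifnot(inherits(table, "gene_pattern_table"))
  lm <- table$length[table$concordant_monophyly]
  ln <- table$length[table$concordant_naked_coral]
  if (!length(lm) || !length(ln)) {
    return(list(testable = FALSE, n_monophyly = length(lm),
                n_naked_coral = length(ln),
                median_monophyly = if (length(lm)) stats::median(lm),
                median_naked_coral = if (length(ln)) stats::median(ln)))
  }
  mw <- mann_whitney_u(lm, ln, mode = mode)
  list(testable = TRUE, n_monophyly = length(lm),
       n_naked_coral = length(ln),
       median_monophyly = stats::median(lm),
       median_naked_coral = stats::median(ln),
       U = mw$U, p_value = mw$p_value, mode = mw$mode)
}
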