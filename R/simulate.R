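# Simulator of trees, alignments and multi-gene datasets with the taxon
# structure the analyses assume (3 Complexa, 6 Robusta, 3 Corallimorpharia,
# 2 Actiniaria, 1 octocoral outgroup by default).

#' Scenario specification for the multi-gene simulator
#'
#' Defaults emulate the study design: 15 taxa in five groups, 291 genes, a
#' root-to-tip depth of 0.3 expected substitutions per site, log-normal gene
#' lengths with median 400 codons (so the expected amino-acid supermatrix is
#' on the order of 1.2e5 columns), a 15% minority of genes generated under
#' the discordant topology at one third the length of the concordant genes.
#'
#' @param hypothesis generating backbone: `"monophyly"` or `"naked_coral"`.
#' @param n_complexa,n_robusta,n_corallimorpharia,n_actiniaria,n_outgroup
#'   taxon counts per group.
#' @param depth expected root-to-tip substitutions per site.
#' @param n_genes number of genes.
#' @param length_median,length_sigma log-normal gene-length model (codons);
#'   draws are floored at 30 codons.
#' @param discordant_fraction fraction of genes generated under the
#'   alternative topology (in `[0, 1)`).
#' @param discordant_length_factor length multiplier of discordant genes.
#' @param composition_bias optional
#'   `list(group = <group>, shift = <named vector>)` applied to simulated
#'   nucleotide genes.
#' @param seed integer seed.
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(hypothesis = c("monophyly", "naked_coral"),
                          n_complexa = 3, n_robusta = 6,
                          n_corallimorpharia = 3, n_actiniaria = 2,
                          n_outgroup = 1, depth = 0.3, n_genes = 291,
                          length_median = 400, length_sigma = 0.4,
                          discordant_fraction = 0.15,
                          discordant_length_factor = 1 / 3,
                          composition_bias = NULL, seed = 1) {
  hypothesis <- match.arg(hypothesis)
  counts <- c(complexa = n_complexa, robusta = n_robusta,
              corallimorpharia = n_corallimorpharia,
              actiniaria = n_actiniaria, outgroup = n_outgroup)
  if (any(counts < 1)) stop("every group needs at least one taxon")
  if (discordant_fraction < 0 || discordant_fraction >= 1)
    stop("discordant_fraction must be in [0, 1)")
  if (depth <= 0 || length_median < 30) stop("invalid depth or length model")
  structure(list(hypothesis = hypothesis, counts = counts, depth = depth,
                 n_genes = as.integer(n_genes),
                 length_median = length_median, length_sigma = length_sigma,
                 discordant_fraction = discordant_fraction,
                 discordant_length_factor = discordant_length_factor,
                 composition_bias = composition_bias,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# ultrametric group crown of height h (single-taxon groups are bare tips)
.crown_newick <- function(labels, h) {
  if (length(labels) == 1) return(list(txt = labels, stemless = TRUE))
  tr <- ape::rcoal(length(labels), tip.label = labels)
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * h / d
  list(txt = sub(";$", "", ape::write.tree(tr)), stemless = FALSE)
}

# both backbones over the same within-group crowns; node depths are fixed
# fractions of the root-to-tip depth D
.scenario_trees <- function(spec) {
  D <- spec$depth
  counts <- spec$counts
  labels <- list(
    complexa = sprintf("Comp%02d", seq_len(counts["complexa"])),
    robusta = sprintf("Rob%02d", seq_len(counts["robusta"])),
    corallimorpharia = sprintf("Cor%02d",
                               seq_len(counts["corallimorpharia"])),
    actiniaria = sprintf("Act%02d", seq_len(counts["actiniaria"])),
    outgroup = sprintf("Out%02d", seq_len(counts["outgroup"])))
  groups <- taxon_groups(stats::setNames(
    rep(names(labels), lengths(labels)), unlist(labels)))
  crown_h <- 0.25 * D
  sub <- lapply(labels, function(l) .crown_newick(l, crown_h))
  # attach a crown so its tips end at depth D, given its stem starts at `at`
  att <- function(g, at) {
    if (sub[[g]]$stemless)
      sprintf("%s:%g", sub[[g]]$txt, D - at)
    else
      sprintf("%s:%g", sub[[g]]$txt, D - at - crown_h)
  }
  mk <- function(inner) {
    # root at depth 0; Act joins at 0.2 D; next splits at 0.4 D and 0.55 D
    sprintf("(%s,(%s,%s:%g):%g);",
            att("outgroup", 0), att("actiniaria", 0.2 * D), inner,
            0.2 * D, 0.2 * D)
  }
  pair <- function(g1, g2, at, join) {
    sprintf("(%s,%s):%g", att(g1, join), att(g2, join), join - at)
  }
  mono <- mk(sprintf("(%s,%s)", att("corallimorpharia", 0.4 * D),
                     pair("complexa", "robusta", 0.4 * D, 0.55 * D)))
  naked <- mk(sprintf("(%s,%s)", att("complexa", 0.4 * D),
                      pair("corallimorpharia", "robusta", 0.4 * D,
                           0.55 * D)))
  list(monophyly = ape::read.tree(text = mono),
       naked_coral = ape::read.tree(text = naked),
       groups = groups)
}

#' Generating tree of a scenario
#'
#' Backbone follows the chosen hypothesis; within-group subtrees are random
#' coalescent-style ultrametric trees; all root-to-tip path lengths equal
#' the requested depth.
#'
#' @param spec a [scenario_spec()].
#' @return list with `tree` (rooted `"phylo"`), `alternative` (the tree of
#'   the competing hypothesis over the same taxa) and `groups`.
#' @export
make_scenario_tree <- function(spec) {
  set.seed(spec$seed)
  tr <- .scenario_trees(spec)
  if (spec$hypothesis == "monophyly")
    list(tree = tr$monophyly, alternative = tr$naked_coral,
         groups = tr$groups)
  else
    list(tree = tr$naked_coral, alternative = tr$monophyly,
         groups = tr$groups)
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies and
#' evolved edge-wise via [transition_matrix()]; each site carries a
#' discrete-gamma category (or the invariant class, with probability
#' `p_inv`) for its whole history.
#'
#' @param tree `"phylo"` tree with branch lengths.
#' @param model a [substitution_model()] with frequencies set.
#' @param n_sites number of columns (>= 1).
#' @param seed optional integer seed.
#' @return a nucleotide or amino-acid [alignment()].
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (is.null(model$freqs)) stop("model frequencies unset")
  states <- model$states
  mix <- model_mixture(model)
  rates <- c(variable_rates(model), 0)
  prob <- c(rep((1 - mix$p_inv) / mix$ncat, mix$ncat), mix$p_inv)
  site_cls <- sample.int(length(rates), n_sites, replace = TRUE, prob = prob)
  me <- model_eigen(model)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  st <- matrix(0L, nnode, n_sites)
  root <- tree$edge[1, 1]
  st[root, ] <- sample.int(length(states), n_sites, TRUE, prob = me$pi)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    t <- tree$edge.length[k]
    for (cls in unique(site_cls)) {
      sel <- which(site_cls == cls)
      if (rates[cls] == 0) {
        st[ch, sel] <- st[p, sel]
        next
      }
      P <- pmat_eigen(me, t, rates[cls])
      for (s in unique(st[p, sel])) {
        j <- sel[st[p, sel] == s]
        st[ch, j] <- sample.int(length(states), length(j), TRUE,
                                prob = pmax(P[s, ], 0))
      }
    }
  }
  m <- matrix(states[st[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(m) <- tree$tip.label
  matrix_alignment(m, model$alphabet)
}

# simulate a stop-free codon alignment (3 * n_codons columns); codon columns
# containing a stop in any taxon are redrawn, conditioning the process on
# stop-free coding sequences
simulate_codon_alignment <- function(tree, model, n_codons) {
  aln <- simulate_alignment(tree, model, 3 * n_codons)
  m <- alignment_matrix(aln)
  for (it in 1:100) {
    bad <- which(vapply(seq_len(n_codons), function(cd) {
      cols <- (3 * cd - 2):(3 * cd)
      any(apply(m[, cols, drop = FALSE], 1, paste, collapse = "") %in%
            STOP_CODONS)
    }, TRUE))
    if (!length(bad)) break
    redo <- simulate_alignment(tree, model, 3 * length(bad))
    rm2 <- alignment_matrix(redo)[rownames(m), , drop = FALSE]
    for (i in seq_along(bad))
      m[, (3 * bad[i] - 2):(3 * bad[i])] <- rm2[, (3 * i - 2):(3 * i)]
  }
  matrix_alignment(m, "nucleotide",
                   codon_positions = rep(1:3, n_codons))
}

aa_companion <- function(nt_aln) {
  aa <- vapply(nt_aln$sequences, function(s) {
    r <- translate_codons(s)
    r[r == "*"] <- "X"
    paste(r, collapse = "")
  }, "")
  alignment(nt_aln$taxa, unname(aa), alphabet = "amino_acid",
            source_name = nt_aln$source_name)
}

#' Simulate a multi-gene dataset with a discordant minority
#'
#' `floor(discordant_fraction * n_genes)` genes are simulated on the
#' alternative-hypothesis tree, the rest on the primary tree; gene lengths
#' are log-normal (in codons), with discordant genes scaled by
#' `discordant_length_factor` (mirroring the observation that genes
#' supporting the minority topology are shorter). Genes are simulated as
#' codon triplets under the nucleotide model, with translated amino-acid
#' companions, so back-translation round-trips exactly.
#'
#' @param spec a [scenario_spec()].
#' @param model nucleotide [substitution_model()] with frequencies set.
#' @return list of class `"gene_set"`: `genes` (each with `nt`, `aa`,
#'   `label`, `n_codons`), `groups`, `trees`, and a `manifest` data.frame.
#' @export
simulate_gene_set <- function(spec, model) {
  set.seed(spec$seed)
  tr <- .scenario_trees(spec)
  primary <- tr[[spec$hypothesis]]
  altname <- setdiff(c("monophyly", "naked_coral"), spec$hypothesis)
  alt <- tr[[altname]]
  n_disc <- floor(spec$discordant_fraction * spec$n_genes)
  labels <- rep(c(spec$hypothesis, altname),
                c(spec$n_genes - n_disc, n_disc))
  lens <- round(exp(log(spec$length_median) +
                      spec$length_sigma * stats::rnorm(spec$n_genes)))
  lens[labels == altname] <- round(lens[labels == altname] *
                                     spec$discordant_length_factor)
  lens <- pmax(lens, 30)
  genes <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    tree_g <- if (labels[g] == spec$hypothesis) primary else alt
    nt <- simulate_codon_alignment(tree_g, model, lens[g])
    if (!is.null(spec$composition_bias)) {
      nt <- inject_composition_bias(nt, tr$groups,
                                    spec$composition_bias$group,
                                    spec$composition_bias$shift)
    }
    nt$source_name <- sprintf("gene%03d", g)
    aa <- aa_companion(nt)
    genes[[g]] <- list(nt = nt, aa = aa, label = labels[g],
                       n_codons = lens[g])
  }
  manifest <- data.frame(gene = vapply(genes, function(g) g$nt$source_name,
                                       ""),
                         n_codons = lens, n_nt = 3 * lens,
                         label = labels)
  structure(list(genes = genes, groups = tr$groups,
                 trees = list(primary = primary, alternative = alt),
                 manifest = manifest), class = "gene_set")
}

#' Inject a compositional bias into one taxon group
#'
#' For each site of the target-group taxa the state is redrawn, with a
#' probability proportional to the size of the shift (the smallest
#' probability admitting a valid redraw distribution), from a distribution
#' tilted toward the perturbed frequencies; other taxa are untouched. The
#' expected composition of the target group moves by exactly the shift
#' vector.
#'
#' @param aln a [alignment()].
#' @param groups a [taxon_groups()] map.
#' @param target_group group whose taxa receive the bias.
#' @param frequency_shift named numeric vector over the states, summing to
#'   zero; observed frequencies plus the shift must stay on the simplex.
#' @return the biased [alignment()].
#' @export
inject_composition_bias <- function(aln, groups, target_group,
                                    frequency_shift) {
  states <- states_of(aln$alphabet)
  shift <- frequency_shift[states]
  shift[is.na(shift)] <- 0
  if (abs(sum(shift)) > 1e-8) stop("frequency_shift must sum to zero")
  f <- observed_frequencies(aln)
  if (any(f + shift < -1e-12) || any(f + shift > 1))
    stop("shifted frequencies leave the simplex")
  if (all(shift == 0)) return(aln)
  # smallest resampling probability delta with a valid redraw distribution
  # q = f + shift/delta; then E[new freqs] = f + shift exactly
  delta <- max(c(-shift / pmax(f, 1e-12),
                 shift / pmax(1 - f, 1e-12), 1e-6))
  delta <- min(delta, 1)
  q <- pmax(f + shift / delta, 0)
  q <- q / sum(q)
  m <- alignment_matrix(aln)
  targets <- intersect(group_taxa(groups, target_group), aln$taxa)
  if (!length(targets)) stop("no taxa of group '", target_group, "'")
  for (tax in targets) {
    i <- match(tax, aln$taxa)
    resample <- stats::runif(ncol(m)) < delta & m[i, ] %in% states
    m[i, resample] <- sample(states, sum(resample), TRUE, prob = q)
  }
  matrix_alignment(m, aln$alphabet, aln$source_name, aln$codon_positions)
}
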