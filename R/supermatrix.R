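# Back-translation, concatenation and partition schemes for the supermatrix
# analyses.

translate_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3 != 0) stop("coding sequence length not a multiple of 3")
  cod <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(GENETIC_CODE_STD[cod])
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity
  aa
}

#' Back-translate an amino-acid alignment onto coding nucleotides
#'
#' Each amino-acid column becomes one codon column-triple; amino-acid gaps
#' become `---`. For every taxon the translation of its coding sequence must
#' equal its ungapped amino-acid row.
#'
#' @param aa_alignment amino-acid [alignment()].
#' @param cds named character vector of unaligned coding sequences (one per
#'   taxon; a trailing stop codon is tolerated).
#' @return a nucleotide [alignment()] of length `3 x` the amino-acid length,
#'   with codon positions recorded for partitioning.
#' @export
back_translate <- function(aa_alignment, cds) {
  if (aa_alignment$alphabet != "amino_acid")
    stop("back_translate needs an amino-acid alignment")
  if (!all(aa_alignment$taxa %in% names(cds)))
    stop("missing coding sequences for: ",
         paste(setdiff(aa_alignment$taxa, names(cds)), collapse = ", "))
  out <- character(length(aa_alignment$taxa))
  for (i in seq_along(aa_alignment$taxa)) {
    tax <- aa_alignment$taxa[i]
    row <- strsplit(aa_alignment$sequences[i], "")[[1]]
    nt <- toupper(gsub("\\s", "", cds[[tax]]))
    aa_nogap <- row[row != "-"]
    tr <- translate_codons(nt)
    if (length(tr) == length(aa_nogap) + 1 && tr[length(tr)] == "*")
      tr <- tr[-length(tr)]  # trailing stop codon
    if (length(tr) != length(aa_nogap))
      stop("coding sequence of ", tax, " codes for ", length(tr),
           " residues but the alignment row has ", length(aa_nogap))
    stops <- which(tr == "*")
    if (length(stops))
      stop("internal stop codon in ", tax, " at codon ", stops[1])
    mism <- which(tr != aa_nogap & tr != "X" & aa_nogap != "X")
    if (length(mism))
      stop("translation mismatch for ", tax, " at residue ", mism[1],
           " (", tr[mism[1]], " vs ", aa_nogap[mism[1]], ")")
    codons <- substring(nt, seq(1, 3 * length(tr), 3),
                        seq(3, 3 * length(tr), 3))
    res <- character(length(row))
    res[row == "-"] <- "---"
    res[row != "-"] <- codons
    out[i] <- paste(res, collapse = "")
  }
  alignment(aa_alignment$taxa, out, alphabet = "nucleotide",
            source_name = aa_alignment$source_name,
            codon_positions = rep(1:3, length.out = 3 * n_columns(aa_alignment)))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' All genes must share the identical taxon set (one-to-one orthologs; there
#' is no missing-data padding). Columns are appended in input order and the
#' gene boundaries recorded as charsets.
#'
#' @param gene_alignments list of [alignment()]s; names (or the alignments'
#'   `source_name`s) become gene names.
#' @return an object of class `"supermatrix"` with fields `alignment`,
#'   `charsets` (gene -> c(start, end), 1-based inclusive) and `provenance`.
#' @export
concatenate <- function(gene_alignments) {
  if (!length(gene_alignments)) stop("no gene alignments")
  nm <- names(gene_alignments)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(seq_along(gene_alignments), function(i) {
      s <- gene_alignments[[i]]$source_name
      if (nzchar(s)) s else sprintf("gene%03d", i)
    }, "")
  taxa <- gene_alignments[[1]]$taxa
  alphabet <- gene_alignments[[1]]$alphabet
  for (g in gene_alignments) {
    if (!setequal(g$taxa, taxa))
      stop("taxon sets differ across genes (one-to-one orthologs required)")
    if (g$alphabet != alphabet) stop("mixed alphabets")
  }
  lens <- vapply(gene_alignments, n_columns, 0)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  seqs <- vapply(taxa, function(tax) {
    paste(vapply(gene_alignments, function(g)
      g$sequences[match(tax, g$taxa)], ""), collapse = "")
  }, "")
  cps <- lapply(gene_alignments, `[[`, "codon_positions")
  cp <- if (!any(vapply(cps, is.null, TRUE))) unlist(cps)
  charsets <- lapply(seq_along(lens), function(i)
    c(unname(starts[i]), unname(ends[i])))
  names(charsets) <- nm
  structure(list(
    alignment = alignment(taxa, unname(seqs), alphabet = alphabet,
                          source_name = "supermatrix",
                          codon_positions = cp),
    charsets = charsets,
    provenance = nm), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa, %d genes, %d columns (%s)\n",
              length(x$alignment$taxa), length(x$charsets),
              n_columns(x$alignment), x$alignment$alphabet))
  invisible(x)
}

#' Build a partition scheme over a supermatrix
#'
#' `by_gene` gives one subset per charset; `by_codon` three subsets per gene
#' (codon positions 1, 2, 3), i.e. the pre-merge partition definitions.
#'
#' @param sm a [concatenate()] supermatrix.
#' @param scheme `"unpartitioned"`, `"by_gene"` or `"by_codon"` (the latter
#'   requires codon bookkeeping from [back_translate()] or the simulator).
#' @return an object of class `"partition_scheme"`: subsets with `name`,
#'   `columns`, a display `range`, `model` slot and `rate_multiplier`.
#' @export
build_partitions <- function(sm, scheme = c("unpartitioned", "by_gene",
                                            "by_codon")) {
  scheme <- match.arg(scheme)
  L <- n_columns(sm$alignment)
  subsets <- switch(scheme,
    unpartitioned = list(list(name = "all", columns = seq_len(L),
                              range = sprintf("1-%d", L))),
    by_gene = lapply(names(sm$charsets), function(g) {
      cs <- sm$charsets[[g]]
      list(name = g, columns = seq(cs[1], cs[2]),
           range = sprintf("%d-%d", cs[1], cs[2]))
    }),
    by_codon = {
      if (sm$alignment$alphabet != "nucleotide" ||
          is.null(sm$alignment$codon_positions))
        stop("by_codon requires a coding nucleotide supermatrix with codon positions")
      cp <- sm$alignment$codon_positions
      unlist(lapply(names(sm$charsets), function(g) {
        cs <- sm$charsets[[g]]
        cols <- seq(cs[1], cs[2])
        lapply(1:3, function(pos) {
          list(name = sprintf("%s_pos%d", g, pos),
               columns = cols[cp[cols] == pos],
               range = sprintf("%d-%d\\3", cs[1] + pos - 1, cs[2]))
        })
      }), recursive = FALSE)
    })
  for (i in seq_along(subsets)) {
    subsets[[i]]$model <- NULL
    subsets[[i]]$rate_multiplier <- 1
  }
  structure(list(scheme = scheme, subsets = subsets, n_columns = L),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("partition scheme '%s': %d subsets over %d columns\n",
              x$scheme, length(x$subsets), x$n_columns))
  invisible(x)
}

#' Joint log-likelihood of a partitioned supermatrix
#'
#' Subsets share the topology and branch lengths; each subset has its own
#' substitution model and a positive rate multiplier scaling the shared
#' branch lengths (proportional branch-length model).
#'
#' @param sm a supermatrix.
#' @param scheme a [build_partitions()] scheme.
#' @param tree shared `"phylo"` tree with branch lengths.
#' @param models one fitted [substitution_model()] per subset (recycled if a
#'   single model is given).
#' @return total log-likelihood (sum over subsets).
#' @export
partitioned_log_likelihood <- function(sm, scheme, tree, models) {
  if (inherits(models, "substitution_model"))
    models <- rep(list(models), length(scheme$subsets))
  if (length(models) != length(scheme$subsets))
    stop("need one model per subset")
  mult <- vapply(scheme$subsets, `[[`, 0, "rate_multiplier")
  if (any(mult <= 0)) stop("rate multipliers must be positive")
  total <- 0
  for (i in seq_along(scheme$subsets)) {
    sub <- subset_columns(sm$alignment, scheme$subsets[[i]]$columns)
    tr <- tree
    tr$edge.length <- tr$edge.length * mult[i]
    total <- total + log_likelihood(sub, tr, models[[i]])
  }
  total
}

#' Fit per-subset models and rate multipliers on a fixed topology
#'
#' Optimizes each subset's model parameters and rate multiplier on the
#' shared tree, then renormalizes so the alignment-length-weighted mean
#' multiplier is one (compensating in the shared branch lengths).
#'
#' @param sm a supermatrix.
#' @param scheme a [build_partitions()] scheme.
#' @param tree shared `"phylo"` tree with branch lengths.
#' @param base_model model skeleton used for every subset.
#' @param free parameter blocks optimized per subset.
#' @return list with the updated `scheme` (models, multipliers), rescaled
#'   `tree`, and total `log_likelihood`.
#' @export
fit_partition_models <- function(sm, scheme, tree, base_model,
                                 free = c("alpha", "p_inv")) {
  mods <- vector("list", length(scheme$subsets))
  mult <- numeric(length(scheme$subsets))
  lens <- vapply(scheme$subsets, function(s) length(s$columns), 0)
  for (i in seq_along(scheme$subsets)) {
    sub <- subset_columns(sm$alignment, scheme$subsets[[i]]$columns)
    fit <- optimize_model(sub, tree, base_model, free = free)
    m <- fit$model
    # rate multiplier: 1-D scaling of the shared branch lengths
    o <- stats::optimize(function(lc) {
      tr <- tree
      tr$edge.length <- tr$edge.length * exp(lc)
      log_likelihood(sub, tr, m)
    }, c(log(0.05), log(20)), maximum = TRUE, tol = 1e-3)
    mods[[i]] <- m
    mult[i] <- exp(o$maximum)
  }
  wmean <- sum(lens * mult) / sum(lens)
  mult <- mult / wmean
  tree$edge.length <- tree$edge.length * wmean
  for (i in seq_along(scheme$subsets)) {
    scheme$subsets[[i]]$model <- mods[[i]]
    scheme$subsets[[i]]$rate_multiplier <- mult[i]
  }
  ll <- partitioned_log_likelihood(sm, scheme, tree, mods)
  list(scheme = scheme, tree = tree, log_likelihood = ll)
}

#' Write a partition scheme as NEXUS SETS block or RAxML partition file
#'
#' @param scheme a [build_partitions()] scheme.
#' @param path output file.
#' @param dialect `"nexus"` (charset lines) or `"raxml"`.
#' @param datatype RAxML data-type tag (e.g. `"DNA"`, `"WAG"`/`"JTT"`).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(scheme, path, dialect = c("nexus", "raxml"),
                             datatype = "DNA") {
  dialect <- match.arg(dialect)
  lines <- if (dialect == "nexus") {
    c("#NEXUS", "BEGIN SETS;",
      vapply(scheme$subsets, function(s)
        sprintf("  charset %s = %s;", s$name, s$range), ""),
      "END;")
  } else {
    vapply(scheme$subsets, function(s)
      sprintf("%s, %s = %s", datatype, s$name, s$range), "")
  }
  writeLines(lines, path)
  invisible(path)
}
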