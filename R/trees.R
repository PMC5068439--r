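#' Read trees from Newick or NEXUS files
#'
#' Trees are represented as \pkg{ape} `"phylo"` objects. Numeric internal
#' node labels are interpreted as support values and kept in `node.label`.
#' Polytomies are accepted on read; each tree carries a logical `"binary"`
#' attribute. Unrooted trees keep their basal multifurcation.
#'
#' @param path file path, or a Newick string when `text = TRUE`.
#' @param format `"auto"`, `"newick"` or `"nexus"`.
#' @param text read `path` itself as Newick text.
#' @return a list of `"phylo"` trees (input order preserved).
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       text = FALSE) {
  format <- match.arg(format)
  if (text) {
    trees <- ape::read.tree(text = path)
  } else {
    if (format == "auto") {
      first <- readLines(path, n = 1)
      format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
                else "newick"
    }
    trees <- if (format == "nexus") ape::read.nexus(path)
             else ape::read.tree(path)
  }
  if (is.null(trees)) stop("could not parse any tree from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(unclass(trees), function(tr) {
    class(tr) <- "phylo"
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      stop("negative branch length in input tree")
    attr(tr, "binary") <- ape::is.binary(tr)
    tr
  })
  names(trees) <- NULL
  trees
}

#' Write a tree as Newick text
#'
#' Round-trips topology, branch lengths (6 decimals) and support values.
#'
#' @param tree a `"phylo"` object, optionally with numeric `node.label`
#'   support values.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @param support_as `"percent"` writes supports as integer percentages
#'   (values on a 0-1 scale are rescaled), `"probability"` writes them on the
#'   0-1 scale (values on a percent scale are divided by 100).
#' @return the Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL,
                       support_as = c("percent", "probability")) {
  support_as <- match.arg(support_as)
  lab <- tree$node.label
  if (!is.null(lab)) {
    num <- suppressWarnings(as.numeric(lab))
    if (!all(is.na(num[nzchar(lab)]))) {
      mx <- max(num, na.rm = TRUE)
      if (support_as == "percent") {
        if (mx <= 1) num <- num * 100
        lab <- ifelse(is.na(num), "", as.character(round(num)))
      } else {
        if (mx > 1) num <- num / 100
        lab <- ifelse(is.na(num), "", format(num, digits = 6, trim = TRUE))
      }
      tree$node.label <- lab
    }
  }
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---------------------------------------------------------------------------
# bipartitions

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the taxa in two; splits are canonicalized as the
#' side that does not contain the reference taxon (by default the
#' alphabetically first leaf) so they can be compared across trees and leaf
#' orders.
#'
#' @param tree a `"phylo"` object.
#' @param ref reference taxon label for orientation.
#' @return character vector of split keys (sorted labels joined by `"|"`).
#' @export
tree_splits <- function(tree, ref = NULL) {
  labs <- tree$tip.label
  if (is.null(ref)) ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1 || length(side) >= length(labs) - 1) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

split_key <- function(taxa_in, all_taxa, ref = NULL) {
  if (is.null(ref)) ref <- sort(all_taxa)[1]
  side <- taxa_in
  if (ref %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = "|")
}

#' Test whether a set of taxa forms a clade (unrooted bipartition test)
#' @param tree a `"phylo"` object.
#' @param taxa taxon labels; must be a non-trivial subset of the leaves.
#' @return logical.
#' @export
has_clade <- function(tree, taxa) {
  labs <- tree$tip.label
  taxa <- intersect(taxa, labs)
  if (length(taxa) <= 1) return(length(taxa) == 1)
  if (length(taxa) >= length(labs)) return(TRUE)
  key <- split_key(taxa, labs)
  key %in% tree_splits(tree)
}

# Build a tree from mutually compatible splits (all oriented away from the
# same reference taxon, deduplicated); `freqs` become internal node labels.
splits_to_tree <- function(split_sets, freqs, all_taxa, digits = 4) {
  stopifnot(length(split_sets) == length(freqs))
  build <- function(taxa, idx) {
    maximal <- idx[!vapply(idx, function(i) any(vapply(idx, function(j)
      j != i && length(split_sets[[j]]) > length(split_sets[[i]]) &&
        all(split_sets[[i]] %in% split_sets[[j]]), TRUE)), TRUE)]
    covered <- unlist(split_sets[maximal])
    parts <- vapply(maximal, function(i) {
      s <- split_sets[[i]]
      inner <- setdiff(idx, i)
      inner <- inner[vapply(inner, function(j)
        all(split_sets[[j]] %in% s), TRUE)]
      paste0(build(s, inner),
             format(round(freqs[i], digits), trim = TRUE))
    }, character(1))
    singles <- setdiff(taxa, covered)
    paste0("(", paste(c(parts, singles), collapse = ","), ")")
  }
  txt <- build(all_taxa, seq_along(split_sets))
  ape::read.tree(text = paste0(txt, ";"))
}

compatible_splits <- function(a, b) {
  # both oriented away from the same reference taxon
  ia <- intersect(a, b)
  length(ia) == 0 || setequal(ia, a) || setequal(ia, b)
}
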