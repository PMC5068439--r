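# Plain-text serialization of fitted substitution models, and the
# bar-chart rendering hook for composition profiles.

#' Serialize a substitution model to a structured text block
#'
#' States are written in the fixed order A,C,G,T for nucleotides and
#' alphabetically for amino acids; exchangeabilities are the upper triangle
#' in row-major order. The block round-trips through [read_model()].
#'
#' @param model a [substitution_model()] (frequencies must be set).
#' @param path optional file; when `NULL` the lines are returned.
#' @return character vector of lines, invisibly when written to a file.
#' @export
write_model <- function(model, path = NULL) {
  if (is.null(model$freqs)) stop("model frequencies unset")
  ut <- model$rates[lower.tri(model$rates)]  # upper triangle, row-major
  lines <- c(
    "model_block 1",
    paste("alphabet", model$alphabet),
    paste("type", model$type),
    paste("states", paste(model$states, collapse = " ")),
    paste("frequencies", paste(format(model$freqs, digits = 10,
                                      trim = TRUE), collapse = " ")),
    paste("exchangeabilities", paste(format(ut, digits = 10,
                                            trim = TRUE),
                                     collapse = " ")),
    paste("gamma_shape", if (is.null(model$gamma_shape)) "none"
          else format(model$gamma_shape, digits = 10)),
    paste("n_categories", model$n_categories),
    paste("p_inv", format(model$p_inv, digits = 10)),
    paste("plus_F", model$plus_F))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a substitution model from its text-block serialization
#' @param path file written by [write_model()] (or its lines, with
#'   `text = TRUE`).
#' @param text treat `path` as the lines themselves.
#' @return a [substitution_model()].
#' @export
read_model <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) stop("missing field '", key, "' in model block")
    tok <- strsplit(trimws(sub(paste0("^", key, " "), "", ln)),
                    "\\s+")[[1]]
    tok[nzchar(tok)]
  }
  alphabet <- field("alphabet")
  type <- field("type")
  freqs <- as.numeric(field("frequencies"))
  ut <- as.numeric(field("exchangeabilities"))
  gs <- field("gamma_shape")
  ns <- length(states_of(alphabet))
  m <- substitution_model(alphabet, type, freqs = freqs,
                          gamma_shape = if (gs == "none") NULL
                          else as.numeric(gs),
                          n_categories = as.integer(field("n_categories")),
                          p_inv = as.numeric(field("p_inv")),
                          plus_F = as.logical(field("plus_F")))
  R <- matrix(0, ns, ns, dimnames = list(m$states, m$states))
  R[lower.tri(R)] <- ut
  R <- R + t(R)
  m$rates <- R
  m
}

#' Bar chart of a composition profile
#'
#' Renders per-taxon A+T content (nucleotides) or FYMINK/GARP fractions
#' (amino acids) with base graphics.
#'
#' @param x a [composition_profile()].
#' @param ... passed to [graphics::barplot()].
#' @return the profile, invisibly.
#' @export
plot.composition_profile <- function(x, ...) {
  pt <- x$per_taxon
  if (x$alphabet == "nucleotide") {
    graphics::barplot(stats::setNames(pt$AT_content, pt$taxon),
                      las = 2, ylab = "A+T content", ...)
  } else {
    h <- rbind(FYMINK = pt$FYMINK, GARP = pt$GARP)
    colnames(h) <- pt$taxon
    graphics::barplot(h, beside = TRUE, las = 2,
                      ylab = "residue-class fraction",
                      legend.text = TRUE, ...)
  }
  invisible(x)
}
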