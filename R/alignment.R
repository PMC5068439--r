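#' Multiple sequence alignments
#'
#' An alignment is an ordered set of equal-length sequences over a nucleotide
#' or amino-acid alphabet. Gaps (`-`) and ambiguity codes are carried through
#' I/O verbatim; how they are treated is decided by each consuming operation.
#'
#' @param taxa character vector of unique taxon labels.
#' @param sequences character vector of equal-length sequences (one string per
#'   taxon, same order as `taxa`).
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `NULL` to auto-detect
#'   (at least half of the residues in `ACGTNU-` implies nucleotide).
#' @param source_name free-text provenance label (e.g. a gene name).
#' @param codon_positions optional integer vector (values 1/2/3) recording the
#'   codon position of every column of a coding nucleotide alignment.
#' @return An object of class `"seq_alignment"` with fields `taxa`,
#'   `sequences`, `alphabet`, `source_name`.
#' @export
alignment <- function(taxa, sequences, alphabet = NULL, source_name = "",
                      codon_positions = NULL) {
  taxa <- as.character(taxa)
  sequences <- toupper(as.character(sequences))
  if (length(taxa) != length(sequences))
    stop("taxa and sequences must have the same length")
  if (length(taxa) == 0) stop("empty alignment")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  n <- nchar(sequences)
  if (length(unique(n)) != 1)
    stop("sequence length mismatch: lengths ",
         paste(unique(n), collapse = ", "))
  if (is.null(alphabet)) alphabet <- detect_alphabet(sequences)
  alphabet <- match.arg(alphabet, c("nucleotide", "amino_acid"))
  ok <- names(ambiguity_of(alphabet))
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop("characters not in the ", alphabet, " alphabet: ",
         paste(bad, collapse = " "))
  if (!is.null(codon_positions) && length(codon_positions) != n[1])
    stop("codon_positions must have one entry per column")
  structure(list(taxa = taxa, sequences = sequences, alphabet = alphabet,
                 source_name = source_name,
                 codon_positions = codon_positions),
            class = "seq_alignment")
}

detect_alphabet <- function(sequences) {
  chars <- strsplit(paste(sequences, collapse = ""), "")[[1]]
  frac <- mean(chars %in% c("A", "C", "G", "T", "N", "U", "-"))
  if (frac >= 0.5) "nucleotide" else "amino_acid"
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: %d taxa, %d columns%s\n", x$alphabet,
              length(x$taxa), n_columns(x),
              if (nzchar(x$source_name)) paste0(" [", x$source_name, "]")
              else ""))
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln a `seq_alignment`.
#' @return integer column count.
#' @export
n_columns <- function(aln) nchar(aln$sequences[1])

#' Character matrix view of an alignment (taxa x columns)
#' @param aln a `seq_alignment`.
#' @return character matrix with taxa as rownames.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- aln$taxa
  m
}

matrix_alignment <- function(m, alphabet, source_name = "",
                             codon_positions = NULL) {
  alignment(rownames(m), apply(m, 1, paste, collapse = ""),
            alphabet = alphabet, source_name = source_name,
            codon_positions = codon_positions)
}

#' Extract a set of columns from an alignment
#' @param aln a `seq_alignment`.
#' @param cols integer vector of 1-based column indices.
#' @return a `seq_alignment` over the selected columns (in the given order).
#' @export
subset_columns <- function(aln, cols) {
  m <- alignment_matrix(aln)[, cols, drop = FALSE]
  cp <- if (!is.null(aln$codon_positions)) aln$codon_positions[cols]
  matrix_alignment(m, aln$alphabet, aln$source_name, cp)
}

# ---------------------------------------------------------------------------
# readers / writers

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fas", "fasta", "faa", "fna")) return("fasta")
  if (ext %in% c("phy", "phylip")) return("phylip")
  if (ext %in% c("nex", "nexus", "nxs")) return("nexus")
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) "fasta"
  else if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
  else "phylip"
}

#' Read an alignment from FASTA, PHYLIP or NEXUS
#'
#' PHYLIP files are read in the relaxed dialect (labels delimited by
#' whitespace, no 10-character truncation); interleaved continuation blocks
#' cycle through the taxa in header order. NEXUS `DATA`/`CHARACTERS` blocks
#' are accepted in sequential or interleaved form.
#'
#' @param path file path.
#' @param format `"auto"` (by extension, then content sniffing), `"fasta"`,
#'   `"phylip"` or `"nexus"`.
#' @param alphabet optional override of alphabet auto-detection.
#' @return a [alignment()] object; taxa keep their order of first appearance.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip",
                                            "nexus"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  rec <- switch(format,
                fasta = read_fasta_records(path),
                phylip = read_phylip_records(path),
                nexus = read_nexus_records(path))
  alignment(rec$taxa, rec$sequences, alphabet = alphabet,
            source_name = basename(path))
}

read_fasta_records <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- sub("\\s.*$", "", taxa)
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1 > ends[i]) return("")
    gsub("\\s", "", paste(lines[(hdr[i] + 1):ends[i]], collapse = ""))
  }, character(1))
  list(taxa = taxa, sequences = seqs)
}

read_phylip_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header in ", path)
  ntax <- as.integer(hdr[1])
  nchar_exp <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) < ntax) stop("fewer sequence rows than the PHYLIP header")
  taxa <- character(ntax)
  seqs <- character(ntax)
  for (i in seq_len(ntax)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    taxa[i] <- tok[1]
    seqs[i] <- paste(tok[-1], collapse = "")
  }
  extra <- body[-seq_len(ntax)]
  for (j in seq_along(extra)) {
    i <- ((j - 1) %% ntax) + 1
    seqs[i] <- paste0(seqs[i], gsub("\\s", "", extra[j]))
  }
  if (any(nchar(seqs) != nchar_exp))
    stop("PHYLIP sequence length does not match header (expected ",
         nchar_exp, ")")
  list(taxa = taxa, sequences = seqs)
}

read_nexus_records <- function(path) {
  lines <- readLines(path)
  txt <- paste(lines, collapse = "\n")
  m <- regexpr("(?is)matrix\\s*\\n(.*?);", txt, perl = TRUE)
  if (m == -1) stop("no MATRIX statement in NEXUS file ", path)
  block <- regmatches(txt, m)
  block <- sub("(?is)^matrix\\s*\\n", "", block, perl = TRUE)
  block <- sub(";\\s*$", "", block)
  rows <- strsplit(block, "\n")[[1]]
  rows <- rows[nzchar(trimws(rows))]
  rows <- rows[!grepl("^\\s*\\[", rows)]   # comments
  taxa <- character(0)
  seqs <- list()
  for (r in rows) {
    r <- trimws(r)
    name <- sub("^('[^']*'|\\S+).*$", "\\1", r)
    seq <- gsub("\\s", "", substring(r, nchar(name) + 1))
    name <- gsub("^'|'$", "", name)
    if (!name %in% taxa) {
      taxa <- c(taxa, name)
      seqs[[name]] <- seq
    } else {
      seqs[[name]] <- paste0(seqs[[name]], seq)
    }
  }
  list(taxa = taxa, sequences = unlist(seqs[taxa], use.names = FALSE))
}

#' Write an alignment to FASTA, PHYLIP or NEXUS
#'
#' @param aln a [alignment()] object.
#' @param path output file path.
#' @param format output format; PHYLIP uses the relaxed dialect, NEXUS writes
#'   a sequential `DATA` block (or interleaved when `interleave` is set).
#' @param interleave optional line width for interleaved NEXUS output.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus"),
                            interleave = NULL) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_along(aln$taxa)) {
      writeLines(paste0(">", aln$taxa[i]), con)
      s <- aln$sequences[i]
      starts <- seq(1, nchar(s), by = 60)
      writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
    }
  } else if (format == "phylip") {
    writeLines(sprintf("%d %d", length(aln$taxa), n_columns(aln)), con)
    writeLines(paste(aln$taxa, aln$sequences), con)
  } else {
    dt <- if (aln$alphabet == "nucleotide") "DNA" else "PROTEIN"
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                         length(aln$taxa), n_columns(aln)),
                 sprintf("  FORMAT DATATYPE=%s GAP=- MISSING=?%s;", dt,
                         if (is.null(interleave)) "" else " INTERLEAVE=YES"),
                 "  MATRIX"), con)
    if (is.null(interleave)) {
      writeLines(paste("   ", aln$taxa, aln$sequences), con)
    } else {
      n <- n_columns(aln)
      for (s0 in seq(1, n, by = interleave)) {
        chunk <- substring(aln$sequences, s0, min(s0 + interleave - 1, n))
        writeLines(paste("   ", aln$taxa, chunk), con)
        writeLines("", con)
      }
    }
    writeLines(c("  ;", "END;"), con)
  }
  invisible(path)
}

#' Observed state frequencies of an alignment
#'
#' Counts only unambiguous residues (gaps and ambiguity codes are excluded
#' from the denominator).
#' @param aln a `seq_alignment`.
#' @return named numeric vector over the alphabet's states, summing to one.
#' @export
observed_frequencies <- function(aln) {
  states <- states_of(aln$alphabet)
  chars <- strsplit(paste(aln$sequences, collapse = ""), "")[[1]]
  cnt <- table(factor(chars, levels = states))
  f <- as.numeric(cnt)
  if (sum(f) == 0) stop("alignment has no unambiguous residues")
  names(f) <- states
  f / sum(f)
}
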