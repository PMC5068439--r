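# Alphabets, ambiguity codes, the standard genetic code, and the published
# JTT amino-acid replacement model.

NT_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# IUPAC nucleotide ambiguity codes -> compatible states
NT_AMBIGUITY <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
  "?" = c("A", "C", "G", "T"), "." = c("A", "C", "G", "T")
)

AA_AMBIGUITY <- local({
  amb <- as.list(AA_STATES)
  names(amb) <- AA_STATES
  amb$B <- c("D", "N")        # Asx
  amb$Z <- c("E", "Q")        # Glx
  amb$J <- c("I", "L")
  amb$X <- AA_STATES
  amb$U <- AA_STATES          # selenocysteine etc. treated as unknown
  amb$O <- AA_STATES
  amb[["-"]] <- AA_STATES
  amb[["?"]] <- AA_STATES
  amb[["."]] <- AA_STATES
  amb
})

# standard genetic code, codon -> one-letter amino acid ("*" = stop)
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# amino-acid classes encoded by A+T-rich and G+C-rich codons
FYMINK_SET <- c("F", "Y", "M", "I", "N", "K")
GARP_SET <- c("G", "A", "R", "P")

# Published JTT replacement model (Jones, Taylor & Thornton 1992),
# exchangeability counts (lower triangle, column-major) and equilibrium
# frequencies, in the conventional A R N D C Q E G H I L K M F P S T W Y V
# order; reordered to the package's alphabetical state order below.
.jtt_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.jtt_lower <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194,
  378, 475, 9, 11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38,
  646, 44, 5, 74, 101, 64, 126, 20, 17, 528, 34, 86, 58, 81, 391,
  47, 12, 263, 30, 10, 15, 503, 232, 8, 70, 16, 10, 49, 767, 130,
  112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5, 59, 69, 17,
  23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55,
  8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25,
  52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226,
  24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16
)

.jtt_freqs_raw <- c(
  0.076747923252076758, 0.051690948309051694, 0.042644957355042652,
  0.051543948456051550, 0.019802980197019805, 0.040751959248040752,
  0.061829938170061841, 0.073151926848073159, 0.022943977056022944,
  0.053760946239053767, 0.091903908096091905, 0.058675941324058678,
  0.023825976174023829, 0.040125959874040135, 0.050900949099050907,
  0.068764931235068771, 0.058564941435058568, 0.014260985739014262,
  0.032101967898032102, 0.066004933995066004
)

JTT_RATES <- local({
  m <- matrix(0, 20, 20, dimnames = list(.jtt_order, .jtt_order))
  m[lower.tri(m)] <- .jtt_lower
  m <- m + t(m)
  m[AA_STATES, AA_STATES]
})

JTT_FREQS <- local({
  f <- .jtt_freqs_raw
  names(f) <- .jtt_order
  f <- f / sum(f)
  f[AA_STATES]
})

states_of <- function(alphabet) {
  switch(alphabet, nucleotide = NT_STATES, amino_acid = AA_STATES,
         stop("unknown alphabet: ", alphabet))
}

ambiguity_of <- function(alphabet) {
  switch(alphabet, nucleotide = NT_AMBIGUITY, amino_acid = AA_AMBIGUITY,
         stop("unknown alphabet: ", alphabet))
}
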