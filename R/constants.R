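# Canonical gene inventory, the invertebrate mitochondrial genetic code, and
# small sequence helpers shared across the package.

#' Canonical mitochondrial gene names
#'
#' The 37 canonical metazoan mitochondrial genes (13 protein-coding genes,
#' 2 rRNAs, 22 tRNAs) plus the A+T-rich control region, in the naming
#' convention used throughout the package: `cox1..3`, `cob`, `nad1..6`,
#' `nad4l`, `atp6`, `atp8`, `rrnS`, `rrnL`, `trnX` (with `trnL1`/`trnL2`
#' and `trnS1`/`trnS2` for the duplicated leucine/serine tRNAs), and
#' `AT_rich`.
#'
#' @return Character vector of the 38 canonical feature names.
#' @export
canonical_gene_names <- function() {
  c(MITO_PCGS, MITO_RRNAS, MITO_TRNAS, "AT_rich")
}

MITO_PCGS <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")

MITO_RRNAS <- c("rrnS", "rrnL")

MITO_TRNAS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                "trnY")

# Standard insect mitochondrial tRNA anticodons (5'->3', RNA alphabet).
# trnL1 decodes CUN (anticodon UAG), trnL2 decodes UUR (UAA);
# trnS1 decodes AGN (UCU), trnS2 decodes UCN (UGA).
MITO_ANTICODONS <- c(
  trnA = "UGC", trnC = "GCA", trnD = "GUC", trnE = "UUC", trnF = "GAA",
  trnG = "UCC", trnH = "GUG", trnI = "GAU", trnK = "CUU", trnL1 = "UAG",
  trnL2 = "UAA", trnM = "CAU", trnN = "GUU", trnP = "UGG", trnQ = "UUG",
  trnR = "UCG", trnS1 = "UCU", trnS2 = "UGA", trnT = "UGU", trnV = "UAC",
  trnW = "UCA", trnY = "GUA")

# Single-letter amino acid carried by each tRNA (for product labels).
TRNA_AA <- c(
  trnA = "Ala", trnC = "Cys", trnD = "Asp", trnE = "Glu", trnF = "Phe",
  trnG = "Gly", trnH = "His", trnI = "Ile", trnK = "Lys", trnL1 = "Leu",
  trnL2 = "Leu", trnM = "Met", trnN = "Asn", trnP = "Pro", trnQ = "Gln",
  trnR = "Arg", trnS1 = "Ser", trnS2 = "Ser", trnT = "Thr", trnV = "Val",
  trnW = "Trp", trnY = "Tyr")

#' Feature class of a canonical gene name
#'
#' @param name Character vector of canonical names.
#' @return Character vector with values `"PCG"`, `"rRNA"`, `"tRNA"`,
#'   `"control"`, or `NA` for unrecognized names.
#' @export
gene_class <- function(name) {
  dplyr::case_when(
    name %in% MITO_PCGS ~ "PCG",
    name %in% MITO_RRNAS ~ "rRNA",
    name %in% MITO_TRNAS ~ "tRNA",
    name == "AT_rich" ~ "control",
    TRUE ~ NA_character_
  )
}

#' The invertebrate mitochondrial genetic code
#'
#' Translation table 5 (ATA = Met, AGA/AGG = Ser, TGA = Trp; stops TAA and
#' TAG), as a named character vector mapping codons (DNA alphabet) to
#' one-letter amino acids, `"*"` for stops.
#'
#' @return Named character vector of length 64.
#' @export
mito_genetic_code <- function() {
  code <- .mitocomp_cache$genetic_code
  if (is.null(code)) {
    code <- Biostrings::getGeneticCode("5")
    code <- stats::setNames(as.character(code), names(code))
    .mitocomp_cache$genetic_code <- code
  }
  code
}

.mitocomp_cache <- new.env(parent = emptyenv())

sense_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code != "*"]
}

stop_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code == "*"]
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Split a DNA string into single characters.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Codons of a DNA string read in frame 0; trailing partial codon dropped.
codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Round half away from zero (report-table convention; base round() is
# round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
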