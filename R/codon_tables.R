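# Standard genetic code and a human codon-usage frequency table.
# Usage values are occurrences per thousand codons in human coding sequence
# (standard compilation); they act as stepping-rate weights for the
# codon-dependent elongation model and as sampling weights for synthetic genes.

GENETIC_CODE_DNA <- c(
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

STOP_CODONS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == "*"]
SENSE_CODONS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"]

HUMAN_CODON_USAGE_PER1000 <- c(
  TTT = 17.6, TTC = 20.3, TTA =  7.7, TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA =  7.2, CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA =  7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA =  7.1, GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG =  4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG =  6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG =  6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG =  7.4,
  TAT = 12.2, TAC = 15.3,
  CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
  AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
  TGT = 10.6, TGC = 12.6, TGG = 13.2,
  CGT =  4.5, CGC = 10.4, CGA =  6.2, CGG = 11.4,
  AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
  GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5
)

#' Human codon-usage weights
#'
#' Relative usage frequencies of the 61 sense codons in human coding
#' sequence, normalized to sum to one. These drive both synthetic-gene
#' sampling and the codon-dependent elongation-rate assignment.
#'
#' @param uniform If `TRUE`, return equal weight for every sense codon
#'   instead of the human table.
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
#' @examples
#' w <- human_codon_usage()
#' sum(w)  # 1
human_codon_usage <- function(uniform = FALSE) {
  if (uniform) {
    w <- rep(1 / length(SENSE_CODONS), length(SENSE_CODONS))
    names(w) <- SENSE_CODONS
    return(w)
  }
  HUMAN_CODON_USAGE_PER1000 / sum(HUMAN_CODON_USAGE_PER1000)
}

#' Translate DNA codons to amino acids
#' @param codons Character vector of 3-letter DNA codons.
#' @return Character vector of one-letter amino acids (`*` for stop).
#' @keywords internal
translate_codons <- function(codons) {
  aa <- GENETIC_CODE_DNA[codons]
  if (anyNA(aa)) stopf("unrecognized codon(s): %s",
                       paste(unique(codons[is.na(aa)]), collapse = ", "))
  unname(aa)
}

# Most frequent human codon per amino acid, used to reverse-translate tag
# amino-acid sequences into a representative nucleotide sequence.
preferred_codon <- function(aa) {
  tab <- HUMAN_CODON_USAGE_PER1000
  vapply(aa, function(a) {
    cands <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == a]
    cands <- intersect(cands, names(tab))
    if (length(cands) == 0L) stopf("no codon for amino acid '%s'", a)
    cands[which.max(tab[cands])]
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(nt) {
  nt <- toupper(gsub("U", "T", nt))
  if (nchar(nt) %% 3 != 0) stopf("sequence length %d is not divisible by 3",
                                 nchar(nt))
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}
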