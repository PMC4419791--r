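# Standard genetic code tables shared across modules. Stop codons are
# TAA/TAG/TGA; sense codons are kept in a fixed order so that count vectors,
# rate matrices and CA input columns always line up.

GENETIC_CODE_MAP <- Biostrings::GENETIC_CODE

STOP_CODONS <- names(GENETIC_CODE_MAP)[GENETIC_CODE_MAP == "*"]
SENSE_CODONS <- names(GENETIC_CODE_MAP)[GENETIC_CODE_MAP != "*"]
AA_OF_CODON <- GENETIC_CODE_MAP[SENSE_CODONS]

# synonym families keyed by amino acid (one-letter)
SYN_FAMILIES <- split(SENSE_CODONS, AA_OF_CODON)
FAMILY_SIZE <- lengths(SYN_FAMILIES)

# amino acids with >= 2 synonymous codons; their 59 codons are the columns of
# the codon-usage correspondence analysis and the basis of GC3s
DEGENERATE_AAS <- names(SYN_FAMILIES)[FAMILY_SIZE > 1L]
DEGENERATE_CODONS <- unname(unlist(SYN_FAMILIES[DEGENERATE_AAS]))

N_SYN <- FAMILY_SIZE[AA_OF_CODON]         # per sense codon, its family size
names(N_SYN) <- SENSE_CODONS

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition_pair <- function(x, y) {
  (x %in% PURINES & y %in% PURINES) | (x %in% PYRIMIDINES & y %in% PYRIMIDINES)
}

# 61 x 3 matrix of codon bases, and pairwise structure masks used by the
# GY94 rate matrix and the NG86 pathway counts
CODON_BASES <- do.call(rbind, strsplit(SENSE_CODONS, ""))
rownames(CODON_BASES) <- SENSE_CODONS

.gy94_struct <- local({
  n <- length(SENSE_CODONS)
  ndiff <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    same <- outer(CODON_BASES[, p], CODON_BASES[, p], "==")
    ndiff <- ndiff + !same
    ts <- ts | (!same & outer(CODON_BASES[, p] %in% PURINES,
                              CODON_BASES[, p] %in% PURINES, "==") )
  }
  single <- ndiff == 1L
  syn <- outer(AA_OF_CODON, AA_OF_CODON, "==")
  # ts is only meaningful where exactly one position differs
  list(single = single, ts = ts & single, syn = syn)
})

split_codons <- function(cds) {
  nc <- nchar(cds)
  if (nc == 0L || nc %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3; run validate_and_trim_cds() first")
  }
  substring(cds, seq(1L, nc, 3L), seq(3L, nc, 3L))
}

codons_to_cds <- function(codons) paste(codons, collapse = "")

#' Translate an in-frame coding sequence
#'
#' Translates a CDS under the standard genetic code. A single terminal stop
#' codon is dropped; internal stops or ambiguous codons translate to `*` /
#' `X` respectively.
#'
#' @param cds Character scalar, in-frame nucleotide sequence (ACGTN).
#' @return Character scalar amino-acid sequence.
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) > 1L && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  aa <- GENETIC_CODE_MAP[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
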