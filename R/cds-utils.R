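# CDS cleanup mirroring the usual ORF hygiene applied to gene-catalog
# transcripts before codon-level analysis: restore frame, drop the trailing
# partial codon, strip the terminal stop, and collapse redundant ORFs per
# gene id to the longest one.

#' Validate and trim a raw coding sequence
#'
#' Picks the reading frame (offset 0, 1 or 2) that yields the longest run of
#' codons free of internal stop codons, drops any trailing partial codon,
#' and strips a single terminal stop codon. Sequences for which no frame is
#' free of internal stops are rejected.
#'
#' @param raw Character scalar, nucleotide sequence over ACGTN
#'   (case-insensitive).
#' @return A list with elements `cds` (the trimmed in-frame sequence, or
#'   `NA_character_` if rejected), `ok` (logical), `frame` (leading bases
#'   trimmed, or `NA`), and `actions` (character vector describing every
#'   modification made).
#' @examples
#' validate_and_trim_cds("ATGAAATAG")$cds  # "ATGAAA"
#' @export
validate_and_trim_cds <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single character string")
  }
  seq <- toupper(raw)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside the ACGTN alphabet")
  }
  actions <- character(0)
  best <- NULL
  for (frame in 0:2) {
    body <- substr(seq, frame + 1L, nchar(seq))
    n_codon <- nchar(body) %/% 3L
    if (n_codon == 0L) next
    body <- substr(body, 1L, n_codon * 3L)
    codons <- split_codons(body)
    n <- length(codons)
    internal_stop <- codons[-n] %in% STOP_CODONS
    if (any(internal_stop)) next
    if (is.null(best) || n > best$n) best <- list(frame = frame, codons = codons, n = n)
  }
  if (is.null(best)) {
    return(list(cds = NA_character_, ok = FALSE, frame = NA_integer_,
                actions = "rejected: no reading frame free of internal stop codons"))
  }
  if (best$frame > 0L) {
    actions <- c(actions, sprintf("trimmed %d leading base(s) to restore frame", best$frame))
  }
  dropped_tail <- (nchar(seq) - best$frame) %% 3L
  if (dropped_tail > 0L) {
    actions <- c(actions, sprintf("dropped %d trailing base(s) (partial codon)", dropped_tail))
  }
  codons <- best$codons
  if (codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
    actions <- c(actions, "stripped terminal stop codon")
  }
  if (length(codons) == 0L) {
    return(list(cds = NA_character_, ok = FALSE, frame = best$frame,
                actions = c(actions, "rejected: no codons left after trimming")))
  }
  list(cds = codons_to_cds(codons), ok = TRUE, frame = best$frame, actions = actions)
}

#' Keep the longest ORF per gene id
#'
#' When several candidate ORFs map to the same gene identifier, retains the
#' longest sequence for each id (ties broken by first occurrence).
#'
#' @param seqs Named character vector of sequences; names are gene ids.
#' @return Named character vector with one sequence per unique id.
#' @export
keep_longest_orf <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ord <- order(nchar(seqs), decreasing = TRUE)
  seqs <- seqs[ord]
  seqs[!duplicated(names(seqs))]
}

#' Read coding sequences from a FASTA file
#'
#' Record ids are taken up to the first whitespace; letters are upper-cased.
#'
#' @param path Path to a FASTA file of nucleotide sequences.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (nucleotide or protein).
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
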