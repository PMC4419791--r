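# Independent oracles used by the tests: a brute-force affine-gap global
# alignment DP, an enumeration-based synonymous site counter, and small
# graph constructors. These deliberately re-derive results from first
# principles rather than calling the package's own code paths.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap global alignment score; a gap of length L costs
# open + L * ext (both terminal and internal gaps are penalized).
gotoh_score <- function(a, b, open = 10, ext = 0.5, mat = blosum62) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Synonymous site count of a codon by direct enumeration of its nine
# single-nucleotide neighbours under the standard genetic code, with
# nonsense (stop-creating) mutations disregarded.
enum_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  total <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
    muts <- vapply(alts, function(b) { x <- codon; substr(x, p, p) <- b; x }, "")
    sense <- setdiff(muts, stops)
    if (length(sense) == 0) next
    total <- total + sum(code[sense] == code[codon]) / length(sense)
  }
  total
}

# Edge list of a planted-partition graph over `blocks` equal blocks.
planted_partition_edges <- function(n_per_block = 10L, blocks = 3L,
                                    p_in = 0.9, p_out = 0.02) {
  n <- n_per_block * blocks
  truth <- rep(seq_len(blocks), each = n_per_block)
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- if (truth[i] == truth[j]) p_in else p_out
      if (stats::runif(1) < p) {
        from <- c(from, paste0("g", i)); to <- c(to, paste0("g", j))
      }
    }
  }
  list(edges = data.frame(from = from, to = to, weight = 1),
       truth = stats::setNames(truth, paste0("g", seq_len(n))))
}

# Random protein sequence (uniform over the 20 amino acids).
random_protein <- function(len) {
  paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"), len, TRUE),
        collapse = "")
}

strip_stop <- function(cds) {
  nc <- nchar(cds)
  if (substr(cds, nc - 2, nc) %in% c("TAA", "TAG", "TGA")) substr(cds, 1, nc - 3) else cds
}
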