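# Goldman-Yang (GY94) codon substitution model: 61 x 61 rate matrix with
# transition/transversion parameter kappa, nonsynonymous parameter omega and
# codon equilibrium frequencies pi; transition probabilities by
# eigendecomposition in the pi^(1/2)-symmetrized basis (the model is
# time-reversible). The matrix is scaled so that one unit of t corresponds
# to one expected codon substitution per codon site at stationarity.

#' GY94 instantaneous rate matrix
#'
#' Off-diagonal rate q_ij = pi_j * kappa^\[transition\] * omega^\[nonsynonymous\]
#' for codon pairs differing at exactly one position, 0 otherwise (stop
#' codons are not part of the state space, so mutations into stops are
#' impossible by construction). Scaled so -sum_i pi_i q_ii = 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium codon frequencies over the 61 sense codons
#'   (recycled uniform if omitted); must be positive and sum to 1.
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = NULL) {
  stopifnot(kappa > 0, omega >= 0)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61, all(pi > 0))
  pi <- pi / sum(pi)
  st <- .gy94_struct
  Q <- matrix(rep(pi, each = 61), 61, 61)
  Q[!st$single] <- 0
  Q[st$ts] <- Q[st$ts] * kappa
  nonsyn <- st$single & !st$syn
  Q[nonsyn] <- Q[nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero total rate)")
  Q <- Q / scale
  dimnames(Q) <- list(SENSE_CODONS, SENSE_CODONS)
  attr(Q, "pi") <- pi
  Q
}

# Eigendecomposition of a reversible Q in the symmetric basis; reused for
# several t values at the same (kappa, omega, pi).
gy94_eigen <- function(Q) {
  pi <- attr(Q, "pi")
  d <- sqrt(pi)
  B <- (d * Q) %*% diag(1 / d)   # D^(1/2) Q D^(-1/2), symmetric
  B <- (B + t(B)) / 2            # clean numerical asymmetry
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, d = d)
}

# P(t) = D^(-1/2) U exp(lambda t) U' D^(1/2); rows renormalized to guard
# against tiny negative round-off.
gy94_probs <- function(eig, t) {
  E <- eig$U %*% (exp(eig$lambda * t) * t(eig$U))
  P <- (1 / eig$d) * E %*% diag(eig$d)
  P[P < 0] <- 0
  P / rowSums(P)
  }

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies estimated from one or more
#' in-frame CDS, multiplied across the three codon positions and
#' renormalized over the 61 sense codons (the codeml default frequency
#' model). Frequencies are floored at `floor` before normalization so the
#' reversible eigendecomposition stays defined.
#'
#' @param cds_set Character vector of in-frame CDS.
#' @param floor Minimum codon frequency before renormalization.
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(cds_set, floor = 1e-8) {
  codons <- unlist(lapply(cds_set, split_codons), use.names = FALSE)
  codons <- codons[codons %in% SENSE_CODONS]
  if (length(codons) == 0L) stop("no sense codons in input")
  bases <- do.call(rbind, strsplit(codons, ""))
  f <- vapply(1:3, function(p) {
    tab <- table(factor(bases[, p], levels = c("A", "C", "G", "T")))
    as.vector(tab) / sum(tab)
  }, numeric(4))
  rownames(f) <- c("A", "C", "G", "T")
  pi <- f[CODON_BASES[, 1], 1] * f[CODON_BASES[, 2], 2] * f[CODON_BASES[, 3], 3]
  pi <- pmax(pi, floor)
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  pi
}

# Proportion of the total substitution flux that is synonymous, for a given
# Q; used to partition t into dN and dS.
gy94_syn_flux <- function(Q) {
  pi <- attr(Q, "pi")
  syn_off <- .gy94_struct$syn & .gy94_struct$single
  sum((pi * Q)[syn_off]) / -sum(pi * diag(Q))
}

# dN and dS from fitted (t, kappa, omega): expected synonymous /
# nonsynonymous substitutions per codon divided by the per-codon numbers of
# synonymous / nonsynonymous sites, the latter defined as the flux
# proportions under the same kappa and pi with omega = 1 (mutational
# opportunity), times 3.
gy94_dn_ds <- function(t, kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  rho_s <- gy94_syn_flux(Q)
  Q1 <- gy94_rate_matrix(kappa, 1, pi)
  rho_s1 <- gy94_syn_flux(Q1)
  dS <- t * rho_s / (3 * rho_s1)
  dN <- t * (1 - rho_s) / (3 * (1 - rho_s1))
  c(dN = dN, dS = dS)
}
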