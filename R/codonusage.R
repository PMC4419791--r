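# Codon usage statistics: per-gene codon counts, RSCU, GC/GC3s,
# correspondence analysis of synonymous codon usage, identification of
# optimal codons from the extremes of a gene ranking, and the Fop / CAI /
# CBI adaptation indices computed against that optimal set.

#' Count codons in a coding sequence
#'
#' Stop codons and codons containing non-ACGT symbols are excluded from the
#' 61 sense-codon counts but tallied in the `excluded_stop` /
#' `excluded_ambiguous` attributes.
#'
#' @param cds Character scalar, in-frame CDS.
#' @return Named integer vector over the 61 sense codons, with attributes
#'   `excluded_stop` and `excluded_ambiguous`.
#' @examples
#' count_codons("ATGTTTTAA")[c("ATG", "TTT")]
#' @export
count_codons <- function(cds) {
  codons <- split_codons(toupper(cds))
  n_stop <- sum(codons %in% STOP_CODONS)
  ambiguous <- !(codons %in% c(SENSE_CODONS, STOP_CODONS))
  counts <- table(factor(codons[codons %in% SENSE_CODONS], levels = SENSE_CODONS))
  out <- as.integer(counts)
  names(out) <- SENSE_CODONS
  attr(out, "excluded_stop") <- n_stop
  attr(out, "excluded_ambiguous") <- sum(ambiguous)
  out
}

#' Build a gene x codon count table
#'
#' @param cds_set Named character vector of in-frame CDS.
#' @return Integer matrix, genes in rows, the 61 sense codons in columns.
#' @export
codon_count_table <- function(cds_set) {
  stopifnot(is.character(cds_set), length(cds_set) > 0L)
  m <- t(vapply(cds_set, function(s) as.vector(count_codons(s)),
                integer(length(SENSE_CODONS))))
  colnames(m) <- SENSE_CODONS
  if (!is.null(names(cds_set))) rownames(m) <- names(cds_set)
  m
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = observed(c) / (family total / family size). Codons of amino
#' acids absent from the gene are reported as `NA` (undefined rather than
#' zero). Met and Trp always have RSCU 1 when present.
#'
#' @param counts Named numeric vector of sense-codon counts (one gene or a
#'   pooled set), as from [count_codons()].
#' @return Named numeric vector of RSCU values over the 61 sense codons.
#' @export
rscu <- function(counts) {
  counts <- counts[SENSE_CODONS]
  fam_tot <- tapply(counts, AA_OF_CODON, sum)[AA_OF_CODON]
  expected <- fam_tot / N_SYN
  out <- ifelse(fam_tot > 0, counts / expected, NA_real_)
  names(out) <- SENSE_CODONS
  out
}

#' GC content and synonymous third-position GC
#'
#' `gc` is the G+C fraction over all coding positions (stop codons
#' excluded). `gc3s` is the G+C fraction at third positions of codons
#' belonging to degenerate synonym families only (ATG, TGG and stops carry
#' no synonymous third position and are excluded); it is `NA` when the gene
#' contains no degenerate codon.
#'
#' @param cds Character scalar, in-frame CDS.
#' @return Named numeric vector `c(gc = , gc3s = )`.
#' @export
gc_metrics <- function(cds) {
  codons <- split_codons(toupper(cds))
  codons <- codons[codons %in% SENSE_CODONS]
  if (length(codons) == 0L) return(c(gc = NA_real_, gc3s = NA_real_))
  bases <- unlist(strsplit(codons, ""), use.names = FALSE)
  gc <- mean(bases %in% c("G", "C"))
  deg <- codons[codons %in% DEGENERATE_CODONS]
  gc3s <- if (length(deg) == 0L) NA_real_ else mean(substr(deg, 3L, 3L) %in% c("G", "C"))
  c(gc = gc, gc3s = gc3s)
}

#' Correspondence analysis of synonymous codon usage
#'
#' Runs a standard correspondence analysis on the gene x codon count matrix
#' restricted to the 59 codons of degenerate synonym families (Met, Trp and
#' stops excluded): the chi-square standardized residual matrix is
#' decomposed by SVD and principal coordinates are returned for genes
#' (rows) and codons (columns). Genes shorter than `min_codons` countable
#' codons are dropped before the analysis. When `expression` is supplied,
#' the sign of axis 1 is fixed so that gene coordinates correlate
#' positively with expression.
#'
#' @param counts Gene x codon count matrix from [codon_count_table()].
#' @param n_axes Number of axes to retain.
#' @param min_codons Minimum countable codons for a gene to enter the CA.
#' @param expression Optional per-gene numeric vector (named or aligned
#'   with `counts` rows) used to orient axis 1.
#' @return A list of class `codon_ca` with `gene_coords`, `codon_coords`
#'   (principal coordinates), `inertia` (per-axis fractions),
#'   `total_inertia`, `dropped` (gene ids excluded as too short) and
#'   `axis1_flipped`.
#' @export
codon_ca <- function(counts, n_axes = 4L, min_codons = 100L, expression = NULL) {
  stopifnot(is.matrix(counts))
  x <- counts[, DEGENERATE_CODONS, drop = FALSE]
  keep <- rowSums(x) >= min_codons
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3L) stop("correspondence analysis needs at least 3 genes after length filtering")
  if (!is.null(expression)) {
    expression <- if (!is.null(names(expression))) expression[rownames(x)] else expression[keep]
  }
  used <- colSums(x) > 0
  x <- x[, used, drop = FALSE]

  n <- sum(x)
  P <- x / n
  r <- rowSums(P)
  cmass <- colSums(P)
  E <- outer(r, cmass)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  k <- min(n_axes, length(sv$d))
  eig <- sv$d^2
  total <- sum(eig)
  if (total < .Machine$double.eps) {
    gene_coords <- matrix(0, nrow(x), k, dimnames = list(rownames(x), paste0("axis", 1:k)))
    codon_coords <- matrix(0, ncol(x), k, dimnames = list(colnames(x), paste0("axis", 1:k)))
    inertia <- rep(0, k)
  } else {
    gene_coords <- sweep(sv$u[, 1:k, drop = FALSE], 1, sqrt(r), "/") %*% diag(sv$d[1:k], k)
    codon_coords <- sweep(sv$v[, 1:k, drop = FALSE], 1, sqrt(cmass), "/") %*% diag(sv$d[1:k], k)
    dimnames(gene_coords) <- list(rownames(x), paste0("axis", 1:k))
    dimnames(codon_coords) <- list(colnames(x), paste0("axis", 1:k))
    inertia <- eig[1:k] / total
  }
  flipped <- FALSE
  if (!is.null(expression) && total > 0) {
    rho <- suppressWarnings(stats::cor(gene_coords[, 1], expression,
                                       method = "spearman", use = "complete.obs"))
    if (!is.na(rho) && rho < 0) {
      gene_coords[, 1] <- -gene_coords[, 1]
      codon_coords[, 1] <- -codon_coords[, 1]
      flipped <- TRUE
    }
  }
  structure(list(gene_coords = gene_coords, codon_coords = codon_coords,
                 inertia = inertia, total_inertia = total,
                 dropped = dropped, axis1_flipped = flipped),
            class = "codon_ca")
}

#' Identify optimal codons from extreme gene groups
#'
#' Pools the codon counts of the genes with the highest and lowest
#' `gene_scores` (by default the top and bottom 10%) and, for every codon of
#' a degenerate synonym family, tests a 2x2 contingency table (this codon
#' vs. the rest of its family, high vs. low group) with Yates-corrected
#' chi-square. A codon is flagged optimal when its within-family relative
#' usage is higher in the high group and the test is significant at
#' `alpha`. `gene_scores` is typically axis 1 of [codon_ca()] (oriented by
#' expression) or an expression measure itself.
#'
#' @param counts Gene x codon count matrix.
#' @param gene_scores Per-gene numeric vector aligned with `counts` rows.
#' @param top_frac,bottom_frac Fractions of genes defining the high/low pools.
#' @param alpha Per-codon significance level (no multiplicity correction,
#'   following common codon-usage practice).
#' @return A data frame of class `optimal_codon_set` with one row per
#'   tested codon: `aa`, `codon`, `high_freq`, `low_freq` (within-family
#'   relative usage), `statistic`, `p`, `optimal`.
#' @export
identify_optimal_codons <- function(counts, gene_scores, top_frac = 0.10,
                                    bottom_frac = 0.10, alpha = 0.01) {
  stopifnot(is.matrix(counts), nrow(counts) == length(gene_scores))
  if (nrow(counts) < 20L) stop("need at least 20 genes to contrast extreme groups")
  ord <- order(gene_scores)
  n <- nrow(counts)
  n_low <- max(1L, floor(bottom_frac * n))
  n_high <- max(1L, floor(top_frac * n))
  low <- colSums(counts[ord[seq_len(n_low)], , drop = FALSE])
  high <- colSums(counts[ord[seq.int(n - n_high + 1L, n)], , drop = FALSE])

  rows <- list()
  for (aa in DEGENERATE_AAS) {
    fam <- SYN_FAMILIES[[aa]]
    fh <- sum(high[fam]); fl <- sum(low[fam])
    if (fh == 0 || fl == 0) {
      warning(sprintf("synonym family %s absent from an extreme pool; skipped", aa))
      next
    }
    for (cod in fam) {
      tab <- matrix(c(high[cod], fh - high[cod], low[cod], fl - low[cod]), 2L,
                    dimnames = list(c("this", "other"), c("high", "low")))
      if (sum(tab) == 0) next
      ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      hf <- high[cod] / fh; lf <- low[cod] / fl
      rows[[length(rows) + 1L]] <- data.frame(
        aa = aa, codon = cod, high_freq = hf, low_freq = lf,
        statistic = unname(ht$statistic), p = unname(ht$p.value),
        optimal = is.finite(ht$p.value) && ht$p.value < alpha && hf > lf,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("optimal_codon_set", class(out))
  out
}

optimal_codon_vector <- function(optimal) {
  if (inherits(optimal, "optimal_codon_set") || is.data.frame(optimal)) {
    optimal$codon[optimal$optimal]
  } else {
    as.character(optimal)
  }
}

#' Frequency of optimal codons (Fop)
#'
#' Fop = (number of optimal codons used) / (number of codons belonging to
#' amino acids that have at least one optimal codon). Met, Trp and stop
#' codons are never counted.
#'
#' @param counts Named count vector for one gene, or a gene x codon matrix.
#' @param optimal An `optimal_codon_set` from [identify_optimal_codons()],
#'   or a character vector of optimal codons.
#' @return Numeric Fop value(s) in \[0, 1\]; `NA` when the gene has no
#'   codon from a family possessing an optimal codon.
#' @export
fop <- function(counts, optimal) {
  opt <- optimal_codon_vector(optimal)
  if (length(opt) == 0L) stop("optimal codon set is empty")
  opt_aas <- unique(AA_OF_CODON[opt])
  countable <- intersect(DEGENERATE_CODONS, SENSE_CODONS[AA_OF_CODON %in% opt_aas])
  if (is.matrix(counts)) {
    num <- rowSums(counts[, intersect(opt, countable), drop = FALSE])
    den <- rowSums(counts[, countable, drop = FALSE])
    ifelse(den > 0, num / den, NA_real_)
  } else {
    den <- sum(counts[countable])
    if (den == 0) NA_real_ else sum(counts[intersect(opt, countable)]) / den
  }
}

#' Relative adaptiveness weights for CAI
#'
#' Computes per-codon relative adaptiveness w(c) = count(c) / max family
#' count on the pooled counts of a highly expressed reference gene set.
#' Zero counts are floored at `pseudo_count` so that log-weights stay
#' finite.
#'
#' @param reference_counts Gene x codon matrix (or pooled named vector) for
#'   the reference set, conventionally the top expression decile.
#' @param pseudo_count Floor applied to zero counts (in count units).
#' @return Named numeric vector of weights over the 59 degenerate-family
#'   codons (Met/Trp excluded from CAI by convention), each in (0, 1\].
#' @export
cai_weights <- function(reference_counts, pseudo_count = 0.5) {
  pooled <- if (is.matrix(reference_counts)) colSums(reference_counts) else reference_counts
  pooled <- pooled[SENSE_CODONS]
  if (sum(pooled, na.rm = TRUE) == 0) stop("reference set has no codon counts")
  pooled <- pmax(pooled, pseudo_count)
  w <- rep(NA_real_, length(SENSE_CODONS))
  names(w) <- SENSE_CODONS
  for (aa in DEGENERATE_AAS) {
    fam <- SYN_FAMILIES[[aa]]
    w[fam] <- pooled[fam] / max(pooled[fam])
  }
  w[DEGENERATE_CODONS]
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights over the gene's
#' codons of degenerate synonym families:
#' exp(sum n_c log w_c / sum n_c).
#'
#' @param counts Named count vector for one gene, or a gene x codon matrix.
#' @param w Weights from [cai_weights()].
#' @return CAI in (0, 1\]; `NA` when the gene has no countable codon.
#' @export
cai <- function(counts, w) {
  cods <- intersect(names(w)[!is.na(w)], DEGENERATE_CODONS)
  lw <- log(w[cods])
  if (is.matrix(counts)) {
    m <- counts[, cods, drop = FALSE]
    tot <- rowSums(m)
    ifelse(tot > 0, exp(as.vector(m %*% lw) / tot), NA_real_)
  } else {
    tot <- sum(counts[cods])
    if (tot == 0) NA_real_ else exp(sum(counts[cods] * lw) / tot)
  }
}

#' Codon bias index (CBI)
#'
#' CBI = (N_opt - N_ran) / (N_tot - N_ran), where N_tot counts the gene's
#' codons in families that possess an optimal codon, N_opt those that are
#' optimal, and N_ran the expected optimal usage under uniform synonym
#' choice (family usage x optimal codons in family / family size).
#'
#' @inheritParams fop
#' @return CBI in \[-1, 1\]; `NA` when the denominator is degenerate.
#' @export
cbi <- function(counts, optimal) {
  opt <- optimal_codon_vector(optimal)
  if (length(opt) == 0L) stop("optimal codon set is empty")
  opt_aas <- unique(AA_OF_CODON[opt])
  one_gene <- function(v) {
    n_tot <- 0; n_opt <- 0; n_ran <- 0
    for (aa in opt_aas) {
      fam <- SYN_FAMILIES[[aa]]
      if (length(fam) < 2L) next
      usage <- sum(v[fam])
      n_tot <- n_tot + usage
      n_opt <- n_opt + sum(v[intersect(fam, opt)])
      n_ran <- n_ran + usage * length(intersect(fam, opt)) / length(fam)
    }
    if (abs(n_tot - n_ran) < .Machine$double.eps * max(1, n_tot)) return(NA_real_)
    (n_opt - n_ran) / (n_tot - n_ran)
  }
  if (is.matrix(counts)) apply(counts, 1L, one_gene) else one_gene(counts)
}

#' Per-gene codon usage summary
#'
#' Convenience wrapper computing length, GC, GC3s, Fop, CAI and CBI for a
#' set of coding sequences against a given optimal codon set and CAI
#' reference.
#'
#' @param cds_set Named character vector of in-frame CDS.
#' @param optimal Optimal codon set (see [fop()]).
#' @param cai_reference Optional gene x codon matrix for the CAI reference
#'   set; defaults to the genes of `cds_set` themselves weighted by the
#'   optimal codons is not meaningful, so when absent CAI is computed with
#'   weights from the pooled counts of all genes.
#' @return Data frame with columns `gene`, `length_codons`, `gc`, `gc3s`,
#'   `fop`, `cai`, `cbi`.
#' @export
usage_summary <- function(cds_set, optimal, cai_reference = NULL) {
  counts <- codon_count_table(cds_set)
  gcs <- t(vapply(cds_set, gc_metrics, c(gc = 0, gc3s = 0)))
  w <- cai_weights(if (is.null(cai_reference)) counts else cai_reference)
  data.frame(
    gene = names(cds_set),
    length_codons = nchar(cds_set) %/% 3L,
    gc = gcs[, "gc"],
    gc3s = gcs[, "gc3s"],
    fop = fop(counts, optimal),
    cai = cai(counts, w),
    cbi = cbi(counts, optimal),
    row.names = NULL, stringsAsFactors = FALSE)
}
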