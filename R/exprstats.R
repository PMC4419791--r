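# Expression statistics: decile ranking within tissues, expression
# breadth, correlations, the binned Fop-vs-breadth curve, family-size
# contrasts (Kruskal-Wallis, one-sided Mann-Whitney), flat-annotation
# hypergeometric enrichment with Benjamini-Hochberg control, and
# pathway-position correlations.

#' Rank genes into expression deciles within each tissue
#'
#' Within each tissue, genes with a positive signal are ranked and divided
#' into ten (near-)equal classes 1..10 (10% quantiles, class sizes
#' differing by at most one); genes without signal get class 0. Ties are
#' broken by stable gene-id order so runs are reproducible. Also returns
#' the per-gene maximum signal across tissues.
#'
#' @param x An `expression_matrix` from [gen_expression_matrix()], or a
#'   numeric gene x tissue signal matrix with dimnames.
#' @return A list of class `decile_ranking` with `decile` (gene x tissue
#'   integer matrix, 0..10), `max_signal`, `max_decile` (per-gene maxima
#'   across tissues) and `mean_decile`.
#' @export
decile_rank <- function(x) {
  signal <- if (inherits(x, "expression_matrix")) x$signal else x
  stopifnot(is.matrix(signal), !is.null(rownames(signal)))
  if (nrow(signal) < 10L) stop("need at least 10 genes to form deciles")
  dec <- matrix(0L, nrow(signal), ncol(signal), dimnames = dimnames(signal))
  for (j in seq_len(ncol(signal))) {
    on_idx <- which(signal[, j] > 0)
    if (length(on_idx) == 0L) next
    ord <- on_idx[order(signal[on_idx, j], rownames(signal)[on_idx])]
    k <- length(ord)
    dec[ord, j] <- as.integer(floor((seq_len(k) - 1L) * 10L / k) + 1L)
  }
  list2 <- list(decile = dec,
                max_signal = apply(signal, 1L, max),
                max_decile = apply(dec, 1L, max),
                mean_decile = rowMeans(dec))
  structure(list2, class = "decile_ranking")
}

#' Expression breadth
#'
#' Number of tissues in which each gene scored at least one hit.
#'
#' @param x An `expression_matrix`, or a logical/0-1 gene x tissue hit
#'   matrix.
#' @return Named integer vector of breadths in 0..n_tissues.
#' @export
expression_breadth <- function(x) {
  hit <- if (inherits(x, "expression_matrix")) x$hit else x
  stopifnot(is.matrix(hit))
  out <- as.integer(rowSums(hit > 0))
  names(out) <- rownames(hit)
  out
}

#' Correlation with explicit missing-data handling
#'
#' Pearson or Spearman correlation after pairwise deletion of missing
#' values; degenerate inputs (fewer than 3 complete pairs, or zero
#' variance) yield `NA` with a reason rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p` (two-sided), `n` (complete pairs),
#'   `method` and `reason` (`NA` unless the result is undefined).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = method,
                reason = "fewer than 3 complete pairs"))
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = method,
                reason = "zero variance"))
  }
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, method = method,
       reason = NA_character_)
}

#' Class-mean Fop by expression breadth
#'
#' Groups genes by breadth class, computes the mean Fop and its standard
#' error per class, and the Pearson correlation across the class means --
#' the construction behind bias-vs-breadth summary curves.
#'
#' @param breadth Integer vector of per-gene breadths.
#' @param fop_values Numeric vector of per-gene Fop, aligned with
#'   `breadth`.
#' @return A list with `curve` (data frame `breadth`, `mean_fop`, `se`,
#'   `n`; empty classes skipped) and `class_mean_r` (list from
#'   [correlate()], `NA` with reason when fewer than 3 classes).
#' @export
binned_fop_curve <- function(breadth, fop_values) {
  stopifnot(length(breadth) == length(fop_values))
  ok <- is.finite(breadth) & is.finite(fop_values)
  d <- split(fop_values[ok], breadth[ok])
  curve <- data.frame(
    breadth = as.numeric(names(d)),
    mean_fop = vapply(d, mean, 0),
    se = vapply(d, function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0, 0),
    n = lengths(d), row.names = NULL)
  cmr <- correlate(curve$breadth, curve$mean_fop, method = "pearson")
  list(curve = curve, class_mean_r = cmr)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based one-way analysis of variance with tie correction, suitable
#' for comparing groups of unequal size; p-value from the chi-square
#' approximation with df = groups - 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @return A list of class `kw_result` with `K`, `df`, `p`,
#'   `group_sizes` and `all_tied` (TRUE when every observation is
#'   identical, in which case K is reported as 0).
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) < 5L) warning("fewer than 5 observations; chi-square approximation is poor")
  sizes <- table(groups)
  if (stats::sd(values) == 0) {
    return(structure(list(K = 0, df = nlevels(groups) - 1L, p = 1,
                          group_sizes = sizes, all_tied = TRUE),
                     class = "kw_result"))
  }
  ht <- stats::kruskal.test(values, groups)
  structure(list(K = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, group_sizes = sizes, all_tied = FALSE),
            class = "kw_result")
}

#' One-sided Mann-Whitney U test
#'
#' Wilcoxon rank-sum with an explicit direction: `direction = "less"`
#' tests the alternative that `a` is stochastically smaller than `b`.
#' Exact p-values are used for small tie-free samples, the normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param a,b Numeric samples.
#' @param direction `"less"` or `"greater"` (alternative for `a` relative
#'   to `b`).
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   distribution.
#' @return A list with `U`, `p`, `direction`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_one_sided <- function(a, b, direction = c("less", "greater"),
                                   exact = NULL) {
  direction <- match.arg(direction)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  use_exact <- if (is.null(exact)) {
    min(length(a), length(b)) <= 8L && length(a) + length(b) <= 20L &&
      !anyDuplicated(c(a, b))
  } else exact
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = direction,
                                            exact = use_exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, direction = direction,
       n_a = length(a), n_b = length(b), exact = use_exact)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values: q_i = min over j with p_j >= p_i of
#' p_j * m / rank_j, capped at 1; invariant to input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric overrepresentation test against a flat annotation
#'
#' For each term, tests whether the gene set contains at least as many
#' term-annotated genes as observed under hypergeometric sampling from the
#' background, then adjusts across terms with Benjamini-Hochberg.
#'
#' @param gene_set Character vector of genes of interest (must be a subset
#'   of `background`).
#' @param background Character vector of background genes.
#' @param term_map Data frame with columns `gene`, `term` (one row per
#'   annotation), or a named list term -> genes.
#' @param fdr Significance threshold on the q-value.
#' @return Data frame with one row per term: `term`, `k` (set genes with
#'   term), `K` (background genes with term), `n` (set size), `N`
#'   (background size), `p`, `q`, `significant`.
#' @export
hypergeom_enrichment <- function(gene_set, background, term_map, fdr = 0.05) {
  if (length(gene_set) == 0L || length(background) == 0L) {
    stop("gene set and background must be non-empty")
  }
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) stop("gene_set must be a subset of background")
  terms <- if (is.data.frame(term_map)) {
    split(term_map$gene, term_map$term)
  } else term_map
  N <- length(background); n <- length(gene_set)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), background)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, gene_set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the background")
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr
  out[order(out$p), , drop = FALSE]
}

#' Per-branch correlation of a gene statistic with pathway position
#'
#' Spearman correlation of the pathway position index against a per-gene
#' statistic (Fop, omega, expression level or breadth), computed within
#' each branch; branches with fewer than 3 annotated genes, or constant
#' positions, are reported as not testable.
#'
#' @param pathway Data frame `gene`, `branch`, `position` (as from
#'   [gen_pathway_table()]).
#' @param gene_stats Named numeric vector, gene -> statistic.
#' @param method Correlation method.
#' @return Data frame `branch`, `r`, `p`, `n`, `testable`, `reason`.
#' @export
pathway_position_correlation <- function(pathway, gene_stats,
                                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "branch", "position") %in% names(pathway)))
  rows <- lapply(split(pathway, pathway$branch), function(d) {
    stat <- gene_stats[d$gene]
    res <- correlate(d$position, unname(stat), method = method)
    data.frame(branch = d$branch[1], r = res$r, p = res$p, n = res$n,
               testable = is.na(res$reason),
               reason = ifelse(is.na(res$reason), NA_character_, res$reason),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
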