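# Pairwise divergence: protein-guided codon alignment, the Nei-Gojobori
# (NG86) counting estimator with Jukes-Cantor correction, pairwise
# maximum-likelihood estimation under the GY94 codon model, and the
# standard post-hoc quality filters (dS < 0.01; dS or dN > 2; omega > 10).

#' Codon-aware global alignment of two coding sequences
#'
#' Translates both CDS, aligns the proteins globally (Needleman-Wunsch with
#' affine gaps, BLOSUM62, EMBOSS-Needle-like default penalties), threads
#' the codons back through the protein alignment, and removes codon columns
#' containing a gap. Aligning at the protein level guarantees the reading
#' frame survives the alignment.
#'
#' @param cds_a,cds_b In-frame coding sequences (terminal stop allowed,
#'   internal stops rejected).
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @return A list of class `codon_alignment`: `a`, `b` (gap-free aligned
#'   CDS of equal length), `dropped_columns` (gap codon columns removed),
#'   `score` (protein alignment score), `identity` (protein identity over
#'   retained columns).
#' @export
align_codon_pair <- function(cds_a, cds_b, gap_open = 10, gap_extend = 0.5) {
  prep <- function(cds) {
    codons <- split_codons(toupper(cds))
    if (length(codons) > 1L && codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    if (any(codons %in% STOP_CODONS)) stop("internal stop codon in input CDS")
    codons
  }
  ca <- prep(cds_a); cb <- prep(cds_b)
  pa <- translate_cds(codons_to_cds(ca)); pb <- translate_cds(codons_to_cds(cb))
  if (nchar(pa) == 0L || nchar(pb) == 0L) stop("empty protein after validation")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  out_a <- ca[ia[keep]]; out_b <- cb[ib[keep]]
  structure(list(a = codons_to_cds(out_a), b = codons_to_cds(out_b),
                 dropped_columns = sum(!keep),
                 score = Biostrings::score(aln),
                 identity = if (any(keep)) mean(sa[keep] == sb[keep]) else NA_real_),
            class = "codon_alignment")
}

aligned_codon_pair <- function(aln, cds_b = NULL) {
  if (inherits(aln, "codon_alignment")) {
    list(a = split_codons(aln$a), b = split_codons(aln$b))
  } else {
    stopifnot(is.character(aln), is.character(cds_b))
    a <- split_codons(toupper(aln)); b <- split_codons(toupper(cds_b))
    if (length(a) != length(b)) stop("aligned sequences must have equal codon length")
    list(a = a, b = b)
  }
}

# --- NG86 -------------------------------------------------------------------

# Per-codon synonymous site count: at each position, the fraction of
# single-nucleotide changes that are synonymous among changes not creating
# a stop codon ("nonsense mutations are disregarded"). Returns c(syn, total)
# where total excludes stop-bound changes.
.ng86_site_table <- local({
  NTS <- c("A", "C", "G", "T")
  syn_sites <- numeric(length(SENSE_CODONS))
  tot_sites <- numeric(length(SENSE_CODONS))
  for (i in seq_along(SENSE_CODONS)) {
    cod <- SENSE_CODONS[i]
    for (p in 1:3) {
      alts <- NTS[NTS != substr(cod, p, p)]
      muts <- vapply(alts, function(b) { x <- cod; substr(x, p, p) <- b; x }, "")
      sense <- !(muts %in% STOP_CODONS)
      if (!any(sense)) next
      syn_sites[i] <- syn_sites[i] +
        sum(GENETIC_CODE_MAP[muts[sense]] == GENETIC_CODE_MAP[cod]) / sum(sense)
      tot_sites[i] <- tot_sites[i] + 1
    }
  }
  data.frame(codon = SENSE_CODONS, syn = syn_sites, total = tot_sites,
             row.names = SENSE_CODONS)
})

#' NG86 synonymous site count of a codon
#'
#' @param codon A sense codon.
#' @return Number of synonymous sites (0..3) under the NG86 convention
#'   (mutations to stop codons disregarded).
#' @export
ng86_syn_sites <- function(codon) .ng86_site_table[toupper(codon), "syn"]

# Average synonymous / nonsynonymous differences between two codons over
# all mutational pathways that do not pass through a stop codon.
.ng86_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else if (k == 2L) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1,2,3)], pos[c(1,3,2)], pos[c(2,1,3)],
         pos[c(2,3,1)], pos[c(3,1,2)], pos[c(3,2,1)])
  }
  walk <- function(order) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS) return(NULL)
      if (GENETIC_CODE_MAP[nxt] == GENETIC_CODE_MAP[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (length(res) == 0L) {
    # all pathways hit a stop: fall back to counting through them anyway
    res <- lapply(perms, function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        aa1 <- GENETIC_CODE_MAP[cur]; aa2 <- GENETIC_CODE_MAP[nxt]
        aa1 <- ifelse(is.na(aa1), "*", aa1); aa2 <- ifelse(is.na(aa2), "*", aa2)
        if (identical(aa1, aa2)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

#' NG86 counting estimate of dN and dS
#'
#' Nei-Gojobori counting estimator: synonymous/nonsynonymous site counts by
#' enumeration of single-nucleotide neighbours, pathway-averaged difference
#' counts for codons differing at more than one position, and Jukes-Cantor
#' correction of the proportions. Codon columns containing a stop or an
#' ambiguous codon are skipped.
#'
#' @param aln A `codon_alignment` from [align_codon_pair()], or an aligned
#'   in-frame CDS string (then `cds_b` must be given).
#' @param cds_b Second aligned CDS when `aln` is a plain string.
#' @return A one-row data frame (class `substitution_estimate`) with
#'   `dN`, `dS`, `omega`, `t`, `kappa`, `lnL`, `method`, `n_codons`,
#'   `saturated`. `t`, `kappa` and `lnL` are `NA` for this counting method;
#'   `omega` is `NA` when `dS` is 0 or undefined.
#' @export
ng86 <- function(aln, cds_b = NULL) {
  pair <- aligned_codon_pair(aln, cds_b)
  ok <- pair$a %in% SENSE_CODONS & pair$b %in% SENSE_CODONS
  a <- pair$a[ok]; b <- pair$b[ok]
  if (length(a) == 0L) stop("no comparable codon columns")
  S <- sum(.ng86_site_table[a, "syn"] + .ng86_site_table[b, "syn"]) / 2
  Ntot <- sum(.ng86_site_table[a, "total"] + .ng86_site_table[b, "total"]) / 2
  N <- Ntot - S
  ne <- which(a != b)
  Sd <- 0; Nd <- 0
  if (length(ne) > 0) {
    diffs <- mapply(.ng86_path_diffs, a[ne], b[ne])
    Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p)) NA_real_ else if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(data.frame(dN = dN, dS = dS, omega = omega, t = NA_real_,
                       kappa = NA_real_, lnL = NA_real_, method = "NG86",
                       n_codons = length(a), saturated = saturated,
                       stringsAsFactors = FALSE),
            class = c("substitution_estimate", "data.frame"))
}

# --- GY94 pairwise maximum likelihood --------------------------------------

gy94_pair_frequencies <- function(a, b, freq_model) {
  cds <- c(codons_to_cds(a), codons_to_cds(b))
  switch(freq_model,
    F3x4 = f3x4_frequencies(cds),
    F1x4 = {
      bases <- unlist(strsplit(c(a, b), ""), use.names = FALSE)
      f <- table(factor(bases, levels = c("A", "C", "G", "T")))
      f <- as.vector(f) / sum(f)
      names(f) <- c("A", "C", "G", "T")
      pi <- f[CODON_BASES[, 1]] * f[CODON_BASES[, 2]] * f[CODON_BASES[, 3]]
      pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
      names(pi) <- SENSE_CODONS
      pi
    },
    F61 = {
      tab <- table(factor(c(a, b), levels = SENSE_CODONS))
      pi <- pmax(as.vector(tab), 0.5)
      pi <- pi / sum(pi)
      names(pi) <- SENSE_CODONS
      pi
    },
    stop("freq_model must be one of F3x4, F1x4, F61"))
}

#' Pairwise maximum-likelihood dN/dS under the GY94 codon model
#'
#' Fits branch length t (expected codon substitutions per codon), kappa and
#' omega to one aligned sequence pair by maximizing the reversible pairwise
#' likelihood sum_sites log(pi_i P(t)_ij). Each of `n_repeats` repeats runs
#' `n_restarts` bounded quasi-Newton optimizations from random starting
#' points and keeps the solution with the highest log-likelihood; the
#' retained dN, dS and omega are then averaged over repeats. dN and dS are
#' derived from the fitted parameters by partitioning the expected
#' substitution flux into synonymous and nonsynonymous classes and dividing
#' by the corresponding site proportions (computed at omega = 1).
#'
#' @inheritParams ng86
#' @param freq_model Codon frequency model: `"F3x4"` (default, codeml's
#'   default), `"F1x4"` or `"F61"`, estimated from the pair itself.
#' @param n_restarts Random restarts per repeat.
#' @param n_repeats Independent repeats whose best-lnL solutions are
#'   averaged.
#' @param seed Optional integer seed for the restart draws.
#' @param bounds List with elements `t`, `kappa`, `omega`, each a length-2
#'   numeric range for the bounded optimization.
#' @return A one-row data frame (class `substitution_estimate`) with
#'   averaged `dN`, `dS`, `omega`, `t`, `kappa`, the best `lnL` across
#'   repeats, `method = "GY94"`, `n_codons`, `n_repeats` and `converged`.
#' @export
gy94_ml <- function(aln, cds_b = NULL, freq_model = "F3x4", n_restarts = 3L,
                    n_repeats = 10L, seed = NULL,
                    bounds = list(t = c(1e-4, 50), kappa = c(0.1, 100),
                                  omega = c(1e-4, 20))) {
  pair <- aligned_codon_pair(aln, cds_b)
  ok <- pair$a %in% SENSE_CODONS & pair$b %in% SENSE_CODONS
  a <- pair$a[ok]; b <- pair$b[ok]
  if (length(a) == 0L) stop("no comparable codon columns")
  if (length(a) < 30L) warning("fewer than 30 codon columns; ML estimates may be unstable")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pi <- gy94_pair_frequencies(a, b, freq_model)
  ia <- match(a, SENSE_CODONS); ib <- match(b, SENSE_CODONS)
  pat <- stats::aggregate(list(n = rep(1L, length(ia))), by = list(i = ia, j = ib), FUN = sum)

  nll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    Q <- gy94_rate_matrix(kappa, omega, pi)
    P <- gy94_probs(gy94_eigen(Q), t)
    lik <- pi[pat$i] * P[cbind(pat$i, pat$j)]
    if (any(lik <= 0)) return(1e10)
    -sum(pat$n * log(lik))
  }
  lower <- log(c(bounds$t[1], bounds$kappa[1], bounds$omega[1]))
  upper <- log(c(bounds$t[2], bounds$kappa[2], bounds$omega[2]))
  p_diff <- mean(a != b)
  t0 <- min(max(-log(max(1 - p_diff * 1.1, 0.05)), bounds$t[1] * 2), 2)

  repeats <- vector("list", n_repeats)
  any_conv <- FALSE
  for (r in seq_len(n_repeats)) {
    best <- NULL
    for (s in seq_len(n_restarts)) {
      # first restart of every repeat anchors at a data-informed start;
      # the others draw from the central band of the (log) parameter box
      start <- if (s == 1L) {
        log(c(t0, 2, 0.5))
      } else {
        stats::runif(3, lower + 0.25 * (upper - lower), upper - 0.25 * (upper - lower))
      }
      fit <- tryCatch(
        stats::optim(pmin(pmax(start, lower), upper), nll, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 300, factr = 1e9)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) next
    any_conv <- TRUE
    est <- exp(best$par)
    dd <- gy94_dn_ds(est[1], est[2], est[3], pi)
    repeats[[r]] <- c(t = est[1], kappa = est[2], omega = est[3],
                      dN = unname(dd["dN"]), dS = unname(dd["dS"]),
                      lnL = -best$value)
  }
  repeats <- do.call(rbind, Filter(Negate(is.null), repeats))
  if (is.null(repeats)) {
    return(structure(data.frame(dN = NA_real_, dS = NA_real_, omega = NA_real_,
                                t = NA_real_, kappa = NA_real_, lnL = NA_real_,
                                method = "GY94", n_codons = length(a),
                                n_repeats = 0L, converged = FALSE,
                                stringsAsFactors = FALSE),
                     class = c("substitution_estimate", "data.frame")))
  }
  avg <- colMeans(repeats)
  structure(data.frame(dN = avg["dN"], dS = avg["dS"],
                       omega = if (avg["dS"] > 0) avg["dN"] / avg["dS"] else NA_real_,
                       t = avg["t"], kappa = avg["kappa"],
                       lnL = max(repeats[, "lnL"]), method = "GY94",
                       n_codons = length(a), n_repeats = nrow(repeats),
                       converged = any_conv, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("substitution_estimate", "data.frame"))
}

#' Apply the standard dN/dS quality filters
#'
#' Discards estimates in rule order: (1) dS < 0.01 (unreliable omega),
#' (2) dS > 2 or dN > 2 (saturation), (3) omega > 10 (abnormally high
#' ratio). Estimates with undefined dS or dN are discarded separately.
#' Retained estimates receive a selection class: purifying (omega < 1),
#' neutral (omega = 1), positive (omega > 1).
#'
#' @param estimates Data frame with columns `dN`, `dS` and optionally
#'   `omega` (recomputed as dN/dS when absent or NA).
#' @return A list with `retained` (the surviving rows plus
#'   `selection_class`) and `report` (data frame of per-rule discard counts
#'   and the retained count; counts sum to the input size).
#' @export
filter_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  n <- nrow(estimates)
  if (n == 0L) {
    report <- data.frame(rule = c("undefined", "ds_lt_0.01", "saturated_gt_2",
                                  "omega_gt_10", "retained"),
                         threshold = c(NA, "dS < 0.01", "dS > 2 or dN > 2",
                                       "omega > 10", NA),
                         count = integer(5), stringsAsFactors = FALSE)
    return(list(retained = estimates, report = report))
  }
  omega <- if ("omega" %in% names(estimates)) estimates$omega else NA_real_
  omega <- ifelse(is.na(omega) & !is.na(estimates$dS) & estimates$dS > 0,
                  estimates$dN / estimates$dS, omega)
  undefined <- is.na(estimates$dS) | is.na(estimates$dN)
  r1 <- !undefined & estimates$dS < 0.01
  r2 <- !undefined & !r1 & (estimates$dS > 2 | estimates$dN > 2)
  r3 <- !undefined & !r1 & !r2 & !is.na(omega) & omega > 10
  keep <- !(undefined | r1 | r2 | r3)
  retained <- estimates[keep, , drop = FALSE]
  om <- omega[keep]
  retained$selection_class <- ifelse(is.na(om), NA_character_,
                              ifelse(om < 1, "purifying",
                              ifelse(om > 1, "positive", "neutral")))
  report <- data.frame(
    rule = c("undefined", "ds_lt_0.01", "saturated_gt_2", "omega_gt_10", "retained"),
    threshold = c(NA, "dS < 0.01", "dS > 2 or dN > 2", "omega > 10", NA),
    count = c(sum(undefined), sum(r1), sum(r2), sum(r3), sum(keep)),
    stringsAsFactors = FALSE)
  list(retained = retained, report = report)
}
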