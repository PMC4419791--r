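# Synthetic two-species datasets with planted ground truth: codon bias
# coupled to expression decile, an 8-tissue expression design with
# presence/absence hits, power-law gene family sizes spanning the six
# size classes, and ortholog divergence simulated under the GY94 codon
# model with known (t, kappa, omega).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default planted optimal codon set
#'
#' One optimal codon per degenerate amino acid, chosen A/T-ending where
#' possible (T-ending preferred), which reproduces the empirical situation
#' in which optimal codons avoid G/C at the third position and Fop is
#' negatively correlated with GC3s.
#'
#' @param ending Preferred third-position bases, in priority order.
#' @return Named character vector, amino acid -> optimal codon.
#' @export
default_optimal_codons <- function(ending = c("T", "A")) {
  vapply(DEGENERATE_AAS, function(aa) {
    fam <- sort(SYN_FAMILIES[[aa]])
    for (e in ending) {
      hit <- fam[substr(fam, 3, 3) == e]
      if (length(hit) > 0) return(hit[1])
    }
    fam[1]
  }, "")
}

#' Linear bias-by-decile ramp
#'
#' @param b_max Bias strength in the top expression decile.
#' @param b_min Bias strength in the bottom decile.
#' @return Numeric vector of length 10, non-decreasing, in \[0, 1\].
#' @export
bias_ramp <- function(b_max = 0.8, b_min = 0.02) seq(b_min, b_max, length.out = 10)

#' Generator configuration
#'
#' Bundles and validates the parameters of the synthetic dataset generator.
#'
#' @param n_families Number of gene families to simulate.
#' @param size_exponent Exponent of the discrete power law for family sizes.
#' @param max_family_size Largest family size drawable.
#' @param n_tissues Number of tissues in the expression design.
#' @param optimal_codons Named map amino acid -> single optimal codon,
#'   covering every degenerate amino acid exactly once.
#' @param bias_by_decile Numeric length-10 vector, bias strength b per
#'   expression decile 1..10; must be non-decreasing and within \[0, 1\].
#' @param divergence_range List with positive length-2 ranges `t`, `kappa`,
#'   `omega` for the per-family divergence parameters.
#' @param mean_gene_length Mean gene length in codons (including start and
#'   stop).
#' @param min_gene_length Minimum gene length in codons.
#' @param seed Integer seed recorded in generated datasets.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_families = 60L,
                             size_exponent = 2.5,
                             max_family_size = 150L,
                             n_tissues = 8L,
                             optimal_codons = default_optimal_codons(),
                             bias_by_decile = bias_ramp(),
                             divergence_range = list(t = c(0.1, 0.5),
                                                     kappa = c(1.5, 3),
                                                     omega = c(0.05, 0.6)),
                             mean_gene_length = 300L,
                             min_gene_length = 120L,
                             seed = 1L) {
  stopifnot(n_families >= 1, size_exponent > 0, max_family_size >= 2,
            n_tissues >= 1, mean_gene_length >= 10,
            min_gene_length >= 3, min_gene_length <= mean_gene_length)
  if (!setequal(names(optimal_codons), DEGENERATE_AAS)) {
    stop("optimal_codons must name exactly one codon per degenerate amino acid")
  }
  bad <- vapply(DEGENERATE_AAS,
                function(aa) !(optimal_codons[[aa]] %in% SYN_FAMILIES[[aa]]), TRUE)
  if (any(bad)) stop("optimal codon outside its amino acid's synonym family: ",
                     paste(DEGENERATE_AAS[bad], collapse = ", "))
  if (length(bias_by_decile) != 10L || any(bias_by_decile < 0) ||
      any(bias_by_decile > 1) || is.unsorted(bias_by_decile)) {
    stop("bias_by_decile must be 10 non-decreasing values in [0, 1]")
  }
  for (nm in c("t", "kappa", "omega")) {
    rg <- divergence_range[[nm]]
    if (is.null(rg) || length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2]) {
      stop("divergence_range$", nm, " must be a positive ascending range")
    }
  }
  structure(list(n_families = as.integer(n_families),
                 size_exponent = size_exponent,
                 max_family_size = as.integer(max_family_size),
                 n_tissues = as.integer(n_tissues),
                 optimal_codons = optimal_codons,
                 bias_by_decile = bias_by_decile,
                 divergence_range = divergence_range,
                 mean_gene_length = as.integer(mean_gene_length),
                 min_gene_length = as.integer(min_gene_length),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a codon-biased coding sequence
#'
#' Amino acids are drawn uniformly; at each site of a degenerate family the
#' planted optimal codon is chosen with probability b + (1 - b)/n_syn and
#' every other synonym with probability (1 - b)/n_syn, where b is the bias
#' strength of the gene's expression decile. The first codon is ATG and the
#' last a stop codon.
#'
#' @param length_codons Total gene length in codons (including ATG and
#'   stop); must be at least 2.
#' @param decile Expression decile 1..10 controlling bias strength.
#' @param config A [generator_config()].
#' @param seed Optional seed for reproducibility.
#' @return Character scalar CDS.
#' @export
gen_biased_cds <- function(length_codons, decile, config = generator_config(),
                           seed = NULL) {
  if (!is.numeric(length_codons) || length_codons < 2) {
    stop("length_codons must be at least 2")
  }
  if (!is.numeric(decile) || length(decile) != 1L || decile < 1 || decile > 10 ||
      decile != round(decile)) {
    stop("decile must be an integer in 1..10")
  }
  with_seed(seed, {
    b <- config$bias_by_decile[decile]
    n_interior <- as.integer(length_codons) - 2L
    aas <- sample(names(SYN_FAMILIES), n_interior, replace = TRUE)
    codons <- character(n_interior)
    for (aa in unique(aas)) {
      idx <- which(aas == aa)
      fam <- SYN_FAMILIES[[aa]]
      if (length(fam) == 1L) {
        codons[idx] <- fam
      } else {
        opt <- config$optimal_codons[[aa]]
        p <- rep((1 - b) / length(fam), length(fam))
        names(p) <- fam
        p[opt] <- p[opt] + b
        codons[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
      }
    }
    paste0("ATG", paste(codons, collapse = ""), "TAA")
  })
}

#' Evolve a coding sequence under the GY94 model
#'
#' Each codon site evolves independently under the continuous-time Markov
#' chain defined by [gy94_rate_matrix()]; stop codons are outside the state
#' space so they are unreachable and no indels are introduced. A terminal
#' stop codon on the input is preserved unchanged.
#'
#' @param cds In-frame CDS (terminal stop allowed, internal stops rejected).
#' @param t Branch length in expected codon substitutions per codon (>= 0).
#' @param kappa,omega GY94 parameters (> 0).
#' @param pi Codon equilibrium frequencies (default uniform over the 61
#'   sense codons).
#' @param seed Optional seed.
#' @return Character scalar CDS of the same length.
#' @export
evolve_cds_gy94 <- function(cds, t, kappa = 2, omega = 0.2, pi = NULL,
                            seed = NULL) {
  stopifnot(t >= 0, kappa > 0, omega >= 0)
  codons <- split_codons(toupper(cds))
  stop_tail <- character(0)
  if (length(codons) > 1L && codons[length(codons)] %in% STOP_CODONS) {
    stop_tail <- codons[length(codons)]
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% STOP_CODONS)) stop("internal stop codon in input CDS")
  if (!all(codons %in% SENSE_CODONS)) stop("ambiguous codons cannot be evolved")
  if (t == 0) return(toupper(cds))
  with_seed(seed, {
    Q <- gy94_rate_matrix(kappa, omega, pi)
    P <- gy94_probs(gy94_eigen(Q), t)
    idx <- match(codons, SENSE_CODONS)
    out <- character(length(codons))
    for (i in unique(idx)) {
      sites <- which(idx == i)
      out[sites] <- sample(SENSE_CODONS, length(sites), replace = TRUE, prob = P[i, ])
    }
    codons_to_cds(c(out, stop_tail))
  })
}

#' Random coding sequence from a codon frequency distribution
#'
#' Draws codons independently from `pi` (uniform over the 61 sense codons
#' by default). Such a sequence is stationary under [gy94_rate_matrix()]
#' with the same `pi`, which makes it the correct ancestral sequence for
#' parameter-recovery and stationarity experiments.
#'
#' @param length_codons Number of codons.
#' @param pi Codon frequencies over the 61 sense codons.
#' @param seed Optional seed.
#' @return Character scalar CDS (no start/stop structure imposed).
#' @export
random_cds <- function(length_codons, pi = NULL, seed = NULL) {
  stopifnot(length_codons >= 1)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61)
  with_seed(seed,
    paste(sample(SENSE_CODONS, length_codons, replace = TRUE, prob = pi),
          collapse = ""))
}

# discrete power-law family sizes on 2..max
draw_family_sizes <- function(n, exponent, max_size) {
  support <- 2:max_size
  p <- support^(-exponent)
  support[sample.int(length(support), n, replace = TRUE, prob = p / sum(p))]
}

#' Generate a synthetic two-species gene family set
#'
#' Families are populated by evolving one ancestral biased CDS into all
#' members of both species under the GY94 model with per-family
#' (t, kappa, omega). Family sizes follow a discrete power law (when
#' `n_families >= 30`, one family per size class is guaranteed by seeding
#' the first six families with representative sizes). Larger families are
#' planted with lower mean expression decile and breadth, and higher omega.
#'
#' @param config A [generator_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A list of class `synthetic_dataset` with `genes` (data frame:
#'   `gene`, `species`, `family`, `cds`, `decile`, `breadth_true`),
#'   `tissue_deciles` (gene x tissue matrix of planted per-tissue deciles,
#'   0 = not expressed), `families` (data frame with planted `size`,
#'   `n_a`, `n_b`, `size_class`, `t`, `kappa`, `omega`, `decile`),
#'   `optimal_codons`, `config` and `seed`.
#' @export
gen_family_set <- function(config = generator_config(), seed = config$seed) {
  with_seed(seed, {
    nf <- config$n_families
    sizes <- draw_family_sizes(nf, config$size_exponent, config$max_family_size)
    if (nf >= 30L) {
      anchors <- pmin(c(2L, 3L, 7L, 14L, 50L, 120L), config$max_family_size)
      sizes[seq_along(anchors)] <- anchors
    }
    rng <- config$divergence_range
    genes <- list(); fam_rows <- list(); tissue_rows <- list()
    for (f in seq_len(nf)) {
      s <- sizes[f]
      # size-2 families are one-to-one orthologs; larger families split
      # binomially (allowing lineage-specific "orphan" families)
      n_a <- if (s == 2L) 1L else stats::rbinom(1L, s, 0.5)
      n_b <- s - n_a
      # planted couplings: decile decreasing, omega increasing with size
      mu <- 10 - 2.2 * log2(s)
      fam_decile <- min(10L, max(1L, as.integer(round(mu + stats::rnorm(1, 0, 1)))))
      size_span <- log2(config$max_family_size) - 1
      u <- if (size_span <= 0) 0 else min(1, max(0, (log2(s) - 1) / size_span))
      t_f <- stats::runif(1, rng$t[1], rng$t[2])
      kappa_f <- stats::runif(1, rng$kappa[1], rng$kappa[2])
      omega_f <- rng$omega[1] + u * (rng$omega[2] - rng$omega[1]) *
        stats::runif(1, 0.8, 1.2)
      omega_f <- min(max(omega_f, rng$omega[1]), rng$omega[2])
      len <- max(config$min_gene_length,
                 as.integer(round(stats::rlnorm(1, log(config$mean_gene_length), 0.25))))
      anc <- gen_biased_cds(len, fam_decile, config)
      species <- c(rep("A", n_a), rep("B", n_b))
      for (g in seq_len(s)) {
        cds <- evolve_cds_gy94(anc, t_f / 2, kappa_f, omega_f)
        cds <- paste0("ATG", substr(cds, 4L, nchar(cds)))  # keep the start codon planted
        g_decile <- min(10L, max(1L, as.integer(round(fam_decile + stats::rnorm(1, 0, 0.7)))))
        p_hit <- stats::plogis((g_decile - 2.5) / 1.3)
        expressed <- stats::runif(config$n_tissues) < p_hit
        td <- ifelse(expressed,
                     pmin(10L, pmax(1L, as.integer(round(g_decile + stats::rnorm(config$n_tissues, 0, 1))))),
                     0L)
        gid <- sprintf("F%04d_%s%02d", f, species[g], sum(species[seq_len(g)] == species[g]))
        genes[[length(genes) + 1L]] <- data.frame(
          gene = gid, species = species[g], family = sprintf("F%04d", f),
          cds = cds, decile = g_decile, breadth_true = sum(td > 0),
          stringsAsFactors = FALSE)
        tissue_rows[[length(tissue_rows) + 1L]] <- td
      }
      fam_rows[[f]] <- data.frame(
        family = sprintf("F%04d", f), size = s, n_a = n_a, n_b = n_b,
        size_class = classify_family_size(n_a, n_b),
        t = t_f, kappa = kappa_f, omega = omega_f, decile = fam_decile,
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    tissue_deciles <- do.call(rbind, tissue_rows)
    dimnames(tissue_deciles) <- list(genes$gene,
                                     sprintf("tissue%02d", seq_len(config$n_tissues)))
    structure(list(genes = genes, tissue_deciles = tissue_deciles,
                   families = do.call(rbind, fam_rows),
                   optimal_codons = config$optimal_codons,
                   config = config, seed = seed),
              class = "synthetic_dataset")
  })
}

#' Generate a gene x tissue expression matrix from a synthetic dataset
#'
#' Signals are log-normal with gene/tissue-specific mean tied to the
#' planted per-tissue decile; a cell scores a "hit" (and a nonzero signal)
#' according to `hit_prob`.
#'
#' @param dataset A `synthetic_dataset` from [gen_family_set()].
#' @param hit_prob Either `NULL` (default: a cell is a hit exactly when its
#'   planted tissue decile is > 0) or a single probability in \[0, 1\]
#'   applied to every cell.
#' @param signal_sd Log-scale noise of the signal.
#' @param seed Optional seed.
#' @return A list of class `expression_matrix` with `signal` and `hit`
#'   (gene x tissue matrices) and `tissues`.
#' @export
gen_expression_matrix <- function(dataset, hit_prob = NULL, signal_sd = 0.3,
                                  seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  td <- dataset$tissue_deciles
  with_seed(seed, {
    if (is.null(hit_prob)) {
      hit <- td > 0
    } else {
      stopifnot(is.numeric(hit_prob), hit_prob >= 0, hit_prob <= 1)
      hit <- matrix(stats::runif(length(td)) < hit_prob, nrow(td), ncol(td))
    }
    mu <- 0.45 * pmax(td, 1)
    signal <- matrix(stats::rlnorm(length(td), as.vector(mu), signal_sd),
                     nrow(td), ncol(td))
    signal[!hit] <- 0
    dimnames(signal) <- dimnames(td)
    dimnames(hit) <- dimnames(td)
    structure(list(signal = signal, hit = hit, tissues = colnames(td)),
              class = "expression_matrix")
  })
}

#' Generate a synthetic pathway-position table
#'
#' Genes are spread over `n_branches` pathway branches with integer
#' position indices numbered upstream to downstream; a per-gene covariate
#' (standing in for Fop, breadth or omega) is planted as
#' `intercept + slope * position + noise`.
#'
#' @param n_genes Total number of genes (>= 3).
#' @param slope Planted monotone coupling between position and covariate
#'   (0 for a null).
#' @param n_branches Number of branches.
#' @param noise Standard deviation of the covariate noise.
#' @param intercept Covariate value at position 0.
#' @param seed Optional seed.
#' @return Data frame `gene`, `branch`, `position`, `covariate`.
#' @export
gen_pathway_table <- function(n_genes, slope, n_branches = 4L, noise = 0.1,
                              intercept = 0.6, seed = NULL) {
  if (n_genes < 3) stop("n_genes must be at least 3")
  with_seed(seed, {
    branch <- sort(rep_len(seq_len(n_branches), n_genes))
    pos <- unlist(lapply(split(branch, branch), seq_along), use.names = FALSE)
    data.frame(gene = sprintf("P%04d", seq_len(n_genes)),
               branch = sprintf("branch%d", branch),
               position = pos,
               covariate = intercept + slope * pos + stats::rnorm(n_genes, 0, noise),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `speciesA.fasta`, `speciesB.fasta` (60-column wrap),
#' `expression.tsv` (long format: gene, tissue, signal, hit) and
#' `truth.tsv` (per-family planted parameters plus the optimal codon set in
#' a header comment) into `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param expr An `expression_matrix` for the same dataset.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, expr, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"), inherits(expr, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$genes
  paths <- c(
    a = file.path(dir, "speciesA.fasta"),
    b = file.path(dir, "speciesB.fasta"),
    expr = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_fasta(stats::setNames(g$cds[g$species == "A"], g$gene[g$species == "A"]), paths["a"])
  write_fasta(stats::setNames(g$cds[g$species == "B"], g$gene[g$species == "B"]), paths["b"])
  long <- data.frame(
    gene = rep(rownames(expr$signal), ncol(expr$signal)),
    tissue = rep(colnames(expr$signal), each = nrow(expr$signal)),
    signal = as.vector(expr$signal),
    hit = as.integer(as.vector(expr$hit)), stringsAsFactors = FALSE)
  utils::write.table(long, paths["expr"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$families
  truth$optimal_codons <- paste(dataset$optimal_codons, collapse = ",")
  truth$seed <- dataset$seed
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
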