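# End-to-end orchestration: simulate a two-species dataset (or load
# user-supplied FASTA/TSV inputs), run codon-usage statistics, optimal
# codon identification, ortholog clustering, dN/dS estimation with the
# standard filters, family-size statistics, pathway-position correlations
# and term enrichment, writing every artifact as a TSV/FASTA with a
# manifest. All stochastic stages run under one seed, so identical
# configurations give byte-identical outputs.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-to-statistics workflow
#'
#' Executes simulate -> codon stats -> optimal codons -> cluster -> dnds ->
#' family stats -> pathway -> enrichment in dependency order and writes all
#' outputs under `out_dir`. When `fasta_a`/`fasta_b` are supplied they
#' replace the simulated sequences (they must exist at call time; the
#' configuration is validated before any stage runs).
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [generator_config()] for the simulation stage.
#' @param seed Integer seed governing every stochastic stage.
#' @param dnds_method `"ng86"` (fast counting, default) or `"gy94"`
#'   (pairwise maximum likelihood) for the single-copy ortholog pairs.
#' @param inflation,min_identity,min_coverage Clustering parameters passed
#'   to [similarity_graph()] and [mcl()].
#' @param ca_min_codons Minimum gene length (countable codons) for the
#'   correspondence analysis.
#' @param alpha Per-codon significance level for optimal codon calls.
#' @param fdr Enrichment significance threshold.
#' @param fasta_a,fasta_b Optional paths to user CDS FASTA files.
#' @param n_repeats Repeats for the GY94 maximum-likelihood method.
#' @return Invisibly, a list with the stage results and `manifest` (data
#'   frame of written files with md5 checksums).
#' @export
run_pipeline <- function(out_dir, config = generator_config(), seed = config$seed,
                         dnds_method = c("ng86", "gy94"), inflation = 1.5,
                         min_identity = 0.4, min_coverage = 0.5,
                         ca_min_codons = 100L, alpha = 0.01, fdr = 0.05,
                         fasta_a = NULL, fasta_b = NULL, n_repeats = 3L) {
  dnds_method <- match.arg(dnds_method)
  for (p in c(fasta_a, fasta_b)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log_msg <- function(stage, ...) message(sprintf("[%s] %s", stage, paste0(...)))

  with_seed(seed, {
    # --- simulate ----------------------------------------------------------
    log_msg("simulate", "generating dataset (seed ", seed, ")")
    dataset <- gen_family_set(config, seed = NULL)
    expr <- gen_expression_matrix(dataset)
    paths <- c(paths, write_dataset(dataset, expr, out_dir))
    genes <- dataset$genes
    if (!is.null(fasta_a)) {
      log_msg("simulate", "overriding species A sequences from ", fasta_a)
      seqs_a <- read_cds_fasta(fasta_a)
      genes <- genes[genes$species != "A", , drop = FALSE]
      genes <- rbind(genes, data.frame(gene = names(seqs_a), species = "A",
                                       family = NA, cds = unname(seqs_a),
                                       decile = NA, breadth_true = NA))
    }
    if (!is.null(fasta_b)) {
      seqs_b <- read_cds_fasta(fasta_b)
      genes <- genes[genes$species != "B", , drop = FALSE]
      genes <- rbind(genes, data.frame(gene = names(seqs_b), species = "B",
                                       family = NA, cds = unname(seqs_b),
                                       decile = NA, breadth_true = NA))
    }
    cds <- stats::setNames(genes$cds, genes$gene)

    # flat annotation: one term enriched among single-copy families,
    # background terms spread uniformly
    single_fams <- dataset$families$family[dataset$families$size_class == "single-copy"]
    is_single <- genes$family %in% single_fams
    ann <- do.call(rbind, list(
      data.frame(gene = genes$gene[stats::runif(nrow(genes)) <
                                     ifelse(is_single, 0.6, 0.1)],
                 term = "GO:translation", stringsAsFactors = FALSE),
      data.frame(gene = genes$gene[stats::runif(nrow(genes)) < 0.25],
                 term = "GO:kinase_activity", stringsAsFactors = FALSE),
      data.frame(gene = genes$gene[stats::runif(nrow(genes)) < 0.3],
                 term = "GO:metabolism", stringsAsFactors = FALSE)))
    paths <- c(paths, annotation = write_tsv(ann, file.path(out_dir, "annotation.tsv")))

    # --- codon statistics --------------------------------------------------
    log_msg("codon-stats", "counting codons for ", length(cds), " genes")
    trimmed <- vapply(cds, function(s) validate_and_trim_cds(s)$cds, "")
    counts <- codon_count_table(trimmed)
    ranking <- decile_rank(expr)
    ca <- codon_ca(counts, min_codons = ca_min_codons,
                   expression = ranking$mean_decile[rownames(counts)])
    log_msg("codon-stats", "CA retained ", nrow(ca$gene_coords), " genes, dropped ",
            length(ca$dropped), " shorter than ", ca_min_codons, " codons")
    ca_genes <- data.frame(gene = rownames(ca$gene_coords), ca$gene_coords,
                           row.names = NULL)
    ca_codons <- data.frame(codon = rownames(ca$codon_coords), ca$codon_coords,
                            row.names = NULL)
    paths <- c(paths,
               ca_genes = write_tsv(ca_genes, file.path(out_dir, "ca_genes.tsv")),
               ca_codons = write_tsv(ca_codons, file.path(out_dir, "ca_codons.tsv")))

    # --- optimal codons ----------------------------------------------------
    log_msg("optimal-codons", "contrasting extreme 10% groups at alpha = ", alpha)
    sub_counts <- counts[rownames(ca$gene_coords), , drop = FALSE]
    opt <- identify_optimal_codons(sub_counts, ca$gene_coords[, 1], alpha = alpha)
    paths <- c(paths, optimal = write_tsv(opt, file.path(out_dir, "optimal_codons.tsv")))

    usage <- usage_summary(trimmed, opt)
    usage$breadth <- expression_breadth(expr)[usage$gene]
    usage$mean_decile <- ranking$mean_decile[usage$gene]
    usage$max_decile <- ranking$max_decile[usage$gene]
    paths <- c(paths, usage = write_tsv(usage, file.path(out_dir, "gene_usage.tsv")))

    # --- clustering --------------------------------------------------------
    log_msg("cluster", "all-vs-all alignment; identity >= ", min_identity,
            ", coverage >= ", min_coverage, ", inflation = ", inflation)
    prots <- vapply(trimmed, translate_cds, "")
    graph <- similarity_graph(prots[genes$species == "A"], prots[genes$species == "B"],
                              min_identity = min_identity, min_coverage = min_coverage)
    clustering <- mcl(graph, inflation = inflation)
    fam_tab <- merge(clustering$groups, clustering$families, by = "family")
    paths <- c(paths,
               families = write_tsv(fam_tab, file.path(out_dir, "families.tsv")),
               unclustered = write_tsv(
                 data.frame(gene = clustering$unclustered),
                 file.path(out_dir, "unclustered.tsv")))

    # --- dN/dS -------------------------------------------------------------
    # single-copy orthologs plus sampled cross-species pairs from every
    # larger family, so rates can be contrasted across size classes
    pairs <- single_copy_pairs(clustering)
    multi <- clustering$families$family[clustering$families$size_class != "single-copy" &
                                          clustering$families$n_a >= 1 &
                                          clustering$families$n_b >= 1]
    extra <- lapply(multi, function(fm) {
      d <- clustering$groups[clustering$groups$family == fm, ]
      a <- d$gene[d$species == "A"]; b <- d$gene[d$species == "B"]
      k <- min(2L, length(a), length(b))
      data.frame(family = fm,
                 gene_a = sample(a, k), gene_b = sample(b, k),
                 stringsAsFactors = FALSE)
    })
    pairs <- rbind(pairs, do.call(rbind, extra))
    log_msg("dnds", nrow(pairs), " ortholog pairs; method = ", dnds_method,
            "; filters dS < 0.01, dS/dN > 2, omega > 10")
    ests <- lapply(seq_len(nrow(pairs)), function(i) {
      aln <- align_codon_pair(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
      est <- if (dnds_method == "gy94") {
        gy94_ml(aln, n_repeats = n_repeats)
      } else ng86(aln)
      cbind(pairs[i, , drop = FALSE], est, row.names = NULL)
    })
    ests <- do.call(rbind, ests)
    flt <- filter_estimates(ests)
    if (nrow(flt$retained) > 0) {
      retained_cols <- c("gene_a", "gene_b", "selection_class")
      ests$filter_status <- ifelse(
        paste(ests$gene_a, ests$gene_b) %in%
          paste(flt$retained$gene_a, flt$retained$gene_b), "retained", "discarded")
    } else {
      ests$filter_status <- "discarded"
    }
    paths <- c(paths,
               dnds = write_tsv(ests, file.path(out_dir, "pairs_dnds.tsv")),
               filter = write_tsv(flt$report, file.path(out_dir, "filter_report.tsv")))

    # --- family statistics -------------------------------------------------
    log_msg("famstats", "Kruskal-Wallis across size classes")
    gene_class <- stats::setNames(fam_tab$size_class, fam_tab$gene)
    usage$size_class <- gene_class[usage$gene]
    kw_vars <- list(expression_breadth = usage$breadth,
                    expression_level = usage$mean_decile,
                    fop = usage$fop, cai = usage$cai, cbi = usage$cbi,
                    gc = usage$gc, gc3s = usage$gc3s,
                    length_codons = usage$length_codons)
    stats_rows <- lapply(names(kw_vars), function(v) {
      cl <- usage$size_class
      ok <- !is.na(cl) & is.finite(kw_vars[[v]])
      if (length(unique(cl[ok])) < 2L) {
        return(data.frame(variable = v, K = NA, df = NA, p = NA))
      }
      kw <- kruskal_wallis(kw_vars[[v]][ok], cl[ok])
      data.frame(variable = v, K = kw$K, df = kw$df, p = kw$p)
    })
    # omega across size classes, via the family of each retained pair
    if (nrow(flt$retained) >= 5L) {
      fam_class <- stats::setNames(clustering$families$size_class,
                                   clustering$families$family)
      omega_class <- fam_class[flt$retained$family]
      if (length(unique(omega_class)) >= 2L) {
        kw <- kruskal_wallis(flt$retained$omega, omega_class)
        stats_rows <- c(stats_rows, list(
          data.frame(variable = "omega", K = kw$K, df = kw$df, p = kw$p)))
      }
    }
    stats_summary <- do.call(rbind, stats_rows)
    paths <- c(paths, stats = write_tsv(stats_summary,
                                        file.path(out_dir, "stats_summary.tsv")))

    curve <- binned_fop_curve(usage$breadth, usage$fop)
    paths <- c(paths, fig1 = write_tsv(curve$curve, file.path(out_dir, "fig1_curve.tsv")))

    # --- pathway positions -------------------------------------------------
    # positions planted by anti-ranking genes on expression decile, so
    # upstream enzymes are the widely/highly expressed ones
    log_msg("pathway", "building pathway table and correlating with Fop and breadth")
    n_path <- min(60L, nrow(usage))
    path_genes <- sample(usage$gene, n_path)
    pd <- usage[match(path_genes, usage$gene), ]
    branch <- rep_len(1:3, n_path)
    pw <- do.call(rbind, lapply(split(seq_len(n_path), branch), function(idx) {
      d <- pd[idx, ]
      ord <- order(-(d$mean_decile + stats::rnorm(length(idx), 0, 0.8)))
      data.frame(gene = d$gene[ord], branch = paste0("branch", branch[idx][1]),
                 position = seq_along(ord), stringsAsFactors = FALSE)
    }))
    pc_fop <- pathway_position_correlation(pw, stats::setNames(usage$fop, usage$gene))
    pc_breadth <- pathway_position_correlation(pw, stats::setNames(as.numeric(usage$breadth),
                                                                   usage$gene))
    pc_fop$statistic <- "fop"; pc_breadth$statistic <- "breadth"
    pathway_corr <- rbind(pc_fop, pc_breadth)
    paths <- c(paths,
               pathway = write_tsv(pw, file.path(out_dir, "pathway.tsv")),
               pathway_corr = write_tsv(pathway_corr,
                                        file.path(out_dir, "pathway_corr.tsv")))

    # --- enrichment --------------------------------------------------------
    log_msg("enrich", "hypergeometric test, BH FDR < ", fdr)
    single_genes <- fam_tab$gene[fam_tab$size_class == "single-copy"]
    background <- unique(ann$gene)
    set <- intersect(single_genes, background)
    enr <- if (length(set) >= 2L) {
      hypergeom_enrichment(set, background, ann, fdr = fdr)
    } else {
      data.frame(term = character(0), k = integer(0), K = integer(0),
                 n = integer(0), N = integer(0), p = numeric(0),
                 q = numeric(0), significant = logical(0))
    }
    paths <- c(paths, enrichment = write_tsv(enr, file.path(out_dir, "enrichment.tsv")))

    manifest <- data.frame(
      file = basename(unname(paths)),
      md5 = unname(tools::md5sum(unname(paths))),
      bytes = file.size(unname(paths)),
      seed = seed, stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    log_msg("done", length(paths), " artifacts written to ", out_dir)

    invisible(list(dataset = dataset, expression = expr, usage = usage,
                   ca = ca, optimal = opt, clustering = clustering,
                   dnds = ests, filter_report = flt$report,
                   stats_summary = stats_summary, fig1 = curve,
                   pathway_corr = pathway_corr, enrichment = enr,
                   manifest = manifest))
  })
}
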