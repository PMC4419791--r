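test_that("codon counting excludes stops and ambiguous codons but tallies them", {
  x <- count_codons("ATGTTTTAA")
  expect_equal(unname(x["ATG"]), 1L)
  expect_equal(unname(x["TTT"]), 1L)
  expect_equal(sum(x), 2L)
  expect_equal(attr(x, "excluded_stop"), 1L)

  y <- count_codons("ATGNNNTTT")
  expect_equal(sum(y), 2L)
  expect_equal(attr(y, "excluded_ambiguous"), 1L)

  expect_error(count_codons(""), "multiple of 3")
})

test_that("RSCU matches its definition and normalization identity", {
  # Phe TTT=3, TTC=1 -> RSCU 1.5 / 0.5
  x <- count_codons(paste0("ATG", strrep("TTT", 3), "TTC"))
  r <- rscu(x)
  expect_equal(unname(r["TTT"]), 1.5)
  expect_equal(unname(r["TTC"]), 0.5)
  # absent families are NA, not zero
  expect_true(is.na(r["GGG"]))

  # uniform usage within every family -> RSCU 1 everywhere; family sums
  # equal family sizes
  counts <- stats::setNames(rep(1, 61), names(rscu(x)))
  r1 <- rscu(counts)
  expect_true(all(r1 == 1))
  fam <- split(names(r1), Biostrings::GENETIC_CODE[names(r1)])
  for (f in fam) expect_equal(sum(r1[f]), length(f))
})

test_that("GC and GC3s follow their definitions on toy sequences", {
  # ATG GGC: only degenerate codon GGC, third position C -> GC3s = 1
  expect_equal(unname(gc_metrics("ATGGGC")["gc3s"]), 1.0)
  # all-AT sequence -> GC = 0
  expect_equal(unname(gc_metrics("ATTAAA")["gc"]), 0)
  # ATG alone: GC defined, GC3s missing
  m <- gc_metrics("ATG")
  expect_false(is.na(m["gc"]))
  expect_true(is.na(m["gc3s"]))
})

test_that("correspondence analysis degenerates to zero inertia on identical usage", {
  cds <- rep(paste0("ATG", strrep("TTTTTC", 60)), 5)
  names(cds) <- paste0("g", 1:5)
  counts <- codon_count_table(cds)
  ca <- codon_ca(counts, min_codons = 10)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(ca$gene_coords == 0))
})

test_that("total inertia equals the Pearson chi-square statistic over the grand total", {
  set.seed(42)
  counts <- matrix(rpois(30 * 61, 20), 30, 61,
                   dimnames = list(paste0("g", 1:30), names(count_codons("ATG"))))
  ca <- codon_ca(counts, min_codons = 1)
  x <- counts[, intersect(colnames(counts), rownames(ca$codon_coords)), drop = FALSE]
  chi2 <- suppressWarnings(chisq.test(x)$statistic)
  expect_equal(ca$total_inertia, unname(chi2) / sum(x), tolerance = 1e-8)
})

test_that("CA axis 1 separates two gene groups with disjoint preferred synonyms", {
  cfg_at <- generator_config(bias_by_decile = rep(1, 10))
  gc_opt <- default_optimal_codons(ending = c("G", "C"))
  cfg_gc <- generator_config(optimal_codons = gc_opt, bias_by_decile = rep(1, 10))
  set.seed(7)
  grp1 <- vapply(1:10, function(i) gen_biased_cds(200, 10, cfg_at), "")
  grp2 <- vapply(1:10, function(i) gen_biased_cds(200, 10, cfg_gc), "")
  cds <- c(grp1, grp2)
  names(cds) <- paste0("g", seq_along(cds))
  ca <- codon_ca(codon_count_table(cds), min_codons = 50)
  ax1 <- ca$gene_coords[, 1]
  expect_true(all(sign(ax1[1:10]) == sign(ax1[1])))
  expect_true(all(sign(ax1[11:20]) == -sign(ax1[1])))
})

test_that("CA principal coordinates agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  counts <- matrix(rpois(25 * 61, 15), 25, 61,
                   dimnames = list(paste0("g", 1:25), names(count_codons("ATG"))))
  ca <- codon_ca(counts, min_codons = 1, n_axes = 2)
  x <- counts[, rownames(ca$codon_coords), drop = FALSE]
  mc <- MASS::corresp(x, nf = 2)
  # MASS returns standard coordinates; principal = standard * singular value
  for (k in 1:2) {
    ref <- mc$rscore[, k] * mc$cor[k]
    expect_equal(abs(ca$gene_coords[, k]), abs(ref), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_lt(abs(abs(cor(ca$gene_coords[, k], ref)) - 1), 1e-8)
  }
})

test_that("optimal codon identification recovers a planted set and stays empty under uniformity", {
  cfg <- generator_config()
  set.seed(11)
  dec <- sample(1:10, 300, TRUE)
  cds <- vapply(seq_along(dec), function(i) gen_biased_cds(250, dec[i], cfg), "")
  names(cds) <- paste0("g", seq_along(cds))
  counts <- codon_count_table(cds)
  ca <- codon_ca(counts, expression = dec)
  opt <- identify_optimal_codons(counts, ca$gene_coords[, 1])
  called <- opt$codon[opt$optimal]
  truth <- unname(cfg$optimal_codons)
  expect_gte(mean(called %in% truth), 0.9)
  expect_gte(mean(truth %in% called), 0.9)

  # perfectly uniform usage in both pools -> nothing called
  ucounts <- matrix(5L, 40, 61, dimnames = list(paste0("u", 1:40), colnames(counts)))
  uopt <- identify_optimal_codons(ucounts, seq_len(40))
  expect_equal(sum(uopt$optimal), 0)
})

test_that("Fop follows its definition", {
  opt <- default_optimal_codons()
  # gene using only optimal codons -> 1 (plus ATG which never counts)
  cds <- paste0("ATG", strrep(opt[["F"]], 4), strrep(opt[["K"]], 6))
  expect_equal(fop(count_codons(cds), opt), 1.0)
  # 6 optimal of 10 countable codons -> 0.6
  nonopt <- setdiff(c("TTT", "TTC"), opt[["F"]])[1]
  cds2 <- paste0("ATG", strrep(opt[["K"]], 6), strrep(nonopt, 4))
  expect_equal(fop(count_codons(cds2), opt), 0.6)
  # gene of only ATG/TGG codons -> missing
  expect_true(is.na(fop(count_codons("ATGTGGATG"), opt)))
})

test_that("CAI weights use the max-count normalization with a floor for zeros", {
  counts <- count_codons(paste0(strrep("TTT", 10), strrep("TTC", 5)))
  w <- cai_weights(counts)
  expect_equal(unname(w["TTT"]), 1.0)
  expect_equal(unname(w["TTC"]), 0.5)
  # zero counts floored: 0 < w < 1
  zero_fam <- w[c("GGT", "GGC", "GGA", "GGG")]
  expect_true(all(zero_fam > 0 & zero_fam <= 1))
  # duplicating every reference gene leaves w unchanged
  m <- rbind(g1 = counts, g2 = counts)
  class(m) <- "matrix"
  expect_equal(cai_weights(rbind(counts, counts, counts, counts)), w)
})

test_that("CAI is the weighted geometric mean of weights", {
  w <- cai_weights(count_codons(paste0(strrep("TTT", 10), strrep("TTC", 5))))
  # all codons at w = 1 -> CAI 1
  expect_equal(cai(count_codons(strrep("TTT", 8)), w), 1.0)
  # two codons with w 0.25 and 1: geometric mean 0.5
  w2 <- w; w2["TTC"] <- 0.25
  expect_equal(cai(count_codons("TTTTTC"), w2), 0.5)
  # length invariance at fixed composition proportions
  expect_equal(cai(count_codons(strrep("TTTTTC", 3)), w),
               cai(count_codons(strrep("TTTTTC", 30)), w))
})

test_that("CBI hits its limits: 1 all-optimal, 0 at random usage, -1 zero optimal in 2-fold families", {
  opt <- default_optimal_codons()
  all_opt <- paste(rep(opt[["F"]], 10), collapse = "")
  expect_equal(cbi(count_codons(all_opt), opt), 1.0)
  # usage exactly at the random expectation: every Phe codon equally used
  expect_equal(cbi(count_codons(strrep("TTTTTC", 5)), opt), 0.0)
  # zero optimal usage, all codons in 2-fold families -> -1
  nonopt_f <- setdiff(c("TTT", "TTC"), opt[["F"]])[1]
  nonopt_k <- setdiff(c("AAA", "AAG"), opt[["K"]])[1]
  cds <- paste0(strrep(nonopt_f, 5), strrep(nonopt_k, 5))
  expect_equal(cbi(count_codons(cds), opt), -1.0)
})

test_that("index identities hold jointly on a fully optimal gene", {
  opt <- default_optimal_codons()
  cds <- paste(vapply(names(opt), function(a) strrep(opt[[a]], 3), ""), collapse = "")
  counts <- count_codons(cds)
  expect_equal(fop(counts, opt), 1.0)
  expect_equal(cbi(counts, opt), 1.0)
  w <- cai_weights(counts)
  expect_equal(cai(counts, w), 1.0)
})

test_that("Fop is monotone in the planted bias strength", {
  cfg_at <- function(b) generator_config(bias_by_decile = rep(b, 10))
  opt <- default_optimal_codons()
  set.seed(21)
  bs <- seq(0, 1, by = 0.1)
  fops <- vapply(bs, function(b) {
    fop(count_codons(gen_biased_cds(500, 5, cfg_at(b))), opt)
  }, 0)
  expect_gt(cor(bs, fops, method = "spearman"), 0.95)
})
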