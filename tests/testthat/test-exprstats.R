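make_signal <- function(n, tissues = 2, seed = 1) {
  set.seed(seed)
  matrix(rlnorm(n * tissues), n, tissues,
         dimnames = list(sprintf("g%03d", seq_len(n)), paste0("t", seq_len(tissues))))
}

test_that("decile classes are an equal partition with zeros for silent genes", {
  sig <- make_signal(100)
  rk <- decile_rank(sig)
  expect_true(all(table(rk$decile[, 1]) == 10))
  expect_true(all(rk$decile %in% 0:10))
  # silent genes get class 0
  sig2 <- sig; sig2[1:7, 1] <- 0
  rk2 <- decile_rank(sig2)
  expect_true(all(rk2$decile[1:7, 1] == 0))
  sizes <- table(rk2$decile[rk2$decile[, 1] > 0, 1])
  expect_lte(diff(range(sizes)), 1)
  expect_error(decile_rank(sig[1:5, , drop = FALSE]), "at least 10")
})

test_that("tied signals resolve by stable gene-id order and ranks survive monotone maps", {
  sig <- make_signal(30)
  sig[, 1] <- 1  # all tied
  rk <- decile_rank(sig)
  sizes <- table(rk$decile[, 1])
  expect_lte(diff(range(sizes)), 1)
  # ties broken by gene id: first ids get the low classes
  expect_true(rk$decile["g001", 1] <= rk$decile["g030", 1])
  # strictly monotone transform leaves ranks unchanged
  sig2 <- make_signal(50, seed = 2)
  r1 <- decile_rank(sig2)$decile
  r2 <- decile_rank(exp(sig2 / 2))$decile
  expect_identical(r1, r2)
})

test_that("breadth counts hit tissues", {
  hit <- matrix(0, 3, 8, dimnames = list(c("a", "b", "c"), paste0("t", 1:8)))
  hit["a", 1:3] <- 1
  hit["c", ] <- 1
  br <- expression_breadth(hit)
  expect_equal(unname(br), c(3L, 0L, 8L))
})

test_that("correlations handle exact relationships and degenerate input", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x + 1)$r, 1.0)
  expect_equal(correlate(x, x^3, method = "spearman")$r, 1.0)
  # hand-derived Spearman from the rank formula: d = (1,1,0), r = 1 - 6*2/24
  expect_equal(correlate(c(1, 2, 3), c(2, 1, 3), method = "spearman")$r, 0.5)
  const <- correlate(x, rep(1, 20))
  expect_true(is.na(const$r))
  expect_equal(const$reason, "zero variance")
  short <- correlate(c(1, 2), c(3, 4))
  expect_true(is.na(short$r))
})

test_that("binned Fop curves summarize classes and degenerate to flat or single-point", {
  set.seed(5)
  breadth <- rep(0:8, each = 30)
  fops <- 0.3 + 0.05 * breadth + rnorm(length(breadth), 0, 0.02)
  bc <- binned_fop_curve(breadth, fops)
  expect_equal(nrow(bc$curve), 9)
  expect_true(all(diff(bc$curve$mean_fop) > 0))
  expect_gt(bc$class_mean_r$r, 0.9)
  # constant Fop: flat curve, zero SE
  flat <- binned_fop_curve(breadth, rep(0.5, length(breadth)))
  expect_true(all(flat$curve$mean_fop == 0.5))
  expect_true(all(flat$curve$se == 0))
  # single class: correlation undefined
  single <- binned_fop_curve(rep(4, 10), runif(10))
  expect_equal(nrow(single$curve), 1)
  expect_true(is.na(single$class_mean_r$r))
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  # direct evaluation of the rank-sum formula (no ties):
  # K = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1)
  R <- tapply(rank(vals), grp, sum)
  K_hand <- 12 / (9 * 10) * sum(R^2 / 3) - 3 * 10
  expect_equal(K_hand, 7.2)
  kw <- kruskal_wallis(vals, grp)
  expect_equal(kw$K, 7.2)
  expect_equal(kw$df, 2)
  # all identical observations: K reported as 0 with flag
  tied <- kruskal_wallis(rep(1, 12), rep(c("a", "b", "c"), 4))
  expect_equal(tied$K, 0)
  expect_true(tied$all_tied)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis with two groups tracks the two-sided Mann-Whitney", {
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15, 0.5)
    kw <- kruskal_wallis(c(a, b), rep(c("x", "y"), each = 15))
    mw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_lt(abs(kw$p - mw$p.value), 0.02)
  }
})

test_that("one-sided Mann-Whitney gives the enumeration-exact p and honours direction", {
  # a = {1,2}, b = {3,4}: all 2-subsets of ranks; only one ordering as
  # extreme -> p = 1/C(4,2) = 1/6
  res <- mann_whitney_one_sided(c(1, 2), c(3, 4), direction = "less")
  expect_equal(res$p, 1 / 6, tolerance = 1e-12)
  expect_true(res$exact)
  # direction check: a >> b but testing a < b -> p near 1
  res2 <- mann_whitney_one_sided(100:110, 1:10, direction = "less")
  expect_gt(res2$p, 0.99)
  # exact and approximate agree at n = 8 + 8
  set.seed(7)
  diffs <- replicate(20, {
    a <- rnorm(8); b <- rnorm(8, 0.3)
    pe <- mann_whitney_one_sided(a, b, "less", exact = TRUE)$p
    pa <- mann_whitney_one_sided(a, b, "less", exact = FALSE)$p
    abs(pe - pa)
  })
  expect_lt(max(diffs), 0.01)
})

test_that("hypergeometric enrichment matches closed forms and flags by BH q", {
  bg <- sprintf("g%02d", 1:20)
  term_map <- data.frame(gene = bg[1:5], term = "T1")
  res <- hypergeom_enrichment(bg[1:5], bg, term_map)
  # all 5 annotated genes drawn in a set of 5: p = 1/C(20,5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)
  # k = 0 -> p = 1
  res0 <- hypergeom_enrichment(bg[6:10], bg, term_map)
  expect_equal(res0$p, 1)
  # term in every background gene -> p = 1
  all_map <- data.frame(gene = bg, term = "Tall")
  res1 <- hypergeom_enrichment(bg[1:5], bg, all_map)
  expect_equal(res1$p, 1)
  expect_error(hypergeom_enrichment(character(0), bg, term_map), "non-empty")
  expect_error(hypergeom_enrichment(c("zzz"), bg, term_map), "subset")
})

test_that("BH adjustment reproduces the step-up formula and is order invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  set.seed(8)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pathway correlations equal correlate() on each branch's pairs", {
  tab <- gen_pathway_table(40, slope = -0.03, n_branches = 2, noise = 0.05, seed = 9)
  stats_vec <- stats::setNames(tab$covariate, tab$gene)
  pc <- pathway_position_correlation(tab, stats_vec)
  for (b in unique(tab$branch)) {
    d <- tab[tab$branch == b, ]
    ref <- correlate(d$position, d$covariate, method = "spearman")
    expect_equal(pc$r[pc$branch == b], ref$r)
    expect_equal(pc$p[pc$branch == b], ref$p)
  }
})
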