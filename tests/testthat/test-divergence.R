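test_that("identical sequences align perfectly with no dropped columns", {
  cds <- gen_biased_cds(100, 5, generator_config(), seed = 1)
  aln <- align_codon_pair(cds, cds)
  expect_equal(aln$dropped_columns, 0)
  expect_equal(aln$identity, 1.0)
  expect_identical(aln$a, aln$b)
  expect_equal(nchar(aln$a) %% 3, 0)
})

test_that("a single internal codon deletion drops exactly one column", {
  cfg <- generator_config()
  cds <- gen_biased_cds(60, 5, cfg, seed = 2)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  del <- paste(codons[-30], collapse = "")
  aln <- align_codon_pair(cds, del)
  expect_equal(aln$dropped_columns, 1)
  expect_equal(nchar(aln$a) / 3, length(codons) - 2)  # minus stop, minus gap column
  expect_identical(aln$a, aln$b)
})

test_that("alignment scores equal a brute-force affine-gap DP oracle on short pairs", {
  set.seed(3)
  for (i in 1:15) {
    a <- random_protein(sample(3:8, 1))
    b <- random_protein(sample(3:8, 1))
    ref <- gotoh_score(a, b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(Biostrings::score(aln), ref, info = paste(a, b))
  }
})

test_that("internal stops are rejected by the aligner", {
  expect_error(align_codon_pair("ATGTAAATGGCT", "ATGGCTGCTGCT"), "internal stop")
})

test_that("NG86 site counts match exhaustive single-mutation enumeration for all 61 codons", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (cod in sense) {
    expect_equal(ng86_syn_sites(cod), enum_syn_sites(cod), info = cod)
  }
  # anchor values derived by hand: TTT -> only TTT>TTC synonymous (1/3);
  # ATG -> all nine changes nonsynonymous (0)
  expect_equal(ng86_syn_sites("TTT"), 1 / 3)
  expect_equal(ng86_syn_sites("ATG"), 0)
})

test_that("NG86 returns zero divergence for identical sequences and flags saturation", {
  cds <- gen_biased_cds(200, 5, generator_config(), seed = 4)
  est <- ng86(align_codon_pair(cds, cds))
  expect_equal(est$dN, 0)
  expect_equal(est$dS, 0)
  expect_true(is.na(est$omega))
  expect_false(est$saturated)
})

test_that("purely synonymous differences give dN = 0 and positive dS", {
  a <- strrep("TTT", 30)
  b <- paste0(strrep("TTC", 3), strrep("TTT", 27))
  est <- ng86(a, b)
  expect_equal(est$dN, 0)
  expect_gt(est$dS, 0)
  expect_equal(est$omega, 0)
  # a fully saturated synonymous contrast is flagged rather than corrected
  sat <- ng86(strrep("TTT", 50), strrep("TTC", 50))
  expect_true(sat$saturated)
  expect_true(is.na(sat$dS))
})

test_that("the GY94 generator matrix is a proper reversible rate matrix", {
  pi <- as.vector(f3x4_frequencies(random_cds(500, seed = 5)))
  Q <- gy94_rate_matrix(kappa = 3, omega = 0.3, pi = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  expect_lt(max(abs(attr(Q, "pi") %*% Q)), 1e-10)
  # detailed balance
  D <- diag(attr(Q, "pi"))
  expect_lt(max(abs(D %*% Q - t(D %*% Q))), 1e-12)
  # unit flux scaling
  expect_equal(-sum(attr(Q, "pi") * diag(Q)), 1, tolerance = 1e-12)
})

test_that("fitted lnL beats every point of a coarse grid sweep", {
  anc <- random_cds(400, seed = 6)
  der <- evolve_cds_gy94(anc, 0.4, 2, 0.3, seed = 7)
  fit <- gy94_ml(anc, der, n_repeats = 1, n_restarts = 2, seed = 8)
  pi <- gy94_pair_frequencies <- codonfam:::gy94_pair_frequencies(
    codonfam:::split_codons(anc), codonfam:::split_codons(der), "F3x4")
  grid_lnL <- function(t, kappa, omega) {
    Q <- gy94_rate_matrix(kappa, omega, pi)
    P <- codonfam:::gy94_probs(codonfam:::gy94_eigen(Q), t)
    ia <- match(codonfam:::split_codons(anc), rownames(Q))
    ib <- match(codonfam:::split_codons(der), rownames(Q))
    sum(log(pi[ia] * P[cbind(ia, ib)]))
  }
  for (t in c(0.1, 0.4, 1)) for (k in c(1, 2, 5)) for (om in c(0.1, 0.3, 1)) {
    expect_gte(fit$lnL + 1e-6, grid_lnL(t, k, om))
  }
})

test_that("dN and dS are non-decreasing in t at fixed kappa and omega", {
  ts <- c(0.05, 0.2, 0.5, 1, 2)
  vals <- t(vapply(ts, function(t) codonfam:::gy94_dn_ds(t, 2, 0.3, rep(1 / 61, 61)),
                   c(dN = 0, dS = 0)))
  expect_true(all(diff(vals[, "dN"]) > 0))
  expect_true(all(diff(vals[, "dS"]) > 0))
})

test_that("ML recovers simulation parameters on a single long pair", {
  anc <- random_cds(1000, seed = 9)
  der <- evolve_cds_gy94(anc, t = 0.5, kappa = 2, omega = 0.2, seed = 10)
  fit <- gy94_ml(anc, der, n_repeats = 2, n_restarts = 2, seed = 11)
  expect_lt(abs(fit$omega - 0.2) / 0.2, 0.25)
  expect_lt(abs(fit$kappa - 2) / 2, 0.35)
  expect_lt(abs(fit$t - 0.5) / 0.5, 0.25)
  expect_true(fit$converged)
})

test_that("identical sequences drive the ML branch length to its lower bound", {
  cds <- random_cds(300, seed = 12)
  fit <- gy94_ml(cds, cds, n_repeats = 1, n_restarts = 1, seed = 13)
  expect_lt(fit$t, 1e-3)
  expect_lt(fit$dS, 1e-3)
  expect_lt(fit$dN, 1e-3)
})

test_that("NG86 and GY94 agree at low divergence with kappa = 1", {
  anc <- random_cds(2000, seed = 14)
  der <- evolve_cds_gy94(anc, t = 0.05, kappa = 1, omega = 0.5, seed = 15)
  g <- gy94_ml(anc, der, freq_model = "F61", n_repeats = 1, n_restarts = 2, seed = 16)
  n <- ng86(anc, der)
  expect_lt(abs(g$omega - n$omega) / g$omega, 0.10)
})

test_that("the three discard rules are applied exactly and bookkeeping balances", {
  est <- data.frame(dN = c(0.4 * 0.005, 0.4 * 0.05, 0.4 * 2.5),
                    dS = c(0.005, 0.05, 2.5),
                    omega = c(0.4, 0.4, 0.4))
  flt <- filter_estimates(est)
  expect_equal(nrow(flt$retained), 1)
  expect_equal(flt$retained$dS, 0.05)
  expect_equal(flt$report$count[flt$report$rule == "ds_lt_0.01"], 1)
  expect_equal(flt$report$count[flt$report$rule == "saturated_gt_2"], 1)

  # omega > 10 rule (dN and dS themselves unremarkable)
  hi <- data.frame(dN = 1.5, dS = 0.12, omega = 12.5)
  flt2 <- filter_estimates(hi)
  expect_equal(nrow(flt2$retained), 0)
  expect_equal(flt2$report$count[flt2$report$rule == "omega_gt_10"], 1)

  # empty input
  flt3 <- filter_estimates(est[0, ])
  expect_equal(sum(flt3$report$count), 0)

  # bookkeeping property on random inputs
  set.seed(17)
  rnd <- data.frame(dN = rexp(200, 2), dS = rexp(200, 2))
  rnd$omega <- ifelse(rnd$dS > 0, rnd$dN / rnd$dS, NA)
  flt4 <- filter_estimates(rnd)
  discarded <- sum(flt4$report$count[flt4$report$rule != "retained"])
  expect_equal(discarded + nrow(flt4$retained), 200)
  expect_equal(flt4$report$count[flt4$report$rule == "retained"], nrow(flt4$retained))
  # selection classes follow the omega = 1 boundary
  expect_true(all((flt4$retained$omega < 1) == (flt4$retained$selection_class == "purifying")))
})
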