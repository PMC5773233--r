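test_that("LD estimation matches dosage correlations and repairs indefiniteness", {
  set.seed(1)
  g <- matrix(sample(0:2, 200, replace = TRUE), ncol = 2)
  g <- cbind(g, g[, 1])  # duplicated SNP column
  ld <- ld_from_panel(g, c("a", "b", "a2"))
  expect_equal(ld$r["a", "a2"], 1)
  expect_equal(diag(ld$r), c(a = 1, b = 1, a2 = 1))
  expect_equal(ld$n_samples, 100L)

  mono <- cbind(g[, 1], rep(2L, 100))
  expect_error(ld_from_panel(mono, c("ok", "bad")), "bad")
  expect_error(ld_from_panel(matrix(3, 10, 2)), "\\[0, 2\\]")
  expect_error(ld_from_panel(g[1, , drop = FALSE]), "2 reference samples")

  # independent SNPs: off-diagonal correlations are sampling noise
  set.seed(2)
  ind <- matrix(rbinom(5000 * 4, 2, 0.3), ncol = 4)
  r <- ld_from_panel(ind)$r
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # an indefinite pseudo-correlation gets clipped back to PSD, unit diagonal
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  rep_r <- mendelEnrich:::repair_psd(bad)
  expect_gte(min(eigen(rep_r, symmetric = TRUE)$values), -1e-8)
  expect_equal(diag(rep_r), rep(1, 3))
})

test_that("gene statistic is the chi-squared(1) transform of p-values", {
  expect_equal(gene_statistic(0.3173), 1, tolerance = 1e-3)
  expect_equal(gene_statistic(rep(0.3173, 5)), 5 * gene_statistic(0.3173))
  expect_lt(gene_statistic(1 - 1e-12), 1e-6)
  # round trip with the chi-squared tail
  p <- c(0.01, 0.2, 0.77)
  expect_equal(gene_statistic(p),
               sum(qchisq(p, 1, lower.tail = FALSE)))
  expect_warning(t0 <- gene_statistic(c(0.5, 1)), "clamped")
  expect_true(is.finite(t0))
  expect_error(gene_statistic(numeric()), "no p-values")
})

test_that("null simulation is seed-reproducible and matches closed forms", {
  k <- 6
  ident <- diag(k)
  expect_identical(simulate_null(ident, 100, seed = 5),
                   simulate_null(ident, 100, seed = 5))
  # identity LD: T* ~ chi-squared(k)
  t_star <- simulate_null(ident, 2e4, seed = 11)
  expect_equal(quantile(t_star, 0.95, names = FALSE),
               qchisq(0.95, k), tolerance = 0.05)
  expect_equal(mean(t_star), k, tolerance = 0.05)
  # perfect correlation collapses to k times one chi-squared(1) draw
  ones <- matrix(1, 4, 4)
  t_ones <- simulate_null(ones, 2e4, seed = 12)
  expect_equal(quantile(t_ones, 0.95, names = FALSE),
               4 * qchisq(0.95, 1), tolerance = 0.05)
})

test_that("block-diagonal LD decomposes into independent block statistics", {
  blk <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))
  ld_ab <- matrix(0, 7, 7)
  ld_ab[1:4, 1:4] <- blk(4, 0.8)
  ld_ab[5:7, 5:7] <- blk(3, 0.8)
  whole <- simulate_null(ld_ab, 3e4, seed = 21)
  parts <- simulate_null(blk(4, 0.8), 3e4, seed = 22) +
           simulate_null(blk(3, 0.8), 3e4, seed = 23)
  for (q in c(0.25, 0.5, 0.9, 0.95)) {
    expect_equal(quantile(whole, q, names = FALSE),
                 quantile(parts, q, names = FALSE), tolerance = 0.06)
  }
})

test_that("empirical gene p-values are smoothed, monotone and analytically consistent", {
  plan <- simulation_plan(c(1000, 5000), seed = 3)
  expect_error(simulation_plan(c(100, 100)), "increasing")
  p_zero <- gene_pvalue(0, diag(3), plan)
  expect_equal(p_zero$p_empirical, 1, tolerance = 2e-3)
  expect_gte(p_zero$p_empirical, 1 / (p_zero$n_simulations + 1))
  # single-SNP gene: empirical p tracks the chi-squared(1) tail
  for (t_obs in c(0.5, 3.84, 6.63)) {
    pe <- gene_pvalue(t_obs, diag(1), simulation_plan(c(2e4), seed = 9))
    analytic <- pchisq(t_obs, 1, lower.tail = FALSE)
    expect_lt(abs(pe$p_empirical - analytic),
              4 * sqrt(analytic * (1 - analytic) / 2e4) + 1e-3)
  }
  # monotone in the statistic for a fixed plan/seed
  ps <- sapply(c(0, 1, 4, 9, 16), function(t_obs)
    gene_pvalue(t_obs, diag(4), plan)$p_empirical)
  expect_true(all(diff(ps) <= 0))
  # escalation: extreme statistic exhausts the stages and stays smoothed
  esc <- gene_pvalue(200, diag(2), simulation_plan(c(100, 1000), seed = 4))
  expect_equal(esc$n_simulations, 1000)
  expect_equal(esc$p_empirical, 1 / 1001)
  expect_true(esc$converged)
  mild <- gene_pvalue(0.5, diag(2), simulation_plan(c(100, 1000), seed = 4))
  expect_equal(mild$n_simulations, 100)
})

test_that("run_gene_tests handles missing panel SNPs, omitted genes and gene-order stability", {
  set.seed(31)
  loci <- tiny_loci()
  windows <- make_windows(loci, 50000)
  variants <- tiny_variants()
  sel <- select_variants(variants, windows)
  geno <- matrix(rbinom(60 * 3, 2, 0.4), nrow = 60,
                 dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  panel <- list(genotypes = geno)  # rs5 absent: G3 has no usable SNP
  plan <- simulation_plan(c(500), seed = 8)
  res <- run_gene_tests(sel, panel, plan)
  expect_setequal(res$results$gene_symbol, c("G1", "G2"))
  expect_equal(res$omitted, "G3")
  expect_equal(res$n_dropped_snps, 1L)
  expect_equal(res$summary$n_genes, 2L)
  expect_s3_class(res$summary$enrichment, "enrichment_test")
  expect_true(all(res$results$p_empirical > 0 & res$results$p_empirical <= 1))

  # per-gene results do not depend on window input ordering
  sel2 <- select_variants(variants, windows[c(3, 1, 2), ])
  res2 <- run_gene_tests(sel2, panel, plan)
  expect_identical(res$results, res2$results)
})
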