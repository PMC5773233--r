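test_that("generators are pure functions of (config, seed) and restore RNG state", {
  cfg <- small_syn_config()
  set.seed(123); before <- .Random.seed
  l1 <- gen_gene_loci(cfg, 7L)
  expect_identical(.Random.seed, before)
  expect_identical(l1, gen_gene_loci(cfg, 7L))
  p1 <- gen_reference_panel(cfg, 7L)
  expect_identical(p1, gen_reference_panel(cfg, 7L))
  s1 <- gen_summary_stats(cfg, l1, p1, 7L)
  expect_identical(s1, gen_summary_stats(cfg, l1, p1, 7L))
  f1 <- gen_omim_fixture(cfg, 7L)
  expect_identical(f1, gen_omim_fixture(cfg, 7L))
  expect_false(identical(l1, gen_gene_loci(cfg, 8L)))
})

test_that("gene loci respect count, length bounds and pairwise non-overlap", {
  cfg <- small_syn_config()
  loci <- gen_gene_loci(cfg, 3L)
  expect_equal(nrow(loci), cfg$n_genes)
  lens <- loci$tx_end - loci$tx_start + 1
  expect_true(all(lens >= cfg$gene_length_range_bp[1] - 1 &
                  lens <= cfg$gene_length_range_bp[2] + 1))
  expect_true(all(loci$tx_start >= 1))
  expect_true(all(loci$tx_end <= cfg$chromosome_length_bp))
  for (cc in unique(loci$chromosome)) {
    sub <- loci[loci$chromosome == cc, ]
    sub <- sub[order(sub$tx_start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$tx_start[-1] > sub$tx_end[-nrow(sub)]))
    }
  }
  tight <- syn_config(n_genes = 50L, chromosome_length_bp = 1e5,
                      gene_length_range_bp = c(5e3, 1e4))
  expect_error(gen_gene_loci(tight, 1L), "too short")
})

test_that("reference panel dosages match drawn allele frequencies and LD structure", {
  cfg <- syn_config(n_variants = 60L, n_reference_samples = 10000L,
                    ld_block_size = 10L, ld_rho = 0.8)
  panel <- gen_reference_panel(cfg, 5L)
  expect_equal(dim(panel$genotypes), c(10000L, 60L))
  expect_true(all(panel$genotypes %in% 0:2))
  emp_maf <- colMeans(panel$genotypes) / 2
  expect_lt(max(abs(emp_maf - panel$snps$maf)), 0.02)

  # rho = 0: adjacent dosage correlations are noise
  cfg0 <- syn_config(n_variants = 40L, n_reference_samples = 10000L,
                     ld_block_size = 10L, ld_rho = 0)
  g0 <- gen_reference_panel(cfg0, 6L)$genotypes
  adj0 <- sapply(seq_len(39), function(j) cor(g0[, j], g0[, j + 1]))
  expect_lt(max(abs(adj0)), 0.05)

  # rho = 0.8: adjacent dosage correlation matches a direct bivariate
  # threshold-model oracle at the same allele frequencies
  adj <- within_block_adjacent(panel)
  oracle <- mapply(function(f1, f2) dosage_corr_oracle(0.8, f1, f2),
                   adj$maf1, adj$maf2)
  expect_lt(mean(abs(adj$r - oracle)), 0.03)
  expect_gt(mean(adj$r), 0.3)  # strong LD survives thresholding, attenuated
})

test_that("summary statistics are calibrated under the null and loaded at causal SNPs", {
  cfg <- syn_config(n_genes = 10L, n_variants = 4000L, lambda = 0,
                    causal_fraction = 0, n_reference_samples = 50L,
                    chromosome_length_bp = 2e6)
  loci <- gen_gene_loci(cfg, 1L)
  panel <- gen_reference_panel(cfg, 2L)
  frac <- sapply(1:10, function(s)
    mean(gen_summary_stats(cfg, loci, panel, s)$variants$p_value < 0.05))
  sigma <- sqrt(0.05 * 0.95 / 4000)
  expect_true(all(abs(frac - 0.05) < 3 * sigma + 0.01))

  cfg6 <- syn_config(n_genes = 10L, n_variants = 2000L, lambda = 6,
                     causal_fraction = 0.5, n_reference_samples = 50L,
                     chromosome_length_bp = 2e6)
  loci6 <- gen_gene_loci(cfg6, 3L)
  panel6 <- gen_reference_panel(cfg6, 4L)
  z_abs <- unlist(lapply(1:12, function(s) {
    ss <- gen_summary_stats(cfg6, loci6, panel6, s)
    idx <- match(unlist(ss$manifest$causal_snp), ss$variants$variant_id)
    qnorm(ss$variants$p_value[idx] / 2, lower.tail = FALSE)
  }))
  # causal |z| ~ |N(lambda, 1)|, so the mean is close to lambda
  expect_equal(mean(z_abs), 6, tolerance = 0.1)
  # causal SNPs sit inside their gene's window
  ss1 <- gen_summary_stats(cfg6, loci6, panel6, 1)
  for (g in ss1$manifest$causal_genes) {
    snp <- ss1$manifest$causal_snp[[g]]
    v <- ss1$variants[ss1$variants$variant_id == snp, ]
    lr <- loci6[loci6$gene_symbol == g, ]
    expect_true(v$chromosome == lr$chromosome &
                v$position >= lr$tx_start - cfg6$flank_bp &
                v$position <= lr$tx_end + cfg6$flank_bp)
  }
})

test_that("the phenotype fixture plants classes, unlinked records and duplicates as configured", {
  cfg <- small_syn_config()
  fx <- gen_omim_fixture(cfg, seed = 9L)
  man <- fx$manifest
  expect_equal(sum(man$kind == "linked"), cfg$n_genes)
  expect_equal(sum(man$kind == "unlinked"), cfg$n_omim_extra_unlinked)
  expect_equal(sum(man$kind == "none"), cfg$n_omim_none)
  expect_equal(sum(man$kind == "duplicate"), cfg$n_omim_duplicates)
  expect_true(all(lengths(man$classes[man$kind == "none"]) == 0))
  expect_true(all(lengths(man$classes[man$kind != "none"]) >= 1))
  # morbidmap covers exactly the linked records
  mm <- read_morbidmap(fx$morbidmap_text)
  expect_setequal(mm$mim_id, man$mim_id[man$kind %in% c("linked", "duplicate")])
  # zero-record degenerate case parses to empty outputs
  cfg0 <- syn_config(n_genes = 1L, n_omim_extra_unlinked = 0L,
                     n_omim_none = 0L, n_omim_duplicates = 0L)
  fx0 <- gen_omim_fixture(cfg0, 1L, gene_symbols = character())
  expect_equal(nrow(parse_omim_records(fx0$records_text)), 0L)
  expect_equal(nrow(read_morbidmap(fx0$morbidmap_text)), 0L)
})

test_that("annotation catalogs deduplicate genes and plant a recoverable enriched term", {
  cfg <- syn_config(catalog_n_terms = 30L, catalog_universe_size = 1000L,
                    catalog_enriched_fold = 10)
  genes <- sprintf("GENE%03d", 1:100)
  causal <- genes[1:10]
  cat_gen <- gen_annotation_catalog(cfg, genes, causal, seed = 4L)
  expect_true(all(vapply(cat_gen$catalog$terms,
                         function(t) !anyDuplicated(t$genes), logical(1))))
  expect_true(all(cat_gen$manifest$planted_genes %in% causal))
  res <- overrep_test(causal, cat_gen$catalog)
  expect_equal(res$term_id[1], cat_gen$manifest$enriched_term)
  # null catalog: no planted term, no catalog-wide Bonferroni significance
  null_gen <- gen_annotation_catalog(cfg, genes, character(), seed = 4L)
  expect_true(is.na(null_gen$manifest$enriched_term))
})
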