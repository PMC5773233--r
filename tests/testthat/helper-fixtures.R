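# Shared fixture builders. Everything is generated in code; no binary data.

tiny_omim_text <- function() {
  paste(
    "*RECORD*",
    "*FIELD* NO",
    "100001",
    "*FIELD* TI",
    "#100001 FIRST SYNDROME",
    "*FIELD* CS",
    "Severe myopia; cataract;",
    "*RECORD*",
    "*FIELD* NO",
    "100002",
    "*FIELD* TI",
    "#100002 SECOND SYNDROME",
    "*FIELD* CS",
    "myopic astigmatism and hypermetropia;",
    "*RECORD*",
    "*FIELD* NO",
    "100003",
    "*FIELD* TI",
    "#100003 THIRD SYNDROME, NO SYNOPSIS",
    sep = "\n")
}

tiny_loci <- function() {
  data.frame(
    gene_symbol = c("G1", "G2", "G3"),
    chromosome = c("1", "1", "2"),
    tx_start = c(100000L, 190000L, 500000L),
    tx_end = c(120000L, 240000L, 520000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
}

tiny_variants <- function() {
  data.frame(
    variant_id = sprintf("rs%d", 1:6),
    chromosome = c("1", "1", "1", "1", "2", "2"),
    position = c(50000L, 100000L, 170000L, 300000L, 510000L, 900000L),
    p_value = c(0.5, 0.04, 0.2, 0.9, 1e-6, 0.3),
    maf = c(0.1, 0.2, 0.3, 0.4, 0.05, NA),
    stringsAsFactors = FALSE)
}

# brute-force one-sided binomial upper tail, the independent oracle
bf_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# brute-force (variant, window) membership scan
bf_select <- function(variants, windows) {
  hits <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    variants$variant_id[variants$chromosome == w$chromosome &
                        variants$position >= w$start &
                        variants$position <= w$end]
  })
  names(hits) <- windows$gene_symbol
  hits
}

random_instance <- function(seed, n_var = 200, n_win = 20, chroms = c("1", "2")) {
  set.seed(seed)
  variants <- data.frame(
    variant_id = sprintf("v%04d", seq_len(n_var)),
    chromosome = sample(chroms, n_var, replace = TRUE),
    position = sample.int(1e6, n_var, replace = TRUE),
    p_value = runif(n_var),
    maf = runif(n_var, 0.01, 0.5),
    stringsAsFactors = FALSE)
  start <- sample.int(1e6, n_win, replace = TRUE)
  windows <- data.frame(
    chromosome = sample(chroms, n_win, replace = TRUE),
    start = start,
    end = start + sample.int(2e5, n_win, replace = TRUE),
    gene_symbol = sprintf("g%03d", seq_len(n_win)),
    stringsAsFactors = FALSE)
  list(variants = variants, windows = windows)
}

small_syn_config <- function(...) {
  syn_config(n_genes = 10L, n_variants = 500L, n_reference_samples = 50L,
             chromosome_length_bp = 2e6, n_omim_extra_unlinked = 3L,
             n_omim_none = 2L, n_omim_duplicates = 2L, ...)
}

# adjacent same-block SNP pairs of a reference panel, with dosage correlation
within_block_adjacent <- function(panel) {
  m <- nrow(panel$snps)
  same <- panel$snps$block[-m] == panel$snps$block[-1]
  j <- which(same)
  data.frame(
    r = sapply(j, function(k) cor(panel$genotypes[, k],
                                  panel$genotypes[, k + 1])),
    maf1 = panel$snps$maf[j], maf2 = panel$snps$maf[j + 1])
}

# independent Monte-Carlo oracle for the dosage correlation implied by the
# latent threshold model: bivariate normal latents at correlation rho,
# binarized at each SNP's frequency, summed over two haplotype copies
dosage_corr_oracle <- function(rho, f1, f2, n = 2e5, seed = 1234) {
  set.seed(seed)
  dose <- function() {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(z1 < qnorm(f1), z2 < qnorm(f2))
  }
  d <- dose() + dose()
  cor(d[, 1], d[, 2])
}
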