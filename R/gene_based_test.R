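#' Estimate a local LD matrix from a reference genotype panel
#'
#' Pairwise product-moment correlations of genotype dosages, the standard
#' summary of linkage disequilibrium used by gene-based tests. The estimate
#' is repaired to positive semi-definiteness when sampling noise pushes an
#' eigenvalue below zero: eigenvalues are clipped at 1e-8, the matrix is
#' reconstructed and re-normalized to unit diagonal.
#'
#' @param genotypes numeric sample-by-SNP matrix of dosages in [0, 2].
#' @param snp_ids SNP identifiers; default column names.
#' @return object of class \code{"ld_matrix"}: list with \code{snp_ids},
#'   \code{r} (correlation matrix) and \code{n_samples}.
#' @export
ld_from_panel <- function(genotypes, snp_ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L) stop_arg("need at least 2 reference samples")
  if (any(genotypes < 0 | genotypes > 2, na.rm = TRUE)) {
    stop_arg("dosages must lie in [0, 2]")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  vars <- apply(genotypes, 2L, stats::var)
  if (any(vars == 0)) {
    stop_arg("zero-variance (monomorphic) SNP(s): ",
             paste(snp_ids[vars == 0], collapse = ", "),
             "; drop monomorphic SNPs before LD estimation")
  }
  r <- stats::cor(genotypes)
  r <- repair_psd(r)
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r = r, n_samples = nrow(genotypes)),
            class = "ld_matrix")
}

#' @keywords internal
repair_psd <- function(r, tol = 1e-8) {
  eg <- eigen(r, symmetric = TRUE)
  if (min(eg$values) >= tol) return(r)
  vals <- pmax(eg$values, tol)
  m <- eg$vectors %*% (vals * t(eg$vectors))
  stats::cov2cor(m)
}

as_ld_matrix <- function(x) {
  if (inherits(x, "ld_matrix")) return(x)
  r <- as.matrix(x)
  ids <- colnames(r) %||% paste0("snp", seq_len(ncol(r)))
  structure(list(snp_ids = ids, r = repair_psd(r), n_samples = NA_integer_),
            class = "ld_matrix")
}

#' Gene-level sum-of-chi-squared statistic
#'
#' Converts each SNP's two-sided association p-value to a 1-df chi-squared
#' value via the upper-tail quantile function (the z-squared equivalence)
#' and sums over the gene's SNPs. Signed effect estimates must be reduced to
#' p-values first. p-values of exactly 0 or 1 are clamped to the
#' representable open interval with a warning.
#'
#' @param p_values vector of per-SNP p-values in (0, 1).
#' @return the statistic T = sum of chi-squared(1) quantiles.
#' @examples
#' gene_statistic(0.3173)  # about 1
#' @export
gene_statistic <- function(p_values) {
  if (!length(p_values)) stop_arg("no p-values supplied")
  if (any(is.na(p_values))) stop_arg("NA p-value")
  eps <- .Machine$double.xmin
  if (any(p_values <= 0 | p_values >= 1)) {
    warning("p-value(s) at or beyond (0, 1) clamped", call. = FALSE)
    p_values <- pmin(pmax(p_values, eps), 1 - .Machine$double.eps / 2)
  }
  sum(stats::qchisq(p_values, df = 1, lower.tail = FALSE))
}

#' Adaptive simulation plan for the gene-based null
#'
#' Stage sizes for the Monte-Carlo null, escalating while the number of null
#' statistics at or above the observed one is still below \code{min_tail}
#' (precision grows only where the p-value is small enough to need it).
#'
#' @param stages strictly increasing simulation counts.
#' @param min_tail escalate while fewer than this many null exceedances.
#' @param seed master seed; per-gene seeds are offset by gene index so
#'   results do not depend on gene ordering.
#' @return object of class \code{"simulation_plan"}.
#' @export
simulation_plan <- function(stages = c(1e3, 1e4, 1e5, 1e6), min_tail = 10L,
                            seed = 1L) {
  stages <- as.numeric(stages)
  if (!length(stages) || any(diff(stages) <= 0)) {
    stop_arg("stage sizes must be strictly increasing")
  }
  structure(list(stages = stages, min_tail = as.integer(min_tail),
                 seed = as.integer(seed)), class = "simulation_plan")
}

#' Simulate the LD-aware null distribution of the gene statistic
#'
#' Draws zero-mean multivariate normal vectors with covariance equal to the
#' LD correlation matrix (factorized once) and returns the sum of squares of
#' each draw — the null law of the sum-of-chi-squared statistic when the
#' per-SNP z-scores are correlated according to local LD.
#'
#' @param ld an \code{ld_matrix} (or plain correlation matrix).
#' @param n_sims number of draws (>= 1).
#' @param seed RNG seed.
#' @return numeric vector of simulated statistics.
#' @export
simulate_null <- function(ld, n_sims, seed = 1L) {
  ld <- as_ld_matrix(ld)
  stopifnot(n_sims >= 1)
  k <- ncol(ld$r)
  L <- t(tryCatch(chol(ld$r), error = function(e)
    chol(ld$r + diag(1e-8, k))))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(k * n_sims), nrow = k)
  colSums((L %*% z)^2)
}

#' Empirical gene-level p-value by adaptive Monte-Carlo
#'
#' Empirical p-value with add-one smoothing,
#' \code{(#\{T* >= T\} + 1) / (n_sims + 1)}, escalating through the plan's
#' stage sizes while fewer than \code{min_tail} null statistics reach the
#' observed value.
#'
#' @param statistic observed statistic T (>= 0).
#' @param ld the gene's LD matrix.
#' @param plan a \code{\link{simulation_plan}}; its seed drives the draws.
#' @param seed optional override of the plan seed for this gene.
#' @return list with \code{statistic}, \code{n_snps}, \code{n_simulations},
#'   \code{p_empirical}, \code{tail_count}, \code{converged}.
#' @export
gene_pvalue <- function(statistic, ld, plan = simulation_plan(),
                        seed = NULL) {
  stopifnot(statistic >= 0)
  ld <- as_ld_matrix(ld)
  seed <- seed %||% plan$seed
  n_used <- tail_ct <- 0
  for (s in seq_along(plan$stages)) {
    n_used <- plan$stages[s]
    t_star <- simulate_null(ld, n_used, seed = seed + (s - 1L))
    tail_ct <- sum(t_star >= statistic)
    if (tail_ct >= plan$min_tail) break
  }
  list(statistic = statistic, n_snps = ncol(ld$r),
       n_simulations = n_used,
       p_empirical = (tail_ct + 1) / (n_used + 1),
       tail_count = tail_ct,
       converged = tail_ct >= plan$min_tail ||
         n_used == plan$stages[length(plan$stages)])
}

#' Run the LD-aware gene-based test over a window selection
#'
#' For each gene window: match its variants into the reference panel, drop
#' panel-missing and monomorphic SNPs (tallied), estimate local LD, compute
#' the sum-of-chi-squared statistic from the GWAS p-values and obtain an
#' empirical p-value from the LD-matched multivariate-normal null. The
#' summary counts genes reaching nominal significance and feeds that count
#' into the one-sided binomial enrichment test at p0 = alpha.
#'
#' @param selection a \code{window_selection}.
#' @param panel a reference panel: list with \code{genotypes} (sample-by-SNP
#'   dosage matrix, SNP ids as column names), e.g. from
#'   \code{\link{gen_reference_panel}} or \code{\link{read_panel}}.
#' @param plan a \code{\link{simulation_plan}}; per-gene seeds are
#'   \code{plan$seed + gene index} in alphabetical gene order.
#' @param alpha nominal significance level for the summary (default 0.05).
#' @return object of class \code{"gene_test_results"}: list with
#'   \code{results} (data frame gene_symbol, n_snps, statistic,
#'   n_simulations, p_empirical, converged), \code{omitted} (genes with no
#'   usable SNP), \code{n_dropped_snps} and \code{summary} (n_genes,
#'   n_significant, alpha, enrichment: an \code{enrichment_test}).
#' @export
run_gene_tests <- function(selection, panel, plan = simulation_plan(),
                           alpha = 0.05) {
  stopifnot(inherits(selection, "window_selection"))
  geno <- panel$genotypes
  v <- selection$variants
  genes <- names(selection$per_gene)
  rows <- vector("list", length(genes))
  omitted <- character()
  dropped <- 0L
  for (gi in seq_along(genes)) {
    idx <- selection$per_gene[[gi]]
    ids <- v$variant_id[idx]
    present <- ids %in% colnames(geno)
    dropped <- dropped + sum(!present)
    ids <- ids[present]
    if (length(ids)) {
      sub <- geno[, ids, drop = FALSE]
      mono <- apply(sub, 2L, stats::var) == 0
      dropped <- dropped + sum(mono)
      ids <- ids[!mono]
    }
    if (!length(ids)) {
      omitted <- c(omitted, genes[gi])
      next
    }
    ld <- ld_from_panel(geno[, ids, drop = FALSE], ids)
    t_obs <- gene_statistic(v$p_value[idx][present][!mono])
    res <- gene_pvalue(t_obs, ld, plan, seed = plan$seed + gi)
    rows[[gi]] <- data.frame(gene_symbol = genes[gi], n_snps = length(ids),
                             statistic = t_obs,
                             n_simulations = res$n_simulations,
                             p_empirical = res$p_empirical,
                             converged = res$converged,
                             stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results)) {
    results <- data.frame(gene_symbol = character(), n_snps = integer(),
                          statistic = numeric(), n_simulations = numeric(),
                          p_empirical = numeric(), converged = logical(),
                          stringsAsFactors = FALSE)
  }
  rownames(results) <- NULL
  n_sig <- sum(results$p_empirical < alpha)
  enr <- if (nrow(results)) {
    binomial_enrichment_test(n_sig, nrow(results), alpha)
  }
  structure(list(results = results, omitted = omitted,
                 n_dropped_snps = dropped,
                 summary = list(n_genes = nrow(results),
                                n_significant = n_sig, alpha = alpha,
                                enrichment = enr)),
            class = "gene_test_results")
}

#' @export
print.gene_test_results <- function(x, ...) {
  cat("LD-aware gene-based association test\n")
  cat(sprintf("  %d genes tested (%d omitted, %d SNPs dropped)\n",
              x$summary$n_genes, length(x$omitted), x$n_dropped_snps))
  cat(sprintf("  %d genes with empirical p < %.3g\n",
              x$summary$n_significant, x$summary$alpha))
  if (!is.null(x$summary$enrichment)) {
    cat(sprintf("  gene-count enrichment P %s\n",
                format_pvalue(x$summary$enrichment$p_binomial)))
  }
  invisible(x)
}

#' Read a reference genotype panel
#'
#' Plain tab-delimited sample-by-SNP dosage matrix with a header of SNP ids
#' and optional first column of sample ids.
#'
#' @param x file path or character text.
#' @return list with \code{genotypes} matrix (samples x SNPs).
#' @export
read_panel <- function(x) {
  df <- utils::read.delim(
    text = paste(read_lines_arg(x), collapse = "\n"),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) && !is.numeric(df[[1L]])) {
    rownames(df) <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  list(genotypes = as.matrix(df))
}
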