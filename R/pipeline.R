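#' Configuration for a full pipeline run
#'
#' Collects every tunable the pipeline stages need. Inputs come either from
#' files (\code{paths}) or from the synthetic generators
#' (\code{synthetic}); exactly one must be supplied. Defaults mirror the
#' usual analysis settings: a 50 kb flank, MAF > 0.01, nominal alpha 0.05
#' and a 1E-04 reporting threshold for top-hit-only GWAS files.
#'
#' @param synthetic a \code{\link{syn_config}}, or \code{NULL}.
#' @param paths named list of input files (\code{omim}, \code{morbidmap},
#'   \code{gene_ids}, \code{loci}, \code{summary_stats}, optionally
#'   \code{panel}, \code{gmt}, \code{lexicon}), or \code{NULL}.
#' @param flank_bp window flank in bp.
#' @param min_maf minimum minor allele frequency (strict).
#' @param alpha nominal significance level.
#' @param autosomal_only drop X/Y/MT candidate genes before windowing.
#' @param gene_set which mined gene set supplies the candidates (default
#'   \code{"all-ametropia"}, the union over refractive classes).
#' @param tophit_threshold reporting threshold of top-hit-only GWAS files.
#' @param n_window_estimate denominator for top-hit mode: the (conservative)
#'   count of reference-panel variants within the candidate windows.
#' @param plan a \code{\link{simulation_plan}} for the gene-based test.
#' @param seed master seed for synthetic inputs.
#' @param stages which stages to execute after mining/windowing; any of
#'   \code{"genetest"}, \code{"overrep"} (the mining, window and enrichment
#'   stages always run).
#' @param out_dir optional run directory for stage outputs.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(synthetic = NULL, paths = NULL,
                       flank_bp = 50000, min_maf = 0.01, alpha = 0.05,
                       autosomal_only = TRUE, gene_set = "all-ametropia",
                       tophit_threshold = 1e-4, n_window_estimate = NULL,
                       plan = simulation_plan(), seed = 1L,
                       stages = c("genetest", "overrep"),
                       out_dir = NULL) {
  if (is.null(synthetic) == is.null(paths)) {
    stop_arg("supply exactly one of `synthetic` or `paths`")
  }
  stopifnot(flank_bp >= 0, alpha > 0, alpha < 1,
            tophit_threshold > 0, tophit_threshold < 1)
  structure(as.list(environment()), class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    cs <- config$synthetic
    seed <- config$seed
    loci <- gen_gene_loci(cs, seed)
    panel <- gen_reference_panel(cs, seed + 1L)
    ss <- gen_summary_stats(cs, loci, panel, seed + 2L)
    omim <- gen_omim_fixture(cs, seed + 3L, gene_symbols = loci$gene_symbol)
    cat_gen <- gen_annotation_catalog(cs, loci$gene_symbol,
                                      ss$manifest$causal_genes, seed + 4L)
    list(records = omim$records_text, morbidmap = omim$morbidmap_text,
         gene_ids = omim$gene_id_text, loci = loci,
         variants = ss$variants, panel = panel, catalog = cat_gen$catalog,
         lexicon = default_lexicon(),
         manifest = list(stats = ss$manifest, omim = omim$manifest,
                         catalog = cat_gen$manifest))
  } else {
    p <- config$paths
    lex <- if (!is.null(p$lexicon)) read_lexicon(p$lexicon)
           else default_lexicon()
    list(records = p$omim, morbidmap = p$morbidmap, gene_ids = p$gene_ids,
         loci = read_gene_loci(p$loci),
         variants = read_summary_stats(p$summary_stats),
         panel = if (!is.null(p$panel)) read_panel(p$panel),
         catalog = if (!is.null(p$gmt)) read_gmt(p$gmt),
         lexicon = lex, manifest = NULL)
  }
}

#' Run the full enrichment pipeline
#'
#' Executes, in order: phenotype mining, candidate-window construction,
#' variant selection with MAF filtering, the SNP-count enrichment tests
#' (nominal and experiment-wise, with QQ/Manhattan data), then optionally
#' the LD-aware gene-based test and the annotation-term overrepresentation
#' screen. Deterministic for fixed inputs and seeds; when \code{out_dir} is
#' set, every stage output is written under it with fixed names.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{"run_report"}: nested list with per-stage
#'   counts, all test results, the software version and a config echo.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_run_inputs(config)

  mining <- mine_phenotypes(inputs$records, inputs$morbidmap,
                            inputs$gene_ids, inputs$lexicon, inputs$loci)
  gset <- mining$gene_sets[[config$gene_set]]
  if (is.null(gset)) {
    stop_arg("stage mine: no gene set named '", config$gene_set, "'")
  }
  loci <- inputs$loci[inputs$loci$gene_symbol %in% gset$gene_symbols, ,
                      drop = FALSE]
  n_unlocated <- length(setdiff(gset$gene_symbols, loci$gene_symbol))
  excluded <- NULL
  if (config$autosomal_only) {
    part <- filter_autosomal(loci)
    loci <- part$autosomal
    excluded <- part$excluded
  }
  if (!nrow(loci)) stop_arg("stage windows: no candidate loci left")

  windows <- make_windows(loci, config$flank_bp)
  variants <- filter_maf(inputs$variants, config$min_maf)
  selection <- select_variants(variants, windows)
  n_sel <- nrow(selection$variants)
  if (!n_sel) stop_arg("stage select: no variants fall in any window")

  thr <- experiment_wise_threshold(n_sel)
  k_nom <- count_exceedances(selection, config$alpha)
  k_exp <- count_exceedances(selection, thr)
  enrichment <- list(
    n_selected = n_sel,
    nominal = binomial_enrichment_test(k_nom, n_sel, config$alpha),
    experiment_wise = binomial_enrichment_test(k_exp, n_sel, thr),
    experiment_wise_threshold = thr,
    qq = qq_data(selection$variants$p_value),
    manhattan = manhattan_data(selection, config$alpha, thr))

  gene_tests <- NULL
  if ("genetest" %in% config$stages && !is.null(inputs$panel)) {
    gene_tests <- run_gene_tests(selection, inputs$panel, config$plan,
                                 config$alpha)
  }
  overrep <- NULL
  if ("overrep" %in% config$stages && !is.null(inputs$catalog)) {
    res <- suppressWarnings(overrep_test(gset, inputs$catalog))
    overrep <- list(results = res,
                    highly_enriched = filter_highly_enriched(res))
  }

  report <- structure(list(
    counts = list(
      records_parsed = mining$report$n_records,
      phenotypes_classified = mining$report$n_classified,
      phenotypes_linked = mining$report$n_linked_phenotypes,
      phenotypes_skipped = mining$report$n_skipped,
      candidate_genes = length(gset$gene_symbols),
      genes_unlocated = n_unlocated,
      genes_excluded_nonautosomal = if (is.null(excluded)) 0L
                                    else nrow(excluded),
      windows = nrow(windows),
      variants_selected = n_sel,
      exceedances_nominal = k_nom,
      exceedances_experiment_wise = k_exp,
      genes_tested = if (is.null(gene_tests)) NA_integer_
                     else gene_tests$summary$n_genes,
      significant_terms = if (is.null(overrep)) NA_integer_
                          else nrow(overrep$highly_enriched)),
    mining = mining$report,
    gene_set = gset,
    enrichment = enrichment,
    gene_tests = gene_tests,
    overrep = overrep,
    manifest = inputs$manifest,
    version = as.character(utils::packageVersion("mendelEnrich")),
    config = config[setdiff(names(config), "synthetic")]
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, selection, config)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Candidate-gene GWAS enrichment run\n")
  c_ <- x$counts
  cat(sprintf("  phenotypes: %d parsed, %d classified, %d linked (%d skipped)\n",
              c_$records_parsed, c_$phenotypes_classified,
              c_$phenotypes_linked, c_$phenotypes_skipped))
  cat(sprintf("  candidates: %d genes -> %d windows -> %d variants\n",
              c_$candidate_genes, c_$windows, c_$variants_selected))
  e <- x$enrichment
  cat(sprintf("  nominal: %d observed vs %.4g expected, P %s\n",
              e$nominal$observed, e$nominal$expected,
              format_pvalue(e$nominal$p_binomial)))
  cat(sprintf("  experiment-wise (P < %.3g): %d observed, P %s\n",
              e$experiment_wise_threshold, e$experiment_wise$observed,
              format_pvalue(e$experiment_wise$p_binomial)))
  if (!is.null(x$gene_tests)) {
    cat(sprintf("  gene-based: %d of %d genes at p < %.3g, P %s\n",
                x$gene_tests$summary$n_significant,
                x$gene_tests$summary$n_genes, x$gene_tests$summary$alpha,
                format_pvalue(x$gene_tests$summary$enrichment$p_binomial)))
  }
  if (!is.null(x$overrep)) {
    cat(sprintf("  overrepresentation: %d highly enriched term(s)\n",
                nrow(x$overrep$highly_enriched)))
  }
  invisible(x)
}

write_run_outputs <- function(report, selection, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_tsv_file(selection$variants, out("selected_variants.tsv"))
  write_json_file(lapply(selection$per_gene, function(ix)
    selection$variants$variant_id[ix]), out("per_gene_variants.json"))
  write_tsv_file(as.data.frame(report$enrichment$qq), out("qq_data.tsv"))
  write_tsv_file(report$enrichment$manhattan, out("manhattan_data.tsv"))
  if (!is.null(report$gene_tests)) {
    write_tsv_file(report$gene_tests$results, out("gene_tests.tsv"))
  }
  if (!is.null(report$overrep)) {
    write_tsv_file(as.data.frame(report$overrep$results),
                   out("overrepresentation.tsv"))
  }
  enr <- report$enrichment
  write_json_file(list(
    counts = report$counts,
    nominal = unclass(enr$nominal)[c("observed", "n_tests", "p0", "expected",
                                     "fold", "p_binomial", "p_is_bound")],
    experiment_wise = unclass(enr$experiment_wise)[
      c("observed", "n_tests", "p0", "expected", "fold", "p_binomial",
        "p_is_bound")],
    version = report$version), out("run_report.json"))
  invisible(config$out_dir)
}

#' Enrichment test for top-hit-only GWAS files
#'
#' Some GWAS releases list only the variants below a reporting threshold
#' (for example, every variant with P < 1E-04). Enrichment is then assessed
#' by counting the reported hits that fall inside the candidate windows and
#' comparing against \code{n_window_estimate * threshold}, where
#' \code{n_window_estimate} is the number of reference-panel variants within
#' the windows — an overestimate of the variants actually tested, hence a
#' conservative upper bound on the denominator (and the resulting p-value).
#' Sex chromosomes are kept, matching GWAS panels that include X.
#'
#' @param config a \code{\link{run_config}} whose \code{paths} (or direct
#'   arguments below) supply the inputs; \code{n_window_estimate} is
#'   required.
#' @param variants optional pre-loaded top-hit summary-statistic data frame.
#' @param loci optional pre-loaded candidate gene loci.
#' @return object of class \code{"tophit_report"}: list with
#'   \code{observed}, \code{n_window_estimate}, \code{threshold},
#'   \code{expected}, \code{test} (an \code{enrichment_test}),
#'   \code{per_gene_counts} and \code{denominator_note}.
#' @export
run_tophit_mode <- function(config, variants = NULL, loci = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$n_window_estimate)) {
    stop_arg("top-hit mode needs n_window_estimate: the count of reference",
             " variants within the candidate windows")
  }
  if (is.null(variants)) variants <- read_summary_stats(
    config$paths$summary_stats)
  if (is.null(loci)) loci <- read_gene_loci(config$paths$loci)
  thr <- config$tophit_threshold
  if (any(variants$p_value >= thr)) {
    warning("top-hit file contains p-values at or above the reporting ",
            "threshold; they are not counted", call. = FALSE)
  }
  windows <- make_windows(loci, config$flank_bp)
  selection <- select_variants(variants, windows)
  observed <- count_exceedances(selection, thr)
  test <- binomial_enrichment_test(observed, config$n_window_estimate, thr)
  structure(list(
    observed = observed,
    n_window_estimate = config$n_window_estimate,
    threshold = thr,
    expected = test$expected,
    test = test,
    per_gene_counts = lengths(selection$per_gene),
    denominator_note = paste("conservative upper bound: full reference",
                             "variant list, not the subset actually tested")
  ), class = "tophit_report")
}

#' @export
print.tophit_report <- function(x, ...) {
  cat("Top-hit enrichment (reporting threshold P <",
      format(x$threshold), ")\n")
  cat(sprintf("  observed %d in-window hits vs %.3g expected of %d (%s)\n",
              x$observed, x$expected, x$n_window_estimate,
              x$denominator_note))
  cat("  binomial P", format_pvalue(x$test$p_binomial), "\n")
  invisible(x)
}
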