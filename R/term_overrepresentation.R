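#' Read an annotation catalog from a GMT file
#'
#' GMT dialect: one term per line, tab-delimited as term id, description,
#' then the annotated gene symbols. The reference universe defaults to the
#' union of all annotated genes but can be supplied explicitly (e.g. all
#' protein-coding genes).
#'
#' @param x file path or character text.
#' @param universe optional character vector of reference gene symbols.
#' @return object of class \code{"annotation_catalog"}: list with
#'   \code{terms} (named list of \code{list(name, genes)}) and
#'   \code{universe}.
#' @export
read_gmt <- function(x, universe = NULL) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop_arg("GMT line needs >= 3 fields: ", ln)
    genes <- unique(parts[-(1:2)])
    terms[[parts[1L]]] <- list(name = parts[2L],
                               genes = genes[nzchar(genes)])
  }
  annotation_catalog(terms, universe)
}

#' @rdname read_gmt
#' @param terms named list of \code{list(name, genes)}.
#' @export
annotation_catalog <- function(terms, universe = NULL) {
  terms <- lapply(terms, function(t) {
    t$genes <- unique(as.character(t$genes))
    t
  })
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(terms, `[[`, "genes"),
                              use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  outside <- setdiff(unlist(lapply(terms, `[[`, "genes"), use.names = FALSE),
                     universe)
  if (length(outside)) {
    stop_arg("annotated gene(s) missing from the universe: ",
             paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_catalog")
}

#' Write an annotation catalog to GMT
#' @param catalog an \code{annotation_catalog}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$terms), function(id) {
    t <- catalog$terms[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Annotation-term overrepresentation test
#'
#' For each catalog term with at least one query hit, compares the observed
#' number of query genes annotated to the term with the null expectation
#' \code{n_query * |term| / |universe|}. The default p-value is the
#' one-sided binomial upper tail of the observed count given
#' \code{Binomial(n_query, |term|/|universe|)} — the classical
#' overrepresentation construction — with an exact hypergeometric
#' (sampling-without-replacement) alternative behind a flag. Raw p-values
#' are Bonferroni-corrected across the terms actually tested; terms with no
#' query hit are neither tested nor counted in the correction (settable via
#' \code{test_zero_hits}).
#'
#' @param query character vector of gene symbols, or a gene-set list with a
#'   \code{gene_symbols} field.
#' @param catalog an \code{annotation_catalog}.
#' @param method \code{"binomial"} (default) or \code{"hypergeometric"}.
#' @param test_zero_hits also test (and correct for) terms with zero query
#'   hits; default \code{FALSE}.
#' @return data frame of class \code{"overrep_results"} with columns
#'   \code{term_id}, \code{term_name}, \code{n_term}, \code{observed},
#'   \code{expected}, \code{fold}, \code{p_raw}, \code{p_corrected}, sorted
#'   by \code{p_raw}; attributes \code{n_query_mapped} and
#'   \code{n_terms_tested}.
#' @export
overrep_test <- function(query, catalog,
                         method = c("binomial", "hypergeometric"),
                         test_zero_hits = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!length(catalog$universe)) stop_arg("empty reference universe")
  if (is.list(query)) query <- query$gene_symbols
  query <- unique(as.character(query))
  mapped <- intersect(query, catalog$universe)
  n_drop <- length(query) - length(mapped)
  if (n_drop > 0) {
    warning(n_drop, " query gene(s) not in the universe dropped",
            call. = FALSE)
  }
  nq <- length(mapped)
  u <- length(catalog$universe)

  rows <- lapply(names(catalog$terms), function(id) {
    t <- catalog$terms[[id]]
    obs <- length(intersect(mapped, t$genes))
    if (obs == 0L && !test_zero_hits) return(NULL)
    frac <- length(t$genes) / u
    p_raw <- if (nq == 0L) 1 else if (method == "binomial") {
      stats::pbinom(obs - 1L, nq, frac, lower.tail = FALSE)
    } else {
      stats::phyper(obs - 1L, length(t$genes), u - length(t$genes), nq,
                    lower.tail = FALSE)
    }
    data.frame(term_id = id, term_name = t$name, n_term = length(t$genes),
               observed = obs, expected = nq * frac,
               fold = if (frac > 0 && nq > 0) obs / (nq * frac) else NaN,
               p_raw = p_raw, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), term_name = character(),
               n_term = integer(), observed = integer(), expected = numeric(),
               fold = numeric(), p_raw = numeric(), stringsAsFactors = FALSE)
  out$p_corrected <- pmin(1, out$p_raw * nrow(out))
  out <- out[order(out$p_raw, -out$fold, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_mapped") <- nq
  attr(out, "n_terms_tested") <- nrow(out)
  class(out) <- c("overrep_results", "data.frame")
  out
}

#' Filter overrepresentation results to strongly enriched terms
#'
#' Keeps terms whose fold enrichment is at least \code{min_fold} and whose
#' corrected p-value is below \code{alpha}, sorted by fold descending —
#' the usual "significant and at least N-fold overrepresented" report.
#'
#' @param results an \code{overrep_results} data frame.
#' @param min_fold minimum fold enrichment (>= 1), default 10.
#' @param alpha corrected-p cutoff, default 0.05.
#' @return the filtered, re-sorted data frame.
#' @export
filter_highly_enriched <- function(results, min_fold = 10, alpha = 0.05) {
  if (min_fold < 1) stop_arg("min_fold must be >= 1")
  keep <- results$fold >= min_fold & results$p_corrected < alpha
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out$fold, out$p_corrected), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample sensitivity of the overrepresentation screen
#'
#' Repeatedly draws uniform random subsets of the query gene set (without
#' replacement), reruns the overrepresentation test plus the high-enrichment
#' filter, and reports how many terms survive per replicate — a measure of
#' how strongly the screened term list depends on gene-set size.
#'
#' @param gene_set character vector (or gene-set list) of query genes.
#' @param subsample_size subset size, <= length of the gene set.
#' @param catalog an \code{annotation_catalog}.
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed (reproducible for a fixed seed).
#' @param min_fold,alpha passed to \code{\link{filter_highly_enriched}}.
#' @param method passed to \code{\link{overrep_test}}.
#' @return list with \code{mean_count} and \code{counts} (per replicate).
#' @export
subsample_sensitivity <- function(gene_set, subsample_size, catalog,
                                  n_reps = 100L, seed = 1L, min_fold = 10,
                                  alpha = 0.05, method = "binomial") {
  if (is.list(gene_set)) gene_set <- gene_set$gene_symbols
  gene_set <- unique(as.character(gene_set))
  if (subsample_size > length(gene_set)) {
    stop_arg("subsample_size exceeds the gene-set size")
  }
  stopifnot(n_reps >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- vapply(seq_len(n_reps), function(i) {
    sub <- sample(gene_set, subsample_size)
    res <- suppressWarnings(overrep_test(sub, catalog, method = method))
    nrow(filter_highly_enriched(res, min_fold, alpha))
  }, integer(1))
  list(mean_count = mean(counts), counts = counts)
}
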