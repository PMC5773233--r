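#' Expected count of sub-threshold tests under the null
#'
#' Under the null hypothesis that candidate-region variants are no more often
#' associated than chance, the expected number of tests attaining p-values
#' below a cutoff \code{p0} is \code{n_tests * p0}. The rounded value (half
#' away from zero) is what summary tables usually print.
#'
#' @param n_tests number of tests (N >= 0).
#' @param p0 per-test null exceedance probability in [0, 1].
#' @return list with \code{expected} and \code{expected_rounded}.
#' @examples
#' expected_count(24554, 0.05)  # 1227.7, rounded 1228
#' @export
expected_count <- function(n_tests, p0) {
  stopifnot(n_tests >= 0, p0 >= 0, p0 <= 1)
  e <- n_tests * p0
  list(expected = e, expected_rounded = as.integer(round_half_up(e)))
}

#' Experiment-wise significance threshold
#'
#' The per-test p-value cutoff \code{1 / n_tests} at which, under the null,
#' about one of the N tests is expected to pass.
#'
#' @param n_tests number of tests (>= 1).
#' @return the threshold \code{1 / n_tests}, exactly.
#' @export
experiment_wise_threshold <- function(n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop_arg("n_tests must be a single integer >= 1")
  }
  1 / n_tests
}

#' One-sided binomial enrichment test
#'
#' Tests whether an observed count of threshold-exceeding tests is larger
#' than expected by chance: \code{p = P(K >= observed)} for
#' \code{K ~ Binomial(n_tests, p0)}, the exact upper tail evaluated in
#' log-space so that extreme counts keep a finite result. A p-value below
#' double-precision tail resolution is floored at the smallest positive
#' representable double and flagged, and the print method reports such
#' values as a bound ("< 2.2e-16"), never as 0.
#'
#' @param observed observed count k, 0 <= k <= n_tests.
#' @param n_tests number of tests N.
#' @param p0 per-test null exceedance probability, 0 < p0 < 1.
#' @return object of class \code{"enrichment_test"}: list with
#'   \code{observed}, \code{n_tests}, \code{p0}, \code{expected},
#'   \code{expected_rounded}, \code{fold} (observed/expected),
#'   \code{p_binomial}, \code{log_p} (natural log) and \code{p_is_bound}.
#' @examples
#' binomial_enrichment_test(15, 24554, 1 / 24554)
#' @export
binomial_enrichment_test <- function(observed, n_tests, p0) {
  stopifnot(length(observed) == 1L, length(n_tests) == 1L, length(p0) == 1L)
  if (is.na(observed) || observed < 0 || observed > n_tests) {
    stop_arg("observed must satisfy 0 <= observed <= n_tests")
  }
  if (p0 <= 0 || p0 >= 1) stop_arg("p0 must lie strictly in (0, 1)")
  log_p <- if (observed == 0) 0 else
    stats::pbinom(observed - 1, n_tests, p0, lower.tail = FALSE, log.p = TRUE)
  p <- max(exp(log_p), .Machine$double.xmin)
  exp_ct <- expected_count(n_tests, p0)
  structure(list(
    observed = as.integer(observed),
    n_tests = as.integer(n_tests),
    p0 = p0,
    expected = exp_ct$expected,
    expected_rounded = exp_ct$expected_rounded,
    fold = if (exp_ct$expected > 0) observed / exp_ct$expected else NaN,
    p_binomial = p,
    log_p = log_p,
    p_is_bound = p < .Machine$double.eps
  ), class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  p_str <- if (x$p_is_bound) "< 2.2e-16" else
    paste("=", signif(x$p_binomial, 2))
  cat("One-sided binomial enrichment test\n")
  cat(sprintf("  observed %d of %d tests at p0 = %.3g (expected %.4g)\n",
              x$observed, x$n_tests, x$p0, x$expected))
  cat(sprintf("  fold enrichment = %.3g, P %s\n", x$fold, p_str))
  invisible(x)
}

#' Format a p-value the way result tables print it
#'
#' Values below double-precision tail resolution print as the bound
#' \code{"< 2.2e-16"}.
#' @param p numeric p-value(s).
#' @param digits significant digits.
#' @return character vector.
#' @export
format_pvalue <- function(p, digits = 2) {
  ifelse(p < .Machine$double.eps, "< 2.2e-16",
         format(signif(p, digits), scientific = TRUE))
}

#' Count variants exceeding a significance threshold
#'
#' Counts variants in the global (deduplicated) selection with
#' \code{p_value < threshold}; the inequality is strict, matching the usual
#' "exceeded P < alpha" phrasing.
#'
#' @param selection a \code{window_selection} (or any data frame with a
#'   \code{p_value} column).
#' @param threshold p-value cutoff in (0, 1).
#' @return integer count.
#' @export
count_exceedances <- function(selection, threshold) {
  if (threshold <= 0 || threshold >= 1) stop_arg("threshold must be in (0,1)")
  p <- if (inherits(selection, "window_selection")) selection$variants$p_value
       else selection$p_value
  sum(p < threshold)
}

#' QQ-plot data with a null confidence envelope
#'
#' Ordered observed p-values against their uniform-null expectations
#' \code{i/(N+1)}, with a pointwise 95\% envelope per rank from the order-
#' statistic law: the i-th smallest of N uniforms follows Beta(i, N+1-i), so
#' the envelope is that distribution's 2.5\% and 97.5\% quantiles. All
#' quantities also returned on the -log10 scale used for plotting.
#'
#' @param p_values vector of p-values, each in (0, 1].
#' @return data frame of class \code{"qq_data"} with columns
#'   \code{observed}, \code{expected}, \code{lower}, \code{upper} and their
#'   \code{neglog10_*} counterparts, sorted by rank.
#' @export
qq_data <- function(p_values) {
  if (!length(p_values)) stop_arg("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_arg("p-values must lie in (0, 1]")
  }
  n <- length(p_values)
  i <- seq_len(n)
  out <- data.frame(
    observed = sort(p_values),
    expected = i / (n + 1),
    lower = stats::qbeta(0.025, i, n + 1 - i),
    upper = stats::qbeta(0.975, i, n + 1 - i)
  )
  out$neglog10_observed <- -log10(out$observed)
  out$neglog10_expected <- -log10(out$expected)
  out$neglog10_lower <- -log10(out$upper)   # small p <-> large -log10
  out$neglog10_upper <- -log10(out$lower)
  class(out) <- c("qq_data", "data.frame")
  out
}

#' Manhattan-plot data for a window selection
#'
#' Rows (chromosome, position, -log10 p, gene symbol) with a cumulative
#' genome coordinate for plotting, plus the nominal and experiment-wise
#' guide lines as attributes. A variant captured by several windows is
#' labelled with all capturing genes (comma-separated).
#'
#' @param selection a \code{window_selection}.
#' @param nominal_alpha nominal significance guide line (default 0.05).
#' @param experiment_wise experiment-wise guide line; default
#'   \code{1/nrow(selection$variants)}.
#' @return data frame with attributes \code{nominal_alpha} and
#'   \code{experiment_wise}.
#' @export
manhattan_data <- function(selection, nominal_alpha = 0.05,
                           experiment_wise = NULL) {
  stopifnot(inherits(selection, "window_selection"))
  v <- selection$variants
  if (!nrow(v)) stop_arg("empty selection")
  if (is.null(experiment_wise)) {
    experiment_wise <- experiment_wise_threshold(nrow(v))
  }
  genes <- rep("", nrow(v))
  for (g in names(selection$per_gene)) {
    ix <- selection$per_gene[[g]]
    genes[ix] <- ifelse(nzchar(genes[ix]), paste(genes[ix], g, sep = ","), g)
  }
  chrom_levels <- chrom_sort_order(v$chromosome)
  chrom_max <- vapply(chrom_levels,
                      function(cc) max(v$position[v$chromosome == cc]),
                      numeric(1))
  offsets <- stats::setNames(c(0, cumsum(chrom_max))[seq_along(chrom_levels)],
                             chrom_levels)
  out <- data.frame(chromosome = v$chromosome, position = v$position,
                    cumulative_pos = offsets[v$chromosome] + v$position,
                    neglog10_p = -log10(v$p_value), gene_symbol = genes,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cumulative_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nominal_alpha") <- nominal_alpha
  attr(out, "experiment_wise") <- experiment_wise
  out
}

#' Plot a QQ panel with its null envelope
#'
#' @param x a \code{qq_data} object.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @export
plot.qq_data <- function(x, ...) {
  graphics::plot(x$neglog10_expected, x$neglog10_observed,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 pch = 20, ...)
  graphics::polygon(c(x$neglog10_expected, rev(x$neglog10_expected)),
                    c(x$neglog10_lower, rev(x$neglog10_upper)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::points(x$neglog10_expected, x$neglog10_observed, pch = 20)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Plot a Manhattan panel with guide lines
#'
#' @param md data frame from \code{\link{manhattan_data}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{md}.
#' @export
plot_manhattan <- function(md, ...) {
  chroms <- unique(md$chromosome)
  cols <- rep(c("grey30", "steelblue"), length.out = length(chroms))
  graphics::plot(md$cumulative_pos, md$neglog10_p,
                 col = cols[match(md$chromosome, chroms)], pch = 20,
                 xlab = "Cumulative genome position",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(attr(md, "nominal_alpha")), lty = 2)
  graphics::abline(h = -log10(attr(md, "experiment_wise")), lty = 3)
  invisible(md)
}
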