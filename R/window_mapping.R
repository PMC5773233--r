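#' Read a gene-locus table
#'
#' Accepts either a 4/5-column BED file (chrom, start, end, name, [strand];
#' 0-based half-open, converted to 1-based closed on read) or a tab-delimited
#' table with a header containing \code{symbol}, \code{chrom}, \code{start},
#' \code{end} and optionally \code{strand} (1-based closed). Chromosome
#' labels are normalized with \code{\link{normalize_chrom}}.
#'
#' @param x file path or character text.
#' @param format \code{"auto"}, \code{"bed"} or \code{"tsv"}.
#' @return data frame with columns \code{gene_symbol}, \code{chromosome},
#'   \code{tx_start}, \code{tx_end}, \code{strand}.
#' @export
read_gene_loci <- function(x, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(gene_symbol = character(), chromosome = character(),
                      tx_start = integer(), tx_end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (format == "auto") {
    format <- if (any(tolower(first) %in% c("symbol", "gene_symbol"))) "tsv"
              else "bed"
  }
  if (format == "bed") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 4L)) stop_arg("BED loci need >= 4 columns")
    out <- data.frame(
      gene_symbol = vapply(parts, `[`, character(1), 4L),
      chromosome = normalize_chrom(vapply(parts, `[`, character(1), 1L)),
      tx_start = as.integer(vapply(parts, `[`, character(1), 2L)) + 1L,
      tx_end = as.integer(vapply(parts, `[`, character(1), 3L)),
      strand = vapply(parts, function(p) if (length(p) >= 6L) p[6L]
                      else if (length(p) >= 5L && p[5L] %in% c("+", "-")) p[5L]
                      else "*", character(1)),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    sym <- df[[intersect(c("symbol", "gene_symbol"), names(df))[1L]]]
    chrom_col <- intersect(c("chrom", "chromosome", "chr"), names(df))[1L]
    out <- data.frame(gene_symbol = as.character(sym),
                      chromosome = normalize_chrom(df[[chrom_col]]),
                      tx_start = as.integer(df$start),
                      tx_end = as.integer(df$end),
                      strand = as.character(df$strand %||% "*"),
                      stringsAsFactors = FALSE)
  }
  if (any(out$tx_start > out$tx_end)) stop_arg("locus with start > end")
  out
}

#' Read GWAS summary statistics
#'
#' Tab-delimited with a header; columns \code{SNP}, \code{CHR}, \code{POS},
#' \code{P} and optionally \code{MAF} (case-insensitive). Gzipped files are
#' read transparently. Chromosome labels are normalized.
#'
#' @param x file path or character text.
#' @return data frame with columns \code{variant_id}, \code{chromosome},
#'   \code{position}, \code{p_value}, \code{maf} (NA when absent).
#' @export
read_summary_stats <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    df <- utils::read.delim(gzfile(x), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(text = paste(read_lines_arg(x), collapse = "\n"),
                            stringsAsFactors = FALSE)
  }
  names(df) <- toupper(names(df))
  need <- c("SNP", "CHR", "POS", "P")
  if (!all(need %in% names(df))) {
    stop_arg("summary statistics need columns SNP, CHR, POS, P")
  }
  out <- data.frame(variant_id = as.character(df$SNP),
                    chromosome = normalize_chrom(df$CHR),
                    position = as.integer(df$POS),
                    p_value = as.numeric(df$P),
                    maf = if ("MAF" %in% names(df)) as.numeric(df$MAF)
                          else NA_real_,
                    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

validate_variants <- function(v) {
  if (!nrow(v)) return(invisible(v))
  if (any(v$p_value <= 0 | v$p_value > 1, na.rm = TRUE)) {
    stop_arg("variant p-values must lie in (0, 1]")
  }
  if (any(v$position < 1L, na.rm = TRUE)) stop_arg("variant position < 1")
  invisible(v)
}

#' Build flanking windows around gene loci
#'
#' One genomic interval per locus: the transcription span extended by
#' \code{flank_bp} on each side, clipped at position 1, strand ignored.
#' Coordinates are 1-based closed throughout.
#'
#' @param loci data frame from \code{\link{read_gene_loci}}.
#' @param flank_bp non-negative flank size in base pairs (default 50 kb, the
#'   usual reach of regulatory GWAS signals around a gene).
#' @return data frame with columns \code{chromosome}, \code{start},
#'   \code{end}, \code{gene_symbol}.
#' @examples
#' loci <- data.frame(gene_symbol = "G1", chromosome = "1",
#'                    tx_start = 100000L, tx_end = 120000L, strand = "+")
#' make_windows(loci, 50000)
#' @export
make_windows <- function(loci, flank_bp = 50000L) {
  if (length(flank_bp) != 1L || is.na(flank_bp) || flank_bp < 0) {
    stop_arg("flank_bp must be a single non-negative number")
  }
  data.frame(chromosome = loci$chromosome,
             start = pmax(1, loci$tx_start - as.numeric(flank_bp)),
             end = loci$tx_end + as.numeric(flank_bp),
             gene_symbol = loci$gene_symbol,
             stringsAsFactors = FALSE)
}

#' Select summary-statistic variants falling inside gene windows
#'
#' A variant belongs to a gene's list iff it lies on the same chromosome and
#' within the closed window interval (boundaries inclusive). The global list
#' is the deduplicated union over windows — a variant captured by several
#' overlapping gene windows counts once globally but is retained in every
#' capturing gene's per-gene list (those feed the gene-based test). Output
#' ordering is deterministic: (chromosome, position, variant id).
#'
#' @param variants data frame from \code{\link{read_summary_stats}}.
#' @param windows data frame from \code{\link{make_windows}}.
#' @return an object of class \code{"window_selection"}: list with
#'   \code{variants} (global deduplicated data frame), \code{per_gene}
#'   (named list of integer row indices into \code{variants}),
#'   \code{n_genes} and \code{flank_note}.
#' @export
select_variants <- function(variants, windows) {
  stopifnot(is.data.frame(variants), is.data.frame(windows))
  ord <- order(match(variants$chromosome,
                     chrom_sort_order(variants$chromosome)),
               variants$position, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  rownames(v) <- NULL
  wins <- windows[order(windows$gene_symbol), , drop = FALSE]

  per_gene <- stats::setNames(vector("list", nrow(wins)), wins$gene_symbol)
  hit <- logical(nrow(v))
  by_chrom <- split(seq_len(nrow(v)), v$chromosome)
  for (i in seq_len(nrow(wins))) {
    idx <- by_chrom[[wins$chromosome[i]]]
    if (is.null(idx)) { per_gene[[i]] <- integer(); next }
    pos <- v$position[idx]
    lo <- findInterval(wins$start[i] - 1, pos) + 1L
    hi <- findInterval(wins$end[i], pos)
    sel <- if (lo <= hi) idx[lo:hi] else integer()
    per_gene[[i]] <- sel
    hit[sel] <- TRUE
  }
  keep <- which(hit)
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  structure(list(
    variants = {g <- v[keep, , drop = FALSE]; rownames(g) <- NULL; g},
    per_gene = lapply(per_gene, function(ix) remap[ix]),
    n_genes = nrow(wins),
    flank_note = attr(windows, "flank_bp")
  ), class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat("Window selection:", nrow(x$variants), "unique variants across",
      x$n_genes, "gene windows\n")
  sizes <- lengths(x$per_gene)
  cat("  per-gene variants: median", stats::median(sizes),
      "range", paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' Partition gene loci into autosomal and excluded
#'
#' Loci on X, Y or MT (after label normalization) are moved to the excluded
#' list, mirroring GWAS panels restricted to autosomes. The partition is
#' exhaustive and disjoint.
#'
#' @param loci gene-locus data frame.
#' @param unrecognized \code{"lenient"} (default) excludes loci with
#'   unrecognized chromosome labels with a warning; \code{"strict"} errors.
#' @return list with \code{autosomal} and \code{excluded} data frames.
#' @export
filter_autosomal <- function(loci, unrecognized = c("lenient", "strict")) {
  unrecognized <- match.arg(unrecognized)
  chrom <- normalize_chrom(loci$chromosome)
  auto <- is_autosome_label(chrom)
  sex_mt <- chrom %in% c("X", "Y", "MT")
  unknown <- !auto & !sex_mt
  if (any(unknown)) {
    msg <- paste("unrecognized chromosome label(s):",
                 paste(unique(chrom[unknown]), collapse = ", "))
    if (unrecognized == "strict") stop_arg(msg)
    warning(msg, " - excluded", call. = FALSE)
  }
  list(autosomal = loci[auto, , drop = FALSE],
       excluded = loci[!auto, , drop = FALSE])
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with \code{maf > min_maf} (strict inequality). Variants
#' with missing MAF are retained and counted in a warning, since top-hit
#' style summary files often omit frequencies.
#'
#' @param variants summary-statistic data frame.
#' @param min_maf minimum minor allele frequency in [0, 0.5]; default 0.01.
#' @return the filtered data frame, with attribute \code{n_missing_maf}.
#' @export
filter_maf <- function(variants, min_maf = 0.01) {
  if (min_maf < 0 || min_maf > 0.5) stop_arg("min_maf must be in [0, 0.5]")
  missing <- is.na(variants$maf)
  keep <- missing | variants$maf > min_maf
  if (any(missing & keep)) {
    warning(sum(missing), " variant(s) with missing MAF retained",
            call. = FALSE)
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_maf") <- sum(missing)
  out
}
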