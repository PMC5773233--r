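#' @keywords internal
"_PACKAGE"

#' Normalize chromosome labels
#'
#' Harmonizes chromosome labels across input files: strips any "chr" prefix,
#' uppercases, and maps the numeric sex/mitochondrial codes used by some GWAS
#' tools ("23" to "X", "24" to "Y", "25"/"M" to "MT").
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_chrom(c("chr1", "X", "chrX", "23", "M"))
#' @export
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x %in% c("25", "M")] <- "MT"
  x
}

#' @keywords internal
is_autosome_label <- function(x) {
  suppressWarnings(!is.na(as.integer(x)))
}

# round half away from zero (round() rounds half to even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

chrom_sort_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.integer(u))
  special <- match(u, c("X", "Y", "MT"))
  key <- ifelse(!is.na(num), num, 1000L + ifelse(is.na(special), 99L, special))
  u[order(key, u)]
}

stop_arg <- function(...) stop(..., call. = FALSE)

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
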