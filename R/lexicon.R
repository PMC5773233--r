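#' Refractive-error term lexicon
#'
#' A lexicon maps each refractive-error class (myopia, hyperopia, astigmatism,
#' ametropia_other) to the search terms used to detect that class in clinical
#' synopsis text. Matching is case-insensitive and whole-word: a term never
#' matches inside a longer word, with the hyphen treated as a letter-joining
#' character so that "near-sighted" and "nearsighted" are both caught by the
#' single term "near-sighted".
#'
#' The default lexicon ships as an editable YAML file
#' (\code{system.file("extdata", "refractive_lexicon.yaml", package =
#' "mendelEnrich")}) so a curated term list can be dropped in without code
#' changes.
#'
#' @param path path to a YAML file mapping class labels to term lists; when
#'   \code{NULL} the packaged default is used.
#' @return a named list of character vectors with class
#'   \code{"term_lexicon"}.
#' @examples
#' lex <- read_lexicon()
#' names(lex)
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "refractive_lexicon.yaml",
                        package = "mendelEnrich")
  }
  lex <- yaml::read_yaml(path)
  lex <- lapply(lex, function(terms) as.character(unlist(terms)))
  validate_lexicon(lex)
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() read_lexicon(NULL)

#' @keywords internal
validate_lexicon <- function(lex) {
  if (!length(lex) || is.null(names(lex)) || any(!nzchar(names(lex)))) {
    stop_arg("lexicon must be a named list of term vectors")
  }
  n_terms <- vapply(lex, length, integer(1))
  if (any(n_terms == 0L)) {
    stop_arg("every lexicon class needs at least one term: ",
             paste(names(lex)[n_terms == 0L], collapse = ", "))
  }
  all_terms <- tolower(unlist(lex, use.names = FALSE))
  if (anyDuplicated(all_terms)) {
    stop_arg("term(s) listed under more than one class: ",
             paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "))
  }
  structure(lex, class = "term_lexicon")
}

# Turn a lexicon term into a whole-word, case-insensitive PCRE pattern.
# Letters and "-" are word characters; "-" inside a term is optional so the
# hyphenated and fused spellings both match; internal whitespace matches any
# whitespace run.
term_pattern <- function(term) {
  esc <- gsub("([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1", term, perl = TRUE)
  esc <- gsub("-", "-?", esc, fixed = TRUE)
  esc <- gsub("\\s+", "\\\\s+", esc)
  paste0("(?<![\\p{L}-])", esc, "(?![\\p{L}-])")
}
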