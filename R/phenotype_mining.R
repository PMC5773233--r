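#' Parse OMIM-style flat-text phenotype records
#'
#' Reads a flat-text catalog of Mendelian phenotype records in the classic
#' field-tagged dialect: records are separated by a line \code{*RECORD*}, the
#' identifier lives under a \code{*FIELD* NO} line (a 6-digit MIM-style id),
#' the title under \code{*FIELD* TI}, and the clinical synopsis under
#' \code{*FIELD* CS}. Unknown fields are kept in the raw block but otherwise
#' ignored.
#'
#' @param x a file path, or a character vector holding the raw text (either a
#'   single string with embedded newlines or one element per line).
#' @return a data frame with one row per record and columns \code{mim_id},
#'   \code{title}, \code{clinical_text} (\code{""} when the record has no
#'   clinical-synopsis section) and \code{raw_block}, in file order.
#' @export
parse_omim_records <- function(x) {
  lines <- read_lines_arg(x)
  empty <- data.frame(mim_id = character(), title = character(),
                      clinical_text = character(), raw_block = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) return(empty)

  # byte offset of the start of each line, for error reporting
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))
  rec_marks <- which(trimws(lines) == "*RECORD*")
  if (!length(rec_marks)) {
    stop_arg("malformed record at byte offset 0: no *RECORD* delimiter found")
  }
  starts <- rec_marks + 1L
  ends <- c(rec_marks[-1L] - 1L, length(lines))

  recs <- lapply(seq_along(starts), function(i) {
    if (starts[i] > ends[i]) return(NULL)  # empty trailing record block
    block <- lines[starts[i]:ends[i]]
    if (!any(nzchar(trimws(block)))) return(NULL)
    fields <- split_fields(block)
    if (is.null(fields[["NO"]])) {
      stop_arg("malformed record at byte offset ",
               offsets[rec_marks[i]], ": missing *FIELD* NO id line")
    }
    mim_id <- trimws(fields[["NO"]][1L])
    data.frame(
      mim_id = mim_id,
      title = paste(fields[["TI"]] %||% character(), collapse = "\n"),
      clinical_text = paste(fields[["CS"]] %||% character(), collapse = "\n"),
      raw_block = paste(block, collapse = "\n"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(list(empty), recs))
  if (anyDuplicated(out$mim_id)) {
    stop_arg("duplicate mim_id in record file: ",
             paste(unique(out$mim_id[duplicated(out$mim_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
}

# split a record block into a name -> lines-of-content map
split_fields <- function(block) {
  tag <- regmatches(block, regexec("^\\*FIELD\\*\\s+(\\S+)\\s*$", block))
  is_hdr <- lengths(tag) == 2L
  if (!any(is_hdr)) return(list())
  hdr_idx <- which(is_hdr)
  names_f <- vapply(tag[is_hdr], `[`, character(1), 2L)
  out <- list()
  for (j in seq_along(hdr_idx)) {
    from <- hdr_idx[j] + 1L
    to <- if (j < length(hdr_idx)) hdr_idx[j + 1L] - 1L else length(block)
    content <- if (from <= to) block[from:to] else character()
    out[[names_f[j]]] <- c(out[[names_f[j]]], content)
  }
  out
}

#' Classify the refractive-error content of a phenotype record
#'
#' Scans the clinical synopsis text of a record for the lexicon's terms and
#' reports every match with its class, term and character offset. Matching is
#' case-insensitive and whole-word (see \code{\link{read_lexicon}}); a record
#' with no matching term yields an empty classification, which is not an
#' error.
#'
#' @param record a single-row data frame (or list) with \code{mim_id} and
#'   \code{clinical_text}, as returned by \code{\link{parse_omim_records}}.
#' @param lexicon a \code{term_lexicon}; default packaged lexicon.
#' @return a list with \code{mim_id}, \code{classes_found} (character vector)
#'   and \code{matches} (data frame of class, term, offset).
#' @export
classify_refractive <- function(record, lexicon = default_lexicon()) {
  lexicon <- validate_lexicon(unclass(lexicon))
  text <- as.character(record$clinical_text %||% "")[1L]
  matches <- data.frame(class = character(), term = character(),
                        offset = integer(), stringsAsFactors = FALSE)
  if (nzchar(text)) {
    for (cls in names(lexicon)) {
      for (term in lexicon[[cls]]) {
        m <- gregexpr(term_pattern(term), text, perl = TRUE,
                      ignore.case = TRUE)[[1L]]
        if (m[1L] != -1L) {
          matches <- rbind(matches, data.frame(
            class = cls, term = term, offset = as.integer(m),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  matches <- matches[order(matches$offset, matches$class, matches$term), ,
                     drop = FALSE]
  rownames(matches) <- NULL
  list(mim_id = as.character(record$mim_id %||% NA_character_)[1L],
       classes_found = unique(matches$class),
       matches = matches)
}

#' @rdname classify_refractive
#' @param records data frame of records.
#' @return \code{classify_refractive_all}: a list of classifications, one per
#'   record, named by \code{mim_id}.
#' @export
classify_refractive_all <- function(records, lexicon = default_lexicon()) {
  out <- lapply(seq_len(nrow(records)), function(i)
    classify_refractive(records[i, , drop = FALSE], lexicon))
  names(out) <- records$mim_id
  out
}

#' Read a morbidmap-style phenotype-to-gene table
#'
#' Tab-delimited dialect: phenotype label, comma-separated gene symbols,
#' phenotype MIM id.
#'
#' @param x file path or character text.
#' @return data frame with columns \code{phenotype}, \code{gene_symbols},
#'   \code{mim_id}.
#' @export
read_morbidmap <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(phenotype = character(), gene_symbols = character(),
                      mim_id = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop_arg("morbidmap line(s) with fewer than 3 columns: line ",
                         paste(which(bad), collapse = ", "))
  data.frame(phenotype = vapply(parts, `[`, character(1), 1L),
             gene_symbols = vapply(parts, `[`, character(1), 2L),
             mim_id = trimws(vapply(parts, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Read a mim2gene-style gene-id table
#'
#' Tab-delimited dialect: MIM id, entry type, NCBI (Entrez) gene id, HGNC
#' approved symbol, Ensembl gene id.
#'
#' @param x file path or character text.
#' @return data frame with columns \code{mim_id}, \code{type}, \code{entrez},
#'   \code{symbol}, \code{ensembl}.
#' @export
read_gene_id_table <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  cols <- c("mim_id", "type", "entrez", "symbol", "ensembl")
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), 5L), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", 5L))[1:5])
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

#' Link classified phenotypes to their causal genes
#'
#' Joins refractive classifications against a morbidmap-style table to find
#' the causal gene(s) of each phenotype, then resolves stable gene ids via a
#' mim2gene-style table. Only phenotypes with at least one detected
#' refractive class and at least one mapped gene yield links; classified
#' phenotypes without an identifiable gene are reported on a skipped-list
#' side channel rather than silently dropped. A gene symbol present in the
#' morbidmap but absent from the id table keeps its link (with an empty
#' \code{gene_id}) and raises a warning.
#'
#' @param classifications list of classifications from
#'   \code{\link{classify_refractive_all}}.
#' @param morbidmap data frame from \code{\link{read_morbidmap}} (or a path /
#'   text accepted by it).
#' @param gene_ids data frame from \code{\link{read_gene_id_table}} (or a
#'   path / text).
#' @param loci optional gene-locus table (see \code{\link{read_gene_loci}})
#'   used to annotate each link with its chromosome.
#' @return a list with \code{links} (data frame: mim_id, gene_symbol,
#'   gene_id, chromosome), \code{skipped} (mim ids of classified phenotypes
#'   with no mapped gene) and \code{n_unresolved_ids}.
#' @export
link_genes <- function(classifications, morbidmap, gene_ids, loci = NULL) {
  if (!is.data.frame(morbidmap)) morbidmap <- read_morbidmap(morbidmap)
  if (!is.data.frame(gene_ids)) gene_ids <- read_gene_id_table(gene_ids)
  classified <- Filter(function(cl) length(cl$classes_found) > 0L,
                       classifications)
  links <- data.frame(mim_id = character(), gene_symbol = character(),
                      gene_id = character(), chromosome = character(),
                      stringsAsFactors = FALSE)
  skipped <- character()
  unresolved <- character()
  for (cl in classified) {
    rows <- morbidmap[morbidmap$mim_id == cl$mim_id, , drop = FALSE]
    syms <- unique(trimws(unlist(strsplit(rows$gene_symbols, ",", fixed = TRUE))))
    syms <- syms[nzchar(syms)]
    if (!length(syms)) {
      skipped <- c(skipped, cl$mim_id)
      next
    }
    ids <- gene_ids$entrez[match(syms, gene_ids$symbol)]
    unresolved <- c(unresolved, syms[is.na(ids)])
    ids[is.na(ids)] <- ""
    chrom <- rep(NA_character_, length(syms))
    if (!is.null(loci)) {
      chrom <- loci$chromosome[match(syms, loci$gene_symbol)]
    }
    links <- rbind(links, data.frame(
      mim_id = cl$mim_id, gene_symbol = syms, gene_id = ids,
      chromosome = chrom, stringsAsFactors = FALSE))
  }
  if (length(unresolved)) {
    warning(length(unresolved), " gene symbol(s) without a resolvable id: ",
            paste(unique(unresolved), collapse = ", "), call. = FALSE)
  }
  rownames(links) <- NULL
  list(links = links, skipped = skipped,
       n_unresolved_ids = length(unresolved))
}

#' Build per-class candidate gene sets from phenotype-gene links
#'
#' Aggregates phenotype-to-gene links into deduplicated gene sets: one
#' "any-<class>" set per refractive class (phenotypes listing that class,
#' possibly among others), one exclusive "<class>-only" set per class
#' (phenotypes whose only refractive class is that class), and the union set
#' "all-ametropia". Gene identity for deduplication is the approved symbol; a
#' gene linked to several phenotypes appears once, and the surplus links are
#' reported as the duplicate count.
#'
#' @param linkage result of \code{\link{link_genes}} (or its \code{links}
#'   data frame).
#' @param classifications list from \code{\link{classify_refractive_all}}.
#' @return named list of gene sets; each has \code{name},
#'   \code{gene_symbols} (unique, first-seen order), \code{provenance}
#'   (contributing mim ids, one per link) and \code{n_duplicates}.
#' @export
build_gene_sets <- function(linkage, classifications) {
  links <- if (is.data.frame(linkage)) linkage else linkage$links
  class_of <- lapply(classifications, `[[`, "classes_found")
  all_classes <- unique(unlist(class_of, use.names = FALSE))

  one_set <- function(name, mims) {
    sel <- links[links$mim_id %in% mims, , drop = FALSE]
    syms <- sel$gene_symbol
    uniq <- unique(syms)
    list(name = name, gene_symbols = uniq, provenance = sel$mim_id,
         n_duplicates = length(syms) - length(uniq))
  }

  sets <- list()
  for (cls in all_classes) {
    any_m <- names(class_of)[vapply(class_of, function(cc) cls %in% cc,
                                    logical(1))]
    only_m <- names(class_of)[vapply(class_of, function(cc) identical(cc, cls),
                                     logical(1))]
    sets[[paste0("any-", cls)]] <- one_set(paste0("any-", cls), any_m)
    sets[[paste0(cls, "-only")]] <- one_set(paste0(cls, "-only"), only_m)
  }
  linked_m <- names(class_of)[lengths(class_of) > 0L]
  sets[["all-ametropia"]] <- one_set("all-ametropia", linked_m)
  sets
}

#' Run the full phenotype-mining stage
#'
#' Convenience wrapper: parse records, classify them, link genes and build
#' the per-class gene sets, returning a mining report alongside the sets.
#'
#' @inheritParams parse_omim_records
#' @inheritParams link_genes
#' @param lexicon term lexicon.
#' @return list with \code{records}, \code{classifications}, \code{linkage},
#'   \code{gene_sets} and \code{report} (entity / classified / linked /
#'   skipped / duplicate counts).
#' @export
mine_phenotypes <- function(x, morbidmap, gene_ids,
                            lexicon = default_lexicon(), loci = NULL) {
  records <- parse_omim_records(x)
  classifications <- classify_refractive_all(records, lexicon)
  linkage <- link_genes(classifications, morbidmap, gene_ids, loci)
  sets <- build_gene_sets(linkage, classifications)
  n_classified <- sum(lengths(lapply(classifications, `[[`,
                                     "classes_found")) > 0L)
  report <- list(
    n_records = nrow(records),
    n_classified = n_classified,
    n_linked_phenotypes = length(unique(linkage$links$mim_id)),
    n_skipped = length(linkage$skipped),
    n_links = nrow(linkage$links),
    n_duplicates_all = sets[["all-ametropia"]]$n_duplicates,
    set_sizes = vapply(sets, function(s) length(s$gene_symbols), integer(1))
  )
  list(records = records, classifications = classifications,
       linkage = linkage, gene_sets = sets, report = report)
}
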