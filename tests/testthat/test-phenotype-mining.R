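test_that("record parsing handles the field-tagged dialect, empty input and malformed records", {
  expect_equal(nrow(parse_omim_records("")), 0L)
  expect_equal(nrow(parse_omim_records(character())), 0L)

  recs <- parse_omim_records(tiny_omim_text())
  expect_equal(recs$mim_id, c("100001", "100002", "100003"))
  expect_match(recs$clinical_text[1], "Severe myopia")
  expect_identical(recs$clinical_text[3], "")  # no CS section
  expect_true(all(vapply(seq_len(nrow(recs)), function(i)
    recs$clinical_text[i] == "" ||
      grepl(recs$clinical_text[i], recs$raw_block[i], fixed = TRUE),
    logical(1))))

  no_id <- "*RECORD*\n*FIELD* TI\nUNTITLED THING"
  expect_error(parse_omim_records(no_id), "byte offset")
  dup <- paste(rep(tiny_omim_text(), 2), collapse = "\n")
  expect_error(parse_omim_records(dup), "duplicate")
})

test_that("parsed fixture records match the generator manifest in file order", {
  cfg <- small_syn_config()
  fx <- gen_omim_fixture(cfg, seed = 1L)
  recs <- parse_omim_records(fx$records_text)
  expect_equal(recs$mim_id, fx$manifest$mim_id)
  expect_equal(nrow(recs), nrow(fx$manifest))
})

test_that("refractive classification is whole-word, case-insensitive and offset-reporting", {
  lex <- default_lexicon()
  cl1 <- classify_refractive(list(mim_id = "1", clinical_text =
                                  "Severe myopia; cataract"), lex)
  expect_setequal(cl1$classes_found, "myopia")
  expect_equal(cl1$matches$offset,
               as.integer(regexpr("myopia", "Severe myopia; cataract")))

  cl2 <- classify_refractive(list(mim_id = "2", clinical_text =
    "myopic astigmatism and hypermetropia"), lex)
  expect_setequal(cl2$classes_found, c("myopia", "astigmatism", "hyperopia"))

  expect_length(classify_refractive(list(mim_id = "3", clinical_text = ""),
                                    lex)$classes_found, 0L)
  # never matches inside a longer word
  expect_length(classify_refractive(list(mim_id = "4", clinical_text =
    "amyopiaX and pseudohyperopia"), lex)$classes_found, 0L)
  # hyphen joins letters: both spellings of a hyphenated term match
  for (txt in c("Patient is near-sighted.", "Patient is nearsighted.")) {
    expect_setequal(classify_refractive(list(mim_id = "5",
      clinical_text = txt), lex)$classes_found, "myopia")
  }
  # uppercase clinical prose
  expect_setequal(classify_refractive(list(mim_id = "6", clinical_text =
    "HIGH MYOPIA"), lex)$classes_found, "myopia")
})

test_that("lexicon validation enforces non-empty classes and unique terms", {
  expect_s3_class(default_lexicon(), "term_lexicon")
  expect_error(validate_lexicon(list(myopia = character())), "at least one")
  expect_error(validate_lexicon(list(a = "myopia", b = "Myopia")),
               "more than one class")
})

test_that("gene linkage keeps per-phenotype links, skips unmapped, warns on unresolved ids", {
  recs <- parse_omim_records(tiny_omim_text())
  recs$clinical_text[3] <- "hyperopia noted"  # make all 3 classified
  cls <- classify_refractive_all(recs)
  morbid <- paste("Syndrome A\tG1,G2\t100001",
                  "Syndrome B\tG1\t100002", sep = "\n")
  ids <- "600001\tgene\t111\tG1\tENSG00000000001"
  expect_warning(lk <- link_genes(cls, morbid, ids), "resolvable")
  expect_equal(nrow(lk$links), 3L)          # G1+G2 for 100001, G1 for 100002
  expect_equal(lk$skipped, "100003")        # classified but unmapped
  expect_equal(lk$links$gene_id[lk$links$gene_symbol == "G1"],
               c("111", "111"))
  expect_equal(lk$links$gene_id[lk$links$gene_symbol == "G2"], "")
  # two phenotypes mapping to the same gene stay distinct links
  g1 <- lk$links[lk$links$gene_symbol == "G1", ]
  expect_setequal(g1$mim_id, c("100001", "100002"))
})

test_that("gene sets deduplicate symbols and report surplus links", {
  # 130 myopia links over 119 unique genes: 7 genes carry 11 surplus links
  genes <- sprintf("G%03d", 1:119)
  surplus <- rep(sprintf("G%03d", 1:7), times = c(2, 2, 2, 2, 1, 1, 1))
  all_links <- c(genes, surplus)
  mims <- sprintf("%06d", 200000 + seq_along(all_links))
  links <- data.frame(mim_id = mims, gene_symbol = all_links,
                      gene_id = "", chromosome = NA, stringsAsFactors = FALSE)
  cls <- lapply(mims, function(m) list(mim_id = m, classes_found = "myopia",
                                       matches = NULL))
  names(cls) <- mims
  sets <- build_gene_sets(links, cls)
  expect_length(sets[["any-myopia"]]$gene_symbols, 119L)
  expect_equal(sets[["any-myopia"]]$n_duplicates, 11L)
  expect_length(sets[["any-myopia"]]$provenance, 130L)
  # surplus-link identity: sum over genes of (links - 1) floored at 0
  tab <- table(links$gene_symbol)
  expect_equal(sum(pmax(tab - 1L, 0L)), sets[["any-myopia"]]$n_duplicates)
})

test_that("exclusive sets are subsets of any-class sets and respect mixed classes", {
  mk <- function(m, cls) list(mim_id = m, classes_found = cls, matches = NULL)
  cls <- list(`1` = mk("1", "myopia"),
              `2` = mk("2", c("astigmatism", "myopia")),
              `3` = mk("3", "hyperopia"),
              `4` = mk("4", character()))
  links <- data.frame(mim_id = c("1", "2", "3"),
                      gene_symbol = c("A", "B", "C"), gene_id = "",
                      chromosome = NA, stringsAsFactors = FALSE)
  sets <- build_gene_sets(links, cls)
  expect_setequal(sets[["any-myopia"]]$gene_symbols, c("A", "B"))
  expect_setequal(sets[["myopia-only"]]$gene_symbols, "A")
  expect_setequal(sets[["all-ametropia"]]$gene_symbols, c("A", "B", "C"))
  for (cl in c("myopia", "astigmatism", "hyperopia")) {
    expect_true(all(sets[[paste0(cl, "-only")]]$gene_symbols %in%
                    sets[[paste0("any-", cl)]]$gene_symbols))
  }
})

test_that("mining round trip recovers exactly the planted classes and gene sets", {
  cfg <- small_syn_config()
  for (seed in c(2L, 17L)) {
    fx <- gen_omim_fixture(cfg, seed = seed)
    mined <- suppressWarnings(mine_phenotypes(
      fx$records_text, fx$morbidmap_text, fx$gene_id_text))
    man <- fx$manifest
    for (i in seq_len(nrow(man))) {
      got <- sort(mined$classifications[[man$mim_id[i]]]$classes_found)
      expect_equal(got, sort(man$classes[[i]]), info = man$mim_id[i])
    }
    expect_setequal(mined$linkage$skipped,
                    man$mim_id[man$kind == "unlinked"])
    planted_genes <- unique(man$gene[!is.na(man$gene)])
    expect_setequal(mined$gene_sets[["all-ametropia"]]$gene_symbols,
                    planted_genes)
    # per-class any-sets equal the genes of records planted with that class
    for (cl in names(cfg$class_mix)) {
      has_cl <- vapply(man$classes, function(cc) cl %in% cc, logical(1))
      want <- unique(man$gene[has_cl & !is.na(man$gene)])
      gs <- mined$gene_sets[[paste0("any-", cl)]]
      got <- if (is.null(gs)) character() else gs$gene_symbols
      expect_setequal(got, want)
    }
  }
})
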