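# Synthetic-data generators: every input the pipeline consumes, with a
# manifest of planted ground truth. All generators are pure functions of
# (config, seed): they save and restore the caller's RNG state.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for the synthetic study generators
#'
#' Desk-scale defaults: 2 chromosomes of 10 Mb, 100 genes, 20,000 variants
#' in AR(1) LD blocks of 20 SNPs (rho = 0.8), a 2000-sample reference panel,
#' 10\% of genes causal with a planted non-centrality of 6 at the causal
#' SNP, and a 1000-gene annotation universe with one 10-fold enriched term.
#'
#' @param n_chromosomes,chromosome_length_bp genome shape.
#' @param n_genes,gene_length_range_bp gene count and transcription-span
#'   lengths (bp).
#' @param flank_bp candidate-window flank (bp).
#' @param n_variants,maf_range variant grid size and allele-frequency range.
#' @param ld_block_size,ld_rho LD block length (SNPs) and AR(1) correlation
#'   of the latent Gaussian within a block.
#' @param n_reference_samples reference-panel size.
#' @param causal_fraction fraction of genes carrying a causal SNP.
#' @param lambda expected |z| at the causal SNP (non-centrality).
#' @param n_omim_extra_unlinked,n_omim_none,n_omim_duplicates extra
#'   phenotype records: classified-but-unlinked, no refractive terms, and
#'   records reusing an already-linked gene (duplicates).
#' @param class_mix named probabilities over refractive classes.
#' @param multi_class_prob chance a record lists a second refractive class.
#' @param catalog_n_terms,catalog_term_size_range,catalog_enriched_fold,catalog_universe_size
#'   annotation-catalog shape.
#' @return list of class \code{"syn_config"}.
#' @export
syn_config <- function(n_chromosomes = 2L,
                       chromosome_length_bp = 1e7,
                       n_genes = 100L,
                       gene_length_range_bp = c(1e4, 1e5),
                       flank_bp = 5e4,
                       n_variants = 2e4,
                       maf_range = c(0.01, 0.5),
                       ld_block_size = 20L,
                       ld_rho = 0.8,
                       n_reference_samples = 2000L,
                       causal_fraction = 0.1,
                       lambda = 6,
                       n_omim_extra_unlinked = 10L,
                       n_omim_none = 5L,
                       n_omim_duplicates = 5L,
                       class_mix = c(myopia = 0.65, hyperopia = 0.15,
                                     astigmatism = 0.10,
                                     ametropia_other = 0.10),
                       multi_class_prob = 0.15,
                       catalog_n_terms = 50L,
                       catalog_term_size_range = c(5L, 50L),
                       catalog_enriched_fold = 10,
                       catalog_universe_size = 1000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$chromosome_length_bp > 0,
            cfg$n_genes >= 1, cfg$n_variants >= 1,
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$lambda >= 0, cfg$causal_fraction >= 0,
            cfg$causal_fraction <= 1, cfg$n_reference_samples >= 2,
            abs(sum(cfg$class_mix) - 1) < 1e-8)
  structure(cfg, class = "syn_config")
}

#' Generate non-overlapping gene loci
#'
#' Places genes uniformly along each chromosome without overlap: gene
#' lengths are drawn from the configured range and the remaining free space
#' is split into inter-gene gaps by a stick-breaking draw.
#'
#' @param config a \code{\link{syn_config}}.
#' @param seed RNG seed.
#' @return gene-locus data frame (columns as \code{\link{read_gene_loci}}).
#' @export
gen_gene_loci <- function(config, seed = 1L) {
  stopifnot(inherits(config, "syn_config"))
  with_seed(seed, {
    per_chrom <- table(rep_len(seq_len(config$n_chromosomes), config$n_genes))
    rows <- list()
    gi <- 0L
    for (cc in seq_len(config$n_chromosomes)) {
      n_c <- as.integer(per_chrom[[as.character(cc)]])
      lens <- round(stats::runif(n_c, config$gene_length_range_bp[1],
                                 config$gene_length_range_bp[2]))
      free <- config$chromosome_length_bp - sum(lens)
      if (free < n_c + 1) {
        stop_arg("chromosome too short to place ", n_c, " genes")
      }
      fracs <- diff(c(0, sort(stats::runif(n_c)), 1))
      gaps <- floor(fracs * free)
      starts <- cumsum(gaps[seq_len(n_c)]) + cumsum(c(0, lens[-n_c])) + 1
      rows[[cc]] <- data.frame(
        gene_symbol = sprintf("GENE%03d", gi + seq_len(n_c)),
        chromosome = as.character(cc),
        tx_start = as.integer(starts),
        tx_end = as.integer(starts + lens - 1),
        strand = sample(c("+", "-"), n_c, replace = TRUE),
        stringsAsFactors = FALSE)
      gi <- gi + n_c
    }
    do.call(rbind, rows)
  })
}

#' Generate an LD-structured reference genotype panel
#'
#' Variant positions are drawn uniformly per chromosome and grouped into
#' consecutive LD blocks. Within a block each haplotype carries a latent
#' AR(1) Gaussian (correlation \code{ld_rho^|i-j|}); thresholding the latent
#' value at each SNP's drawn allele frequency yields the allele, and the two
#' haplotypes sum to the 0/1/2 dosage.
#'
#' @param config a \code{\link{syn_config}}.
#' @param seed RNG seed.
#' @return object of class \code{"reference_panel"}: list with
#'   \code{genotypes} (samples x SNPs integer matrix, SNP ids as column
#'   names) and \code{snps} (data frame snp_id, chromosome, position, maf,
#'   block).
#' @export
gen_reference_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "syn_config"))
  with_seed(seed, {
    per_chrom <- table(rep_len(seq_len(config$n_chromosomes),
                               config$n_variants))
    snp_rows <- list()
    for (cc in seq_len(config$n_chromosomes)) {
      n_c <- as.integer(per_chrom[[as.character(cc)]])
      pos <- sort(sample.int(config$chromosome_length_bp, n_c))
      snp_rows[[cc]] <- data.frame(
        chromosome = as.character(cc), position = pos,
        block = paste0(cc, "_", ceiling(seq_len(n_c) / config$ld_block_size)),
        stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, snp_rows)
    snps$snp_id <- sprintf("var%06d", seq_len(nrow(snps)))
    snps$maf <- stats::runif(nrow(snps), config$maf_range[1],
                             config$maf_range[2])
    snps <- snps[, c("snp_id", "chromosome", "position", "maf", "block")]

    n <- config$n_reference_samples
    m <- nrow(snps)
    rho <- config$ld_rho
    sd_innov <- sqrt(1 - rho^2)
    thresh <- stats::qnorm(snps$maf)
    geno <- matrix(0L, nrow = n, ncol = m,
                   dimnames = list(NULL, snps$snp_id))
    new_block <- c(TRUE, snps$block[-1L] != snps$block[-m])
    for (copy in 1:2) {
      z_prev <- numeric(n)
      for (j in seq_len(m)) {
        z <- if (new_block[j]) stats::rnorm(n)
             else rho * z_prev + sd_innov * stats::rnorm(n)
        geno[, j] <- geno[, j] + (z < thresh[j])
        z_prev <- z
      }
    }
    structure(list(genotypes = geno, snps = snps),
              class = "reference_panel")
  })
}

#' Generate GWAS summary statistics with planted causal genes
#'
#' Per-SNP z-scores are drawn block-wise from the LD-implied multivariate
#' normal (drawing in z-space is equivalent in distribution to simulating
#' phenotypes and regressing, and orders of magnitude faster): the block
#' covariance is the latent AR(1) correlation, the mean is zero under the
#' null, and for a causal gene the mean at SNP j of the causal block is
#' \code{lambda * rho^|j - c|} — the causal SNP's non-centrality propagated
#' through LD. Two-sided normal-tail p-values complete the record.
#'
#' @param config a \code{\link{syn_config}}.
#' @param loci gene loci from \code{\link{gen_gene_loci}}.
#' @param panel reference panel from \code{\link{gen_reference_panel}} (its
#'   SNP grid is the variant grid).
#' @param seed RNG seed.
#' @return list with \code{variants} (summary-statistic data frame) and
#'   \code{manifest} (causal genes, causal SNP per gene, parameters echoed).
#' @export
gen_summary_stats <- function(config, loci, panel, seed = 1L) {
  stopifnot(inherits(config, "syn_config"),
            inherits(panel, "reference_panel"))
  snps <- panel$snps
  m <- nrow(snps)
  with_seed(seed, {
    n_causal <- round(config$causal_fraction * nrow(loci))
    causal_genes <- if (n_causal > 0) {
      sort(sample(loci$gene_symbol, n_causal))
    } else character()

    mu <- numeric(m)
    causal_snp <- stats::setNames(rep(NA_character_, length(causal_genes)),
                                  causal_genes)
    block_of <- snps$block
    idx_in_block <- stats::ave(seq_len(m), block_of, FUN = seq_along)
    for (g in causal_genes) {
      lr <- loci[loci$gene_symbol == g, ]
      cand <- which(snps$chromosome == lr$chromosome &
                    snps$position >= lr$tx_start - config$flank_bp &
                    snps$position <= lr$tx_end + config$flank_bp)
      inside <- cand[snps$position[cand] >= lr$tx_start &
                     snps$position[cand] <= lr$tx_end]
      if (length(inside)) cand <- inside
      if (!length(cand)) next
      c_idx <- if (length(cand) == 1L) cand else sample(cand, 1L)
      causal_snp[g] <- snps$snp_id[c_idx]
      same <- which(block_of == block_of[c_idx])
      mu[same] <- mu[same] +
        config$lambda * config$ld_rho^abs(idx_in_block[same] -
                                          idx_in_block[c_idx])
    }

    # AR(1) innovations, restarting at block boundaries
    new_block <- c(TRUE, block_of[-1L] != block_of[-m])
    rho <- config$ld_rho
    sd_innov <- sqrt(1 - rho^2)
    e <- numeric(m)
    for (j in seq_len(m)) {
      e[j] <- if (new_block[j]) stats::rnorm(1)
              else rho * e[j - 1L] + sd_innov * stats::rnorm(1)
    }
    z <- mu + e
    p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    variants <- data.frame(variant_id = snps$snp_id,
                           chromosome = snps$chromosome,
                           position = snps$position,
                           p_value = p, maf = snps$maf,
                           stringsAsFactors = FALSE)
    manifest <- list(causal_genes = causal_genes,
                     causal_snp = as.list(causal_snp),
                     lambda = config$lambda, ld_rho = config$ld_rho,
                     n_variants = m, seed = seed)
    list(variants = variants, manifest = manifest)
  })
}

syn_filler_features <- c(
  "Growth retardation", "Sensorineural hearing loss", "Cataract",
  "Joint hypermobility", "Cleft palate", "Scoliosis",
  "Developmental delay", "Micrognathia", "Ectopia lentis",
  "Aortic root dilatation", "Blue sclerae", "Brachydactyly")

#' Generate an OMIM-style fixture with planted refractive classes
#'
#' Emits record text in the field-tagged dialect read by
#' \code{\link{parse_omim_records}}, plus consistent morbidmap and gene-id
#' tables. One linked record is planted per supplied gene symbol (class
#' drawn from the configured mix), plus extra classified-but-unlinked
#' records, records without any refractive term, and duplicate records that
#' reuse an already-linked gene. The manifest records exactly what was
#' planted.
#'
#' @param config a \code{\link{syn_config}}.
#' @param seed RNG seed.
#' @param gene_symbols genes to link; default \code{GENE001..GENEnnn} per
#'   the config.
#' @param lexicon lexicon whose terms are embedded; default packaged.
#' @return list with \code{records_text}, \code{morbidmap_text},
#'   \code{gene_id_text} (single strings) and \code{manifest} (data frame:
#'   mim_id, classes, terms, gene).
#' @export
gen_omim_fixture <- function(config, seed = 1L, gene_symbols = NULL,
                             lexicon = default_lexicon()) {
  stopifnot(inherits(config, "syn_config"))
  if (is.null(gene_symbols)) {
    gene_symbols <- sprintf("GENE%03d", seq_len(config$n_genes))
  }
  with_seed(seed, {
    n_link <- length(gene_symbols)
    n_dup <- min(config$n_omim_duplicates, n_link)
    plan <- data.frame(
      gene = c(gene_symbols,
               if (n_dup) sample(gene_symbols, n_dup),
               rep(NA_character_, config$n_omim_extra_unlinked),
               rep(NA_character_, config$n_omim_none)),
      kind = c(rep("linked", n_link), rep("duplicate", n_dup),
               rep("unlinked", config$n_omim_extra_unlinked),
               rep("none", config$n_omim_none)),
      stringsAsFactors = FALSE)
    n_rec <- nrow(plan)
    plan <- plan[sample.int(n_rec), , drop = FALSE]
    plan$mim_id <- sprintf("%06d", sample(100000:699999, n_rec))

    classes <- names(config$class_mix)
    rec_classes <- vector("list", n_rec)
    rec_terms <- vector("list", n_rec)
    blocks <- character(n_rec)
    for (i in seq_len(n_rec)) {
      cls <- character()
      if (plan$kind[i] != "none") {
        cls <- sample(classes, 1L, prob = config$class_mix)
        if (stats::runif(1) < config$multi_class_prob) {
          cls <- c(cls, sample(setdiff(classes, cls), 1L))
        }
      }
      terms <- vapply(cls, function(cc) sample(lexicon[[cc]], 1L),
                      character(1))
      rec_classes[[i]] <- sort(cls)
      rec_terms[[i]] <- unname(terms)
      filler <- sample(syn_filler_features, 3L)
      cs <- c(filler[1:2],
              if (length(terms)) paste0(toupper(substring(terms, 1, 1)),
                                        substring(terms, 2)),
              filler[3L])
      blocks[i] <- paste(c(
        "*RECORD*",
        "*FIELD* NO", plan$mim_id[i],
        "*FIELD* TI", paste0("#", plan$mim_id[i], " SYNTHETIC SYNDROME ", i),
        "*FIELD* CS", paste0(sample(cs), ";")
      ), collapse = "\n")
    }

    linked <- plan$kind %in% c("linked", "duplicate")
    morbid <- sprintf("Synthetic syndrome %s\t%s\t%s",
                      plan$mim_id[linked], plan$gene[linked],
                      plan$mim_id[linked])
    genes_u <- unique(plan$gene[linked])
    gene_ids <- sprintf("%06d\tgene\t%d\t%s\tENSG%011d",
                        700000 + seq_along(genes_u),
                        10000 + seq_along(genes_u), genes_u,
                        seq_along(genes_u))
    manifest <- data.frame(mim_id = plan$mim_id, kind = plan$kind,
                           gene = plan$gene, stringsAsFactors = FALSE)
    manifest$classes <- rec_classes
    manifest$terms <- rec_terms
    list(records_text = paste(blocks, collapse = "\n"),
         morbidmap_text = paste(morbid, collapse = "\n"),
         gene_id_text = paste(gene_ids, collapse = "\n"),
         manifest = manifest)
  })
}

#' Generate an annotation catalog with one planted enriched term
#'
#' Random terms over a gene universe (the supplied symbols padded with
#' background genes up to the configured universe size). When causal genes
#' are supplied, one designated term over-samples them so that a query of
#' the causal genes is fold-enriched at the configured level in expectation;
#' with no causal genes every term is a uniform draw (a null catalog).
#'
#' @param config a \code{\link{syn_config}}.
#' @param gene_symbols genes that must be in the universe.
#' @param causal_genes subset of \code{gene_symbols} to over-sample.
#' @param seed RNG seed.
#' @return list with \code{catalog} (an \code{annotation_catalog}) and
#'   \code{manifest} (enriched term id and its planted genes).
#' @export
gen_annotation_catalog <- function(config, gene_symbols,
                                   causal_genes = character(), seed = 1L) {
  stopifnot(inherits(config, "syn_config"),
            all(causal_genes %in% gene_symbols))
  with_seed(seed, {
    u_size <- max(config$catalog_universe_size, length(gene_symbols))
    universe <- c(gene_symbols,
                  sprintf("BG%04d", seq_len(u_size - length(gene_symbols))))
    sizes <- sample(config$catalog_term_size_range[1]:
                    config$catalog_term_size_range[2],
                    config$catalog_n_terms, replace = TRUE)
    terms <- lapply(seq_len(config$catalog_n_terms), function(i) {
      list(name = sprintf("synthetic process %d", i),
           genes = sample(universe, sizes[i]))
    })
    names(terms) <- sprintf("T%04d", seq_len(config$catalog_n_terms))

    enriched_id <- NA_character_
    planted <- character()
    if (length(causal_genes)) {
      s_max <- config$catalog_term_size_range[2]
      n_plant <- min(length(causal_genes),
                     max(1L, round(config$catalog_enriched_fold *
                                   length(causal_genes) * s_max / u_size)))
      planted <- sample(causal_genes, n_plant)
      enriched_id <- names(terms)[1L]
      rest <- sample(setdiff(universe, causal_genes), s_max - n_plant)
      terms[[enriched_id]]$genes <- c(planted, rest)
      terms[[enriched_id]]$name <- "synthetic enriched process"
    }
    list(catalog = annotation_catalog(terms, universe),
         manifest = list(enriched_term = enriched_id,
                         planted_genes = planted))
  })
}
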