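Package: mendelEnrich
Title: GWAS Enrichment Analysis of Mendelian-Syndrome Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines Mendelian phenotype catalogs (OMIM-style flat-text records
    with morbidmap/mim2gene-style gene-mapping tables) for syndromes featuring
    refractive errors, builds per-class candidate gene sets, and tests whether
    genome-wide association study (GWAS) summary-statistic variants within a
    flanking window of those genes are enriched for association signal.
    Provides one-sided binomial tests on threshold-exceeding variant counts,
    experiment-wise significance thresholds, QQ-plot confidence envelopes from
    Beta order statistics, Manhattan-plot data, an LD-aware gene-based
    association test (sum of chi-squared statistics with a multivariate-normal
    Monte-Carlo null on the local linkage-disequilibrium matrix), and
    annotation-term overrepresentation tests with fold-enrichment filtering
    and subsample sensitivity analysis. A synthetic-data module generates
    every input the pipeline consumes, with a manifest of planted ground
    truth, so the whole analysis is exercisable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
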