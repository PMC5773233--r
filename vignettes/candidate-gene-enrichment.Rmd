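---
title: "Candidate-gene GWAS enrichment: models, assumptions and design choices"
author: "mendelEnrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene GWAS enrichment: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelEnrich)
```

## The scientific question

Mendelian syndromes that feature a refractive error (myopia, hyperopia,
astigmatism) identify genes whose severe disruption derails eye growth. The
hypothesis this package operationalizes is that *common* polymorphisms in or
near those same genes contribute to ordinary, nonsyndromic refractive error.
The test: mine a Mendelian phenotype catalog for refractive-error syndromes
and their causal genes, then ask whether GWAS summary-statistic variants
within a flanking window of those genes carry more association signal than
chance predicts.

## Stage 1 — phenotype mining

Records in the classic field-tagged flat-text dialect (`*RECORD*` /
`*FIELD* NO` / `*FIELD* CS`) are parsed and their clinical synopses scanned
against a term lexicon grouped by refractive class. Matching is
case-insensitive and whole-word: word boundaries fall at non-letter
characters, with `-` treated as letter-joining so `near-sighted` and
`nearsighted` are one term. A term never fires inside a longer word
(`amyopiaX` matches nothing). The lexicon ships as an editable YAML file so
a curated clinical term list can replace the default
(myopia/myopic/near-sighted(ness); hyperopia/hypermetropia/far-sighted(ness)
and adjectival forms; astigmatism/astigmatic; ametropia/refractive error);
configurability was preferred over hard-coding because published term lists
vary between curation efforts. Classification scans only the clinical
synopsis, not the record title: synopses are the clinically curated field,
titles repeat syndrome names that may contain class words incidentally.

Phenotype-to-gene links come from morbidmap/mim2gene-style mapping tables.
Classified phenotypes with no mapped gene are reported on a skipped-list
side channel rather than dropped silently, because the fraction of
gene-resolved phenotypes is itself a result. Gene sets are built per class
both inclusively (`any-myopia`: every phenotype listing myopia, alone or
with other classes) and exclusively (`myopia-only`), plus the union
`all-ametropia`. Deduplication is by approved gene symbol; genes causing
several syndromes contribute one set member and the surplus links are
reported as the duplicate count.

## Stage 2 — windows and variant capture

Candidate regions are the transcription span of each gene extended by a
flank (default 50 kb on each side, clipped at position 1) — wide enough to
capture the regulatory variation where most GWAS signal sits, narrow enough
to keep the candidate set gene-specific. Coordinates are 1-based closed
throughout; BED input (0-based half-open) is converted at read time so the
conversion lives in one place. Chromosome labels are normalized (`chr`
prefix stripped, `23` read as X). Variants are filtered to MAF strictly
greater than the minimum (default 0.01); missing MAF is tolerated with a
tally because top-hit exports often omit frequencies.

A variant inside two overlapping gene windows is counted **once** in the
global selection — the enrichment denominator describes one list of unique
SNPs — but is retained in every capturing gene's per-gene list, which is
what the gene-based test consumes. Selection output ordering is
deterministic (chromosome, position, id), so reruns are byte-identical.

## Stage 3 — SNP-count enrichment statistics

With $N$ selected variants and a per-test null exceedance probability
$p_0$, the expected sub-threshold count is $N p_0$ (printed rounded half
away from zero) and the experiment-wise threshold is $1/N$, the cutoff at
which about one test should pass by chance. The enrichment test is the
exact one-sided binomial upper tail
$P(K \ge k),\; K \sim \mathrm{Bin}(N, p_0)$, evaluated in log space;
exceedance counting uses a strict `<`. The experiment-wise test uses
$p_0 = 1/N$ exactly rather than a rounded printed threshold. p-values
below double-precision tail resolution are floored at the smallest positive
double and *flagged*, printing as the bound `< 2.2e-16` — never as zero.

Two caveats are deliberate properties of the method, not bugs. First, the
binomial model assumes independent variants; linkage disequilibrium makes
sub-threshold exceedances arrive in correlated clumps, so the count variance
exceeds $N p_0 (1-p_0)$ and the nominal-threshold test is anticonservative
under strong LD. That is precisely why the pipeline also carries an LD-aware
gene-based test, and why the sharper experiment-wise count (whose exceedances
are rarer and less clumped) is the pipeline's headline rejection statistic.
Second, in top-hit mode (summary files listing only variants below a
reporting threshold, default 1E-04) the denominator must come from a
reference variant list; the full reference count overstates the number of
variants actually tested, so both the expected count and the binomial
p-value are conservative, and the run report labels the denominator as a
conservative upper bound.

QQ envelopes use the order-statistic law: the $i$-th smallest of $N$
uniforms is $\mathrm{Beta}(i, N+1-i)$, so each rank gets the 2.5% and
97.5% quantiles of that distribution — pointwise intervals, not a
simultaneous band, so about 5% of ranks fall outside under the null and
simultaneous-coverage statements should not be read into the shading.
Expected quantiles are $i/(N+1)$.

## Stage 4 — LD-aware gene-based test

Per gene, each SNP's two-sided p-value maps to a 1-df chi-squared value
through the upper-tail quantile (the $z^2$ equivalence) and the gene
statistic is the sum $T=\sum_j Q(p_j)$. Under the null with LD, the per-SNP
z-scores are correlated multivariate normal, so the null of $T$ is simulated
by drawing $y \sim \mathcal N(0, R)$ with $R$ the local LD (dosage
correlation) matrix and accumulating $\sum_j y_j^2$; the empirical p-value
uses add-one smoothing, $(\#\{T^* \ge T\}+1)/(n_{\mathrm{sims}}+1)$, which
keeps p strictly positive and slightly conservative. $R$ is estimated from
a reference panel; sampling noise can make the estimate indefinite, so
eigenvalues are clipped at $10^{-8}$ and the matrix re-normalized to unit
diagonal before the one-off Cholesky factorization. Monomorphic panel SNPs
are an error at the LD layer (the caller drops them with a tally) because a
zero-variance column has no defined correlation.

Simulation precision is adaptive: stages of $10^3/10^4/10^5/10^6$ draws,
escalating only while fewer than 10 null statistics reach $T$ — genes with
unremarkable p-values stop cheap, small p-values get the precision they
need. Per-gene seeds are the plan's master seed plus the gene's index in
alphabetical order, so results are reproducible and independent of input
gene ordering. Overlapping genes legitimately share SNPs; no deduplication
is applied at the gene level. The gene-level summary feeds the count of
nominally significant genes back into the binomial enrichment test.

## Stage 5 — term overrepresentation

For a query gene set mapped into a reference universe, each annotation term
with at least one query hit is tested: expected count
$n_q \cdot |{\rm term}|/|U|$, fold = observed/expected, p-value the
one-sided binomial upper tail (the classical overrepresentation
construction; an exact hypergeometric variant is available behind a flag —
at query sizes far below the universe the two are nearly identical).
Bonferroni correction runs over the terms actually tested; zero-hit terms
are neither tested nor counted (a documented switch restores the
all-catalog denominator, since curation tools differ on this point). The
screening filter keeps terms that are both significant after correction and
at least 10-fold enriched, sorted by fold. The subsample sensitivity
analysis re-runs the screen on random subsets of the query set to show how
the surviving-term count depends on gene-set size.

## The synthetic study generator

Every input is generated from a config plus a seed, with a manifest of the
planted truth; all generators save and restore the caller's RNG state, so
they are pure functions of `(config, seed)`.

* **Loci**: non-overlapping spans placed by stick-breaking on each
  chromosome. Defaults: 2 chromosomes × 10 Mb, 100 genes of 10–100 kb.
* **Reference panel**: per haplotype, a latent AR(1) Gaussian
  ($\rho = 0.8$, blocks of 20 SNPs) thresholded at each SNP's drawn allele
  frequency (uniform 0.01–0.5); two haplotypes sum to the 0/1/2 dosage.
  Thresholding attenuates the dosage correlation below the latent $\rho$
  (strongly so for rare alleles) — tests validate the dosage LD against an
  independent bivariate threshold-model oracle rather than against the
  latent $\rho$ itself.
* **Summary statistics**: z-scores drawn block-wise from the latent
  AR(1) multivariate normal; a causal gene's block gets mean
  $\lambda \rho^{|j-c|}$ around its causal SNP (default $\lambda = 6$,
  10% of genes causal), i.e. LD-propagated non-centrality. Drawing in
  z-space is distributionally equivalent to simulating phenotypes and
  regressing, and orders of magnitude faster.
* **Phenotype fixture**: one linked record per gene with classes drawn
  from a mix dominated by myopia, plus classified-but-unlinked records,
  records without refractive terms, and duplicate records reusing a linked
  gene, so every mining side channel is exercised.
* **Annotation catalog**: random terms over a 1000-gene universe; one term
  over-samples the causal genes to reach the configured 10-fold enrichment
  in expectation (planted into the largest term size so the signal is
  identifiable above the Poisson noise of small terms).

What the generator does **not** emulate: realistic human LD maps and
recombination structure, allele-frequency/effect-size coupling, imputation
error, population stratification, and annotation term overlap/ontology
structure. Passing tests therefore demonstrate internal statistical
correctness and end-to-end recovery of planted signal under an idealized
genome — not robustness to the confounders of real GWAS data.

## Numerical choices and problem sizes

Tolerances follow the estimator's own noise: Monte-Carlo checks use
2–3$\sigma$ binomial bounds at the simulated size; closed-form comparisons
(chi-squared quantiles, Beta envelopes) use exact values. Test and
validation runs use deliberately desk-scale sizes — 500 null genes per LD
regime for gene-test calibration, $10^5$ draws for the chi-squared limit
check, 50 synthetic end-to-end seeds per regime with a 100-sample panel
(panel size only affects LD-estimation precision, not the exceedance
statistics), 20 catalog-recovery seeds, 100 mining round-trip seeds — the
suite completes in minutes on one CPU. For the pooled uniformity check of
gene-level p-values the Kolmogorov–Smirnov distance is taken over the
combined regimes (n = 1000): the expected KS distance of a perfectly
uniform sample is $\approx 0.87/\sqrt{n}$, so a 0.05 bound is only
meaningfully testable at four-figure sample sizes.

## Known limitations

* The nominal-threshold SNP-count binomial test inherits the method's
  independence assumption; under block LD it over-rejects (measured ~15%
  at $\alpha = 0.05$ under the synthetic null with $\rho = 0.8$, blocks of
  20). Interpret it descriptively; rely on the experiment-wise count and
  the gene-based test for inference.
* The gene-based null draws from the *estimated* LD matrix; with small
  reference panels the estimate is noisy and empirical p-values inherit
  that noise.
* Term overrepresentation treats annotation terms as independent gene bags;
  no ontology propagation is performed, and Bonferroni over tested terms is
  conservative for overlapping terms.
* Text mining is lexicon-bound: phenotypes described with vocabulary
  outside the lexicon are invisible, and no dioptric severity thresholds
  are inferred from prose.
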