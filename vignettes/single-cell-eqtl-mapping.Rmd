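---
title: "Mapping single-cell cis-eQTLs with scqtlmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-cell cis-eQTLs with scqtlmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqtlmap)
```

## The problem

An expression quantitative trait locus (eQTL) is a genetic variant whose
genotype is statistically associated with a gene's expression level. Bulk
eQTL mapping averages over the cell mixture and can hide effects confined
to one cell type; with per-cell genotype calls (e.g., VarTrix applied to
10x data, or somatic-variant mosaics in a tumor sample) and per-cell UMI
counts from the same cells, the association can instead be tested within
each cell group separately. scqtlmap implements that workflow: it joins
the two matrices over their shared cell barcodes, normalizes and filters,
enumerates candidate cis SNP–gene pairs from genomic annotations, tests
each pair per cell group under one of three regression models, corrects
for multiple testing, and draws genotype-stratified plots.

UMI counts are sparse and overdispersed: most entries are zero, partly
because the transcript was absent and partly because it was not captured.
The package's default association model is therefore a zero-inflated
negative binomial (ZINB): a point mass at zero with probability $\pi$
mixed with a negative binomial with mean $\mu$ and dispersion (size)
$\theta$,

$$P(Y = y) = \pi\,\mathbb{1}(y = 0) + (1-\pi)\,
\frac{\Gamma(y+\theta)}{\Gamma(\theta)\,y!}
\left(\frac{\theta}{\theta+\mu}\right)^{\theta}
\left(\frac{\mu}{\theta+\mu}\right)^{y},$$

so that $P(Y=0) = \pi + (1-\pi)\left(\theta/(\theta+\mu)\right)^\theta$.

## Data model and genotype encoding

Genotypes arrive as integer storage codes: in the three-class mode
1 = homozygous reference, 2 = homozygous alternative, 3 = heterozygous,
0 = missing; the binary mode keeps only 1 = variant absent, 2 = present,
0 = missing. Storage codes are not dosages — regression uses the additive
recoding 1→0, 3→1, 2→2 (binary: 1→0, 2→1), with 0 mapped to `NA`. The
recoded matrix carries a `dosage` marker and refuses to be recoded twice,
so the two scales cannot be silently confused.

`create_study()` restricts both matrices to the intersection of their
barcode sets. Expression barcode order is canonical (the expression matrix
is usually the larger, primary asset); genotype columns are permuted to
match, and dropped barcodes are counted and reported. Cells with a missing
genotype at a given SNP are excluded pairwise for that SNP only, which
preserves power for well-genotyped SNPs instead of dropping cells
globally. Every pipeline verb appends one row to the study's parameter
log, so a finished study records its own provenance.

## Normalization

Five methods are offered, all writing a separate normalized layer and
leaving raw counts untouched (models that need counts keep using them):

| method | definition | notes |
|---|---|---|
| `logNormalize` | $\ln(1 + 10^4 \cdot c_{gj} / \sum_g c_{gj})$ | the dominant single-cell convention; the $10^4$ scale factor is this package's choice |
| `CPM` | counts per million | columns sum to $10^6$ |
| `TPM` | length-normalized, then per-million | needs a length for every gene; UMI counts have no length bias, so this is provided for completeness and protocol compatibility |
| `DESeq` | counts / median-of-ratios size factor | factors from genes with positive geometric means; falls back to positive-count geometric means (with a warning) when no gene is expressed everywhere |
| `limma` | quantile normalization of $\log_2(\mathrm{CPM} + 0.5)$ | makes all cell-wise distributions identical; "limma-based" is interpreted as quantile normalization, documented here because the name alone does not pin down a method |

Cells with zero total counts are rejected outright — every size factor is
undefined for them, and imputing them would fabricate signal.

## Quality control

`filter_gene_snp()` applies two literal-threshold rules:

* a gene is kept when its expression **exceeds** `expression_min`
  (strictly) in at least `expression_cells_percent`% of cells, computed on
  the normalized layer when one exists (the threshold is then in
  normalized units, which the parameter log records);
* a SNP is kept when **every** genotype class required by the encoding
  mode occurs in at least `snp_cells_percent`% (default 10) of the cells
  with a non-missing genotype at that SNP. Missing cells are excluded from
  the denominator; a SNP genotyped nowhere is dropped with a warning.

The class rule is deliberately strict: a class below the threshold gives
the regression almost no leverage, and under Hardy–Weinberg proportions it
implies a practical minor-allele-frequency floor of roughly
$\sqrt{0.10} \approx 0.32$ for three-class data. Filtering before or after
normalization is both supported; the order is recorded in the parameter
log rather than hard-coded.

## Cis pairing

A SNP is a cis candidate for a gene when it lies on the same chromosome
within `[gene_start − upstream, gene_end + downstream]`, 1-based with
inclusive boundaries (Ensembl convention), the lower bound floored at 1.
Strand is ignored — "upstream" always means lower coordinates — because
with the symmetric default windows (100 kb each side) the distinction is
immaterial, and window parameters are symmetric in intent. Chromosome
names are compared after stripping a leading `chr`, so `chr1` matches `1`
across annotation sources. Annotations come from local files (TSV, BED4,
GFF3 for genes; TSV or minimal VCF for SNPs): offline inputs keep runs
reproducible where a live annotation-service query would not be.

## Association testing

Per cell group and candidate pair:

* **linear** (normalized layer): OLS slope of expression on dosage,
  two-sided t-test with $n-2$ df. Constant expression returns slope 0,
  p 1; constant dosage skips the pair with a reason code.
* **poisson** (raw counts): log-link Poisson regression, Wald test on the
  slope, bounded IRLS iterations; non-convergence skips the pair.
* **zinb** (raw counts, default): the pooled-vs-per-class likelihood-ratio
  test. The null fits one ZINB to all cells; the alternative fits one ZINB
  per genotype class (all three parameters free per class, hence
  $3(G-1)$ df). Classes with fewer than `min_cells_per_class` (default 10)
  cells are dropped; fewer than two remaining classes skips the pair. The
  reported effect is $\log_2$ of the ratio of fitted overall means
  $(1-\pi)\mu$ between the highest- and lowest-dosage classes, which is
  what "fold change between extreme genotypes" means under the mixture.

The ZINB optimizer works on transformed parameters
($\mathrm{logit}\,\pi$, $\log\mu$, $\log\theta$) with BFGS, starting from
moment estimates ($\mu_0$ = mean of positive counts; $\theta_0$ by the
method of moments clipped to $[0.01, 100]$; $\pi_0$ = excess zero fraction
clipped to $[0.01, 0.95]$) plus two jittered restarts. The restart jitter
is seeded from a hash of the (SNP, gene) ids, so results do not depend on
evaluation order. Two guarantees are enforced rather than hoped for: the
reported likelihood never falls below the likelihood at initialization,
and each class fit is floored at the pooled parameters, which makes the
LRT statistic non-negative by construction. P-values are floored at
1e-300 before adjustment so numerical zeros survive the step-up/step-down
arithmetic.

Adjustment runs within each cell group across all of its tests (not pooled
across groups: groups ask distinct biological questions and may have very
different test counts). Non-finite p-values propagate as `NA` and are
excluded from the effective number of tests. Significance requires both
`adjusted_p < p_adjust_threshold` (default 0.05) and
`|effect| ≥ logfc_threshold` (default 0.1); the full unthresholded table
stays on the study for inspection.

## Visualization

`plot_qtl()` draws one panel per cell group (composed side by side) with
genotype class on the x-axis in dosage order: jittered points with class
mean bars (`QTLplot`), `violin`, `boxplot`, or per-class histograms
(`histplot`). Optional outlier trimming removes cells whose expression
exceeds the median plus four times the scaled MAD
($1.4826 \times$ the raw MAD, the normal-consistency convention); with
constant values the MAD is zero and nothing exceeds the median, so nothing
is dropped. Every plot's underlying tidy table is exported next to the
image — tests and reviews assert on data, never on pixels — and the point
jitter is seeded, so plot data are byte-deterministic.

## The synthetic-data generator

`simulate_qtl_data()` produces the ground-truth datasets used throughout
the test suite. Genotypes are drawn per SNP under Hardy–Weinberg
proportions at a minor-allele frequency sampled from `maf_range`, with
`missing_rate` entries set to missing; genotypes are per cell (a clonal
mosaic, matching the single-sample somatic use case) rather than per
donor. Expression is ZINB per gene; for planted pairs the NB mean is
scaled per dosage class as $\mu_d = \mu \cdot 2^{\mathrm{lfc}\cdot d/2}$,
so the overall-mean ratio between extreme classes equals
$2^{\mathrm{lfc}}$ exactly. Annotations place truth SNPs inside their
gene's default window, scatter half of the null SNPs into windows of
random genes, and park the rest on a separate chromosome so the pairing
logic always has true negatives. Each component draws from its own named
RNG substream derived from the seed, so enlarging one component never
perturbs another.

Defaults — 1000 cells, 100 genes, 80 SNPs, MAF 0.2–0.4, 5% missing
genotypes, $\pi \in [0.2, 0.4]$, $\theta \in [1, 3]$, baseline
$\mu \in [1, 10]$, 10 planted effects at one log₂ unit — describe a
moderately deep UMI experiment with common variants and realistic dropout.
Note that MAFs below ~0.32 produce hom-alt classes under the default 10%
class filter, so some simulated SNPs are legitimately filtered out; that
is the filter working, not a defect. What the generator does **not**
emulate: per-gene library-size covariation, batch effects, doublets,
ambient RNA, donor structure, linkage between SNPs. Passing tests
demonstrate the statistics are implemented correctly under the stated
model, not that real data meet the model's assumptions.

## Numerical choices and degenerate inputs

* ZINB parameter bounds via transformation, not penalties; invalid
  parameter proposals return a large objective value instead of NaN.
* Aggregated likelihood evaluation over unique count values makes each fit
  $O(\#\text{unique counts})$ per iteration.
* All-zero count vectors are degenerate ($\pi \to 1$) and flagged; the
  affected group is unusable and the pair is skipped.
* Zero-variance expression in the linear model is an exact "no effect"
  (slope 0, p 1), not an error; an exact fit reports p 0.
* Ties in quantile normalization are averaged.
* Window lower bounds floor at position 1; empty pair sets and empty
  filter survivors warn and return empty results rather than failing.

## Problem sizes used in the shipped checks

The test suite exercises oracle equivalence on 1000 random instances per
component (filters, pairing, all five adjustment methods, outlier rule),
calibration on 500 null pairs of 500 cells, power on 100 replicates of
1000 cells, and parameter recovery on 100 replicates of 2000 cells; the
acceptance script repeats the same computations from a caller-supplied
seed. These sizes give binomial standard errors of about 1% on the
reported rates while keeping a full run in the minutes range on a single
core.

## Known limitations

Only cis associations are tested; there is no trans mode. No covariate
adjustment (batch, donor, cell cycle) is available inside the tests — a
strong batch confound will surface as spurious associations. The ZINB LRT
frees all three parameters per class, which is conservative in power
relative to a dosage-as-covariate regression when the true effect is
monotone in dosage. TPM on UMI data divides by transcript length that UMI
counts are not biased by; it is included for protocol compatibility, not
recommended as a default. P-value calibration of the LRT relies on
asymptotics; with classes near the 10-cell minimum the chi-square
reference is approximate.
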