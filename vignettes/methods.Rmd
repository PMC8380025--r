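---
title: "Models and methods behind tissuespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tissuespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

# The analysis

`tissuespec` implements a tissue-level expression analysis for bulk
RNA-seq designs with several tissues and biological replicates (the
motivating design is five conifer tissues — embryo, megagametophyte,
needle, phloem and vegetative bud — with six replicates each, 30
samples in total). The pipeline answers two related questions per
gene: *is it preferentially upregulated in one tissue relative to all
others?* (PUR) and *is its expression confined to a single tissue?*
(the tau index). A hypergeometric singular enrichment analysis then
characterizes the GO functions over-represented in each resulting
gene set.

# Matrix construction

The pipeline starts either from per-sample transcript quantification
tables (Salmon `quant.sf` convention) plus a transcript-to-gene map,
or from a ready-made gene count matrix. From quantification tables,
gene raw counts are the sum of member-transcript `NumReads` and gene
TPM the sum of member-transcript TPM. Because contaminant transcripts
(taxonomy keyword hits: alveolata, metazoa, fungi, bacteria, archaea,
plus explicit exclude lists) are removed *after* quantification, the
removed TPM mass is repaired by rescaling every TPM column back to
10^6. When only a count matrix is available there is no length
information, so the per-million stage is counts-per-million; it plays
the same role in everything downstream.

Between-sample normalization is the trimmed mean of M-values (TMM),
computed from the raw count matrix and applied to the per-million
matrix. We use the standard construction: the reference sample is the
one whose upper-quartile of scaled counts is closest to the mean;
gene-wise log-ratios M and log-abundances A are formed over genes with
positive counts in both samples; the top and bottom 30% by M and 5% by
A are discarded; the factor is `2^` the precision-weighted mean of the
remaining M values (inverse approximate binomial variances as
weights); factors are anchored to geometric mean 1. On data where
samples differ only in sequencing depth all factors are 1; the method
earns its keep under composition bias, which the test-suite exercises
with spiked genes. The implementation reproduces `edgeR`'s TMM factors
to 10 decimal places on shared inputs (a cross-check in the test
suite, not a dependency of the implementation).

Replicate QC is a PCA and a Pearson correlation matrix of the
samples. The underlying values are `log2(count + 1)`: PCA on raw
counts is dominated by a handful of very highly expressed genes, so
the log scale is used deliberately even though the QC is described as
operating on the raw count matrix — the transformation is monotone
per gene and leaves the replicate-clustering question intact.

# Differential expression and the PUR rule

Differential expression uses a negative-binomial exact test on group
sums, the classic construction for small replicated designs.
Replicate counts are scaled to the pair's common effective library
size (geometric mean of library size x TMM factor) and rounded;
group sums `s_a`, `s_b` are formed. Under the null of equal means the
sum of `r` NB(mu, phi) replicates is NB(r mu, phi/r), and the test
conditions on the total `n = s_a + s_b`: the conditional law of `s_a`
is evaluated by enumerating `x = 0..n`, and the two-sided p-value sums
the probabilities of all outcomes no more probable than the observed
one (ties within 1e-12 relative included). At `phi = 0` the components
are Poisson and the conditional law is exactly binomial, which gives
the test its closed-form oracle. For totals above `enum_limit`
(default 10^4) the enumeration is windowed around the conditional mean
(+-50 conditional standard deviations) and the p-value becomes the
doubled smaller tail, capped at 1 — beyond that scale the discrete
two-sided rule and the doubled tail agree to within a few percent and
either is defensible.

Gene-wise dispersions are estimated by method of moments within each
tissue (`v = m + phi m^2`, negatives floored at 0), pooled across
tissues by count-weighted averaging, and shrunk 90% toward the 20%
trimmed-mean common dispersion. This is deliberately simpler than
conditional-ML machinery; its accuracy is covered by recovery tests
(Poisson data yields a common dispersion below 0.02; data simulated at
phi = 0.2 is recovered within [0.1, 0.3]) and the shrinkage weight is
a configurable parameter.

P-values are adjusted to FDR by the Benjamini–Hochberg step-up within
each tissue-pair family separately (10 families for 5 tissues),
mirroring per-contrast adjustment. A gene is **PUR** in tissue t when,
against *every* other tissue u, (i) its pairwise FDR is at most 0.05
and (ii) its mean `log2(TMM + 1)` in t exceeds that in u. Requiring
the FDR condition in all comparisons (rather than at least one) is the
conservative reading of an ambiguous rule and matches the
all-comparisons positivity requirement; it also guarantees a gene can
be PUR in at most one tissue. The exact test reports its own logFC
with a 0.125 pseudocount, but the PUR decision uses only the sign of
the TMM-based difference.

# The tau tissue-specificity index

Before tau, the TMM matrix is filtered: values below 1 are declared
"not expressed" (after log2 transformation this is exactly the
flooring of negative values to zero), and genes expressed in fewer
than 2 samples are removed — a gene seen in a single sample out of 30
carries no replicated evidence. For each retained gene, per-tissue
means `x_i` of the filtered log2 values are formed (the index is
defined on per-tissue means, not on the 30 samples as separate
dimensions), normalized by the maximum, and

    tau = sum_i (1 - x_i / max_j x_j) / (N - 1)

with N the number of tissues. tau is 0 for a uniformly expressed gene
and 1 exactly when every non-maximal tissue mean is exactly zero; the
filter produces exact zeros, so the tau = 1 call uses exact equality,
no epsilon. A gene is called tissue-specific only at tau = 1. On
well-expressed data every tau = 1 gene should also be PUR in the same
tissue — the package asserts this on synthetic data built to have the
DE power for it; on real data occasional exceptions are expected for
genes near the detection limit.

# Enrichment

The singular enrichment analysis is a one-sided hypergeometric test
per GO term against a custom background: with an annotated background
of size N, K background genes carrying the term and an annotated
study set of size n containing k carriers, `p = P(X >= k)`,
`X ~ Hypergeom(N, K, n)`. Only annotated genes count on either side,
genes sharing one annotation identifier can be collapsed to a single
representative (isoform redundancy would otherwise inflate K and k in
lockstep), and terms with fewer than 5 background carriers are not
tested. The PUR gene sets are tested against all genes in the raw
matrix; the tau = 1 sets against the genes surviving the tau filter.
"Hochberg FDR" in the delegated web tool's vocabulary is read as the
Benjamini–Hochberg step-up FDR — the standard meaning in enrichment
tools — with Hochberg's step-up FWER procedure available behind the
`method` switch. No GO-DAG ancestry propagation is performed: the
gene-to-term lists are used as given.

# The synthetic-data generator

`simulate_counts()` draws, per gene, a log-normal relative abundance
(meanlog 0, sdlog 1) and a gamma dispersion (shape 2, rate 10, mean
0.2 — a typical bulk RNA-seq between-replicate value); per sample, a
uniform expected library size on [1e5, 3e5]; counts are
`NB(L_s q_{g,t}, phi_g)` with the per-tissue abundance columns
normalized to sum to 1. Planted **specific** genes (50 per tissue by
default) have abundance exactly zero outside their home tissue — hard
zeros, matching the operational definition under which tau = 1
requires exact zeros after filtering; a leakage parameter (default 0)
exists for robustness experiments. Their home-tissue abundance is
floored at 1.0 on the relative scale (about 300 per million), keeping
them safely above the "not expressed" threshold. Planted **PUR**
genes (40 per tissue) have their abundance multiplied by 8 in the home
tissue. A GO annotation is generated alongside: ~2 random background
terms per gene plus one planted term per tissue covering 80% of that
tissue's planted genes and ~1% of null genes.

The defaults are a desk-scale rendition of the motivating design: the
tissue/replicate layout is kept at 5 x 6, while 2000 genes and
10^5-scale libraries stand in for the hundreds of thousands of contigs
and tens of millions of reads of a real conifer experiment. At these
sizes the per-gene counts (on the order of 10^2) and the
dispersion are realistic, so the statistical behaviour of every stage
is preserved; what the simulation does **not** emulate is assembly
artifacts (fragmented or chimeric contigs), isoform-level differential
usage, correlated genes, or the extreme sparsity of lowly expressed
contigs in real de novo transcriptomes. Passing recovery tests
therefore validate the statistical machinery, not robustness to
assembly noise.

`simulate_quant_files()` additionally splits each gene's counts across
isoforms with a gene-wise Dirichlet draw shared across samples, so
aggregation reproduces the gene matrix exactly; transcript lengths are
uniform on [400, 3000] with effective length `length - 150` (floored
at 25).

# Numerical and design choices

* Matrix text format: tab-separated, genes as rows, no quoting —
  the Trinity matrix convention. Values are written at full precision
  (`as.character` on doubles) so re-runs are byte-identical.
* Strict parsing everywhere: a malformed field fails with its line
  number rather than being coerced, because matrices feed statistics.
* Contaminant keyword matching is case-insensitive on
  whitespace/semicolon/comma-delimited tokens: "bacteria" matches the
  lineage token but not "Bacteriophage-resistance". Unannotated
  contigs are kept — only positive hits are contaminants.
* The log2 pseudocount on the PUR path is 1.0 (maps 0 to 0); the tau
  path uses no pseudocount and relies on the <1 floor instead.
* Ties in the exact test's rejection set use a 1e-12 relative
  tolerance; the tau = 1 test uses exact zero comparison.
* Degenerate inputs: an all-zero gene in a tissue pair is reported
  with p = 1 and logFC = 0, not an error; a sample with zero library
  size, a tissue with one replicate, or a constant matrix for PCA are
  errors.
* All stage problem sizes in tests and the acceptance script (2000
  genes, 5 x 6 design, 10^5-scale libraries) were chosen as the
  package's desk-scale study conditions; they are the generator's
  defaults, not per-test knobs.

# Known limitations

The exact test treats the scaled-and-rounded group sums as NB sums
with the pair-pooled dispersion — a documented approximation of the
full quantile-adjusted conditional ML machinery; its type-I error is
verified empirically (within [0.03, 0.07] at nominal 0.05). The
dispersion estimator is biased low for small replicate numbers at
very low counts; shrinkage toward the common value absorbs most of
this at the default design. Enrichment treats GO terms as a flat
vocabulary; parent terms are not credited with child-term hits.
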