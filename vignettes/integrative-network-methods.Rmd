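---
title: "Methods: integrative gene-lipid-biomarker network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative gene-lipid-biomarker network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmnet)
```

## Scope and assumptions

`mdmnet` analyses a two-group study (group A = reference/control, group B =
condition) observed in three layers: gene-level RNA-seq counts, a serum
lipidome resolved into species with class annotations, and a panel of
soluble inflammation biomarkers. The pipeline assumes

* counts are gene-level integers from a standard quantification workflow,
  with every sample sequenced deeply enough that total counts are positive;
* lipid concentrations (µM) and biomarker levels are positive, roughly
  log-normal quantities, with `NA` marking below-LOQ measurements (allowed
  in the lipid and biomarker panels, never in counts);
* associations of interest are monotone and approximately linear on the
  scales analysed (log2-CPM for genes, raw concentrations for lipids and
  biomarkers), so that Pearson correlation is the appropriate coupling
  statistic.

All stages are deterministic given their inputs; the only randomness in the
package is in the synthetic-data generator, which threads a single seed.

## Differential expression

Between-sample scaling uses trimmed-mean-of-M-values factors: the reference
sample is the one whose 75th-percentile count fraction is closest to the
mean of those quantiles; for each other sample the gene-wise log2 relative
expression ratios are trimmed (30% from each tail by M, 5% from each tail
by A, the standard published trim fractions) and averaged with asymptotic
inverse-variance weights; factors are rescaled to geometric mean 1.
Normalized expression is `log2((c + 0.5)/(N f + 1) * 1e6)`; the 0.5 prior
count keeps zeros finite at the cost of a perturbation of order
`0.5/((2c+1) ln 2)` in depth-invariance, which is why heavily expressed
genes are effectively scale-invariant while low-count genes are mildly
shrunk toward the library average.

Testing uses a moderated t: per-gene pooled variance on
`n_A + n_B - 2` df, an inverse-chi-square prior fitted by matching the first
two moments of `log s^2` (Newton iteration on the trigamma function), a
posterior variance `(d0 s0^2 + d s^2)/(d0 + d)`, and a two-sided p on
`d0 + d` df (capped at the pooled df of all tested genes). When the excess
variance of `log s^2` is non-positive the prior df is infinite and every
posterior variance equals the prior scale, here estimated as the mean of the
per-gene variances; with a single testable feature no moment matching is
possible and the statistic reduces to the ordinary pooled t. The log2 fold
change is the difference of group means of log2-CPM (B minus A) — a
deliberate design choice over a GLM coefficient, because it is closed-form,
exactly testable, and all downstream stages consume only (logFC, p, adj p).
"Adjusted p" is Benjamini-Hochberg throughout, applied within each tested
family, never pooled across stages.

Genes with zero counts in every sample are dropped before normalization
(ratios are undefined for them); genes with zero residual variance are
flagged and excluded from testing rather than given arbitrary statistics.

## Gene-set variation scores

For gene *i* and sample *j* the expression statistic is a Gaussian-kernel
across-sample CDF, `mean_k pnorm((e_ij - e_ik)/h_i)` with bandwidth
`h_i = sd_i/4`. Genes constant across samples receive the neutral value 0.5
(simulated data can produce them; erroring would be wrong). Within each
sample genes are ranked by this statistic, descending, ties broken by row
order, and the symmetric rank statistic `|p/2 - rank|` up-weights both
extremes. For each set the score is the sum of the maximum positive and
minimum negative deviations (each clamped at zero) of a random walk whose
inside-set steps are proportional to the rank statistic (exponent tau = 1)
and whose outside-set steps are uniform; this "maximum difference"
convention keeps scores in [-1, 1] and near zero for incoherent sets. Sets
are intersected with the matrix's genes; sets with fewer than `min_size = 5`
mapped members are dropped, as are sets covering every gene of the matrix,
whose walk has no outside-set steps and is degenerate — that situation
arises in practice when the cascade's selected-gene sub-matrix is small.

## Covariate association and the cascade

"Regressed against" a serum covariate is implemented as per-feature Pearson
correlation with a two-sided t-based p (the slope sign of a univariate
regression equals the sign of r); no multi-covariate adjustment is offered,
matching the univariate presentation of the analyses this package supports.
The cascade reproduces the biomarker-guided pathway analysis: genes
associated with the covariate at p <= 0.05 are re-scored as gene sets, and
set scores are re-associated with the same covariate, reported at p <= 0.05
ranked by PCC. The gene stage is computed by the same function whether
called directly or inside the cascade, so the two are identical by
construction. The confounder scan is the same computation against a
putative confounder (age), reporting the count of genes below a nominal
threshold. Lipid-class covariates enter as ordinary covariate vectors
(class totals by default; species mode is a matter of passing a species row
instead).

## The integrative network

Gene nodes are the genes differential at nominal p < 0.01 — nominal rather
than adjusted because the selection feeds a correlation screen, and the
stricter adjusted cut would leave the model under-populated at cohort scale;
a configurable anchor list (`anchor_gene_panel()` for the motivating
study's eight genes) is appended regardless of p and retained even if
isolated. Each lipid species is scored by the signed mean of its
correlations to the selected genes, then ranked on the absolute mean —
signed averaging first, so balanced positive and negative correlations
cancel by design; a mean-of-|r| alternative is available as a config flag.
The top 50 species, all biomarkers and the gene nodes are then correlated
pairwise within the allowed pair classes (gene-lipid, gene-biomarker,
gene-gene; lipid-lipid, lipid-biomarker and biomarker-biomarker pairs are
never computed), and edges with `|r| > 0.5` and `p < 0.01` are retained.
The magnitude filter is two-sided because inverse gene-lipid relationships
(the PUFA side of the biology) are as informative as direct ones; a
`signed_edge_filter` flag gives the literal one-sided reading. Edge
p-values are nominal by default (a BH option exists) — the filter is a
display/selection rule, not an inference.

Determinism is enforced structurally: candidate sets, pair enumeration and
edge ordering are all sorted by id, so identical inputs give byte-identical
node and edge tables.

## The synthetic study generator

The generator emulates the structure the analysis assumes, not any real
cohort's effect sizes. Defaults: 13 + 15 samples (the two-group design of
the motivating cohort), 2,000 genes (a desk-scale stand-in for the expressed
transcriptome; abundances log-normal with sdlog 1.2 so planted effects are
identifiable), 10% planted DE genes with |log2FC| in {1, 2}, per-gene NB
dispersions log-normal around 0.1, library sizes log-normal around 10^6.
One latent inflammation factor, shifted by 1 SD in group B, couples the
layers: it loads on a 100-gene module drawn from the up-regulated DE genes
(mirroring the biology in which the inflammation-tracking genes are
themselves top DEGs — a disjoint module would make the signed-mean lipid
statistic cancel and the planted structure unrecoverable by design), on a
30-species lipid block, and on all 12 biomarkers, with loading 0.8 (the
latent-factor correlation of each loaded feature's noise-free log level).
The lipidome spans exactly the 13 Lipidyzer classes, with free fatty acids
resolved into named SaFA/MUFA/PUFA species; group-B class effects default to
ceramides and saturated FFAs up 1.5-fold and polyunsaturated FFAs down to
2/3, reproducing the qualitative serum differences of the motivating study,
which reports directions but no usable quantitative effect sizes.

What the generator does *not* emulate: realistic gene-gene correlation
structure beyond the single factor, batch effects, library-preparation
biases, lipid co-regulation within classes, or below-LOQ censoring patterns.
Passing recovery tests therefore demonstrates that the pipeline's statistics
behave as designed under the assumed model — calibrated nulls, unbiased
fold-change recovery, planted-structure ranking — not that any particular
real-data finding is correct.

## Numerical choices and degenerate inputs

* Correlation p-values use the t approximation on n-2 df; |r| = 1 maps to
  p = 0. Pairs with missing values are dropped; fewer than 3 complete pairs
  or a constant vector is an error at the primitive level, and callers that
  scan many features skip and log such features instead of failing.
* The trigamma inversion runs Newton iterations to relative tolerance
  1e-10 with closed-form guards at both extremes.
* Ties are broken by feature/lipid/sample id everywhere a total order is
  needed (gene selections, rankings, edge tables), making every output
  reproducible to the byte.
* The fold-change recovery experiment in the acceptance suite runs the
  generator with `factor_shift = 0, loading = 0` and balanced ±1 fold
  changes: it measures the estimator's bias for the planted effect, so the
  design removes the latent-factor group shift (which would add to module
  genes' effects) and keeps the planted mass balanced (single-direction DE
  at 10% of genes produces a known TMM composition bias that the reference
  implementation reproduces as well).
* Problem sizes in the test and acceptance suites (2,000 genes, 200 lipids,
  10,000-feature null panels, 5-20 seeds per recovery experiment) are the
  package's chosen desk-scale study conditions; they complete in well under
  a minute per suite section on one CPU.

## Known limitations

* No negative-binomial GLM or exact test; the moderated t on log2-CPM is
  the package's defined DGE stage. At very low counts its fold changes are
  shrunk by the prior count.
* No permutation p-values for correlations by default (the t approximation
  is exact under bivariate normality and anti-conservative for heavy-tailed
  data); no partial or age-adjusted correlations.
* The GSVA stage offers only the normalized-expression (Gaussian-kernel)
  mode, not a count-kernel mode.
* MSigDB collections cannot be redistributed; gene-set inputs are the
  user's GMT files, and the workflow's generated collections (planted
  module plus random sets) exist to exercise the machinery.
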