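---
title: "Calling biallelic expression of imprinted and X-linked genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling biallelic expression of imprinted and X-linked genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biallele)
```

## The problem

Imprinted genes are expressed from only one parental allele; X-linked
genes in female cells are silenced on one X by X-chromosome inactivation
(XCI). Aberrant *biallelic* expression of an imprinted gene (loss of
imprinting, LOI) is a hallmark of reprogramming artefacts in pluripotent
stem cells, of some cancers, and of culture-induced epigenetic drift;
biallelic expression of X-linked genes in single cells indicates X
reactivation or escape from XCI. Both can be read out from RNA-seq: at a
heterozygous single-nucleotide variant (SNV), reads carrying the
reference and the alternative allele count the two alleles' transcripts.

`biallele` takes per-SNV allele counts (the output of GATK
ASEReadCounter or any tool emitting the same table) for a curated panel
of imprinted and sex-linked genes and decides, per SNV, per gene, and —
for single-cell data — per cell population, whether there is evidence of
biallelic expression.

## The SNV model and its filters

For an SNV with reference count $r$ and alternative count $a$, define
the overall depth $OD = r + a$, the minor allele count
$MAC = \min(r, a)$, and the allelic ratio
$AR = \min(r,a) / \max(r,a)$ (a minor/total variant is available for
display). An SNV is

* **low-coverage** when $OD < OD_{\min}$;
* **biallelic** when $MAC \ge MAC_{\min}$ and the mode criterion holds;
* **monoallelic** otherwise.

Two alternative mode criteria are supported:

* **Allelic ratio**: $AR \ge AR_{\min}$ (always evaluated on the
  minor/major scale, whatever the display convention).
* **Exact binomial**: the upper tail $P(X \ge MAC)$ for
  $X \sim \mathrm{Bin}(OD, 1/6)$ must not exceed $p_{\max}$. The null
  proportion of 1/6 separates genuine biallelic transcription from
  minor reads generated by sequencing or alignment error; testing
  "greater than 1/6" makes a small number of stray reads at high depth
  insufficient for a call.

The MAC gate applies in both modes; in binomial mode it is a guard
against artefacts at depths where very few minor reads can already give
a small p-value. All comparisons are inclusive ($\ge$, $\le$): at
$OD = 20$ and $AR_{\min} = 0.2$ the smallest passing minor count is
exactly 4. No multiple-testing correction is applied to the per-SNV
binomial p-values: the cutoff is a fixed per-SNV filter, not an
inference about a family of hypotheses, and correcting would make a
call's meaning depend on how many other SNVs happened to be covered.

Defaults are $OD \ge 20$, $MAC \ge 4$, $AR \ge 0.2$ for bulk libraries
of typical depth (>10M reads), and $OD \ge 15$, $MAC \ge 3$,
$AR \ge 0.2$ for single cells (`sc_thresholds()`), trading a little
false-positive control for sensitivity at the lower per-cell depth.

## From SNVs to genes

A gene is called **biallelic** in a sample when at least
`min_biallelic_snvs` of its SNVs are biallelic (default 2 in bulk: a
genuinely biallelic, SNV-bearing transcript should show the signal at
more than one site, and requiring two suppresses isolated artefacts;
default 1 per cell in single-cell data, where SNV coverage is sparse).
Genes with at least one SNV at sufficient depth but too few biallelic
SNVs are **detected, not biallelic**; genes with reads that never reach
$OD_{\min}$ are **below threshold** (the gray square of the summary
panel); genes with no reads at all are **undetected**. The distinction
between the last two is a deliberate two-tier reading of "detected":
coverage too thin to judge is different from no expression evidence,
and conflating them would make threshold choices silently change the
set of "expressed" genes.

The per-gene display statistic `mean_biallelic_ar` is the mean
minor/major ratio over the biallelic SNVs — 1 means perfectly balanced
alleles. In the exported call table, a gene × sample with no biallelic
SNV collapses to a single virtual SNV `rs_multi` carrying the *sum* of
the gene's ref/alt counts; the sum (rather than, say, the maximum) is
the only order-independent aggregate and is meant purely as an
expression indicator. An `rs_multi` row is never biallelic by
construction: it reports `monoallelic`, or `low_coverage` when even the
summed depth is below $OD_{\min}$.

## Single cells

Per-cell calls use the single-cell thresholds; a cell *expresses* a
gene when at least one of the gene's SNVs reaches $OD_{\min}$ in that
cell (the tool only sees SNV-level counts, so SNV coverage is the only
usable expression proxy). A gene enters the analysis when it is
expressed in at least 10 cells in at least one group; it is called
biallelic in a group when at least 20% of its expressing cells carry a
biallelic SNV. Both boundaries are inclusive ("at least"): 2 biallelic
cells out of exactly 10 expressing cells is a call. When per-cell SNV
coverage is too sparse (droplet protocols), `pseudo_bulk()` sums counts
across cells and routes the pool through the bulk caller; pooling
commutes with partitioning, so staged aggregation cannot change the
result.

## X-inactivation metrics

Parental-allele orientation is inferred from a reference developmental
stage in which the maternal X is known to dominate (the mid 2-cell
stage in mouse embryos): per X-linked SNV, the allele with the larger
count *summed over the reference-stage cells* is deemed maternal.
Summing before comparing, rather than a per-cell majority vote, is
robust at low per-cell coverage; tied loci are left unoriented and drop
out downstream.

The per-cell average allelic ratio (AAR) is the arithmetic mean, over
oriented X-linked genes with summed depth $\ge OD_{\min}$ in the cell,
of the gene-level paternal/maternal count ratio. Counts are summed to
gene level before forming ratios; ratios are capped at a configurable
maximum (default 10) so that genes with zero maternal reads contribute
the cap rather than infinity and cell means stay finite. Both choices
(genes-then-cells averaging, the cap) are parameterised because neither
is forced by the data model. An AAR near 0 means exclusively maternal
expression, near 1 a reactivated or balanced X, near the cap a
paternal-skewed X. Stage comparisons use two-sided Wilcoxon rank-sum
tests, computed only when both stages have at least 3 cells; completely
tied samples report p = 1. An X-linked gene is an XCI *escapee* when
its single-cell status is biallelic in at least 2 individuals.

## Benchmarking

Two procedures quantify calling accuracy. `estimate_fdr()` compares RNA
calls with exome-derived genotypes: among SNVs covered by ≥5 reads in
RNA and in both exome replicates, a biallelic RNA call is a false
positive when the site is heterozygous in neither replicate, and
FDR = FP/(TP+FP) is reported over the threshold grid 20–4 / 15–3 /
10–2 (OD–MAC). `fdr_comparison_test()` is the two-proportion chi-square
test with Yates' correction for asking whether relaxing thresholds
raised the false-positive rate. `precision_recall()` sweeps depth ×
(AR or p-value) grids over an experimentally validated truth set,
re-calling every SNV from raw counts at every grid point — no caching
across grid points, so each point's semantics are exactly the
thresholds it advertises. SNVs below the depth cutoff count as "not
called", which is why recall is monotonically non-increasing in the
depth cutoff. The grids default to MAC = 1 so that depth and the mode
criterion are the only active filters, mirroring how such sweeps are
usually presented.

## The simulator

`simulate_bulk()` and `simulate_cells()` generate allele-count tables
with known truth so that every caller in the package is testable
without any external data. Study conditions are fixed in
`sim_config()`:

* six gene classes (imprinted monoallelic, imprinted LOI, X-linked
  subject to XCI, X-linked escapee, Y-linked, autosomal biallelic),
  6 genes × 4 SNVs each by default — enough for stable per-class
  proportions while keeping a full run under a second;
* per-SNV depth negative-binomial with mean 60 and size 4 in bulk
  (heterogeneous expression; Poisson available), divided by 4 with
  size 1 per cell (shallower and burstier, giving realistic dropout);
* per-read error rate 0.005 — the order of post-filter Illumina
  error — so monoallelic loci emit minor reads only through error;
* biallelic loci emit a minor fraction θ = 0.5 (balanced);
* 6 bulk samples alternating female/male; 60 female cells; XCI skew
  0.5 (random inactivation).

A locus' emitted alternative-allele fraction is
$f_\text{eff} = f(1-\varepsilon) + (1-f)\varepsilon$, with $f$ the
biological fraction (0 or 1 for monoallelic, θ for biallelic, the
pooled $1-\text{skew}$ for bulk female X under XCI). Bulk female X
genes under random XCI therefore *look* biallelic — deliberately so:
pooling cells that silenced different X copies is exactly why bulk
RNA-seq cannot resolve XCI status and single-cell data are needed. A
gene × sample is truth-labelled biallelic when its minor fraction
exceeds 5%, a biological floor below which expression is effectively
monoallelic.

What the simulator does *not* model — reference-mapping bias,
mappability artefacts, reads spanning two SNVs, genotyping error in
the catalogs — bounds what passing tests show: they demonstrate that
the decision rules implement their definitions and behave correctly
under binomial sampling noise, not that the thresholds are optimal for
any particular real library.

## Numerical and degenerate-input choices

* Allelic ratio at equal counts is exactly 1 (no special-casing);
  ratios are undefined at zero depth, and callers route $OD = 0$ to
  low-coverage/undetected before computing them.
* At multi-allelic sites the reference and the best-supported
  alternative are kept; ties among alternatives break
  lexicographically, so ingestion is deterministic.
* Catalog SNVs falling in two overlapping genes are assigned to *both*
  genes; counts are reused per gene so that each gene keeps its full
  evidence.
* Coordinates are 1-based internally (VCF convention); BED input is
  converted on load. Strand is annotation-only: allele counts are
  strandless.
* `totalCount` disagreements in input tables are resolved in favour of
  `refCount + altCount` (the two-allele model used throughout), with a
  warning.
* The simulators draw from a generator seeded by `sim_config(seed=)`
  and restore the caller's RNG state afterwards.

## Problem sizes

The shipped tests and the acceptance script run the simulators at the
default sizes above (36 genes × 6 samples bulk; 40–60 cells
single-cell), sweep the binomial oracle to depth 200, and evaluate
monotonicity on 1,000 simulated SNVs — sizes chosen so a scientist can
re-run everything in well under a minute while keeping stochastic
checks comfortably inside their sampling-error bounds.

## Limitations

A gene not called biallelic is not demonstrably monoallelic: absence of
evidence may reflect low coverage, low expression, or absence of
heterozygous SNVs in the locus — a particular concern in inbred mouse
strains. Bulk data cannot resolve XCI. The binomial model ignores
overdispersion; a beta-binomial extension would be natural but is not
implemented. The validated truth-set loaders expect the user to supply
their own validation table; the package ships none.
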