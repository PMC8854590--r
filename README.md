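# biallele

Biallelic-expression calling for imprinted and X/Y-linked genes from
RNA-seq allele counts, in bulk and single-cell data.

## What it is for

Imprinted genes are expressed from a single parental allele, and
X-linked genes in female cells from a single X. Aberrant **biallelic**
expression — loss of imprinting (LOI) in iPSCs, organoids or tumours,
X-reactivation in naive pluripotent cells and early embryos, escape
from X inactivation (XCI) in somatic cells — is readable from RNA-seq
through the read counts of the two alleles at heterozygous SNVs. This
package implements the post-alignment analytical core of that readout
for people assessing pluripotent cell lines, organoids, embryos or
cancer samples: it consumes per-SNV allele-count tables (the GATK
ASEReadCounter dialect), classifies SNVs and genes, aggregates
single-cell evidence, computes X-inactivation metrics, and benchmarks
its own calls.

## The model

For an SNV with reference/alternative read counts $(r, a)$:

* overall depth $OD = r + a$, minor allele count $MAC = \min(r, a)$,
  allelic ratio $AR = \min(r,a)/\max(r,a)$;
* the SNV is **low-coverage** if $OD < OD_{\min}$, **biallelic** if
  $MAC \ge MAC_{\min}$ and either $AR \ge AR_{\min}$ (AR mode) or the
  exact binomial upper tail $P(X \ge MAC)$, $X \sim \mathrm{Bin}(OD,
  1/6)$, is $\le p_{\max}$ (binomial mode); **monoallelic** otherwise;
* a gene is biallelic in a bulk sample when $\ge 2$ of its SNVs are
  biallelic (defaults $OD\ge20$, $MAC\ge4$, $AR\ge0.2$);
* in single-cell data (defaults $OD\ge15$, $MAC\ge3$, $AR\ge0.2$, one
  SNV per cell) a gene is biallelic in a group when $\ge 20\%$ of the
  cells expressing it carry a biallelic SNV, among genes expressed in
  $\ge 10$ cells of $\ge 1$ group;
* the per-cell **average allelic ratio** (AAR) over X-linked genes is
  the mean of gene-level paternal/maternal count ratios (orientation
  inferred from a maternal-dominated reference stage; ratios capped at
  10), with AAR $\approx 1$ indicating two active X chromosomes;
* evaluation: FDR of biallelic calls against exome-derived
  heterozygous genotypes over an (OD, MAC) grid, and precision/recall
  sweeps over validated truth sets.

See the methods vignette (`vignettes/biallelic-calling.Rmd`) for the
full account, including the simulator used as ground truth.

## Worked example

Simulate a six-sample bulk experiment with known ground truth (six
gene classes: imprinted monoallelic, imprinted LOI, X-linked under
XCI, X-linked escapee, Y-linked, autosomal biallelic) and call it:

```r
library(biallele)
sim <- simulate_bulk(sim_config(seed = 1))
fit <- call_biallelic(sim$tables, sim$kb)
print(fit)
#> Biallelic-expression calls: 6 sample(s), 36 gene(s)
#> SNV thresholds: OD >= 20, MAC >= 4, AR >= 0.2 (minor/major); gene: >= 2 biallelic SNV(s)
#> gene x sample statuses:
#>
#>              biallelic detected_not_biallelic        below_threshold
#>                    108                     90                      0
#>             undetected
#>                     18
```

108 gene × sample pairs are biallelic: the LOI and autosomal-biallelic
genes in all six samples, plus the X-linked genes in the three female
samples — pooled bulk female X looks biallelic under random XCI, which
is exactly why XCI calls need single-cell data. The 18 undetected
pairs are the Y-linked genes in the female samples; none of the
monoallelic imprinted genes or male sex-chromosome genes is called.
Per-SNV rows, with the `rs_multi` collapse for genes lacking biallelic
SNVs, come from `call_table(fit)`:

```r
head(call_table(fit), 2)
#>   sample_id               gene_id                     snv_id ref_count
#> 1 sample_01 AUTOSOMAL_BIALLELIC_1 rs_AUTOSOMAL_BIALLELIC_1_1        37
#> 2 sample_01 AUTOSOMAL_BIALLELIC_1 rs_AUTOSOMAL_BIALLELIC_1_2        45
#>   alt_count call_status allelic_ratio p_value
#> 1        46   biallelic     0.8043478      NA
#> 2        43   biallelic     0.9555556      NA
```

Real data enter through `load_knowledge_base()` (gene BED + metadata +
SNV catalog VCFs) and `read_aser_table()`; `sc_call()`,
`pseudo_bulk()`, `infer_orientation()`/`compute_aar()`,
`estimate_fdr()` and `precision_recall()` cover the single-cell, XCI
and benchmarking workflows. A command-line wrapper is installed at
`inst/cli/biallele` (subcommands `call`, `sc-call`, `xci`, `evaluate`,
`simulate`, `render`).

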