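#' Collapse SNV calls for one gene x sample to a gene status
#'
#' A gene is `biallelic` when at least `min_biallelic_snvs` of its SNVs are
#' biallelic (requiring several supporting SNVs filters out sequencing
#' artefacts); `detected_not_biallelic` when at least one SNV reaches the
#' overall-depth threshold but too few are biallelic; `below_threshold`
#' when reads map on its SNVs but none reaches the depth threshold; and
#' `undetected` when no reads map at all. `mean_biallelic_ar` is the mean
#' minor/major allelic ratio over the biallelic SNVs (always minor/major,
#' whatever the display convention) — the closer to 1, the more balanced
#' the two alleles.
#'
#' @param calls Data frame of SNV calls for a single gene and sample, as
#'   produced by [call_snvs()].
#' @param t The `ase_thresholds` used for calling.
#' @param gene_id,sample_id Identifiers (defaulting to those in `calls`).
#' @return One-row data frame: `gene_id`, `sample_id`, `n_snvs_detected`,
#'   `n_snvs_biallelic`, `mean_biallelic_ar`, `status`.
#' @export
collapse_gene <- function(calls, t, gene_id = NULL, sample_id = NULL) {
  stopifnot(inherits(t, "ase_thresholds"))
  if (is.null(gene_id))
    gene_id <- if (nrow(calls)) calls$gene_id[1] else NA_character_
  if (is.null(sample_id))
    sample_id <- if (nrow(calls)) calls$sample_id[1] else NA_character_
  if (nrow(calls)) {
    stopifnot(all(calls$gene_id == gene_id),
              all(calls$sample_id == sample_id))
  }
  n_detected <- sum(calls$od >= t$od_min)
  n_biallelic <- sum(calls$status == "biallelic")
  total_reads <- sum(calls$od)
  mean_ar <- if (n_biallelic > 0) {
    bi <- calls[calls$status == "biallelic", , drop = FALSE]
    mean(compute_ar(bi$ref_count, bi$alt_count, "minor_over_major"))
  } else NA_real_
  status <- if (n_biallelic >= t$min_biallelic_snvs) "biallelic"
    else if (n_detected >= 1L) "detected_not_biallelic"
    else if (total_reads > 0L) "below_threshold"
    else "undetected"
  data.frame(gene_id = gene_id, sample_id = sample_id,
             n_snvs_detected = n_detected, n_snvs_biallelic = n_biallelic,
             mean_biallelic_ar = mean_ar, status = status,
             stringsAsFactors = FALSE)
}

# Gene x sample summary over all knowledge-base genes and all samples
# (genes with no observations in a sample are undetected).
summarize_genes <- function(snv_calls, kb, t, samples) {
  out <- vector("list", nrow(kb$genes) * length(samples))
  i <- 0L
  for (g in kb$genes$gene_id) {
    for (s in samples) {
      rows <- snv_calls[snv_calls$gene_id == g & snv_calls$sample_id == s,
                        , drop = FALSE]
      i <- i + 1L
      out[[i]] <- collapse_gene(rows, t, gene_id = g, sample_id = s)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter gene summaries for display/export
#'
#' `"all"` keeps everything; `"detected"` keeps genes detected (at least
#' one SNV at sufficient depth, or reads below threshold) in at least one
#' sample; `"biallelic_in_any_sample"` keeps genes called biallelic in at
#' least one sample. A kept gene retains its rows for every sample, so the
#' panel stays rectangular.
#'
#' @param summaries Gene-summary data frame (e.g. `fit$gene_summary`).
#' @param which One of `"all"`, `"detected"`, `"biallelic_in_any_sample"`.
#' @return The filtered data frame.
#' @export
gene_display_filter <- function(summaries,
                                which = c("all", "detected",
                                          "biallelic_in_any_sample")) {
  which <- match.arg(which)
  if (which == "all") return(summaries)
  keep_gene <- switch(which,
    detected = unique(summaries$gene_id[summaries$status != "undetected"]),
    biallelic_in_any_sample =
      unique(summaries$gene_id[summaries$status == "biallelic"]))
  summaries[summaries$gene_id %in% keep_gene, , drop = FALSE]
}

#' Export the gene-summary matrix as a tab-delimited file
#'
#' Rows follow genomic position, columns the supplied sample order; the
#' export reflects the chosen display filter.
#'
#' @param x An `ase_calls` object.
#' @param path Output TSV path.
#' @param which Display filter passed to [gene_display_filter()].
#' @return `path`, invisibly.
#' @export
export_gene_summary <- function(x, path, which = "all") {
  stopifnot(inherits(x, "ase_calls"))
  gs <- gene_display_filter(x$gene_summary, which)
  gs$gene_id <- factor(gs$gene_id, levels = x$genes$gene_id)
  gs$sample_id <- factor(gs$sample_id, levels = x$samples)
  gs <- gs[order(gs$gene_id, gs$sample_id), , drop = FALSE]
  gs$gene_id <- as.character(gs$gene_id)
  gs$sample_id <- as.character(gs$sample_id)
  write.table(gs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
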