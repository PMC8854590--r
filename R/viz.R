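#' Render the gene summary panel
#'
#' Dot-matrix view of gene x sample statuses: rows are genes ordered by
#' genomic position, columns are samples in display order. A filled dot
#' marks a biallelic gene — its area grows with the number of supporting
#' biallelic SNVs and its colour brightens towards full orange as the mean
#' minor/major allelic ratio approaches 1 (balanced alleles). An empty
#' circle marks a detected gene with no biallelic call, a gray square a
#' gene whose reads never reach the depth threshold, and a blank cell an
#' undetected gene.
#'
#' @param x An `ase_calls` object.
#' @param file Optional PDF path; `NULL` draws on the active device.
#' @param which Display filter, see [gene_display_filter()].
#' @param sample_order Optional sample ordering (default: the fit's).
#' @return Invisibly, the gene-summary data frame that was drawn.
#' @export
render_gene_panel <- function(x, file = NULL, which = "all",
                              sample_order = NULL) {
  stopifnot(inherits(x, "ase_calls"))
  gs <- gene_display_filter(x$gene_summary, which)
  if (nrow(gs) == 0L) stop("empty gene summary", call. = FALSE)
  samples <- if (is.null(sample_order)) x$samples else sample_order
  stopifnot(all(gs$sample_id %in% samples))
  genes <- x$genes$gene_id[x$genes$gene_id %in% unique(gs$gene_id)]

  if (!is.null(file)) {
    pdf(file, width = max(4, 1 + 0.45 * length(samples)),
        height = max(3, 1 + 0.22 * length(genes)))
    on.exit(dev.off())
  }
  old <- par(mar = c(1, 8, 6, 1)); on.exit(par(old), add = TRUE)
  nx <- length(samples); ny <- length(genes)
  plot(NA, xlim = c(0.5, nx + 0.5), ylim = c(ny + 0.5, 0.5),
       axes = FALSE, xlab = "", ylab = "")
  axis(3, at = seq_len(nx), labels = samples, las = 2, tick = FALSE,
       cex.axis = 0.8)
  axis(2, at = seq_len(ny), labels = genes, las = 2, tick = FALSE,
       cex.axis = 0.7)
  pal <- colorRampPalette(c("#FFF2CC", "#FF8C00"))(101)
  max_snvs <- max(gs$n_snvs_biallelic, 1)
  for (i in seq_len(nrow(gs))) {
    gx <- match(gs$sample_id[i], samples)
    gy <- match(gs$gene_id[i], genes)
    st <- gs$status[i]
    if (st == "biallelic") {
      cex <- 0.8 + 1.7 * sqrt(gs$n_snvs_biallelic[i] / max_snvs)
      col <- pal[1 + round(100 * gs$mean_biallelic_ar[i])]
      points(gx, gy, pch = 21, bg = col, col = "gray30", cex = cex)
    } else if (st == "detected_not_biallelic") {
      points(gx, gy, pch = 1, col = "gray30", cex = 1.1)
    } else if (st == "below_threshold") {
      points(gx, gy, pch = 15, col = "gray70", cex = 1.1)
    }  # undetected: blank
  }
  box(col = "gray80")
  invisible(gs)
}

#' Render the per-SNV panel for one gene
#'
#' One barplot per sample with one stacked bar per SNV (reference reads in
#' blue, alternative in red). Solid bars are biallelic SNVs, transparent
#' bars monoallelic ones, grayscale bars SNVs below the depth threshold.
#' When a gene x sample has no biallelic SNV, a single `rs_multi` bar
#' carries the summed counts to indicate the gene's expression level.
#'
#' @param x An `ase_calls` object.
#' @param gene_id Gene to display (must exist in the knowledge base).
#' @param file Optional PDF path; `NULL` draws on the active device.
#' @return Invisibly, the `call_table` rows that were drawn.
#' @export
render_snv_panel <- function(x, gene_id, file = NULL) {
  stopifnot(inherits(x, "ase_calls"))
  if (!gene_id %in% x$genes$gene_id)
    stop("unknown gene: ", gene_id, call. = FALSE)
  ct <- call_table(x)
  rows <- ct[ct$gene_id == gene_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("gene ", gene_id, " has no reads in any sample", call. = FALSE)
  samples <- x$samples[x$samples %in% unique(rows$sample_id)]

  if (!is.null(file)) {
    pdf(file, width = max(4, 3 * length(samples)), height = 4)
    on.exit(dev.off())
  }
  old <- par(mfrow = c(1, length(samples)), mar = c(6, 4, 3, 1))
  on.exit(par(old), add = TRUE)
  for (s in samples) {
    rs <- rows[rows$sample_id == s, , drop = FALSE]
    cols <- t(vapply(rs$call_status, function(st) switch(st,
      biallelic = c("#1F4E9C", "#C0392B"),
      monoallelic = c(adjustcolor("#1F4E9C", 0.3),
                      adjustcolor("#C0392B", 0.3)),
      low_coverage = c(gray(0.45), gray(0.75))), character(2)))
    barplot(rbind(rs$ref_count, rs$alt_count), names.arg = rs$snv_id,
            col = NA, border = NA, las = 2, main = s,
            ylab = "reads", cex.names = 0.7)
    bp <- barplot(rbind(rs$ref_count, rs$alt_count), add = TRUE,
                  col = NA, border = NA, axes = FALSE, names.arg = NULL)
    for (i in seq_len(nrow(rs))) {
      rect(bp[i] - 0.5, 0, bp[i] + 0.5, rs$ref_count[i],
           col = cols[i, 1], border = NA)
      rect(bp[i] - 0.5, rs$ref_count[i], bp[i] + 0.5,
           rs$ref_count[i] + rs$alt_count[i], col = cols[i, 2],
           border = NA)
    }
  }
  title(main = gene_id, outer = TRUE, line = -1)
  invisible(rows)
}

#' @export
plot.ase_calls <- function(x, which = "all", ...) {
  render_gene_panel(x, file = NULL, which = which, ...)
}
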