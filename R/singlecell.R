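#' Gene-level biallelic fractions across single cells
#'
#' Aggregates per-cell SNV calls into per-group gene statuses. A cell
#' "expresses" a gene when at least one of the gene's SNVs reaches the
#' overall-depth threshold in that cell; a cell is biallelic for the gene
#' when at least one of its SNVs is called biallelic (single-cell
#' thresholds: OD 15, MAC 3, AR 0.2). A gene is kept only when it is
#' expressed in at least `expr_min_cells` cells in at least
#' `expr_min_groups` groups (otherwise `filtered_out`); a kept gene is
#' called biallelic in a group when the fraction of expressing cells with a
#' biallelic SNV is at least `frac_min` (inclusive, default 20\%).
#'
#' @param cells List of per-cell `aser_table`s (the `sample_id` is the
#'   cell id).
#' @param kb A `knowledge_base`.
#' @param groups Data frame mapping `cell_id` to `group_id`
#'   (condition / individual / developmental stage).
#' @param t Single-cell `ase_thresholds`; see [sc_thresholds()].
#' @param frac_min Minimal fraction of expressing cells with a biallelic
#'   SNV.
#' @param expr_min_cells,expr_min_groups Expression filter: a gene must be
#'   expressed in at least this many cells in at least this many groups.
#' @return An object of class `sc_ase`: list with `fractions` (per gene x
#'   group: `n_expressing`, `n_biallelic`, `fraction`, `status` in
#'   biallelic / not_biallelic / filtered_out), `cell_calls` (per-cell SNV
#'   calls), `cell_gene` (per gene x cell expressing/biallelic flags),
#'   `groups`, `thresholds`.
#' @export
sc_call <- function(cells, kb, groups, t = sc_thresholds(),
                    frac_min = 0.2, expr_min_cells = 10,
                    expr_min_groups = 1) {
  stopifnot(length(cells) >= 1L, inherits(t, "ase_thresholds"),
            all(c("cell_id", "group_id") %in% names(groups)))
  if (any(!nzchar(groups$cell_id)) ||
      any(table(groups$group_id) == 0L))
    stop("invalid cell-to-group mapping", call. = FALSE)

  calls <- lapply(cells, function(tab)
    call_snvs(annotate_observations(tab, kb), t))
  cell_calls <- do.call(rbind, calls)
  rownames(cell_calls) <- NULL
  if (nrow(cell_calls) == 0L)
    stop("no knowledge-base SNVs observed in any cell", call. = FALSE)

  # per gene x cell: does the cell express the gene / carry a biallelic SNV
  cg <- aggregate(cbind(expressing = cell_calls$od >= t$od_min,
                        biallelic = cell_calls$status == "biallelic"),
                  by = list(gene_id = cell_calls$gene_id,
                            cell_id = cell_calls$sample_id),
                  FUN = any)
  cg <- merge(cg, groups, by = "cell_id")
  missing_group <- setdiff(unique(cell_calls$sample_id), groups$cell_id)
  if (length(missing_group))
    warning(length(missing_group), " cell(s) absent from the group ",
            "mapping were ignored", call. = FALSE)

  frac <- aggregate(cbind(n_expressing = cg$expressing,
                          n_biallelic = cg$expressing & cg$biallelic),
                    by = list(gene_id = cg$gene_id, group_id = cg$group_id),
                    FUN = sum)
  frac$fraction <- ifelse(frac$n_expressing > 0,
                          frac$n_biallelic / frac$n_expressing, NA_real_)

  # expression filter is gene-global: enough expressing cells in enough groups
  pass <- aggregate(list(n_groups_ok = frac$n_expressing >= expr_min_cells),
                    by = list(gene_id = frac$gene_id), FUN = sum)
  ok_genes <- pass$gene_id[pass$n_groups_ok >= expr_min_groups]
  frac$status <- ifelse(!(frac$gene_id %in% ok_genes), "filtered_out",
                        ifelse(!is.na(frac$fraction) &
                                 frac$fraction >= frac_min,
                               "biallelic", "not_biallelic"))
  frac <- frac[order(frac$gene_id, frac$group_id), , drop = FALSE]
  rownames(frac) <- NULL

  structure(list(fractions = frac, cell_calls = cell_calls,
                 cell_gene = cg, groups = groups, thresholds = t,
                 frac_min = frac_min, expr_min_cells = expr_min_cells,
                 expr_min_groups = expr_min_groups),
            class = "sc_ase")
}

#' @export
print.sc_ase <- function(x, ...) {
  cat("Single-cell biallelic fractions:",
      length(unique(x$groups$cell_id)), "cell(s),",
      length(unique(x$fractions$group_id)), "group(s),",
      length(unique(x$fractions$gene_id)), "gene(s)\n")
  print(table(x$fractions$status))
  invisible(x)
}

#' Pool single cells into one pseudo-bulk sample
#'
#' Sums per-SNV ref/alt counts across cells into a single synthetic
#' sample, to be routed through the bulk caller when per-cell SNV coverage
#' is too sparse for cell-level calls (e.g. droplet-based protocols).
#' Pooling commutes with partitioning: summing subsets and then the
#' subsets' sums equals summing all cells at once.
#'
#' @param cells List of per-cell `aser_table`s.
#' @param sample_id Identifier for the pooled sample.
#' @return An `aser_table` with one row per SNV.
#' @export
pseudo_bulk <- function(cells, sample_id = "pseudo_bulk") {
  stopifnot(length(cells) >= 1L)
  all_obs <- do.call(rbind, lapply(cells, as.data.frame))
  agg <- aggregate(cbind(ref_count = all_obs$ref_count,
                         alt_count = all_obs$alt_count),
                   by = list(contig = all_obs$contig,
                             position = all_obs$position,
                             snv_id = all_obs$snv_id,
                             ref_allele = all_obs$ref_allele,
                             alt_allele = all_obs$alt_allele),
                   FUN = sum)
  agg <- agg[agg$ref_count + agg$alt_count > 0, , drop = FALSE]
  agg$sample_id <- sample_id
  agg <- agg[order(agg$contig, agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  as_aser_table(agg)
}
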