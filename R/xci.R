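#' Infer parental-allele orientation from a reference stage
#'
#' In early embryos the maternal X is the predominantly expressed allele at
#' the reference developmental stage (the mid 2-cell stage in mouse), so
#' for each X-linked SNV locus the allele with the larger read count summed
#' across the reference-stage cells is deemed maternal. Tied loci are not
#' oriented and are excluded downstream; loci absent from the reference
#' stage are likewise not oriented.
#'
#' @param reference_cells List of `aser_table`s for the reference-stage
#'   cells.
#' @param kb A `knowledge_base`; only SNVs on `chrX` (gene annotation)
#'   are oriented.
#' @param chrx_contig Contig name of the X chromosome.
#' @return Data frame of class `allele_orientation`: `contig`, `position`,
#'   `gene_id`, `maternal_allele` (`"ref"` or `"alt"`).
#' @export
infer_orientation <- function(reference_cells, kb, chrx_contig = "chrX") {
  stopifnot(length(reference_cells) >= 1L)
  obs <- do.call(rbind, lapply(reference_cells, function(tab)
    annotate_observations(tab, kb)))
  obs <- obs[obs$contig == chrx_contig, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no X-linked SNVs detected in the reference stage", call. = FALSE)
  agg <- aggregate(cbind(ref_count = obs$ref_count,
                         alt_count = obs$alt_count),
                   by = list(contig = obs$contig, position = obs$position,
                             gene_id = obs$gene_id),
                   FUN = sum)
  agg <- agg[agg$ref_count != agg$alt_count, , drop = FALSE]  # ties excluded
  agg$maternal_allele <- ifelse(agg$ref_count > agg$alt_count, "ref", "alt")
  out <- agg[, c("contig", "position", "gene_id", "maternal_allele")]
  out <- out[order(out$contig, out$position, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("allele_orientation", "data.frame")
  out
}

#' Per-cell average allelic ratio (AAR) over X-linked genes
#'
#' For each oriented X-linked gene in a cell, maternal and paternal read
#' counts are summed over the gene's oriented SNVs; genes whose summed
#' depth reaches `od_min` contribute the ratio paternal/maternal, and the
#' AAR is the arithmetic mean of those ratios across genes. Ratios are
#' capped at `cap` (so a gene with zero maternal reads contributes the cap
#' rather than infinity, keeping means finite). An AAR near 0 indicates
#' exclusively maternal expression (paternal X silenced); near 1, balanced
#' biparental expression (two active X); near the cap, paternal-skewed
#' expression. Cells with no eligible gene are skipped.
#'
#' @param cells List of per-cell `aser_table`s.
#' @param orientation An `allele_orientation` from [infer_orientation()].
#' @param kb A `knowledge_base`.
#' @param od_min Minimal per-gene summed depth for a gene to contribute.
#' @param cap Upper bound on per-gene paternal/maternal ratios.
#' @param stages Optional data frame `cell_id`, `stage` merged onto the
#'   result.
#' @return Data frame: `cell_id`, `n_genes`, `aar` (plus `stage` when
#'   supplied).
#' @export
compute_aar <- function(cells, orientation, kb, od_min = 15, cap = 10,
                        stages = NULL) {
  stopifnot(inherits(orientation, "allele_orientation"))
  per_cell <- lapply(cells, function(tab) {
    obs <- annotate_observations(tab, kb)
    key_obs <- paste(obs$contig, obs$position, obs$gene_id)
    key_or <- paste(orientation$contig, orientation$position,
                    orientation$gene_id)
    idx <- match(key_obs, key_or)
    obs <- obs[!is.na(idx), , drop = FALSE]
    if (nrow(obs) == 0L) return(NULL)
    mat <- orientation$maternal_allele[idx[!is.na(idx)]]
    obs$maternal_count <- ifelse(mat == "ref", obs$ref_count, obs$alt_count)
    obs$paternal_count <- ifelse(mat == "ref", obs$alt_count, obs$ref_count)
    g <- aggregate(cbind(maternal = obs$maternal_count,
                         paternal = obs$paternal_count),
                   by = list(gene_id = obs$gene_id), FUN = sum)
    g <- g[g$maternal + g$paternal >= od_min, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    ratio <- ifelse(g$maternal == 0, cap,
                    pmin(g$paternal / g$maternal, cap))
    data.frame(cell_id = tab$sample_id[1], n_genes = nrow(g),
               aar = mean(ratio), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per_cell)
  if (is.null(res))
    return(data.frame(cell_id = character(), n_genes = integer(),
                      aar = numeric(), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  if (!is.null(stages)) res <- merge(res, stages, by = "cell_id")
  res
}

#' Compare AAR distributions between sequential stages
#'
#' Two-sided Wilcoxon rank-sum tests between consecutive developmental
#' stages (e.g. mid2cell vs late2cell). No p-value is computed when either
#' stage has fewer than 3 profiles.
#'
#' @param profiles Data frame with `aar` and `stage` columns (from
#'   [compute_aar()] with `stages`).
#' @param stage_pairs List of length-2 character vectors, each a pair of
#'   stage labels to compare.
#' @return Data frame: `stage_a`, `stage_b`, `n_a`, `n_b`, `p_value`
#'   (`NA` when a group has n < 3).
#' @export
compare_stages <- function(profiles, stage_pairs) {
  stopifnot(all(c("aar", "stage") %in% names(profiles)))
  known <- unique(profiles$stage)
  out <- lapply(stage_pairs, function(pair) {
    stopifnot(length(pair) == 2L)
    if (!all(pair %in% known))
      stop("unknown stage(s): ",
           paste(setdiff(pair, known), collapse = ", "), call. = FALSE)
    a <- profiles$aar[profiles$stage == pair[1]]
    b <- profiles$aar[profiles$stage == pair[2]]
    p <- if (length(a) < 3L || length(b) < 3L) NA_real_
         else suppressWarnings(
           wilcox.test(a, b, alternative = "two.sided")$p.value)
    # completely tied samples carry no evidence against equality
    if (is.nan(p)) p <- 1
    data.frame(stage_a = pair[1], stage_b = pair[2],
               n_a = length(a), n_b = length(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect genes escaping X inactivation
#'
#' An X-linked gene escapes XCI when it is called biallelic (per-group
#' single-cell status from [sc_call()], groups = individuals) in at least
#' `min_individuals` individuals.
#'
#' @param fractions `fractions` data frame from an [sc_call()] result,
#'   restricted to X-linked genes by the caller (or pass an `sc_ase`
#'   object to use its fractions directly).
#' @param min_individuals Minimal number of groups with biallelic status.
#' @return Character vector of escapee gene ids.
#' @export
detect_escapees <- function(fractions, min_individuals = 2) {
  if (inherits(fractions, "sc_ase")) fractions <- fractions$fractions
  bi <- fractions[fractions$status == "biallelic", , drop = FALSE]
  counts <- table(bi$gene_id)
  sort(names(counts)[counts >= min_individuals])
}
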