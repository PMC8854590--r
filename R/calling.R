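#' SNV filter thresholds
#'
#' Bundles the four SNV filter parameters governing biallelic calls:
#' overall depth (OD, reads on the SNV), minor allele count (MAC, reads on
#' the less frequent allele), the biallelic criterion — a cutoff on the
#' allelic ratio (minor/major) or the p-value of a one-sided exact binomial
#' test of minor proportion greater than 1/6 — and the minimal number of
#' biallelic SNVs required to call a gene biallelic. The MAC gate applies
#' in both modes. All comparisons are inclusive (`AR >= ar_min`,
#' `p <= p_max`).
#'
#' Defaults are the bulk RNA-seq settings (samples with >10M reads):
#' OD 20, MAC 4, AR 0.2, at least 2 biallelic SNVs per gene.
#' [sc_thresholds()] gives the single-cell settings — OD 15, MAC 3,
#' AR 0.2, 1 biallelic SNV — which compensate for the lower per-cell
#' sequencing depth.
#'
#' `ratio_convention` controls only the *reported* allelic ratio
#' (minor/major or minor/total); the AR criterion itself is always
#' evaluated on the minor/major scale.
#'
#' @param od_min Minimum overall depth; SNVs below it are `low_coverage`.
#' @param mac_min Minimum minor allele count for a biallelic call.
#' @param mode `"ar"` (allelic-ratio cutoff) or `"binomial"`.
#' @param ar_min Minor/major allelic-ratio cutoff (mode `"ar"`).
#' @param p_max Binomial p-value cutoff (mode `"binomial"`).
#' @param min_biallelic_snvs Biallelic SNVs required for a biallelic gene.
#' @param ratio_convention `"minor_over_major"` or `"minor_over_total"`.
#' @return An object of class `ase_thresholds`.
#' @export
thresholds <- function(od_min = 20, mac_min = 4,
                       mode = c("ar", "binomial"),
                       ar_min = 0.2, p_max = 0.05,
                       min_biallelic_snvs = 2,
                       ratio_convention = c("minor_over_major",
                                            "minor_over_total")) {
  mode <- match.arg(mode)
  ratio_convention <- match.arg(ratio_convention)
  stopifnot(od_min >= 1, mac_min >= 0, ar_min >= 0, ar_min <= 1,
            p_max > 0, p_max < 1, min_biallelic_snvs >= 1)
  structure(list(od_min = as.integer(od_min),
                 mac_min = as.integer(mac_min),
                 mode = mode, ar_min = ar_min, p_max = p_max,
                 min_biallelic_snvs = as.integer(min_biallelic_snvs),
                 ratio_convention = ratio_convention),
            class = "ase_thresholds")
}

#' @rdname thresholds
#' @param ... Overrides passed on to [thresholds()].
#' @export
sc_thresholds <- function(...) {
  args <- list(...)
  defaults <- list(od_min = 15, mac_min = 3, ar_min = 0.2,
                   min_biallelic_snvs = 1)
  do.call(thresholds, modifyList(defaults, args))
}

#' @export
print.ase_thresholds <- function(x, ...) {
  crit <- if (x$mode == "ar") sprintf("AR >= %g (minor/major)", x$ar_min)
          else sprintf("binomial p <= %g (minor prop > 1/6)", x$p_max)
  cat(sprintf(
    "SNV thresholds: OD >= %d, MAC >= %d, %s; gene: >= %d biallelic SNV(s)\n",
    x$od_min, x$mac_min, crit, x$min_biallelic_snvs))
  invisible(x)
}

#' Allelic ratio of an SNV
#'
#' `minor_over_major` divides the less by the more frequent allele count
#' (1 for perfectly balanced counts); `minor_over_total` divides the minor
#' count by the overall depth (0.5 when balanced). Both are symmetric in
#' ref/alt. Undefined at zero depth: callers must route OD = 0
#' observations to `low_coverage` first.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @param ratio_convention `"minor_over_major"` or `"minor_over_total"`.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
compute_ar <- function(ref_count, alt_count,
                       ratio_convention = c("minor_over_major",
                                            "minor_over_total")) {
  ratio_convention <- match.arg(ratio_convention)
  od <- ref_count + alt_count
  if (any(od == 0)) stop("allelic ratio undefined at zero depth",
                         call. = FALSE)
  minor <- pmin(ref_count, alt_count)
  if (ratio_convention == "minor_over_major")
    minor / pmax(ref_count, alt_count)
  else
    minor / od
}

#' One-sided exact binomial test for biallelic expression
#'
#' Upper-tail probability `P(X >= minor_count)` for
#' `X ~ Binomial(od, 1/6)`: the test asks whether the minor-allele
#' proportion exceeds 1/6, the null expectation used to separate genuine
#' biallelic expression from error-driven minor reads. An SNV passes in
#' binomial mode when this p-value is at or below `p_max`.
#'
#' @param minor_count Observed minor-allele reads (vectorised).
#' @param od Overall depth (`>= 1`).
#' @return Numeric vector of exact tail probabilities.
#' @export
binomial_greater_test <- function(minor_count, od) {
  stopifnot(all(od >= 1), all(minor_count >= 0), all(minor_count <= od))
  pbinom(minor_count - 1, size = od, prob = 1 / 6, lower.tail = FALSE)
}

#' Classify SNV observations
#'
#' Applies the threshold cascade to each row of an allele-count table:
#' `low_coverage` when OD < `od_min`; otherwise `biallelic` when
#' MAC >= `mac_min` and the mode criterion holds (AR(minor/major) >=
#' `ar_min`, or binomial p <= `p_max`); otherwise `monoallelic`. The
#' reported `allelic_ratio` follows `ratio_convention`; `p_value` is
#' filled in binomial mode.
#'
#' @param obs Data frame with `ref_count` and `alt_count` columns (e.g. an
#'   `aser_table`, possibly annotated with `gene_id`).
#' @param t An `ase_thresholds` object.
#' @return `obs` with columns `od`, `mac`, `status`, `allelic_ratio` and
#'   `p_value` appended.
#' @export
call_snvs <- function(obs, t = thresholds()) {
  stopifnot(inherits(t, "ase_thresholds"))
  obs <- as.data.frame(obs)
  od <- obs$ref_count + obs$alt_count
  mac <- pmin(obs$ref_count, obs$alt_count)
  pos <- od > 0
  ar_crit <- rep(NA_real_, nrow(obs))
  ar_rep <- rep(NA_real_, nrow(obs))
  if (any(pos)) {
    ar_crit[pos] <- compute_ar(obs$ref_count[pos], obs$alt_count[pos],
                               "minor_over_major")
    ar_rep[pos] <- compute_ar(obs$ref_count[pos], obs$alt_count[pos],
                              t$ratio_convention)
  }
  p_value <- rep(NA_real_, nrow(obs))
  if (t$mode == "binomial" && any(pos))
    p_value[pos] <- binomial_greater_test(mac[pos], od[pos])

  passes <- if (t$mode == "ar") ar_crit >= t$ar_min else p_value <= t$p_max
  status <- ifelse(od < t$od_min, "low_coverage",
                   ifelse(mac >= t$mac_min & passes,
                          "biallelic", "monoallelic"))
  obs$od <- od
  obs$mac <- mac
  obs$status <- status
  obs$allelic_ratio <- ar_rep
  obs$p_value <- p_value
  obs
}

# Join observations onto the knowledge-base catalogs: keeps only positions
# present in a catalog and duplicates each observation across every gene
# the SNV is assigned to.
annotate_observations <- function(obs, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  cat <- rbind(kb$biallelic_catalog, kb$multiallelic_catalog)
  if (nrow(cat) == 0L) stop("knowledge base has empty catalogs",
                            call. = FALSE)
  key_obs <- paste(obs$contig, obs$position)
  key_cat <- paste(cat$contig, cat$position)
  m <- merge(cbind(obs, .key = key_obs),
             data.frame(.key = key_cat, gene_id = cat$gene_id,
                        stringsAsFactors = FALSE),
             by = ".key")
  m$.key <- NULL
  m
}

#' Call biallelic expression of imprinted and sex-linked genes
#'
#' The central bulk analysis: classifies every knowledge-base SNV in every
#' sample as biallelic / monoallelic / low-coverage under the chosen
#' thresholds and collapses the calls to a gene x sample status matrix.
#'
#' @param aser One `aser_table` or a list of them (one per sample).
#' @param kb A `knowledge_base`; observations at positions absent from its
#'   catalogs are ignored.
#' @param t An `ase_thresholds` object; see [thresholds()].
#' @param workers Number of worker processes for per-sample calling
#'   (results are independent of this value).
#' @return An object of class `ase_calls`: list with `snv_calls` (per-SNV
#'   data frame), `gene_summary` (per gene x sample; see
#'   [collapse_gene()]), `thresholds`, `genes`, and `samples` (sample
#'   display order). Methods: `print`, `summary`, `plot` (gene panel),
#'   [call_table()] for export.
#' @examples
#' sim <- simulate_bulk(sim_config(seed = 1, n_samples = 2))
#' fit <- call_biallelic(sim$tables, sim$kb)
#' summary(fit)
#' @export
call_biallelic <- function(aser, kb, t = thresholds(), workers = 1L) {
  if (inherits(aser, "aser_table")) aser <- list(aser)
  stopifnot(length(aser) >= 1L, inherits(t, "ase_thresholds"))
  per_sample <- function(tab) call_snvs(annotate_observations(tab, kb), t)
  calls <- if (workers > 1L)
    parallel::mclapply(aser, per_sample, mc.cores = workers)
  else
    lapply(aser, per_sample)
  snv_calls <- do.call(rbind, calls)
  rownames(snv_calls) <- NULL
  samples <- unique(vapply(aser, function(x) x$sample_id[1], character(1)))
  gene_summary <- summarize_genes(snv_calls, kb, t, samples)
  structure(list(snv_calls = snv_calls, gene_summary = gene_summary,
                 thresholds = t, genes = kb$genes, samples = samples),
            class = "ase_calls")
}

#' @export
print.ase_calls <- function(x, ...) {
  cat("Biallelic-expression calls:", length(x$samples), "sample(s),",
      nrow(x$genes), "gene(s)\n")
  print(x$thresholds)
  tab <- table(factor(x$gene_summary$status,
                      levels = c("biallelic", "detected_not_biallelic",
                                 "below_threshold", "undetected")))
  cat("gene x sample statuses:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.ase_calls <- function(object, ...) {
  gs <- object$gene_summary
  bi <- gs[gs$status == "biallelic", , drop = FALSE]
  out <- list(
    n_samples = length(object$samples),
    n_genes = nrow(object$genes),
    snv_status = table(object$snv_calls$status),
    gene_status = table(gs$status),
    biallelic_genes = sort(unique(bi$gene_id)))
  class(out) <- "summary.ase_calls"
  out
}

#' @export
print.summary.ase_calls <- function(x, ...) {
  cat("Samples:", x$n_samples, "  Genes:", x$n_genes, "\n")
  cat("SNV calls:\n"); print(x$snv_status)
  cat("Gene x sample statuses:\n"); print(x$gene_status)
  cat("Genes biallelic in >= 1 sample:",
      if (length(x$biallelic_genes))
        paste(x$biallelic_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Extract the per-SNV call table from an `ase_calls` object
#'
#' Produces the exchange-format rows written by [write_call_table()]: for
#' each gene x sample with at least one biallelic SNV, one row per SNV with
#' reads; otherwise a single `rs_multi` row with the gene's summed counts
#' (status `monoallelic`, or `low_coverage` when the summed depth is below
#' `od_min`). SNVs with zero reads are omitted. Rows follow gene genomic
#' position, then the sample display order.
#'
#' @param x An `ase_calls` object.
#' @return A data frame of class `call_table`.
#' @export
call_table <- function(x) {
  stopifnot(inherits(x, "ase_calls"))
  sc <- x$snv_calls[x$snv_calls$od > 0, , drop = FALSE]
  t <- x$thresholds
  out <- list()
  gene_order <- x$genes$gene_id
  for (g in gene_order) {
    for (s in x$samples) {
      rows <- sc[sc$gene_id == g & sc$sample_id == s, , drop = FALSE]
      if (nrow(rows) == 0L) next
      if (any(rows$status == "biallelic")) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, gene_id = g, snv_id = rows$snv_id,
          ref_count = rows$ref_count, alt_count = rows$alt_count,
          call_status = rows$status, allelic_ratio = rows$allelic_ratio,
          p_value = rows$p_value, stringsAsFactors = FALSE)
      } else {
        rc <- sum(rows$ref_count); ac <- sum(rows$alt_count)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, gene_id = g, snv_id = "rs_multi",
          ref_count = rc, alt_count = ac,
          call_status = if (rc + ac < t$od_min) "low_coverage"
                        else "monoallelic",
          allelic_ratio = compute_ar(rc, ac, t$ratio_convention),
          p_value = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), gene_id = character(),
               snv_id = character(), ref_count = integer(),
               alt_count = integer(), call_status = character(),
               allelic_ratio = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("call_table", "data.frame")
  res
}
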