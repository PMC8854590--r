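#' Load the gene/SNV knowledge base
#'
#' Builds the data structure that defines which loci are analysed: a curated
#' set of imprinted genes (with database-source, placental-specific and
#' isoform-dependent annotations) plus genes on the sex chromosomes, and two
#' SNV catalogs (biallelic and multi-allelic sites) assigned to those genes
#' by genomic overlap.
#'
#' Gene intervals are read from a BED file (0-based half-open; converted to
#' 1-based closed internally, the VCF convention used throughout the
#' package). Catalog SNVs are read from VCF; INDELs (REF or ALT longer than
#' one base, or symbolic alleles) are dropped, as are records overlapping no
#' gene interval. A VCF record with exactly one alternate allele goes to the
#' biallelic catalog, records with several to the multi-allelic catalog —
#' each file may contain a mixture. An SNV overlapping several gene
#' intervals is assigned to every overlapping gene, so its counts contribute
#' evidence to each.
#'
#' @param gene_bed_path BED file of gene regions; column 4 is the gene id.
#' @param gene_metadata_path Tab-separated table with columns `gene_id`,
#'   `symbol`, `sources` (comma-separated subset of geneimprint, otago,
#'   santoni, inoue, chrX, chrY), `placental`, `isoform_dependent`.
#' @param biallelic_vcf_path,multiallelic_vcf_path VCF v4.x catalogs of SNV
#'   sites. `multiallelic_vcf_path` may be `NULL`.
#' @param genome_build Free-text genome tag (e.g. `"GRCh38.p13"`).
#'
#' @return An object of class `knowledge_base`: a list with elements
#'   `genome_build`, `genes` (data frame ordered by genomic position),
#'   `biallelic_catalog` and `multiallelic_catalog` (data frames with one
#'   row per SNV x overlapping gene).
#' @seealso [filter_genes()]
#' @export
load_knowledge_base <- function(gene_bed_path, gene_metadata_path,
                                biallelic_vcf_path,
                                multiallelic_vcf_path = NULL,
                                genome_build = "unspecified") {
  for (p in c(gene_bed_path, gene_metadata_path, biallelic_vcf_path,
              multiallelic_vcf_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("file not found: ", p, call. = FALSE)
  }

  bed <- read.delim(gene_bed_path, header = FALSE,
                    stringsAsFactors = FALSE)[, 1:4]
  names(bed) <- c("contig", "bed_start", "bed_end", "gene_id")
  if (nrow(bed) == 0L) stop("empty gene list", call. = FALSE)

  meta <- read.delim(gene_metadata_path, stringsAsFactors = FALSE)
  required <- c("gene_id", "symbol", "sources", "placental",
                "isoform_dependent")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("gene metadata lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  genes <- merge(bed, meta, by = "gene_id")
  if (nrow(genes) == 0L) stop("empty gene list after metadata merge",
                              call. = FALSE)
  # BED is 0-based half-open; internal coordinates are 1-based closed
  genes$start <- genes$bed_start + 1L
  genes$end <- genes$bed_end
  genes$bed_start <- genes$bed_end <- NULL
  bad <- genes$start > genes$end | !nzchar(genes$contig)
  if (any(bad)) {
    message("dropping ", sum(bad), " gene record(s) with invalid intervals")
    genes <- genes[!bad, , drop = FALSE]
  }
  genes$placental <- as.logical(genes$placental)
  genes$isoform_dependent <- as.logical(genes$isoform_dependent)
  genes$sex_linked <- vapply(
    split_sources(genes$sources),
    function(s) any(s %in% c("chrX", "chrY")), logical(1))
  no_src <- !nzchar(genes$sources)
  if (any(no_src)) {
    message("dropping ", sum(no_src), " gene record(s) without any source")
    genes <- genes[!no_src, , drop = FALSE]
  }
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "symbol", "contig", "start", "end",
                     "sources", "placental", "isoform_dependent",
                     "sex_linked")]

  kb <- structure(
    list(genome_build = genome_build,
         genes = genes,
         biallelic_catalog = empty_catalog(),
         multiallelic_catalog = empty_catalog()),
    class = "knowledge_base")

  parts <- read_snv_catalog(biallelic_vcf_path, genes)
  kb$biallelic_catalog <- parts$biallelic
  kb$multiallelic_catalog <- parts$multiallelic
  if (!is.null(multiallelic_vcf_path)) {
    parts <- read_snv_catalog(multiallelic_vcf_path, genes)
    kb$biallelic_catalog <- rbind(kb$biallelic_catalog, parts$biallelic)
    kb$multiallelic_catalog <- rbind(kb$multiallelic_catalog,
                                     parts$multiallelic)
  }
  kb$biallelic_catalog <- order_catalog(kb$biallelic_catalog)
  kb$multiallelic_catalog <- order_catalog(kb$multiallelic_catalog)
  kb
}

empty_catalog <- function() {
  data.frame(contig = character(), position = integer(),
             snv_id = character(), ref_allele = character(),
             alt_alleles = character(), gene_id = character(),
             stringsAsFactors = FALSE)
}

order_catalog <- function(cat) {
  cat <- cat[order(cat$contig, cat$position, cat$gene_id), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

split_sources <- function(x) strsplit(x, ",", fixed = TRUE)

# Parse a sites VCF into SNV catalog rows assigned to overlapping genes.
# Drops INDELs/symbolic alleles and records outside every gene interval.
read_snv_catalog <- function(vcf_path, genes) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(list(biallelic = empty_catalog(), multiallelic = empty_catalog()))
  cat <- data.frame(contig = fix$CHROM,
                    position = as.integer(fix$POS),
                    snv_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                    paste0(fix$CHROM, ":", fix$POS), fix$ID),
                    ref_allele = fix$REF,
                    alt_alleles = fix$ALT,
                    stringsAsFactors = FALSE)

  alts <- split_sources(cat$alt_alleles)
  is_snv <- nchar(cat$ref_allele) == 1L &
    vapply(alts, function(a) length(a) >= 1L && all(nchar(a) == 1L) &&
             all(a %in% c("A", "C", "G", "T")), logical(1)) &
    cat$ref_allele %in% c("A", "C", "G", "T")
  same_as_ref <- mapply(function(a, r) any(a == r), alts, cat$ref_allele)
  keep <- is_snv & !same_as_ref
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("dropping ", n_dropped,
            " catalog record(s): INDEL, symbolic or ref-identical alleles")
  cat <- cat[keep, , drop = FALSE]
  if (nrow(cat) == 0L)
    return(list(biallelic = empty_catalog(), multiallelic = empty_catalog()))

  snv_gr <- GenomicRanges::GRanges(
    cat$contig, IRanges::IRanges(cat$position, cat$position))
  gene_gr <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snv_gr, gene_gr)
  orphan <- setdiff(seq_len(nrow(cat)), S4Vectors::queryHits(hits))
  if (length(orphan))
    warning(length(orphan),
            " catalog record(s) overlap no gene interval; dropped",
            call. = FALSE)
  out <- cat[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
  n_alt <- lengths(split_sources(out$alt_alleles))
  list(biallelic = out[n_alt == 1L, , drop = FALSE],
       multiallelic = out[n_alt > 1L, , drop = FALSE])
}

#' Restrict a knowledge base to selected gene sources
#'
#' Retains genes whose source annotation intersects `sources`, optionally
#' excluding placental-specific and/or isoform-dependent imprinted genes;
#' sex-linked entries are retained only when `chrX`/`chrY` are among the
#' requested sources. Both SNV catalogs are re-pruned to the retained genes.
#' The operation is idempotent and monotone: enlarging `sources` never
#' removes genes.
#'
#' The core imprinted set used for most analyses corresponds to
#' `sources = c("geneimprint", "otago")`.
#'
#' @param kb A `knowledge_base` from [load_knowledge_base()].
#' @param sources Character vector, subset of
#'   `c("geneimprint", "otago", "santoni", "inoue", "chrX", "chrY")`.
#' @param exclude_placental,exclude_isoform_dependent Drop genes carrying
#'   the corresponding flag.
#' @return A pruned `knowledge_base`.
#' @export
filter_genes <- function(kb,
                         sources = c("geneimprint", "otago", "santoni",
                                     "inoue", "chrX", "chrY"),
                         exclude_placental = FALSE,
                         exclude_isoform_dependent = FALSE) {
  stopifnot(inherits(kb, "knowledge_base"))
  allowed <- c("geneimprint", "otago", "santoni", "inoue", "chrX", "chrY")
  bad <- setdiff(sources, allowed)
  if (length(bad))
    stop("unknown sources: ", paste(bad, collapse = ", "), call. = FALSE)
  src <- split_sources(kb$genes$sources)
  keep <- vapply(src, function(s) length(intersect(s, sources)) > 0L,
                 logical(1))
  if (exclude_placental) keep <- keep & !kb$genes$placental
  if (exclude_isoform_dependent) keep <- keep & !kb$genes$isoform_dependent
  kb$genes <- kb$genes[keep, , drop = FALSE]
  rownames(kb$genes) <- NULL
  if (nrow(kb$genes) == 0L)
    warning("no genes retained by filter", call. = FALSE)
  for (slot in c("biallelic_catalog", "multiallelic_catalog")) {
    cat <- kb[[slot]]
    kb[[slot]] <- order_catalog(
      cat[cat$gene_id %in% kb$genes$gene_id, , drop = FALSE])
  }
  kb
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base (", x$genome_build, ")\n", sep = "")
  cat("  genes: ", nrow(x$genes),
      " (", sum(x$genes$sex_linked), " sex-linked)\n", sep = "")
  cat("  biallelic catalog: ", nrow(x$biallelic_catalog),
      " SNV-gene assignments\n", sep = "")
  cat("  multi-allelic catalog: ", nrow(x$multiallelic_catalog),
      " SNV-gene assignments\n", sep = "")
  invisible(x)
}
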