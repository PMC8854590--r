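#' Read a per-sample allele-count table
#'
#' Parses the tab-separated output of GATK ASEReadCounter (one row per SNV:
#' `contig`, `position`, `variantID`, `refAllele`, `altAllele`, `refCount`,
#' `altCount`, `totalCount`). The overall depth (OD) used downstream is
#' always `refCount + altCount` — reads carrying other bases are discarded;
#' when the file's `totalCount` disagrees with that sum a warning is issued
#' and the sum is used. Gzip-compressed files are read transparently.
#'
#' @param path Path to the allele-count TSV (optionally gzipped).
#' @param sample_id Sample (or cell) identifier attached to every row.
#' @return A data frame of class `aser_table` with columns `sample_id`,
#'   `contig`, `position`, `snv_id`, `ref_allele`, `alt_allele`,
#'   `ref_count`, `alt_count`.
#' @export
read_aser_table <- function(path, sample_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("contig", "position", "variantID", "refAllele", "altAllele",
                "refCount", "altCount", "totalCount")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("malformed allele-count header; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("position", "refCount", "altCount", "totalCount")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-integer value in column '", col, "' at data row ", bad[1],
           call. = FALSE)
    tab[[col]] <- v
  }
  od <- tab$refCount + tab$altCount
  n_mismatch <- sum(tab$totalCount != od)
  if (n_mismatch > 0L)
    warning(n_mismatch, " row(s) with totalCount != refCount + altCount; ",
            "overall depth recomputed from ref + alt", call. = FALSE)
  out <- data.frame(sample_id = rep(sample_id, nrow(tab)),
                    contig = tab$contig,
                    position = tab$position,
                    snv_id = tab$variantID,
                    ref_allele = tab$refAllele,
                    alt_allele = tab$altAllele,
                    ref_count = tab$refCount,
                    alt_count = tab$altCount,
                    stringsAsFactors = FALSE)
  class(out) <- c("aser_table", "data.frame")
  out
}

#' Build an allele-count table from a data frame
#'
#' Convenience constructor used by the simulator and by tests: validates
#' the `aser_table` column contract and attaches the class.
#'
#' @param df Data frame with columns `sample_id`, `contig`, `position`,
#'   `snv_id`, `ref_allele`, `alt_allele`, `ref_count`, `alt_count`.
#' @return The validated `aser_table`.
#' @export
as_aser_table <- function(df) {
  required <- c("sample_id", "contig", "position", "snv_id", "ref_allele",
                "alt_allele", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  stopifnot(all(df$ref_count >= 0), all(df$alt_count >= 0))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, required]
  class(df) <- c("aser_table", "data.frame")
  df
}

#' Select the reference and major alternative allele
#'
#' At multi-allelic sites the pipeline reduces the observation to two
#' alleles: the reference and the most represented alternative. Ties among
#' alternative alleles are broken lexicographically so the reduction is
#' deterministic. When no non-reference allele was observed the first
#' catalog alternative is returned as a placeholder with count zero.
#'
#' @param allele_counts Named integer vector of per-allele read counts.
#' @param ref_allele The catalog reference allele (must be a valid base).
#' @param catalog_alts Character vector of catalog alternative alleles,
#'   used as placeholder source when none is observed.
#' @return List with `ref_allele`, `alt_allele`, `ref_count`, `alt_count`.
#' @export
select_major_alt <- function(allele_counts, ref_allele,
                             catalog_alts = NULL) {
  stopifnot(length(allele_counts) >= 1L, !is.null(names(allele_counts)))
  ref_count <- if (ref_allele %in% names(allele_counts))
    unname(allele_counts[[ref_allele]]) else 0L
  alt_counts <- allele_counts[setdiff(names(allele_counts), ref_allele)]
  alt_counts <- alt_counts[alt_counts > 0]
  if (length(alt_counts) == 0L) {
    alt <- if (length(catalog_alts)) catalog_alts[1] else NA_character_
    return(list(ref_allele = ref_allele, alt_allele = alt,
                ref_count = ref_count, alt_count = 0L))
  }
  alt_counts <- alt_counts[order(-alt_counts, names(alt_counts))]
  list(ref_allele = ref_allele, alt_allele = names(alt_counts)[1],
       ref_count = ref_count, alt_count = unname(alt_counts[1]))
}

CALL_STATUSES <- c("biallelic", "monoallelic", "low_coverage")

#' Write / read the per-SNV call table
#'
#' The call table is the pipeline's tabular endpoint: one row per SNV per
#' gene per sample carrying the allele counts, the call status and the
#' allelic ratio (plus the binomial p-value when that mode was used). For a
#' gene x sample with no biallelic SNV, the individual SNV rows are
#' replaced by a single virtual SNV named `rs_multi` holding the summed
#' ref/alt counts over the gene's detected SNVs, as an indication of the
#' gene's expression. Rows are ordered by gene genomic position, then
#' sample, so output is deterministic; the write/read cycle is lossless.
#'
#' @param rows Data frame with columns `sample_id`, `gene_id`, `snv_id`,
#'   `ref_count`, `alt_count`, `call_status`, `allelic_ratio` and
#'   optionally `p_value` (see [call_table()]).
#' @param path Output (input) TSV path; `.gz` suffix writes gzip.
#' @return `write_call_table` returns `path` invisibly; `read_call_table`
#'   returns the data frame with class `call_table`.
#' @export
write_call_table <- function(rows, path) {
  required <- c("sample_id", "gene_id", "snv_id", "ref_count", "alt_count",
                "call_status", "allelic_ratio")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  stopifnot(all(rows$call_status %in% CALL_STATUSES))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if ("p_value" %in% names(tab))
    tab$p_value <- as.numeric(tab$p_value)
  bad <- setdiff(unique(tab$call_status), CALL_STATUSES)
  if (length(bad))
    stop("unknown call_status token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(tab) <- c("call_table", "data.frame")
  tab
}
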