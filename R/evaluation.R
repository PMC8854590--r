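#' Read an exome-derived heterozygous-genotype truth table
#'
#' Tab-separated table with columns `sample_id`, `contig`, `position`,
#' `replicate_id`, `is_heterozygous` and `od_wes` (exome read depth at the
#' site). Each sample needs at least one replicate; the false-discovery
#' procedure requires two.
#'
#' @param path TSV path.
#' @return Data frame of class `genotype_truth`.
#' @export
read_genotype_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "contig", "position", "replicate_id",
                "is_heterozygous", "od_wes")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("genotype truth lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$is_heterozygous <- as.logical(tab$is_heterozygous)
  class(tab) <- c("genotype_truth", "data.frame")
  tab
}

#' False-discovery-rate estimation against exome genotypes
#'
#' For each sample, the eligible SNVs are those covered by at least
#' `od_rna_min` reads in the RNA data and at least `od_wes_min` reads in
#' both exome replicates. At every (OD, MAC) grid point, eligible SNVs are
#' re-called biallelic from the raw counts (allelic-ratio mode); a
#' biallelic RNA call is a true positive when the site is heterozygous in
#' at least one exome replicate and a false positive otherwise.
#' FDR = FP / (TP + FP), undefined (`NA`) when nothing is called. The
#' default grid holds the three threshold pairs 20-4, 15-3 and 10-2.
#'
#' @param observations One `aser_table` or list of them.
#' @param truth A `genotype_truth` table sharing coordinates with the
#'   observations.
#' @param grid Data frame with columns `od_min`, `mac_min`.
#' @param ar_min Allelic-ratio cutoff used at every grid point.
#' @param od_rna_min,od_wes_min Eligibility depths (RNA; both exome
#'   replicates).
#' @return Data frame of class `fdr_grid`: per sample and grid point,
#'   `n_eligible`, `n_called`, `tp`, `fp`, `fdr`.
#' @export
estimate_fdr <- function(observations, truth,
                         grid = data.frame(od_min = c(20, 15, 10),
                                           mac_min = c(4, 3, 2)),
                         ar_min = 0.2, od_rna_min = 5, od_wes_min = 5) {
  if (inherits(observations, "aser_table"))
    observations <- list(observations)
  obs <- do.call(rbind, lapply(observations, as.data.frame))
  stopifnot(all(c("od_min", "mac_min") %in% names(grid)))

  # per sample x site: heterozygous in >=1 replicate; covered in both
  key <- function(s, c, p) paste(s, c, p, sep = "\r")
  tsplit <- split(truth, key(truth$sample_id, truth$contig, truth$position))
  wes <- data.frame(
    .key = names(tsplit),
    het_any = vapply(tsplit, function(d) any(d$is_heterozygous), logical(1)),
    covered_both = vapply(tsplit, function(d)
      length(d$replicate_id) >= 2L && all(d$od_wes >= od_wes_min),
      logical(1)),
    stringsAsFactors = FALSE)

  obs$od <- obs$ref_count + obs$alt_count
  obs$.key <- key(obs$sample_id, obs$contig, obs$position)
  m <- merge(obs, wes, by = ".key")
  eligible <- m[m$od >= od_rna_min & m$covered_both, , drop = FALSE]

  out <- lapply(unique(obs$sample_id), function(s) {
    e <- eligible[eligible$sample_id == s, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      t <- thresholds(od_min = grid$od_min[i], mac_min = grid$mac_min[i],
                      mode = "ar", ar_min = ar_min)
      calls <- call_snvs(e, t)
      called <- calls$status == "biallelic"
      tp <- sum(called & e$het_any)
      fp <- sum(called & !e$het_any)
      data.frame(sample_id = s, od_min = grid$od_min[i],
                 mac_min = grid$mac_min[i], n_eligible = nrow(e),
                 n_called = tp + fp, tp = tp, fp = fp,
                 fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fdr_grid", "data.frame")
  res
}

#' Compare false-positive rates between two threshold settings
#'
#' Two-proportion chi-square test with Yates' continuity correction
#' (two-sided), as used to ask whether relaxing the thresholds increases
#' the false-positive rate appreciably.
#'
#' @param fp1,n1 False positives and total calls under setting 1.
#' @param fp2,n2 Same under setting 2.
#' @return The p-value.
#' @export
fdr_comparison_test <- function(fp1, n1, fp2, n2) {
  stopifnot(n1 > 0, n2 > 0, fp1 >= 0, fp2 >= 0, fp1 <= n1, fp2 <= n2)
  suppressWarnings(
    prop.test(c(fp1, fp2), c(n1, n2), alternative = "two.sided",
              correct = TRUE)$p.value)
}

#' Read a validated truth set
#'
#' Tab-separated table mirroring an experimentally validated call set: one
#' row per SNV per sample with columns `sample_id`, `snv_id`, `label`
#' (`biallelic` or `monoallelic`), `ref_count`, `alt_count` (RNA allele
#' counts) and optionally `od_rna` (defaults to their sum). Rows with more
#' than `od_rna_min` RNA reads are retained.
#'
#' @param path TSV path.
#' @param od_rna_min Strict lower bound on RNA depth (default: more than
#'   five reads).
#' @return Data frame of class `validation_truth`.
#' @export
read_validation_truth <- function(path, od_rna_min = 5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "snv_id", "label", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("validation truth lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stopifnot(all(tab$label %in% c("biallelic", "monoallelic")))
  if (!"od_rna" %in% names(tab))
    tab$od_rna <- tab$ref_count + tab$alt_count
  tab <- tab[tab$od_rna > od_rna_min, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("validation_truth", "data.frame")
  tab
}

#' Precision/recall over a threshold grid
#'
#' Re-calls every truth SNV from its raw counts at each combination of
#' overall depth and allelic-ratio (or binomial p-value) cutoff; SNVs
#' below the depth cutoff count as not called. TP = called biallelic with
#' label biallelic; FP = called with label monoallelic; FN = not called
#' with label biallelic; TN = the rest. Precision = TP/(TP+FP),
#' recall = TP/(TP+FN) (NA when the denominator is zero). Raising the
#' depth cutoff can only move SNVs from called to not-called, so recall is
#' non-increasing in it.
#'
#' @param truth A `validation_truth` data frame.
#' @param od_grid Integer vector of overall-depth cutoffs.
#' @param ar_grid Allelic-ratio cutoffs (mode `"ar"`), or `NULL`.
#' @param p_grid Binomial p-value cutoffs (mode `"binomial"`), or `NULL`.
#'   Exactly one of `ar_grid`/`p_grid` must be given.
#' @param mac_min Minor-allele-count gate applied at every grid point
#'   (default 1: the grid varies depth and the mode criterion only).
#' @return Data frame of class `pr_grid`: per grid point `od_min`,
#'   `cutoff`, `mode`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#' @export
precision_recall <- function(truth, od_grid = seq(5, 50, by = 5),
                             ar_grid = c(0.1, 0.2, 0.3), p_grid = NULL,
                             mac_min = 1) {
  if (nrow(truth) == 0L) stop("empty truth set", call. = FALSE)
  stopifnot(xor(is.null(ar_grid), is.null(p_grid)))
  mode <- if (is.null(p_grid)) "ar" else "binomial"
  cuts <- if (mode == "ar") ar_grid else p_grid
  combos <- expand.grid(od_min = od_grid, cutoff = cuts)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    t <- if (mode == "ar")
      thresholds(od_min = combos$od_min[i], mac_min = mac_min,
                 mode = "ar", ar_min = combos$cutoff[i])
    else
      thresholds(od_min = combos$od_min[i], mac_min = mac_min,
                 mode = "binomial", p_max = combos$cutoff[i])
    calls <- call_snvs(truth, t)
    called <- calls$status == "biallelic"
    is_bi <- truth$label == "biallelic"
    tp <- sum(called & is_bi); fp <- sum(called & !is_bi)
    fn <- sum(!called & is_bi); tn <- sum(!called & !is_bi)
    data.frame(od_min = combos$od_min[i], cutoff = combos$cutoff[i],
               mode = mode, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pr_grid", "data.frame")
  res
}
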