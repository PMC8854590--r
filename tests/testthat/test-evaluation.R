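make_truth <- function(sample_id, contig, position, het, od = 50L) {
  do.call(rbind, lapply(1:2, function(rep_i)
    data.frame(sample_id = sample_id, contig = contig,
               position = position, replicate_id = paste0("rep", rep_i),
               is_heterozygous = het, od_wes = od,
               stringsAsFactors = FALSE)))
}

test_that("FDR against exome genotypes matches an exhaustive hand count", {
  kb <- toy_kb()
  # six SNVs across both toy genes; high/low counts chosen so that at
  # thresholds 20-4 exactly snvs 1,2,4 are biallelic
  obs <- make_obs("s1",
                  c("rs_meg3_1", "rs_meg3_2", "rs_h19_1", "rs_plac_1",
                    "rs_x_1", "rs_y_1"),
                  ref_count = c(16L, 30L, 40L, 25L, 10L, 3L),
                  alt_count = c(4L, 10L, 1L, 10L, 2L, 1L))
  truth <- rbind(
    make_truth("s1", "chr14", 100200L, TRUE),    # biallelic call, het: TP
    make_truth("s1", "chr14", 100300L, FALSE),   # biallelic call, hom: FP
    make_truth("s1", "chr11", 200100L, TRUE),    # monoallelic: unused
    make_truth("s1", "chr11", 300100L, TRUE),    # biallelic call, het: TP
    make_truth("s1", "chrX", 400100L, TRUE),     # OD 12: eligible, uncalled
    make_truth("s1", "chrY", 500100L, FALSE))    # OD 4 < 5: ineligible
  grid <- estimate_fdr(obs, truth)
  g20 <- grid[grid$od_min == 20, ]
  expect_equal(g20$n_eligible, 5)
  expect_equal(g20$tp, 2)
  expect_equal(g20$fp, 1)
  expect_equal(g20$fdr, 1 / 3)
  # brute-force partition at 10-2: snv5 (10/2, AR 0.2) now also called
  g10 <- grid[grid$od_min == 10, ]
  expect_equal(g10$tp, 3)
  expect_equal(g10$fp, 1)
  expect_equal(g10$fdr, 0.25)
})

test_that("heterozygosity in a single replicate suffices for a true positive", {
  kb <- toy_kb()
  obs <- make_obs("s1", "rs_meg3_1", 16L, 4L)
  one_rep_het <- data.frame(
    sample_id = "s1", contig = "chr14", position = 100200L,
    replicate_id = c("rep1", "rep2"),
    is_heterozygous = c(TRUE, FALSE), od_wes = 50L,
    stringsAsFactors = FALSE)
  grid <- estimate_fdr(obs, one_rep_het)
  expect_equal(grid$fp[grid$od_min == 20], 0)
  expect_equal(grid$fdr[grid$od_min == 20], 0)
  # a site covered in only one replicate is ineligible
  single <- one_rep_het[1, , drop = FALSE]
  grid2 <- estimate_fdr(obs, single)
  expect_equal(grid2$n_eligible, rep(0, 3))
  expect_true(all(is.na(grid2$fdr)))
})

test_that("proportion comparison matches the textbook Yates formula", {
  yates_oracle <- function(x1, n1, x2, n2) {
    a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
    n <- n1 + n2
    num <- max(0, abs(a * d - b * c) - n / 2)^2 * n
    chi <- num / ((a + b) * (c + d) * (a + c) * (b + d))
    pchisq(chi, df = 1, lower.tail = FALSE)
  }
  expect_equal(fdr_comparison_test(10, 100, 30, 100),
               yates_oracle(10, 100, 30, 100), tolerance = 1e-12)
  expect_equal(fdr_comparison_test(2, 40, 9, 55),
               yates_oracle(2, 40, 9, 55), tolerance = 1e-12)
  expect_equal(fdr_comparison_test(5, 100, 5, 100), 1.0)
  expect_error(fdr_comparison_test(5, 0, 5, 100))
})

test_that("precision/recall grids equal exhaustive enumeration", {
  truth <- data.frame(
    sample_id = "s1",
    snv_id = sprintf("v%d", 1:8),
    label = rep(c("biallelic", "monoallelic"), each = 4),
    ref_count = c(16L, 30L, 10L, 12L, 40L, 25L, 50L, 8L),
    alt_count = c(4L, 10L, 5L, 2L, 1L, 3L, 12L, 1L),
    stringsAsFactors = FALSE)
  class(truth) <- c("validation_truth", "data.frame")
  grid <- precision_recall(truth, od_grid = c(10, 20),
                           ar_grid = c(0.2, 0.3))
  # independent enumeration oracle
  for (i in seq_len(nrow(grid))) {
    od <- grid$od_min[i]; ar <- grid$cutoff[i]
    called <- with(truth, (ref_count + alt_count) >= od &
                     pmin(ref_count, alt_count) /
                       pmax(ref_count, alt_count) >= ar &
                     pmin(ref_count, alt_count) >= 1)
    is_bi <- truth$label == "biallelic"
    expect_equal(grid$tp[i], sum(called & is_bi))
    expect_equal(grid$fp[i], sum(called & !is_bi))
    expect_equal(grid$fn[i], sum(!called & is_bi))
    expect_equal(grid$tn[i], sum(!called & !is_bi))
    expect_equal(grid$tp[i] + grid$fp[i] + grid$fn[i] + grid$tn[i],
                 nrow(truth))
  }
  # all-biallelic truth called everywhere -> precision = recall = 1
  perfect <- truth[truth$label == "biallelic", ]
  class(perfect) <- c("validation_truth", "data.frame")
  g <- precision_recall(perfect, od_grid = 10, ar_grid = 0.1)
  expect_equal(g$precision, 1)
  expect_equal(g$recall, 1)
  # recall is non-increasing in the depth cutoff
  g2 <- precision_recall(truth, od_grid = c(5, 15, 25, 45),
                         ar_grid = 0.2)
  expect_true(all(diff(g2$recall) <= 0))
  expect_error(precision_recall(truth[0, ], od_grid = 10, ar_grid = 0.2),
               "empty truth")
})

test_that("truth-set loaders validate and filter by depth", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = "s1", snv_id = c("a", "b"),
                         label = c("biallelic", "monoallelic"),
                         ref_count = c(10L, 3L), alt_count = c(5L, 2L)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- read_validation_truth(path)
  expect_equal(nrow(tr), 1L)  # 3+2 = 5 reads is not 'more than five'
  expect_equal(tr$snv_id, "a")

  gpath <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = "s1", contig = "chr1",
                         position = 1L, replicate_id = "rep1",
                         is_heterozygous = TRUE, od_wes = 10L),
              gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(read_genotype_truth(gpath), "genotype_truth")
  expect_error(read_validation_truth(tempfile()), "not found")
})

test_that("synthetic truth reproduces the expected precision/recall shape", {
  # biallelic loci at theta 0.5, monoallelic loci emitting minor reads
  # only through error: precision rises with depth, recall falls
  set.seed(19)
  n <- 150
  od <- rnbinom(2 * n, mu = 30, size = 5) + 1L
  minor_bi <- rbinom(n, od[1:n], 0.5)
  minor_mono <- rbinom(n, od[(n + 1):(2 * n)], 0.06)
  truth <- data.frame(
    sample_id = "s", snv_id = sprintf("v%d", 1:(2 * n)),
    label = rep(c("biallelic", "monoallelic"), each = n),
    ref_count = od - c(minor_bi, minor_mono),
    alt_count = c(minor_bi, minor_mono), stringsAsFactors = FALSE)
  class(truth) <- c("validation_truth", "data.frame")
  g <- precision_recall(truth, od_grid = c(5, 15, 30), ar_grid = 0.2)
  expect_true(all(diff(g$precision) >= 0))
  expect_true(all(diff(g$recall) <= 0))
})
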