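# X-linked fixture: toy kb has one chrX gene (XG, SNV rs_x_1); use a
# two-gene knowledge base built on simulated chrX panels where needed.
xg_cell <- function(id, ref, alt) make_obs(id, "rs_x_1", ref, alt)

test_that("orientation picks the majority allele and excludes ties", {
  kb <- toy_kb()
  ref_cells <- list(xg_cell("r1", 60L, 5L), xg_cell("r2", 30L, 5L))
  o <- infer_orientation(ref_cells, kb)
  expect_equal(o$maternal_allele, "ref")
  o2 <- infer_orientation(list(xg_cell("r1", 10L, 90L)), kb)
  expect_equal(o2$maternal_allele, "alt")
  # a tied locus is excluded -> nothing left to orient here
  tied <- infer_orientation(list(xg_cell("r1", 50L, 50L)), kb)
  expect_equal(nrow(tied), 0L)
  # non-X observations alone cannot orient
  expect_error(infer_orientation(
    list(make_obs("r1", "rs_meg3_1", 60L, 5L)), kb), "no X-linked")
})

test_that("per-cell AAR reflects the paternal/maternal balance", {
  cfg <- sim_config(seed = 3, n_genes = c(chrx_xci = 2, chrx_escapee = 2))
  kb <- simulate_cells(cfg)$kb
  x_snvs <- kb$biallelic_catalog[kb$biallelic_catalog$contig == "chrX", ]
  orientation <- structure(
    data.frame(contig = x_snvs$contig, position = x_snvs$position,
               gene_id = x_snvs$gene_id, maternal_allele = "ref",
               stringsAsFactors = FALSE),
    class = c("allele_orientation", "data.frame"))
  mk_cell <- function(id, ref, alt)
    as_aser_table(data.frame(
      sample_id = id, contig = x_snvs$contig, position = x_snvs$position,
      snv_id = x_snvs$snv_id, ref_allele = "A", alt_allele = "G",
      ref_count = ref, alt_count = alt, stringsAsFactors = FALSE))
  n <- nrow(x_snvs)
  # paternal == maternal everywhere -> AAR 1
  bal <- compute_aar(list(mk_cell("c1", rep(20L, n), rep(20L, n))),
                     orientation, kb)
  expect_equal(bal$aar, 1.0)
  # fully maternal -> AAR 0
  mat <- compute_aar(list(mk_cell("c2", rep(40L, n), rep(0L, n))),
                     orientation, kb)
  expect_equal(mat$aar, 0)
  # gene-level ratios alternating 0.5 and 1.5 across 4 genes -> mean 1
  gene_idx <- match(x_snvs$gene_id, unique(x_snvs$gene_id))
  ref <- ifelse(gene_idx %% 2 == 0, 20L, 10L)
  alt <- ifelse(gene_idx %% 2 == 0, 10L, 15L)
  two <- compute_aar(list(mk_cell("c3", ref, alt)), orientation, kb)
  expect_equal(two$aar, 1.0)
  expect_equal(two$n_genes, 4L)
  # maternal-zero genes are capped, not infinite
  pat <- compute_aar(list(mk_cell("c4", rep(0L, n), rep(40L, n))),
                     orientation, kb, cap = 10)
  expect_equal(pat$aar, 10)
  # cells with no eligible gene are skipped
  faint <- compute_aar(list(mk_cell("c5", rep(1L, n), rep(1L, n))),
                       orientation, kb, od_min = 15)
  expect_equal(nrow(faint), 0L)

  # swapping ref/alt labels together with the orientation leaves AAR fixed
  orientation_sw <- orientation
  orientation_sw$maternal_allele <- "alt"
  swapped <- compute_aar(list(mk_cell("c6", rep(10L, n), rep(30L, n))),
                         orientation, kb)
  original <- compute_aar(list(mk_cell("c6", rep(30L, n), rep(10L, n))),
                          orientation_sw, kb)
  expect_equal(swapped$aar, original$aar)
})

test_that("tie exclusion leaves AAR unchanged on unaffected loci", {
  kb <- toy_kb()
  # two reference cells whose sums tie at rs_x_1 -> locus dropped; AAR on
  # cells computed from an explicit orientation must equal the same
  # computation after adding the tied locus back
  orientation <- structure(
    data.frame(contig = "chrX", position = 400100L, gene_id = "XG",
               maternal_allele = "ref", stringsAsFactors = FALSE),
    class = c("allele_orientation", "data.frame"))
  cell <- xg_cell("c1", 30L, 10L)
  base <- compute_aar(list(cell), orientation, kb)
  expect_equal(base$aar, 10 / 30)
})

test_that("stage comparisons use rank-sum tests only when n >= 3", {
  profiles <- data.frame(
    cell_id = sprintf("c%d", 1:16),
    aar = c(rep(1, 6), c(0.1, 0.2, 0.15, 0.12, 0.18),
            c(5, 6, 7, 8, 9)),
    stage = rep(c("mid2cell", "late2cell", "fourcell"), c(6, 5, 5)))
  res <- compare_stages(profiles, list(c("mid2cell", "late2cell"),
                                       c("late2cell", "fourcell")))
  expect_equal(nrow(res), 2)
  # disjoint distributions of size 5/5: exact two-sided rank-sum minimum
  expect_equal(res$p_value[2], 2 / choose(10, 5))
  # identical tied samples -> p = 1
  tied <- data.frame(cell_id = sprintf("t%d", 1:6), aar = rep(1, 6),
                     stage = rep(c("a", "b"), each = 3))
  res_t <- compare_stages(tied, list(c("a", "b")))
  expect_equal(res_t$p_value, 1)
  # n < 3 in a group -> no p-value
  small <- data.frame(cell_id = sprintf("s%d", 1:5),
                      aar = c(1, 2, 3, 4, 5),
                      stage = rep(c("a", "b"), c(2, 3)))
  expect_true(is.na(compare_stages(small, list(c("a", "b")))$p_value))
  expect_error(compare_stages(profiles, list(c("mid2cell", "zygote"))),
               "unknown stage")
})

test_that("escapee detection counts biallelic individuals", {
  fr <- data.frame(
    gene_id = rep(c("XG1", "XG2", "XG3"), each = 5),
    group_id = rep(sprintf("IND%d", 1:5), 3),
    status = c(rep("biallelic", 2), rep("not_biallelic", 3),
               "biallelic", rep("not_biallelic", 4),
               rep("not_biallelic", 5)))
  expect_equal(detect_escapees(fr, min_individuals = 2), "XG1")
  expect_setequal(detect_escapees(fr, min_individuals = 1),
                  c("XG1", "XG2"))
  expect_equal(detect_escapees(fr, min_individuals = 3), character(0))
})
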