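test_that("a fixed seed reproduces the simulation exactly", {
  a <- simulate_bulk(sim_config(seed = 5, n_samples = 2))
  b <- simulate_bulk(sim_config(seed = 5, n_samples = 2))
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth, b$truth)
  c1 <- simulate_cells(sim_config(seed = 5, n_cells = 8))
  c2 <- simulate_cells(sim_config(seed = 5, n_cells = 8))
  expect_identical(c1$tables, c2$tables)
  # a different seed changes the draw
  d <- simulate_bulk(sim_config(seed = 6, n_samples = 2))
  expect_false(identical(a$tables, d$tables))
  # the simulator leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_bulk(sim_config(seed = 5,
                                                    n_samples = 1)))
  expect_identical(runif(1), before)
})

test_that("zero error rate yields no minor reads at monoallelic loci", {
  cfg <- sim_config(seed = 2, error_rate = 0,
                    n_genes = c(imprinted_monoallelic = 5, chry = 3),
                    sample_sex = rep("male", 2), n_samples = 2)
  sim <- simulate_bulk(cfg)
  for (tab in sim$tables)
    expect_true(all(pmin(tab$ref_count, tab$alt_count) == 0))
})

test_that("balanced biallelic loci approach AR 1 at high depth", {
  cfg <- sim_config(seed = 3, coverage_mean = 5000,
                    coverage_dispersion = 1e6, theta = 0.5,
                    n_genes = c(autosomal_biallelic = 10), n_samples = 1)
  sim <- simulate_bulk(cfg)
  tab <- sim$tables[[1]]
  ar <- compute_ar(tab$ref_count, tab$alt_count, "minor_over_major")
  expect_true(all(ar > 0.9))
})

test_that("bulk calling at defaults recovers the simulated gene classes", {
  sim <- simulate_bulk(sim_config(seed = 4))
  fit <- call_biallelic(sim$tables, sim$kb)
  m <- merge(fit$gene_summary, sim$truth,
             by = c("gene_id", "sample_id"))
  called <- m$status == "biallelic"
  precision <- sum(called & m$expected_biallelic) / sum(called)
  recall <- sum(called & m$expected_biallelic) /
    sum(m$expected_biallelic)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("male sex chromosomes yield no biallelic calls at defaults", {
  cfg <- sim_config(seed = 8, n_genes = c(chrx_xci = 6, chry = 6),
                    sample_sex = rep("male", 4), n_samples = 4)
  sim <- simulate_bulk(cfg)
  fit <- call_biallelic(sim$tables, sim$kb)
  expect_equal(sum(fit$gene_summary$status == "biallelic"), 0)
  expect_equal(sum(fit$snv_calls$status == "biallelic"), 0)
})

test_that("bulk pooling hides XCI while full skew restores monoallelic X", {
  # random XCI (skew 0.5): pooled female X looks biallelic in bulk
  mixed <- simulate_bulk(sim_config(seed = 9, n_genes = c(chrx_xci = 6),
                                    sample_sex = "female", n_samples = 1,
                                    xci_skew = 0.5))
  fit <- call_biallelic(mixed$tables, mixed$kb)
  expect_true(all(fit$gene_summary$status == "biallelic"))
  # every cell silencing the same X: bulk X is monoallelic
  skewed <- simulate_bulk(sim_config(seed = 9, n_genes = c(chrx_xci = 6),
                                     sample_sex = "female", n_samples = 1,
                                     xci_skew = 1))
  fit2 <- call_biallelic(skewed$tables, skewed$kb)
  expect_equal(sum(fit2$gene_summary$status == "biallelic"), 0)
})

test_that("chrY loci are absent from female cells and truth flags are coherent", {
  sim <- simulate_cells(sim_config(seed = 10, n_cells = 6))
  for (tab in sim$tables) expect_false(any(tab$contig == "chrY"))
  expect_false(any(sim$truth$class == "chry"))
  # escapees emit biallelic counts in every cell
  esc <- sim$truth[sim$truth$class == "chrx_escapee", ]
  expect_true(all(esc$biallelic_emitted))
  # XCI genes emit biallelic counts only in reactivated cells
  xci <- sim$truth[sim$truth$class == "chrx_xci", ]
  expect_true(all(!xci$biallelic_emitted))
  re <- simulate_cells(sim_config(seed = 10, n_cells = 6,
                                  cell_x_state = "reactivated"))
  xci_re <- re$truth[re$truth$class == "chrx_xci", ]
  expect_true(all(xci_re$biallelic_emitted))
})

test_that("simulated tables round-trip through the counter dialect", {
  sim <- simulate_bulk(sim_config(seed = 12, n_samples = 1))
  tab <- sim$tables[[1]]
  path <- tempfile(fileext = ".tsv")
  write_aser_table(tab, path)
  back <- read_aser_table(path, tab$sample_id[1])
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(error_rate = 0.6))
  expect_error(sim_config(theta = 0))
  expect_error(sim_config(n_genes = c(bogus_class = 3)))
  expect_error(sim_config(sample_sex = "female", n_samples = 2))
})
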