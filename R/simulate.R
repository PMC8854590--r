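#' Configuration for the allele-count simulators
#'
#' Defines the synthetic study conditions under which the callers are
#' exercised: a panel of genes in six ground-truth classes (imprinted
#' monoallelic, imprinted with loss of imprinting, X-linked subject to
#' XCI, X-linked escapee, Y-linked, autosomal biallelic), each carrying
#' `snvs_per_gene` heterozygous SNVs. Read depth per SNV follows a
#' negative-binomial coverage model (Poisson available); a monoallelic
#' locus emits minor-allele reads only through the per-read error rate,
#' while a biallelic locus emits a minor fraction `theta` (0.5 =
#' balanced). Female bulk samples pool cells with random XCI, so X-linked
#' genes subject to XCI appear biallelic in bulk at skew 0.5; male samples
#' carry a single X and Y allele.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param n_genes Named integer vector: genes per class (names
#'   `imprinted_monoallelic`, `imprinted_loi`, `chrx_xci`,
#'   `chrx_escapee`, `chry`, `autosomal_biallelic`).
#' @param snvs_per_gene SNVs per gene.
#' @param coverage_mean,coverage_dispersion Mean and NB size of per-SNV
#'   depth in bulk samples.
#' @param coverage_model `"nb"` or `"poisson"`.
#' @param error_rate Probability a read reports the silent allele
#'   (default 0.005, in the range of post-filter Illumina error).
#' @param theta Expected minor-allele fraction at biallelic loci.
#' @param n_samples Bulk samples; `sample_sex` defaults to alternating
#'   female/male.
#' @param sample_sex Optional character vector (`"female"`/`"male"`).
#' @param n_cells Cells for [simulate_cells()] (all female).
#' @param cell_coverage_factor Bulk-to-cell mean-depth ratio.
#' @param cell_coverage_dispersion NB size for per-cell depth (smaller =
#'   more dropout).
#' @param xci_skew Probability a cell keeps the maternal (reference) X
#'   active.
#' @param cell_x_state `"xci"` (one X silenced per cell) or
#'   `"reactivated"` (both X active in every cell).
#' @param loi_cell_fraction Fraction of cells in which a
#'   loss-of-imprinting gene emits biallelic counts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = c(imprinted_monoallelic = 6,
                                   imprinted_loi = 6,
                                   chrx_xci = 6,
                                   chrx_escapee = 6,
                                   chry = 6,
                                   autosomal_biallelic = 6),
                       snvs_per_gene = 4,
                       coverage_mean = 60, coverage_dispersion = 4,
                       coverage_model = c("nb", "poisson"),
                       error_rate = 0.005, theta = 0.5,
                       n_samples = 6, sample_sex = NULL,
                       n_cells = 60, cell_coverage_factor = 4,
                       cell_coverage_dispersion = 1,
                       xci_skew = 0.5,
                       cell_x_state = c("xci", "reactivated"),
                       loi_cell_fraction = 1) {
  coverage_model <- match.arg(coverage_model)
  cell_x_state <- match.arg(cell_x_state)
  stopifnot(error_rate >= 0, error_rate < 0.5, theta > 0, theta <= 0.5,
            xci_skew >= 0, xci_skew <= 1,
            loi_cell_fraction >= 0, loi_cell_fraction <= 1)
  classes <- c("imprinted_monoallelic", "imprinted_loi", "chrx_xci",
               "chrx_escapee", "chry", "autosomal_biallelic")
  stopifnot(all(names(n_genes) %in% classes))
  full <- setNames(rep(0L, length(classes)), classes)
  full[names(n_genes)] <- as.integer(n_genes)
  if (is.null(sample_sex))
    sample_sex <- rep(c("female", "male"), length.out = n_samples)
  stopifnot(length(sample_sex) == n_samples,
            all(sample_sex %in% c("female", "male")))
  structure(list(seed = as.integer(seed), n_genes = full,
                 snvs_per_gene = as.integer(snvs_per_gene),
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 coverage_model = coverage_model,
                 error_rate = error_rate, theta = theta,
                 n_samples = as.integer(n_samples),
                 sample_sex = sample_sex,
                 n_cells = as.integer(n_cells),
                 cell_coverage_factor = cell_coverage_factor,
                 cell_coverage_dispersion = cell_coverage_dispersion,
                 xci_skew = xci_skew, cell_x_state = cell_x_state,
                 loi_cell_fraction = loi_cell_fraction),
            class = "sim_config")
}

# gene panel + in-memory knowledge base shared by both simulators
sim_gene_panel <- function(config) {
  classes <- names(config$n_genes)
  contig_of <- c(imprinted_monoallelic = "chr7", imprinted_loi = "chr14",
                 chrx_xci = "chrX", chrx_escapee = "chrX", chry = "chrY",
                 autosomal_biallelic = "chr1")
  source_of <- c(imprinted_monoallelic = "geneimprint,otago",
                 imprinted_loi = "geneimprint,otago",
                 chrx_xci = "chrX", chrx_escapee = "chrX", chry = "chrY",
                 autosomal_biallelic = "geneimprint")
  genes <- do.call(rbind, lapply(classes, function(cl) {
    n <- config$n_genes[[cl]]
    if (n == 0L) return(NULL)
    idx <- seq_len(n)
    # escapees interleave with XCI genes along chrX
    offset <- switch(cl, chrx_escapee = 500000L, 0L)
    data.frame(gene_id = sprintf("%s_%d", toupper(cl), idx),
               symbol = sprintf("%s_%d", toupper(cl), idx),
               contig = contig_of[[cl]],
               start = offset + 1000000L * idx + 1L,
               end = offset + 1000000L * idx + 10000L,
               sources = source_of[[cl]],
               placental = FALSE, isoform_dependent = FALSE,
               sex_linked = cl %in% c("chrx_xci", "chrx_escapee", "chry"),
               class = cl, stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  snvs <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    k <- seq_len(config$snvs_per_gene)
    data.frame(contig = genes$contig[i],
               position = genes$start[i] + 100L * k,
               snv_id = sprintf("rs_%s_%d", genes$gene_id[i], k),
               ref_allele = "A", alt_alleles = "G",
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  }))
  kb <- structure(
    list(genome_build = "synthetic",
         genes = genes[, setdiff(names(genes), "class")],
         biallelic_catalog = order_catalog(snvs),
         multiallelic_catalog = empty_catalog()),
    class = "knowledge_base")
  list(genes = genes, snvs = snvs, kb = kb)
}

sim_draw_depth <- function(n, mean, config, dispersion) {
  if (config$coverage_model == "nb")
    rnbinom(n, mu = mean, size = dispersion)
  else
    rpois(n, mean)
}

# run expr with the RNG seeded from config, restoring the caller's RNG state
with_sim_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# effective alt-read fraction: base biological fraction blurred by error
sim_f_eff <- function(f, eps) f * (1 - eps) + (1 - f) * eps

#' Simulate bulk allele-count tables with known ground truth
#'
#' Draws per-SNV depths from the coverage model and alternative-allele
#' counts from a binomial with the class- and sex-appropriate allele
#' fraction (see [sim_config()]). Sites drawing zero depth are absent from
#' the tables, as in real allele-counter output.
#'
#' @param config A [sim_config()].
#' @return List: `tables` (one `aser_table` per sample), `truth` (per
#'   gene x sample: `class`, `sex`, `minor_fraction` — the true minor
#'   allele fraction of the transcript pool — and `expected_biallelic`,
#'   true when the minor fraction exceeds the 5\% floor below which
#'   expression is effectively monoallelic), `kb` (matching in-memory
#'   knowledge base), `config`.
#' @export
simulate_bulk <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  panel <- sim_gene_panel(config)
  eps <- config$error_rate
  with_sim_rng(config$seed, {
    # expressed allele of each monoallelic imprinted gene, shared by samples
    mono_allele <- setNames(
      sample(c("ref", "alt"), nrow(panel$genes), replace = TRUE),
      panel$genes$gene_id)
    tables <- list(); truth <- list()
    for (s in seq_len(config$n_samples)) {
      sex <- config$sample_sex[s]
      sample_id <- sprintf("sample_%02d", s)
      rows <- list()
      for (i in seq_len(nrow(panel$genes))) {
        g <- panel$genes[i, ]
        f <- switch(g$class,
          imprinted_monoallelic =
            if (mono_allele[[g$gene_id]] == "ref") 0 else 1,
          imprinted_loi = config$theta,
          autosomal_biallelic = config$theta,
          chrx_escapee = if (sex == "female") config$theta else 0,
          chrx_xci = if (sex == "female") 1 - config$xci_skew else 0,
          chry = if (sex == "male") 0 else NA_real_)
        if (is.na(f)) next  # locus absent (chrY in females)
        snvs <- panel$snvs[panel$snvs$gene_id == g$gene_id, , drop = FALSE]
        od <- sim_draw_depth(nrow(snvs), config$coverage_mean, config,
                             config$coverage_dispersion)
        alt <- rbinom(nrow(snvs), od, sim_f_eff(f, eps))
        keep <- od > 0
        if (any(keep))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, contig = snvs$contig[keep],
            position = snvs$position[keep], snv_id = snvs$snv_id[keep],
            ref_allele = snvs$ref_allele[keep],
            alt_allele = snvs$alt_alleles[keep],
            ref_count = (od - alt)[keep], alt_count = alt[keep],
            stringsAsFactors = FALSE)
        minor <- if (is.na(f)) NA_real_ else min(f, 1 - f)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = g$gene_id, sample_id = sample_id, class = g$class,
          sex = sex, minor_fraction = minor,
          expected_biallelic = minor > 0.05, stringsAsFactors = FALSE)
      }
      tables[[sample_id]] <- as_aser_table(do.call(rbind, rows))
    }
    list(tables = tables, truth = do.call(rbind, truth), kb = panel$kb,
         config = config)
  })
}

#' Simulate single-cell allele-count tables with known ground truth
#'
#' Each (female) cell silences one X at random (maternal = reference
#' allele kept active with probability `xci_skew`) unless
#' `cell_x_state = "reactivated"`, in which case both X are active in
#' every cell. Escapee genes emit biallelic counts in every cell;
#' loss-of-imprinting genes emit biallelic counts in a `loi_cell_fraction`
#' of cells; per-cell depth is the bulk mean divided by
#' `cell_coverage_factor`, with heavier dispersion to emulate dropout.
#'
#' @param config A [sim_config()].
#' @return List: `tables` (one `aser_table` per cell), `truth` (per gene x
#'   cell: `class`, `biallelic_emitted`, `active_x`), `cell_meta` (per
#'   cell: `cell_id`, `active_x`), `kb`, `config`.
#' @export
simulate_cells <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  panel <- sim_gene_panel(config)
  eps <- config$error_rate
  mean_cell <- config$coverage_mean / config$cell_coverage_factor
  with_sim_rng(config$seed + 1L, {
    mono_allele <- setNames(
      sample(c("ref", "alt"), nrow(panel$genes), replace = TRUE),
      panel$genes$gene_id)
    tables <- list(); truth <- list(); meta <- list()
    for (c_i in seq_len(config$n_cells)) {
      cell_id <- sprintf("cell_%03d", c_i)
      active_x <- if (config$cell_x_state == "reactivated") "both"
        else if (runif(1) < config$xci_skew) "ref" else "alt"
      meta[[c_i]] <- data.frame(cell_id = cell_id, active_x = active_x,
                                stringsAsFactors = FALSE)
      rows <- list()
      for (i in seq_len(nrow(panel$genes))) {
        g <- panel$genes[i, ]
        if (g$class == "chry") next  # female cells
        bi <- switch(g$class,
          imprinted_monoallelic = FALSE,
          imprinted_loi = runif(1) < config$loi_cell_fraction,
          autosomal_biallelic = TRUE,
          chrx_escapee = TRUE,
          chrx_xci = active_x == "both")
        f <- if (bi) config$theta
          else switch(g$class,
            imprinted_monoallelic =
              if (mono_allele[[g$gene_id]] == "ref") 0 else 1,
            imprinted_loi = if (mono_allele[[g$gene_id]] == "ref") 0 else 1,
            chrx_xci = if (active_x == "ref") 0 else 1)
        snvs <- panel$snvs[panel$snvs$gene_id == g$gene_id, , drop = FALSE]
        od <- sim_draw_depth(nrow(snvs), mean_cell, config,
                             config$cell_coverage_dispersion)
        alt <- rbinom(nrow(snvs), od, sim_f_eff(f, eps))
        keep <- od > 0
        if (any(keep))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = cell_id, contig = snvs$contig[keep],
            position = snvs$position[keep], snv_id = snvs$snv_id[keep],
            ref_allele = snvs$ref_allele[keep],
            alt_allele = snvs$alt_alleles[keep],
            ref_count = (od - alt)[keep], alt_count = alt[keep],
            stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = g$gene_id, cell_id = cell_id, class = g$class,
          biallelic_emitted = bi, active_x = active_x,
          stringsAsFactors = FALSE)
      }
      tables[[cell_id]] <- if (length(rows))
        as_aser_table(do.call(rbind, rows)) else NULL
    }
    tables <- Filter(Negate(is.null), tables)
    list(tables = tables, truth = do.call(rbind, truth),
         cell_meta = do.call(rbind, meta), kb = panel$kb, config = config)
  })
}

#' Write an allele-count table in the counter dialect
#'
#' Writes the tab-separated dialect read back by [read_aser_table()]
#' (columns `contig` ... `totalCount`), e.g. to materialise simulated
#' samples on disk.
#'
#' @param tab An `aser_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_aser_table <- function(tab, path) {
  out <- data.frame(contig = tab$contig, position = tab$position,
                    variantID = tab$snv_id, refAllele = tab$ref_allele,
                    altAllele = tab$alt_allele, refCount = tab$ref_count,
                    altCount = tab$alt_count,
                    totalCount = tab$ref_count + tab$alt_count,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
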