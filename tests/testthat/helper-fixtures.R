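# fixtures are built in code at test time; nothing binary is stored

write_minimal_vcf <- function(path, records) {
  # records: data.frame with chrom, pos, id, ref, alt
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  records$chrom, records$pos, records$id, records$ref,
                  records$alt)
  writeLines(c(header, body), path)
  path
}

# A small knowledge base on disk: two imprinted genes, one X- and one
# Y-linked gene, one placental-specific gene, and a pair of overlapping
# genes sharing an SNV. The VCF carries an INDEL and an orphan record that
# the loader must drop.
write_toy_kb_files <- function(dir = tempfile("kb")) {
  dir.create(dir, showWarnings = FALSE)
  bed <- data.frame(
    contig = c("chr14", "chr11", "chr11", "chrX", "chrY", "chr2", "chr2"),
    start = c(100000L, 200000L, 300000L, 400000L, 500000L, 600000L,
              600300L),
    end = c(100500L, 200500L, 300500L, 400500L, 500500L, 600500L,
            600800L),
    gene_id = c("MEG3", "H19", "PLAC_G", "XG", "YG", "OVL1", "OVL2"))
  write.table(bed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- data.frame(
    gene_id = bed$gene_id,
    symbol = bed$gene_id,
    sources = c("geneimprint,otago", "geneimprint", "otago", "chrX",
                "chrY", "santoni", "inoue"),
    placental = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    isoform_dependent = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  write.table(meta, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_minimal_vcf(file.path(dir, "biallelic.vcf"), data.frame(
    chrom = c("chr14", "chr14", "chr11", "chr11", "chrX", "chrY", "chr2",
              "chr9", "chr14"),
    pos = c(100200L, 100300L, 200100L, 300100L, 400100L, 500100L,
            600400L, 1000L, 100400L),
    id = c("rs_meg3_1", "rs_meg3_2", "rs_h19_1", "rs_plac_1", "rs_x_1",
           "rs_y_1", "rs_ovl_1", "rs_orphan", "rs_indel"),
    ref = c("A", "C", "G", "T", "A", "C", "G", "A", "A"),
    alt = c("G", "T", "A", "C", "G", "T", "A", "G", "<DEL>")))
  write_minimal_vcf(file.path(dir, "multiallelic.vcf"), data.frame(
    chrom = "chr14", pos = 100250L, id = "rs_meg3_multi", ref = "A",
    alt = "G,T"))
  dir
}

toy_kb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- write_toy_kb_files()
      cache <<- suppressWarnings(suppressMessages(load_knowledge_base(
        file.path(dir, "genes.bed"), file.path(dir, "genes.tsv"),
        file.path(dir, "biallelic.vcf"),
        file.path(dir, "multiallelic.vcf"))))
    }
    cache
  }
})

# quick observation-table builder on the toy knowledge base
make_obs <- function(sample_id, snv_id, ref_count, alt_count,
                     kb = toy_kb()) {
  cat <- rbind(kb$biallelic_catalog, kb$multiallelic_catalog)
  idx <- match(snv_id, cat$snv_id)
  stopifnot(!anyNA(idx))
  as_aser_table(data.frame(
    sample_id = sample_id, contig = cat$contig[idx],
    position = cat$position[idx], snv_id = snv_id,
    ref_allele = cat$ref_allele[idx],
    alt_allele = vapply(strsplit(cat$alt_alleles[idx], ","), `[`, "", 1),
    ref_count = ref_count, alt_count = alt_count,
    stringsAsFactors = FALSE))
}

# 12-cell fixture on the toy knowledge base:
# - MEG3 is expressed (>=1 SNV at OD >= 15) in cells 1-10; cells 1-2 carry
#   a biallelic SNV (12/6), cells 3-10 a monoallelic one (20/1); cells
#   11-12 stay below coverage (5/1).
# - H19 is expressed monoallelically in cells 1-9 only.
make_sc_fixture <- function(n_biallelic_cells = 2) {
  lapply(1:12, function(i) {
    id <- sprintf("c%02d", i)
    meg3 <- if (i <= n_biallelic_cells) c(12L, 6L)
      else if (i <= 10) c(20L, 1L) else c(5L, 1L)
    rows <- make_obs(id, "rs_meg3_1", meg3[1], meg3[2])
    if (i <= 9)
      rows <- as_aser_table(rbind(rows,
                                  make_obs(id, "rs_h19_1", 20L, 2L)))
    rows
  })
}

sc_groups <- data.frame(cell_id = sprintf("c%02d", 1:12), group_id = "g1")

# independent exact binomial upper-tail oracle (log-space term sum)
binom_tail_oracle <- function(k, n, p = 1 / 6) {
  if (k <= 0) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}
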