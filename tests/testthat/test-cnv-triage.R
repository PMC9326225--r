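toy_lengths <- c(chr18 = 1e7, chr21 = 1e7, chrX = 1e7, chr1 = 1e7, chr2 = 1e7)

mk_cnv <- function(sample_id = "S1", chrom = "chr1", start = 1e6,
                   end = 1.2e6, copy_state = "deletion",
                   mosaic_fraction = NA_real_, tier = "P") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             copy_state = copy_state, mosaic_fraction = mosaic_fraction,
             tier = tier, size = end - start + 1, stringsAsFactors = FALSE)
}

toy_panel <- function() {
  p <- data.frame(
    gene_symbol = c("PAN1", "PAN2"),
    sources = "review", inheritance_modes = "AD",
    chrom = c("chr1", "chr2"),
    start = c(1e6, 3e6), end = c(1.06e6, 3.06e6),
    stringsAsFactors = FALSE
  )
  class(p) <- c("gene_panel", "data.frame")
  p
}

test_that("near-whole-chromosome events promote to aneuploidies", {
  cfg <- triage_config()
  dup <- mk_cnv(chrom = "chr21", start = 250000, end = 9750000,
                copy_state = "duplication")
  tri <- promote_aneuploidy(dup, toy_lengths, cfg)
  expect_equal(tri$kind, "trisomy")
  expect_equal(tri$label, "T21")

  del_x <- mk_cnv(chrom = "chrX", start = 250000, end = 9750000,
                  copy_state = "deletion", mosaic_fraction = 0.12)
  mono <- promote_aneuploidy(del_x, toy_lengths, cfg)
  expect_equal(mono$kind, "monosomy")
  expect_equal(mono$label, "XO")
  expect_equal(mono$mosaic_fraction, 0.12)   # propagated, never gating

  half <- mk_cnv(chrom = "chr18", start = 1, end = 5e6)
  expect_null(promote_aneuploidy(half, toy_lengths, cfg))

  expect_error(promote_aneuploidy(mk_cnv(chrom = "chr99"), toy_lengths, cfg),
               class = "chdtriage_validation_error")
})

test_that("segmental CNVs triage by tier and panel overlap", {
  cfg <- triage_config()
  panel <- toy_panel()

  p_del <- triage_cnv(mk_cnv(tier = "P"), panel, cfg)
  expect_equal(p_del$evidence_class, "pathogenic_cnv")

  vus_hit <- triage_cnv(mk_cnv(tier = "VUS", start = 0.95e6, end = 1.1e6),
                        panel, cfg)
  expect_equal(vus_hit$evidence_class, "vus_cnv_panel_gene")
  expect_equal(vus_hit$panel_genes_hit, "PAN1")

  # VUS with no panel gene in the interval is not an etiology
  expect_null(triage_cnv(mk_cnv(tier = "VUS", chrom = "chr2", start = 5e6,
                                end = 5.3e6), panel, cfg))
  expect_null(triage_cnv(mk_cnv(tier = "LB"), panel, cfg))
})

test_that("every call lands in exactly one partition bin", {
  cfg <- triage_config()
  panel <- toy_panel()
  set.seed(5)
  n <- 120
  cnvs <- do.call(rbind, lapply(seq_len(n), function(i) {
    chrom <- sample(names(toy_lengths), 1)
    start <- sample.int(9e6, 1)
    size <- sample(c(9e4, 2e5, 9.6e6), 1)   # small / segmental / whole-chrom
    mk_cnv(sample_id = sprintf("S%03d", i), chrom = chrom,
           start = if (size > 9e6) 200000 else start,
           end = if (size > 9e6) 9800000 else start + size - 1,
           copy_state = sample(c("deletion", "duplication"), 1),
           tier = sample(c("B", "LB", "VUS", "LP", "P"), 1))
  }))
  class(cnvs) <- c("cnv_calls", "data.frame")
  tri <- triage_cnvs(cnvs, panel, toy_lengths, cfg)
  expect_equal(sum(tri$partition), n)
  expect_equal(unname(tri$partition[["excluded-small"]]), sum(cnvs$size < 1e5))
  # etiology table covers exactly the three causative bins
  expect_equal(nrow(tri$etiologies),
               sum(tri$partition[c("aneuploidy", "pathogenic_cnv",
                                   "vus_cnv_panel_gene")]))
})

test_that("interval overlap matches a brute-force scan on random fixtures", {
  cfg <- triage_config()
  set.seed(9)
  for (rep in 1:5) {
    panel <- data.frame(
      gene_symbol = sprintf("G%02d", 1:30),
      sources = "review", inheritance_modes = "AD",
      chrom = sample(paste0("chr", 1:4), 30, replace = TRUE),
      start = sample.int(5e6, 30), stringsAsFactors = FALSE
    )
    panel$end <- panel$start + sample.int(2e5, 30)
    class(panel) <- c("gene_panel", "data.frame")
    cnvs <- data.frame(
      sample_id = "S1",
      chrom = sample(paste0("chr", 1:4), 40, replace = TRUE),
      start = sample.int(5e6, 40), stringsAsFactors = FALSE
    )
    cnvs$end <- cnvs$start + sample.int(1e6, 40)
    expect_equal(cnv_panel_genes(cnvs, panel, cfg),
                 overlap_oracle(cnvs, panel))
    cfg_within <- triage_config(cnv_gene_overlap = "containment")
    expect_equal(cnv_panel_genes(cnvs, panel, cfg_within),
                 overlap_oracle(cnvs, panel, containment = TRUE))
  }
})

test_that("mosaic fraction never changes a triage decision", {
  cfg <- triage_config()
  panel <- toy_panel()
  base <- mk_cnv(tier = "P")
  mosaic <- base
  mosaic$mosaic_fraction <- 0.13
  expect_equal(triage_cnv(base, panel, cfg)$evidence_class,
               triage_cnv(mosaic, panel, cfg)$evidence_class)
})

test_that("recurrence counts distinct samples per label", {
  labs <- data.frame(
    sample_id = c("S1", "S2", "S3", "S3", "S4", "S5", "S5"),
    label = c("del(22q)", "del(22q)", "del(22q)", "del(22q)", "T18", "T18",
              "XO"),
    stringsAsFactors = FALSE
  )
  tab <- recurrence_table(labs)
  expect_equal(tab$n_samples[tab$label == "del(22q)"], 3L)  # S3 deduped
  expect_equal(tab$n_samples[tab$label == "T18"], 2L)
  expect_equal(tab$label[1], "del(22q)")                    # sorted by count
  expect_equal(nrow(recurrence_table(labs[0, ])), 0L)
})
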