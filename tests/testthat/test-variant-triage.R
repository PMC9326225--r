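mk_variant <- function(sample_id = "S1", gene = "G1", chrom = "chr1",
                       pos = 100L, ref = "A", alt = "T",
                       consequence = "frameshift", filter_status = "PASS",
                       genotype = "het", ref_depth = 30L, alt_depth = 28L,
                       evidence_codes = "PVS1,PM2,PP3", tier = NULL) {
  df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos, id = ".",
                   ref = ref, alt = alt, gene = gene,
                   consequence = consequence, filter_status = filter_status,
                   genotype = genotype, ref_depth = ref_depth,
                   alt_depth = alt_depth, evidence_codes = evidence_codes,
                   stringsAsFactors = FALSE)
  if (!is.null(tier)) df$tier <- tier
  df
}

mk_panel <- function() {
  p <- data.frame(
    gene_symbol = c("G1", "GAR", "GX"),
    sources = "review",
    inheritance_modes = c("AD", "AR", "XLR"),
    chrom = c("chr1", "chr2", "chrX"),
    start = c(50L, 50L, 50L), end = c(5000L, 5000L, 5000L),
    stringsAsFactors = FALSE
  )
  class(p) <- c("gene_panel", "data.frame")
  p
}

test_that("the allele-fraction gate excludes a 23% het call", {
  # mirrors the recurrent frameshift insertion excluded at 23% in one sample
  cfg <- triage_config()
  v <- mk_variant(ref_depth = 77L, alt_depth = 23L)
  res <- passes_technical_filters(v, cfg)
  expect_false(res$pass)
  expect_equal(res$reason, "het-af")
  # the same depths in a hom call are not gated on fraction
  hom <- passes_technical_filters(mk_variant(ref_depth = 77L, alt_depth = 23L,
                                             genotype = "hom"), cfg)
  expect_true(hom$pass)
})

test_that("technical gates are inclusive at their printed boundaries", {
  cfg <- triage_config()
  # 4 < 5 alternate reads fails even at balanced fraction
  low <- passes_technical_filters(mk_variant(ref_depth = 4L, alt_depth = 4L), cfg)
  expect_false(low$pass)
  expect_equal(low$reason, "alt-depth")
  # exactly 5 reads and fraction 1.0 passes ("no less than 5X")
  expect_true(passes_technical_filters(
    mk_variant(genotype = "hom", ref_depth = 0L, alt_depth = 5L), cfg)$pass)
  # exactly 25% passes ("exceeding or equal to")
  expect_true(passes_technical_filters(
    mk_variant(ref_depth = 15L, alt_depth = 5L), cfg)$pass)
  # an otherwise perfect non-PASS call fails on filter status
  np <- passes_technical_filters(mk_variant(filter_status = "LowQual"), cfg)
  expect_false(np$pass)
  expect_equal(np$reason, "filter-status")
  # het with no depth at all: caught by the depth gate, or reported as
  # "no-depth" when the depth gate is disabled
  nd <- passes_technical_filters(
    mk_variant(ref_depth = 0L, alt_depth = 0L), cfg)
  expect_false(nd$pass)
  expect_equal(nd$reason, "alt-depth")
  nd0 <- passes_technical_filters(
    mk_variant(ref_depth = 0L, alt_depth = 0L),
    triage_config(min_alt_depth = 0L))
  expect_false(nd0$pass)
  expect_equal(nd0$reason, "no-depth")
})

test_that("pass/fail outcome is the conjunction of the individual gates", {
  cfg <- triage_config()
  set.seed(11)
  v <- data.frame(
    filter_status = sample(c("PASS", "LowQual"), 200, replace = TRUE),
    genotype = sample(c("het", "hom", "hemi"), 200, replace = TRUE),
    ref_depth = sample(0:40, 200, replace = TRUE),
    alt_depth = sample(0:40, 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  st <- technical_filter_status(v, cfg)
  tot <- v$ref_depth + v$alt_depth
  expected <- v$filter_status == "PASS" &
    v$alt_depth >= cfg$min_alt_depth &
    (v$genotype != "het" |
       (tot > 0 & v$alt_depth / tot >= cfg$min_het_allele_fraction))
  expect_equal(st$pass, expected)
})

test_that("zygosity consistency follows the inheritance mode", {
  het <- mk_variant()
  expect_true(inheritance_consistent(het, "AD", "male")$ok)
  expect_equal(inheritance_consistent(het, "AD", "male")$mode_used, "AD")

  # AR: a single het never qualifies; two distinct hets are flagged and
  # still excluded (phase unconfirmed)
  expect_false(inheritance_consistent(het, "AR", "female")$ok)
  two <- rbind(mk_variant(pos = 100L), mk_variant(pos = 200L, alt = "G"))
  res <- inheritance_consistent(two, "AR", "female")
  expect_false(res$ok)
  expect_true("suspected_compound_het" %in% res$flags)
  # a hom call does qualify under AR
  expect_true(inheritance_consistent(mk_variant(genotype = "hom"), "AR",
                                     "female")$ok)

  # XLR: hemizygous males qualify
  hemi <- mk_variant(genotype = "hemi", chrom = "chrX")
  xl <- inheritance_consistent(hemi, "XLR", "male")
  expect_true(xl$ok)
  expect_equal(xl$mode_used, "XLR")

  # fixed precedence: AD wins over AR when both are listed
  expect_equal(inheritance_consistent(het, c("AR", "AD"), "male")$mode_used,
               "AD")
  # no modes recorded: cannot qualify
  expect_false(inheritance_consistent(het, character(), "male")$ok)
})

test_that("gene etiologies compose the gates and respect list membership", {
  cfg <- triage_config()
  panel <- mk_panel()
  meta <- data.frame(sample_id = c("S1", "S2"), sex = c("male", "female"),
                     sample_type = "tissue", ultrasound_period = "fetus",
                     phenotype_group = "isolated", stringsAsFactors = FALSE)
  v <- rbind(
    mk_variant(sample_id = "S1", gene = "G1"),                    # panel AD het P
    mk_variant(sample_id = "S1", gene = "CANDX", chrom = "chr3",  # candidate list
               consequence = "splice3"),
    mk_variant(sample_id = "S2", gene = "G1",                     # fails AF gate
               ref_depth = 77L, alt_depth = 23L),
    mk_variant(sample_id = "S2", gene = "NOWHERE", chrom = "chr4"),  # unlisted
    mk_variant(sample_id = "S2", gene = "GAR", chrom = "chr2"),   # AR single het
    mk_variant(sample_id = "S2", gene = "GAR", chrom = "chr2",    # AR second het
               pos = 300L)
  )
  v <- classify_variants(v)
  et <- assign_gene_etiologies(v, panel, candidate_list = c("CANDX", "G1"),
                               meta = meta, cfg = cfg)
  expect_equal(nrow(et), 2L)
  expect_equal(et$evidence_class[et$gene == "G1"], "definitive_panel")
  expect_equal(et$evidence_class[et$gene == "CANDX"], "candidate_gene")
  # panel membership wins over candidate-list membership for G1
  expect_false(any(et$gene == "G1" & et$evidence_class == "candidate_gene"))
  # the failing, unlisted and compound-het variants produce no etiology
  expect_false("S2" %in% et$sample_id)
  dropped <- attr(et, "dropped")
  expect_true("NOWHERE" %in% dropped$gene)
  flagged <- attr(et, "flagged")
  expect_true(any(flagged$gene == "GAR" &
                    grepl("suspected_compound_het", flagged$flags)))
  # every contributing variant re-passes the technical filter and is P/LP
  contributing <- v[v$sample_id == "S1" & v$gene %in% et$gene, ]
  expect_true(all(technical_filter_status(contributing, cfg)$pass))
  expect_true(all(contributing$tier %in% c("Pathogenic", "LikelyPathogenic")))
})

test_that("consequence tallies render half-up percentages that sum to one", {
  v <- data.frame(consequence = rep(
    c("frameshift", "nonsense", "span", "splice3", "splice5", "stopgain"),
    times = c(606, 80, 7, 16, 10, 5)), stringsAsFactors = FALSE)
  tab <- tally_consequences(v)
  expect_equal(sum(tab$count), 724L)
  expect_equal(tab$percent[tab$consequence == "frameshift"], 83.70)
  expect_equal(tab$percent[tab$consequence == "nonsense"], 11.05)
  expect_equal(tab$percent[tab$consequence == "stopgain"], 0.69)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)

  one <- tally_consequences(data.frame(consequence = "missense"))
  expect_equal(one$percent, 100.00)
  expect_equal(nrow(tally_consequences(data.frame(consequence = character()))), 0L)
})
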