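test_that("the generator is byte-deterministic in (spec, seed)", {
  spec <- cohort_spec(seed = 5)
  g1 <- generate_cohort(spec, tempfile("det1"))
  g2 <- generate_cohort(spec, tempfile("det2"))
  for (nm in setdiff(names(g1$paths), "manifest")) {
    expect_equal(unname(tools::md5sum(g1$paths[[nm]])),
                 unname(tools::md5sum(g2$paths[[nm]])),
                 info = nm)
  }
  expect_equal(g1$truth, g2$truth)
  # a different seed shuffles the cohort
  g3 <- generate_cohort(cohort_spec(seed = 6), tempfile("det3"))
  expect_false(identical(unname(tools::md5sum(g1$paths$variants)),
                         unname(tools::md5sum(g3$paths$variants))))
})

test_that("generated inputs re-parse through the readers without warnings", {
  g <- generate_cohort(cohort_spec(seed = 2), tempfile("parse"))
  expect_no_warning({
    v <- read_small_variants(g$paths$variants)
    cnv <- read_cnv_table(g$paths$cnvs)
    meta <- read_sample_meta(g$paths$meta)
    panel <- read_gene_panel(g$paths$panel)
    edges <- read_edges(g$paths$edges)
  })
  expect_equal(nrow(meta), 121L)
  expect_true(all(nzchar(v$evidence_codes)))
  # the three planted chimeras carry their 12-14% fractions
  mf <- sort(cnv$mosaic_fraction[!is.na(cnv$mosaic_fraction)])
  expect_equal(mf, c(0.12, 0.13, 0.14))
})

test_that("planted truth is recovered exactly and decoys all fail one gate", {
  g <- generate_cohort(cohort_spec(seed = 4), tempfile("rec"))
  dir <- dirname(g$paths$variants)
  res <- run_pipeline(dir)
  rec <- truth_recovery_report(g$truth, res$calls)
  expect_true(rec$match)
  expect_equal(sum(res$calls$diagnosed), 42L)
  expect_equal(unname(res$report$category_counts),
               c(16L, 8L, 12L, 13L, 8L))
  expect_equal(unname(res$report$multi_category), c(11L, 2L))
  expect_equal(unname(res$report$channel_counts), c(20L, 12L, 10L))
  # suspected compound hets are flagged and excluded, not silently dropped
  flagged <- attr(res$gene_etiologies, "flagged")
  expect_true(all(g$truth$flagged_compound_het$sample_id %in%
                    flagged$sample_id))
  # network module recovers the planted retained set
  expect_equal(res$expansion$gene[res$expansion$retained],
               res$expansion$gene[res$expansion$panel_neighbors >= 2])
  expect_setequal(res$expansion$gene[res$expansion$retained],
                  g$truth$network_retained)
})

test_that("loosening one gate flips exactly that decoy class", {
  g <- generate_cohort(cohort_spec(seed = 8), tempfile("abl"))
  dir <- dirname(g$paths$variants)
  truth_cat <- g$truth$etiology

  flips_of <- function(cfg) {
    calls <- run_pipeline(dir, cfg)$calls
    calls <- calls[match(truth_cat$sample_id, calls$sample_id), ]
    out <- list()
    for (cat in etiology_categories()) {
      fp <- calls$sample_id[calls[[cat]] & !truth_cat[[cat]]]
      fn <- calls$sample_id[!calls[[cat]] & truth_cat[[cat]]]
      out[[cat]] <- list(fp = fp, fn = fn)
    }
    out
  }

  carriers <- function(cl) {
    unique(g$truth$decoys$sample_id[g$truth$decoys$class == cl])
  }

  # allele-fraction gate at 20%: only the 23%-AF decoys come through, all
  # in the definitive-gene category
  f <- flips_of(triage_config(min_het_allele_fraction = 0.20))
  expect_true(length(f$PLP_definitive_gene$fp) > 0)
  expect_true(all(f$PLP_definitive_gene$fp %in% carriers("low_af")))
  for (cat in setdiff(etiology_categories(), "PLP_definitive_gene")) {
    expect_equal(length(f[[cat]]$fp), 0L, info = cat)
  }
  expect_true(all(lengths(lapply(f, `[[`, "fn")) == 0))

  # depth gate at 0: only the 4-read decoys come through
  f <- flips_of(triage_config(min_alt_depth = 0L))
  expect_true(length(f$PLP_definitive_gene$fp) > 0)
  expect_true(all(f$PLP_definitive_gene$fp %in% carriers("low_depth")))
  for (cat in setdiff(etiology_categories(), "PLP_definitive_gene")) {
    expect_equal(length(f[[cat]]$fp), 0L, info = cat)
  }

  # CNV size gate at 50 kb: only the 90 kb pathogenic decoys come through
  f <- flips_of(triage_config(min_cnv_size = 50000))
  expect_true(length(f$pathogenic_cnv$fp) > 0)
  expect_true(all(f$pathogenic_cnv$fp %in% carriers("cnv_small")))
  for (cat in setdiff(etiology_categories(), "pathogenic_cnv")) {
    expect_equal(length(f[[cat]]$fp), 0L, info = cat)
  }
})

test_that("zero planted positives yield zero diagnoses", {
  spec <- cohort_spec(
    n_samples = 20L,
    sex_split = c(male = 10L, female = 10L),
    ultrasound_split = c(fetus = 10L, neonate = 10L),
    phenotype_split = c(isolated = 10L, non_isolated = 10L, unknown = 0L),
    category_counts = c(PLP_definitive_gene = 0L, PLP_candidate_gene = 0L,
                        aneuploidy = 0L, pathogenic_cnv = 0L,
                        vus_cnv_panel_gene = 0L),
    n_two_category = 0L, n_three_category = 0L,
    channel_split = c(chromosomal_only = 0L, gene_only = 0L, both = 0L),
    n_cnv_vus_decoys = 10L, n_cnv_benign_decoys = 5L, n_cnv_small_decoys = 5L,
    seed = 1L
  )
  g <- generate_cohort(spec, tempfile("zero"))
  res <- run_pipeline(dirname(g$paths$variants))
  expect_equal(sum(res$calls$diagnosed), 0L)
  expect_true(truth_recovery_report(g$truth, res$calls)$match)
})

test_that("unsatisfiable specifications fail loudly, naming the constraint", {
  err <- expect_error(cohort_spec(sex_split = c(male = 60L, female = 52L)),
                      class = "chdtriage_validation_error")
  expect_match(conditionMessage(err), "sex_split")
  # category incidences inconsistent with diagnosed + overlap counts
  expect_error(cohort_spec(n_two_category = 0L),
               class = "chdtriage_validation_error")
  # channel split incompatible with the gene/chromosome incidences
  expect_error(
    cohort_spec(channel_split = c(chromosomal_only = 30L, gene_only = 2L,
                                  both = 10L)),
    class = "chdtriage_validation_error")
})

test_that("the truth-recovery report spots a planted mismatch", {
  g <- generate_cohort(cohort_spec(seed = 10), tempfile("mm"))
  res <- run_pipeline(dirname(g$paths$variants))
  calls <- res$calls
  i <- which(!calls$aneuploidy)[1]
  calls$aneuploidy[i] <- TRUE
  rec <- truth_recovery_report(g$truth, calls)
  expect_false(rec$match)
  expect_equal(rec$n_mismatch, 1L)
  expect_equal(rec$category_summary$fp[
    rec$category_summary$category == "aneuploidy"], 1L)

  calls$sample_id[1] <- "GHOST"
  expect_error(truth_recovery_report(g$truth, calls),
               class = "chdtriage_validation_error")
})
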