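test_that("the adjusted-centre interval brackets its centre and clamps", {
  z <- qnorm(0.975)
  for (x in c(0, 1, 7, 42, 120, 121)) {
    ci <- agresti_coull_ci(x, 121)
    centre <- (x + z^2 / 2) / (121 + z^2)
    expect_lte(ci$p_lower, centre)
    expect_gte(ci$p_upper, centre)
    expect_gte(ci$lower, 0)
    expect_lte(ci$upper, 100)
  }
  # zero successes clamp the lower bound at exactly zero
  expect_equal(agresti_coull_ci(0, 10)$lower, 0.00)
  expect_error(agresti_coull_ci(1, 0), class = "chdtriage_validation_error")
  expect_error(agresti_coull_ci(5, 4), class = "chdtriage_validation_error")
})

test_that("interval width shrinks with n at a fixed success ratio", {
  widths <- vapply(c(20, 50, 121, 500, 2000), function(n) {
    ci <- agresti_coull_ci(round(0.3 * n), n)
    ci$p_upper - ci$p_lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("alternative interval methods are available and differ", {
  ac <- agresti_coull_ci(42, 121)
  wi <- agresti_coull_ci(42, 121, method = "wilson")
  cp <- agresti_coull_ci(42, 121, method = "clopper-pearson")
  expect_false(isTRUE(all.equal(c(ac$p_lower, ac$p_upper),
                                c(wi$p_lower, wi$p_upper))))
  # Clopper-Pearson is conservative: at least as wide as Agresti-Coull here
  expect_gte(cp$p_upper - cp$p_lower, ac$p_upper - ac$p_lower)
})

test_that("odds ratio and exact p match enumeration oracles on random tables", {
  set.seed(21)
  for (i in 1:60) {
    repeat {
      cnt <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
      m <- matrix(cnt, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    a <- cnt[1]; b <- cnt[2]; c <- cnt[3]; d <- cnt[4]
    res <- fisher_or(a, b, c, d)
    expect_equal(res$p_two_sided, fisher_p_oracle(a, b, c, d),
                 tolerance = 1e-10)
    o <- fisher_cmle_oracle(a, b, c, d)
    if (is.finite(o) && o > 0) {
      # fisher.test solves the same score equation with optimise();
      # agreement is bounded by its optimiser tolerance, not by ours
      expect_equal(res$or_cmle, o, tolerance = 1e-3)
    }
  }
})

test_that("odds-ratio edge cases behave as documented", {
  # independence: cross-product 1 implies conditional MLE 1
  res <- fisher_or(6, 3, 4, 2)
  expect_equal(res$or_cmle, 1, tolerance = 1e-6)
  # zero cells flag and collapse to 0 / Inf
  expect_true(fisher_or(0, 5, 3, 4)$zero_cell)
  expect_equal(fisher_or(0, 5, 3, 4)$or_cmle, 0)
  expect_equal(fisher_or(5, 0, 3, 4)$or_cmle, Inf)
  # degenerate margins are hard errors
  expect_error(fisher_or(0, 0, 3, 4), class = "chdtriage_validation_error")
  expect_error(fisher_or(0, 5, 0, 4), class = "chdtriage_validation_error")
  # cross-product estimator selectable
  expect_equal(fisher_or(24, 28, 18, 51, estimator = "cross-product")$or,
               24 * 51 / (28 * 18))
})

toy_calls <- function() {
  ge <- data.frame(
    sample_id = c("S1", "S2"), gene = c("G1", "CAND1"),
    evidence_class = c("definitive_panel", "candidate_gene"),
    inheritance_mode_used = "AD", n_variants = 1L, flags = "",
    stringsAsFactors = FALSE
  )
  ce <- data.frame(
    sample_id = c("S1", "S3"),
    evidence_class = c("aneuploidy", "vus_cnv_panel_gene"),
    label = c("T18", "del(chr5:1-200000)"),
    chrom = c("chr18", "chr5"), start = c(1, 1), end = c(9.6e6, 2e5),
    copy_state = "deletion", tier = c("P", "VUS"),
    mosaic_fraction = NA_real_, panel_genes_hit = c("", "PAN1"),
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    sex = c("female", "male", "female", "male"),
    sample_type = "tissue", ultrasound_period = c("fetus", "fetus", "neonate",
                                                  "neonate"),
    phenotype_group = c("isolated", "non_isolated", "isolated",
                        "non_isolated"),
    stringsAsFactors = FALSE
  )
  list(ge = ge, ce = ce, meta = meta)
}

test_that("category assignment produces one call per sample with channels", {
  x <- toy_calls()
  calls <- assign_categories(x$ge, x$ce, x$meta)
  expect_equal(nrow(calls), 4L)
  s1 <- calls[calls$sample_id == "S1", ]
  expect_true(s1$PLP_definitive_gene && s1$aneuploidy)
  expect_equal(s1$channel, "both")
  expect_equal(calls$channel[calls$sample_id == "S2"], "gene_only")
  # VUS CNV over a panel gene alone is a (chromosomal) diagnosis
  s3 <- calls[calls$sample_id == "S3", ]
  expect_true(s3$diagnosed)
  expect_equal(s3$channel, "chromosomal_only")
  s4 <- calls[calls$sample_id == "S4", ]
  expect_false(s4$diagnosed)
  expect_equal(s4$channel, "none")
  # diagnosed iff at least one category; channel partition is exact
  expect_equal(calls$diagnosed, calls$n_categories > 0)
  expect_equal(sum(calls$channel != "none"), sum(calls$diagnosed))

  bad_ge <- x$ge
  bad_ge$sample_id[1] <- "GHOST"
  expect_error(assign_categories(bad_ge, x$ce, x$meta),
               class = "chdtriage_validation_error")
})

test_that("yield report counts are consistent and carry CIs", {
  x <- toy_calls()
  calls <- assign_categories(x$ge, x$ce, x$meta)
  rep <- yield_report(calls, x$meta, triage_config(),
                      gene_etiologies = x$ge, cnv_etiologies = x$ce)
  expect_equal(rep$n_diagnosed, 3L)
  expect_equal(sum(rep$channel_counts), rep$n_diagnosed)
  expect_equal(rep$overall$percent, percent2(3, 4))
  expect_equal(rep$overall$x, 3L)
  # a cohort of one diagnosed sample yields 100%
  one <- calls[calls$sample_id == "S1", , drop = FALSE]
  rep1 <- yield_report(one, x$meta[1, , drop = FALSE], triage_config())
  expect_equal(rep1$overall$percent, 100.00)
  expect_equal(rep1$overall$upper, 100.00)
})

test_that("landscape matrix orders diagnosed-first and round-trips", {
  x <- toy_calls()
  calls <- assign_categories(x$ge, x$ce, x$meta)
  mat <- landscape_matrix(calls, x$meta)
  expect_equal(dim(mat), c(4L, 10L))   # id + 5 indicators + 4 metadata
  expect_equal(mat$sample_id[1], "S1") # most categories first
  expect_equal(mat$sample_id[4], "S4") # undiagnosed last
  # column sums equal per-category sample counts
  for (cat in etiology_categories()) {
    expect_equal(sum(mat[[cat]]), sum(calls[[cat]]))
  }
  path <- tempfile(fileext = ".tsv")
  write_landscape_matrix(mat, path)
  back <- read_landscape_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(mat))
})

test_that("half-up rounding is used at the percentage boundary", {
  expect_equal(round_half_up(0.125, 2), 0.13)   # base round() would give 0.12
  expect_equal(round_half_up(68.135, 2), 68.14)
  expect_equal(percent2(139, 204), 68.14)
  expect_equal(percent2(606, 724), 83.70)
})
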