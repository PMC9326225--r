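#' Synthetic-cohort specification
#'
#' Describes the cohort the generator builds. The defaults are the study
#' conditions of the motivating cohort: 121 sporadic CHD samples (69 male /
#' 52 female; 79 fetus / 42 neonate; 51 isolated / 68 non-isolated / 2
#' unknown), five planted etiology categories explaining 16, 8, 12, 13 and
#' 8 samples, 11 samples with two categories and 2 with three (42 diagnosed
#' in total, split 20 chromosomal-only / 12 gene-only / 10 both), and three
#' mosaic events with fractions 0.12-0.14.
#'
#' @param n_samples cohort size
#' @param sex_split named counts `c(male=, female=)`
#' @param ultrasound_split named counts `c(fetus=, neonate=)`
#' @param phenotype_split named counts `c(isolated=, non_isolated=, unknown=)`
#' @param category_counts named counts over [etiology_categories()]
#' @param n_two_category samples carrying exactly two categories
#' @param n_three_category samples carrying exactly three categories
#' @param channel_split named counts `c(chromosomal_only=, gene_only=, both=)`
#' @param decoy_rates per-sample counts of technically failing variant
#'   decoys `c(non_pass=, low_depth=, low_af=, benign=)`
#' @param n_cnv_vus_decoys VUS CNVs overlapping no panel gene
#' @param n_cnv_benign_decoys benign/likely-benign CNVs
#' @param n_cnv_small_decoys sub-100kb pathogenic-tier CNVs (size-gate decoys)
#' @param n_panel_genes panel size of the stand-in curated gene panel
#' @param seed integer seed; the generator is byte-deterministic in
#'   `(spec, seed)`
#' @return a validated `cohort_spec` list
#' @export
cohort_spec <- function(n_samples = 121L,
                        sex_split = c(male = 69L, female = 52L),
                        ultrasound_split = c(fetus = 79L, neonate = 42L),
                        phenotype_split = c(isolated = 51L, non_isolated = 68L,
                                            unknown = 2L),
                        category_counts = c(PLP_definitive_gene = 16L,
                                            PLP_candidate_gene = 8L,
                                            aneuploidy = 12L,
                                            pathogenic_cnv = 13L,
                                            vus_cnv_panel_gene = 8L),
                        n_two_category = 11L,
                        n_three_category = 2L,
                        channel_split = c(chromosomal_only = 20L,
                                          gene_only = 12L, both = 10L),
                        decoy_rates = c(non_pass = 1L, low_depth = 1L,
                                        low_af = 1L, benign = 1L),
                        n_cnv_vus_decoys = 60L,
                        n_cnv_benign_decoys = 40L,
                        n_cnv_small_decoys = 20L,
                        n_panel_genes = 60L,
                        seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples),
    sex_split = sex_split, ultrasound_split = ultrasound_split,
    phenotype_split = phenotype_split,
    category_counts = category_counts,
    n_two_category = as.integer(n_two_category),
    n_three_category = as.integer(n_three_category),
    channel_split = channel_split,
    decoy_rates = decoy_rates,
    n_cnv_vus_decoys = as.integer(n_cnv_vus_decoys),
    n_cnv_benign_decoys = as.integer(n_cnv_benign_decoys),
    n_cnv_small_decoys = as.integer(n_cnv_small_decoys),
    n_panel_genes = as.integer(n_panel_genes),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  n <- spec$n_samples
  for (nm in c("sex_split", "ultrasound_split", "phenotype_split")) {
    if (sum(spec[[nm]]) != n) {
      abort("cohort_spec: ", nm, " must sum to n_samples (",
            sum(spec[[nm]]), " != ", n, ")",
            class = "chdtriage_validation_error")
    }
  }
  miss <- setdiff(.CATEGORIES, names(spec$category_counts))
  if (length(miss)) {
    abort("cohort_spec: category_counts missing ", paste(miss, collapse = ", "),
          class = "chdtriage_validation_error")
  }
  layout <- cohort_pattern_layout(spec)  # errors if unsatisfiable
  if (layout$n_diagnosed > n) {
    abort("cohort_spec: diagnosed samples (", layout$n_diagnosed,
          ") exceed n_samples", class = "chdtriage_validation_error")
  }
  spec
}

# Derive the per-sample category patterns implied by a cohort_spec.
# Inclusion-exclusion: category incidences = diagnosed + n2 + 2*n3; the
# channel split fixes how many samples see both sequencing channels.
cohort_pattern_layout <- function(spec) {
  cc <- spec$category_counts
  gene_inc <- sum(cc[c("PLP_definitive_gene", "PLP_candidate_gene")])
  chrom_inc <- sum(cc[c("aneuploidy", "pathogenic_cnv", "vus_cnv_panel_gene")])
  n2 <- spec$n_two_category
  n3 <- spec$n_three_category
  ch <- spec$channel_split
  ng <- ch[["gene_only"]]; nc <- ch[["chromosomal_only"]]; nb <- ch[["both"]]
  n_diag <- ng + nc + nb

  if (sum(cc) != n_diag + n2 + 2L * n3) {
    abort("cohort_spec: category_counts (", sum(cc),
          ") inconsistent with diagnosed samples + overlaps (",
          n_diag + n2 + 2L * n3, ")", class = "chdtriage_validation_error")
  }
  e_g <- gene_inc - ng - nb    # gene incidences beyond one-per-gene-channel-sample
  e_h <- chrom_inc - nc - nb
  if (e_g < 0 || e_h < 0) {
    abort("cohort_spec: channel_split incompatible with category_counts ",
          "(negative extra incidences)", class = "chdtriage_validation_error")
  }
  # three-category samples sit in the 'both' channel with an extra slot on
  # one channel; same-channel pairs absorb the rest
  t_h <- min(n3, e_h)          # {gene, chrom, chrom}
  t_g <- n3 - t_h              # {gene, gene, chrom}
  pairs_h <- e_h - t_h
  pairs_g <- e_g - t_g
  if (t_g < 0 || pairs_g < 0 || pairs_h < 0 ||
      pairs_g + pairs_h != n2 + n3 - nb) {
    abort("cohort_spec: overlap counts unsatisfiable under the channel split",
          class = "chdtriage_validation_error")
  }
  if (pairs_g > ng || pairs_h > nc || nb > n2 + n3) {
    abort("cohort_spec: more same-channel pairs than channel samples",
          class = "chdtriage_validation_error")
  }
  list(n_diagnosed = n_diag, ng = ng, nc = nc, nb = nb,
       t_g = t_g, t_h = t_h, pairs_g = pairs_g, pairs_h = pairs_h)
}

# Greedy assignment of categories to sample slots; max-count-first keeps a
# multiset of remaining category incidences feasible.
draw_categories <- function(remaining, k) {
  avail <- names(remaining)[remaining > 0L]
  if (length(avail) < k) {
    abort("cohort_spec: cannot place ", k, " distinct categories; remaining: ",
          paste(sprintf("%s=%d", names(remaining), remaining), collapse = ", "),
          class = "chdtriage_validation_error")
  }
  take <- avail[order(-remaining[avail], avail)][seq_len(k)]
  take
}

build_patterns <- function(spec) {
  lay <- cohort_pattern_layout(spec)
  cc <- spec$category_counts
  g_rem <- cc[c("PLP_definitive_gene", "PLP_candidate_gene")]
  h_rem <- cc[c("aneuploidy", "pathogenic_cnv", "vus_cnv_panel_gene")]
  pats <- list()
  # both-channel, three categories
  for (i in seq_len(lay$t_h)) {
    p <- c(draw_categories(g_rem, 1L), draw_categories(h_rem, 2L))
    g_rem[p[1L]] <- g_rem[p[1L]] - 1L
    h_rem[p[2:3]] <- h_rem[p[2:3]] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  for (i in seq_len(lay$t_g)) {
    p <- c(draw_categories(g_rem, 2L), draw_categories(h_rem, 1L))
    g_rem[p[1:2]] <- g_rem[p[1:2]] - 1L
    h_rem[p[3L]] <- h_rem[p[3L]] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  # both-channel, two categories
  for (i in seq_len(lay$nb - spec$n_three_category)) {
    p <- c(draw_categories(g_rem, 1L), draw_categories(h_rem, 1L))
    g_rem[p[1L]] <- g_rem[p[1L]] - 1L
    h_rem[p[2L]] <- h_rem[p[2L]] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  # same-channel pairs
  for (i in seq_len(lay$pairs_g)) {
    p <- draw_categories(g_rem, 2L)
    g_rem[p] <- g_rem[p] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  for (i in seq_len(lay$pairs_h)) {
    p <- draw_categories(h_rem, 2L)
    h_rem[p] <- h_rem[p] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  # singles
  for (i in seq_len(lay$ng - lay$pairs_g)) {
    p <- draw_categories(g_rem, 1L)
    g_rem[p] <- g_rem[p] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  for (i in seq_len(lay$nc - lay$pairs_h)) {
    p <- draw_categories(h_rem, 1L)
    h_rem[p] <- h_rem[p] - 1L
    pats[[length(pats) + 1L]] <- p
  }
  if (any(g_rem != 0L) || any(h_rem != 0L)) {
    abort("cohort_spec: category incidences left unplaced",
          class = "chdtriage_validation_error")
  }
  pats
}

# ---- event and gene pools -------------------------------------------------

# recurrent aneuploidies first (T18/T21/XO x3), then unique ones incl. the
# 12%-mosaic trisomy 16
aneuploidy_pool <- function(n) {
  if (n == 0L) {
    return(data.frame(chrom = character(), copy_state = character(),
                      mosaic_fraction = numeric(), start = numeric(),
                      end = numeric(), tier = character(),
                      stringsAsFactors = FALSE))
  }
  base <- data.frame(
    chrom = c(rep(c("chr18", "chr21", "chrX"), each = 3),
              "chr9", "chr13", "chr16"),
    copy_state = c(rep(c("duplication", "duplication", "deletion"), each = 3),
                   "duplication", "duplication", "duplication"),
    mosaic_fraction = c(rep(NA_real_, 11), 0.12),
    stringsAsFactors = FALSE
  )
  extra_chroms <- setdiff(paste0("chr", c(1:8, 10:12, 14, 19, 20)),
                          base$chrom)
  while (nrow(base) < n) {
    k <- nrow(base) - 12L + 1L
    base <- rbind(base, data.frame(chrom = extra_chroms[k],
                                   copy_state = "duplication",
                                   mosaic_fraction = NA_real_,
                                   stringsAsFactors = FALSE))
  }
  base <- base[seq_len(n), , drop = FALSE]
  base$start <- 200001
  base$end <- 9800000      # spans 96% of a 10 Mb mini chromosome
  base$tier <- "P"
  base
}

# recurrent pathogenic CNVs first (6x the 22q11-analogue deletion, 2x the
# 15q11-analogue), then unique events incl. the 13%/14% mosaics
pcnv_pool <- function(n) {
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      copy_state = character(), mosaic_fraction = numeric(),
                      tier = character(), stringsAsFactors = FALSE))
  }
  base <- data.frame(
    chrom = c(rep("chr22", 6), rep("chr15", 2), "chr7", "chr18", "chr11",
              "chr12", "chr17"),
    start = c(rep(1000000, 6), rep(6000000, 2), 8000000, 8500000, 4000000,
              6000000, 6200000),
    end = c(rep(3600000, 6), rep(6500000, 2), 8900000, 9400000, 4300000,
            6200000, 6350000),
    copy_state = c(rep("deletion", 6), rep("deletion", 2), "deletion",
                   "deletion", "duplication", "deletion", "duplication"),
    mosaic_fraction = c(rep(NA_real_, 8), 0.13, 0.14, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  k <- 0L
  while (nrow(base) < n) {
    k <- k + 1L
    base <- rbind(base, data.frame(
      chrom = "chr19", start = 1000000 + 400000 * k,
      end = 1150000 + 400000 * k, copy_state = "duplication",
      mosaic_fraction = NA_real_, stringsAsFactors = FALSE))
  }
  base <- base[seq_len(n), , drop = FALSE]
  base$tier <- "P"
  if (n >= 11L) base$tier[11L] <- "LP"   # one likely-pathogenic event
  base
}

# definitive-gene slot pool: recurrence profile of the real panel hits
definitive_gene_pool <- function(n, panel_fillers) {
  base <- c(rep("COL3A1", 4), rep("MED13L", 3), rep("KDR", 3), rep("ANK3", 3),
            rep("SMAD6", 2), rep("NIPBL", 2), rep("ATP2C1", 2), rep("APC", 2))
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, panel_fillers[seq_len(n - length(base))])
}

candidate_gene_table <- function() {
  data.frame(
    gene = c("SYNE2", "MYLK", "PKP2", "TRPM4", "MIB1", "TCAP", "SON", "DSP"),
    codes = c("PVS1,PM2,PP3", "PVS1,PM2,PP3", "PVS1,PM2,PP3,PP5", "PVS1,PM2",
              "PVS1,PM2,PP3", "PVS1,PM2,PP3", "PVS1,PM2,PP3", "PVS1,PM2,PP3"),
    stringsAsFactors = FALSE
  )
}

# evidence-code sets that the combining rules map to P or LP
plp_code_sets <- function() {
  c("PVS1,PM2,PP3", "PVS1,PM2", "PS1,PS3", "PS2,PM1,PM2", "PM1,PM2,PM4",
    "PVS1,PS1", "PS4,PP1,PP2", "PVS1,PM2,PP3,PP5")
}

.CSQ_PTV <- c("frameshift", "nonsense", "splice3", "splice5", "stopgain")

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Writes every input the pipeline consumes — a multi-sample annotated VCF,
#' a CNV call table, sample metadata, a stand-in curated gene panel with
#' OMIM-style inheritance modes, the adjudicated candidate-gene list, a
#' rare-disease candidate list with a weighted interaction network, and
#' chromosome lengths — into `dir`, together with a `manifest.json`
#' (spec, seed, file MD5 hashes) and returns the planted ground truth.
#'
#' Planted positives are constructed to pass every triage gate; each decoy
#' fails exactly one named gate (non-PASS filter, alternate depth below
#' 5, heterozygous allele fraction below 25%, benign evidence, sub-100kb
#' size, or VUS without panel overlap). Coordinates live on a miniature
#' genome (24 chromosomes of 10 Mb) so whole-chromosome logic is testable
#' at toy scale; aneuploidy chromosomes carry no panel genes.
#'
#' @param spec a [cohort_spec()]
#' @param dir output directory (created if needed)
#' @return list with `paths` (named file paths), `truth` (see
#'   [truth_recovery_report()]), and `spec`
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = tempfile("cohort")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_samples
  ids <- sprintf("CHD%03d", seq_len(n))

  ## ---- gene panel ---------------------------------------------------------
  real_def <- c("COL3A1", "MED13L", "KDR", "ANK3", "SMAD6", "NIPBL",
                "ATP2C1", "APC")
  n_fill <- max(0L, spec$n_panel_genes - length(real_def) - 2L)
  fillers <- sprintf("PNL%03d", seq_len(n_fill))
  ar_genes <- c("PNLAR01", "PNLAR02")
  panel_genes <- c(real_def, fillers, ar_genes)
  panel_chroms <- paste0("chr", c(1:8, 10:12, 15, 17, 22))
  chrom_of <- panel_chroms[(seq_along(panel_genes) - 1L) %% length(panel_chroms) + 1L]
  slot_of <- (seq_along(panel_genes) - 1L) %/% length(panel_chroms)
  gstart <- 1000000 + 250000 * slot_of
  panel <- data.frame(
    gene_symbol = panel_genes,
    sources = rep(c("review", "GWAS", "case-report"),
                  length.out = length(panel_genes)),
    inheritance_modes = c(rep("AD", length(real_def)),
                          rep(c("AD", "AD", "AD;AR"), length.out = n_fill),
                          rep("AR", 2L)),
    chrom = chrom_of, start = gstart, end = gstart + 60000,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  ad_fillers <- fillers[panel$inheritance_modes[match(fillers, panel$gene_symbol)] != "AR"]

  ## ---- per-sample category patterns --------------------------------------
  pats <- build_patterns(spec)
  n_diag <- length(pats)
  ids_shuffled <- sample(ids)
  diag_ids <- ids_shuffled[seq_len(n_diag)]
  pats <- pats[sample(seq_along(pats))]
  names(pats) <- diag_ids

  samples_of <- function(cat) {
    diag_ids[vapply(pats, function(p) cat %in% p, TRUE)]
  }

  ## ---- chromosomal events -------------------------------------------------
  aneu_samples <- sample(samples_of("aneuploidy"))
  aneu <- aneuploidy_pool(length(aneu_samples))
  # monosomy-X events must land in female-designated samples; fix sex later
  xo_rows <- which(aneu$chrom == "chrX" & aneu$copy_state == "deletion")
  aneu$sample_id <- aneu_samples
  forced_female <- aneu$sample_id[xo_rows]

  pcnv_samples <- sample(samples_of("pathogenic_cnv"))
  pcnv <- pcnv_pool(length(pcnv_samples))
  pcnv$sample_id <- pcnv_samples

  def_samples <- sample(samples_of("PLP_definitive_gene"))
  def_genes <- definitive_gene_pool(length(def_samples), ad_fillers)

  vus_samples <- sample(samples_of("vus_cnv_panel_gene"))
  vus_genes <- sample(setdiff(ad_fillers, def_genes), length(vus_samples))
  vus_idx <- match(vus_genes, panel$gene_symbol)
  vus <- data.frame(
    sample_id = vus_samples,
    chrom = panel$chrom[vus_idx],
    start = panel$start[vus_idx] - 80000,
    end = panel$start[vus_idx] + 120000,
    copy_state = rep(c("deletion", "duplication"),
                     length.out = length(vus_samples)),
    mosaic_fraction = rep(NA_real_, length(vus_samples)),
    tier = rep("VUS", length(vus_samples)),
    stringsAsFactors = FALSE
  )

  ## ---- CNV decoys ---------------------------------------------------------
  decoy_chroms <- c("chr14", "chr19", "chr20")
  mk_cnv_decoys <- function(k, tier, size, offset) {
    if (k == 0L) return(NULL)
    data.frame(
      sample_id = sample(ids, k, replace = k > n),
      chrom = decoy_chroms[(seq_len(k) - 1L) %% 3L + 1L],
      start = offset + 300000 * ((seq_len(k) - 1L) %/% 3L),
      end = offset + 300000 * ((seq_len(k) - 1L) %/% 3L) + size - 1,
      copy_state = rep(c("deletion", "duplication"), length.out = k),
      mosaic_fraction = NA_real_,
      tier = rep(tier, length.out = k),
      stringsAsFactors = FALSE
    )
  }
  cnv_vus_decoy <- mk_cnv_decoys(spec$n_cnv_vus_decoys, "VUS", 150000, 500001)
  cnv_benign_decoy <- mk_cnv_decoys(spec$n_cnv_benign_decoys, c("B", "LB"),
                                    120000, 4500001)
  cnv_small_decoy <- mk_cnv_decoys(spec$n_cnv_small_decoys, "P", 90000, 8500001)

  cnv_cols <- c("sample_id", "chrom", "start", "end", "copy_state",
                "mosaic_fraction", "tier")
  aneu_out <- aneu[, cnv_cols]
  pcnv_out <- pcnv[, cnv_cols]
  cnvs <- rbind(aneu_out, pcnv_out, vus[, cnv_cols],
                cnv_vus_decoy[, cnv_cols], cnv_benign_decoy[, cnv_cols],
                cnv_small_decoy[, cnv_cols])
  cnvs <- cnvs[order(cnvs$sample_id, cnvs$chrom, cnvs$start), , drop = FALSE]

  ## ---- sample metadata ----------------------------------------------------
  sex <- stats::setNames(rep("male", n), ids)
  sex[forced_female] <- "female"
  n_more_f <- spec$sex_split[["female"]] - length(forced_female)
  if (n_more_f < 0) abort("cohort_spec: fewer females than planted monosomy-X samples")
  sex[sample(setdiff(ids, forced_female), n_more_f)] <- "female"
  us <- stats::setNames(rep("neonate", n), ids)
  us[sample(ids, spec$ultrasound_split[["fetus"]])] <- "fetus"
  pheno <- stats::setNames(rep("non_isolated", n), ids)
  iso_ids <- sample(ids, spec$phenotype_split[["isolated"]] +
                      spec$phenotype_split[["unknown"]])
  pheno[iso_ids] <- "isolated"
  pheno[iso_ids[seq_len(spec$phenotype_split[["unknown"]])]] <- "unknown"
  stype_pool <- rep_len(rep(c("tissue", "cord_blood", "amniotic_fluid"),
                            times = pmax(1, round(n * c(0.56, 0.35, 0.09)))), n)
  stype <- stats::setNames(sample(stype_pool), ids)
  meta <- data.frame(
    sample_id = ids, sex = unname(sex[ids]),
    sample_type = unname(stype[ids]),
    ultrasound_period = unname(us[ids]),
    phenotype_group = unname(pheno[ids]),
    stringsAsFactors = FALSE
  )
  class(meta) <- c("sample_meta", "data.frame")

  ## ---- small variants -----------------------------------------------------
  cand_tab <- candidate_gene_table()
  cand_samples <- sample(samples_of("PLP_candidate_gene"))
  cand_rows <- (seq_along(cand_samples) - 1L) %% nrow(cand_tab) + 1L

  plp_sets <- plp_code_sets()
  gene_variant_site <- function(gene, k = 1L) {
    i <- match(gene, panel$gene_symbol)
    if (!is.na(i)) {
      list(chrom = panel$chrom[i], pos = panel$start[i] + 17L + 101L * (k - 1L))
    } else {
      # candidate genes live outside the panel; park them on chr3/chr5
      j <- match(gene, cand_tab$gene)
      list(chrom = c("chr3", "chr5")[j %% 2L + 1L],
           pos = 5000000L + 40000L * j + 101L * (k - 1L))
    }
  }
  var_rows <- list()
  add_variant <- function(sample_id, gene, codes, filter = "PASS",
                          ref_depth = 30L, alt_depth = 28L, genotype = "het",
                          consequence = NULL, site_k = 1L) {
    site <- gene_variant_site(gene, site_k)
    if (is.null(consequence)) {
      consequence <- sample(.CSQ_PTV, 1L,
                            prob = c(0.837, 0.11, 0.022, 0.014, 0.017))
    }
    var_rows[[length(var_rows) + 1L]] <<- data.frame(
      sample_id = sample_id, chrom = site$chrom, pos = site$pos, id = ".",
      ref = "A", alt = "AT", gene = gene, consequence = consequence,
      filter_status = filter, genotype = genotype,
      ref_depth = ref_depth, alt_depth = alt_depth,
      evidence_codes = codes, stringsAsFactors = FALSE
    )
  }

  # planted positives: recurrent definitive-gene variants share one site per
  # gene (so gene- and variant-level recurrence emerges), candidates mirror
  # the adjudicated list
  gene_codes <- stats::setNames(
    sample(plp_sets, length(unique(def_genes)), replace = TRUE),
    unique(def_genes))
  gene_codes["COL3A1"] <- "PVS1,PM2,PP3"
  for (i in seq_along(def_samples)) {
    g <- def_genes[i]
    add_variant(def_samples[i], g, gene_codes[[g]],
                consequence = "frameshift")
  }
  for (i in seq_along(cand_samples)) {
    r <- cand_rows[i]
    add_variant(cand_samples[i], cand_tab$gene[r], cand_tab$codes[r],
                consequence = if (cand_tab$gene[r] %in% c("SYNE2", "MYLK", "PKP2"))
                  "splice3" else "frameshift")
  }

  # technically failing decoys: each fails exactly one gate; sites rotate
  # through AD panel filler genes distinct from any positive-bearing gene
  decoy_gene_pool <- setdiff(ad_fillers, c(def_genes, vus_genes))
  decoy_truth <- list()
  decoy_classes <- c("non_pass", "low_depth", "low_af", "benign")
  n_sites <- 5L
  site_genes <- stats::setNames(
    lapply(decoy_classes, function(cl) sample(decoy_gene_pool, n_sites)),
    decoy_classes)
  for (cl in decoy_classes) {
    rate <- spec$decoy_rates[[cl]]
    if (is.na(rate) || rate == 0L) next
    for (r in seq_len(rate)) {
      site_idx <- (match(ids, ids) + r) %% n_sites + 1L
      for (si in seq_len(n)) {
        g <- site_genes[[cl]][site_idx[si]]
        args <- switch(cl,
          non_pass = list(filter = "LowQual", codes = "PVS1,PM2,PP3",
                          consequence = "nonsense"),
          low_depth = list(ref_depth = 4L, alt_depth = 4L,
                           codes = "PVS1,PM2,PP3", consequence = "frameshift"),
          low_af = list(ref_depth = 77L, alt_depth = 23L,
                        codes = "PVS1,PM2,PP3", consequence = "frameshift"),
          benign = list(codes = "BS1,BS2", consequence = "missense")
        )
        do.call(add_variant, c(list(sample_id = ids[si], gene = g,
                                    site_k = r), args))
        decoy_truth[[length(decoy_truth) + 1L]] <- data.frame(
          sample_id = ids[si], class = cl, gene = g, stringsAsFactors = FALSE)
      }
    }
  }

  # inheritance decoys: AR gene with a single het (never qualifies) and an
  # AR gene with two distinct hets (suspected compound het, flagged)
  ar_single <- sample(ids, 3L)
  for (s in ar_single) add_variant(s, "PNLAR01", "PVS1,PM2,PP3")
  ar_comphet <- sample(setdiff(ids, ar_single), 2L)
  for (s in ar_comphet) {
    add_variant(s, "PNLAR02", "PVS1,PM2,PP3", site_k = 1L)
    add_variant(s, "PNLAR02", "PVS1,PM2", site_k = 2L)
  }

  variants <- do.call(rbind, var_rows)
  class(variants) <- c("small_variants", "data.frame")

  ## ---- network ------------------------------------------------------------
  net <- build_network(panel_genes, seed_offset = spec$seed)

  ## ---- ground truth -------------------------------------------------------
  truth_call <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (cat in .CATEGORIES) {
    truth_call[[cat]] <- ids %in% samples_of(cat)
  }
  cat_mat <- as.matrix(truth_call[, .CATEGORIES])
  truth_call$n_categories <- rowSums(cat_mat)
  truth_call$diagnosed <- truth_call$n_categories > 0L
  gch <- truth_call$PLP_definitive_gene | truth_call$PLP_candidate_gene
  hch <- truth_call$aneuploidy | truth_call$pathogenic_cnv |
    truth_call$vus_cnv_panel_gene
  truth_call$channel <- ifelse(gch & hch, "both",
                        ifelse(gch, "gene_only",
                        ifelse(hch, "chromosomal_only", "none")))

  cnv_decoy_truth <- rbind(
    if (!is.null(cnv_vus_decoy))
      data.frame(sample_id = cnv_vus_decoy$sample_id, class = "cnv_vus_no_panel",
                 gene = NA_character_, stringsAsFactors = FALSE),
    if (!is.null(cnv_benign_decoy))
      data.frame(sample_id = cnv_benign_decoy$sample_id, class = "cnv_benign",
                 gene = NA_character_, stringsAsFactors = FALSE),
    if (!is.null(cnv_small_decoy))
      data.frame(sample_id = cnv_small_decoy$sample_id, class = "cnv_small",
                 gene = NA_character_, stringsAsFactors = FALSE)
  )
  truth <- list(
    etiology = truth_call,
    decoys = rbind(do.call(rbind, decoy_truth), cnv_decoy_truth),
    flagged_compound_het = data.frame(sample_id = ar_comphet, gene = "PNLAR02",
                                      stringsAsFactors = FALSE),
    network_retained = net$retained,
    definitive_assignment = data.frame(sample_id = def_samples,
                                       gene = def_genes,
                                       stringsAsFactors = FALSE),
    candidate_assignment = data.frame(sample_id = cand_samples,
                                      gene = cand_tab$gene[cand_rows],
                                      stringsAsFactors = FALSE)
  )

  ## ---- write everything ---------------------------------------------------
  paths <- list(
    variants = file.path(dir, "variants.vcf"),
    cnvs = file.path(dir, "cnv_calls.tsv"),
    meta = file.path(dir, "sample_meta.tsv"),
    panel = file.path(dir, "gene_panel.tsv"),
    candidates = file.path(dir, "candidate_genes.tsv"),
    kggseq = file.path(dir, "kggseq_candidates.tsv"),
    edges = file.path(dir, "edges.tsv"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_small_variants(variants, paths$variants, samples = ids)
  cnvs_out <- cnvs
  class(cnvs_out) <- c("cnv_calls", "data.frame")
  write_cnv_table(cnvs_out, paths$cnvs)
  write_sample_meta(meta, paths$meta)
  write_gene_panel(panel, paths$panel)
  write_gene_list(cand_tab$gene, paths$candidates)
  write_gene_list(net$candidates, paths$kggseq)
  write_edges(net$edges, paths$edges)
  file.copy(system.file("extdata", "mini_genome.tsv", package = "chdtriage",
                        mustWork = TRUE), paths$chrom_lengths, overwrite = TRUE)

  hashes <- tools::md5sum(unlist(paths[names(paths) != "manifest"]))
  manifest <- list(
    generator = "chdtriage::generate_cohort",
    seed = spec$seed,
    spec = spec[setdiff(names(spec), "seed")],
    files = as.list(stats::setNames(unname(hashes),
                                    basename(names(hashes))))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(paths = paths, truth = truth, spec = spec)
}

# candidate list + weighted edges with planted high-confidence panel degree:
# FN1 gets 13 qualifying panel partners, IRS1/CCT5 11 each, RET01..RET07
# get 2..5 (RET01 exactly 2 edges at exactly 0.9 - the inclusive boundary),
# decoys get 1 qualifying edge, 2 sub-threshold edges, or none
build_network <- function(panel_genes, seed_offset = 0L) {
  top <- c(FN1 = 13L, IRS1 = 11L, CCT5 = 11L)
  rets <- stats::setNames(rep(2:5, length.out = 7L), sprintf("RET%02d", 1:7))
  planted <- c(top, rets)
  decoy_one <- sprintf("NETD1%02d", 1:6)    # one qualifying edge
  decoy_sub <- sprintf("NETD2%02d", 1:6)    # two edges at 0.89
  decoy_none <- sprintf("NETD3%02d", 1:6)   # no panel edges
  in_panel_cands <- panel_genes[seq_len(min(6L, length(panel_genes)))]
  candidates <- c(names(planted), decoy_one, decoy_sub, decoy_none,
                  in_panel_cands)

  edges <- list()
  add_edge <- function(a, b, conf) {
    edges[[length(edges) + 1L]] <<- data.frame(
      gene_a = a, gene_b = b, confidence = conf, stringsAsFactors = FALSE)
  }
  pool <- panel_genes
  for (g in names(planted)) {
    partners <- sample(pool, planted[[g]])
    conf <- round(stats::runif(length(partners), 0.90, 0.99), 3)
    if (g == "RET01") conf <- rep(0.9, length(partners))
    for (i in seq_along(partners)) add_edge(g, partners[i], conf[i])
    # plus a sub-threshold edge that must not count
    add_edge(g, sample(pool, 1L), 0.5)
  }
  for (g in decoy_one) add_edge(g, sample(pool, 1L), 0.95)
  for (g in decoy_sub) {
    p <- sample(pool, 2L)
    add_edge(g, p[1L], 0.89)
    add_edge(g, p[2L], 0.899)
  }
  # background panel-panel and candidate-candidate edges
  for (i in 1:10) {
    p <- sample(pool, 2L)
    add_edge(p[1L], p[2L], round(stats::runif(1, 0.3, 0.99), 3))
  }
  add_edge("NETD301", "NETD302", 0.99)
  edges <- normalize_edges(do.call(rbind, edges))
  list(candidates = candidates, edges = edges,
       retained = sort(names(planted)))
}

#' Compare pipeline calls against planted ground truth
#'
#' @param truth the `truth` element returned by [generate_cohort()]
#' @param calls an `etiology_calls` data.frame from the pipeline
#' @return list with `category_summary` (per-category TP/FP/FN/TN over
#'   samples), `n_mismatch` (samples whose category set differs from
#'   truth), `mismatches` (their ids) and `match` (TRUE when recovery is
#'   exact)
#' @export
truth_recovery_report <- function(truth, calls) {
  tr <- truth$etiology
  if (!setequal(tr$sample_id, calls$sample_id)) {
    abort("truth and calls cover different sample sets",
          class = "chdtriage_validation_error")
  }
  calls <- calls[match(tr$sample_id, calls$sample_id), , drop = FALSE]
  summ <- do.call(rbind, lapply(.CATEGORIES, function(cat) {
    t <- tr[[cat]]; c <- calls[[cat]]
    data.frame(category = cat,
               tp = sum(t & c), fp = sum(!t & c),
               fn = sum(t & !c), tn = sum(!t & !c),
               stringsAsFactors = FALSE)
  }))
  mism <- tr$sample_id[rowSums(
    as.matrix(tr[, .CATEGORIES]) != as.matrix(calls[, .CATEGORIES])) > 0]
  list(category_summary = summ, n_mismatch = length(mism),
       mismatches = mism, match = length(mism) == 0L)
}
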