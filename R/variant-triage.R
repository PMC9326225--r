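#' Technical filter for one small variant
#'
#' Applies the three technical gates in fixed order: FILTER must be
#' `"PASS"`; alternate-allele depth must be at least
#' `cfg$min_alt_depth` reads; heterozygous calls must additionally have an
#' alternate-allele fraction `alt/(ref+alt)` of at least
#' `cfg$min_het_allele_fraction`. Both thresholds are inclusive ("no less
#' than 5X", "exceeding or equal to 25%"). The boolean outcome does not
#' depend on gate order; only the reported reason does.
#'
#' @param v a single-row `small_variants` data.frame (or a list with the
#'   same fields)
#' @param cfg a [triage_config()]
#' @return list with `pass` (logical) and `reason` (`""` when passing;
#'   otherwise the first failing gate: `"filter-status"`, `"alt-depth"`,
#'   `"het-af"` or `"no-depth"`)
#' @examples
#' cfg <- triage_config()
#' v <- list(filter_status = "PASS", genotype = "het",
#'           ref_depth = 77L, alt_depth = 23L)
#' passes_technical_filters(v, cfg)  # fails "het-af" at fraction 0.23
#' @export
passes_technical_filters <- function(v, cfg = triage_config()) {
  st <- technical_filter_status(
    data.frame(filter_status = v$filter_status, genotype = v$genotype,
               ref_depth = v$ref_depth, alt_depth = v$alt_depth,
               stringsAsFactors = FALSE),
    cfg
  )
  list(pass = st$pass[1L], reason = st$reason[1L])
}

#' Vectorised technical filter
#'
#' @param variants a `small_variants` data.frame
#' @param cfg a [triage_config()]
#' @return data.frame with logical `pass` and character `reason` per row
#' @export
technical_filter_status <- function(variants, cfg = triage_config()) {
  n <- nrow(variants)
  pass <- rep(TRUE, n)
  reason <- rep("", n)

  bad <- variants$filter_status != "PASS"
  reason[bad & pass] <- "filter-status"
  pass <- pass & !bad

  bad <- variants$alt_depth < cfg$min_alt_depth
  reason[bad & pass] <- "alt-depth"
  pass <- pass & !bad

  tot <- variants$ref_depth + variants$alt_depth
  het <- variants$genotype == "het"
  nodep <- het & tot == 0
  reason[nodep & pass] <- "no-depth"
  pass <- pass & !nodep

  af <- ifelse(tot > 0, variants$alt_depth / tot, NA_real_)
  bad <- het & !is.na(af) & af < cfg$min_het_allele_fraction
  reason[bad & pass] <- "het-af"
  pass <- pass & !bad

  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Check zygosity consistency with OMIM-style inheritance modes
#'
#' Given the pathogenic/likely-pathogenic, technically passing variants of
#' one gene in one sample, decides whether their zygosity is consistent
#' with any of the gene's recorded inheritance modes. Modes are tried in
#' the fixed order AD, XLD, AR, XLR and the first qualifying mode is
#' reported:
#' * AD / XLD: any single het, hom or hemi variant qualifies;
#' * AR: a hom variant qualifies; two or more distinct het variants are
#'   flagged `suspected_compound_het` and do **not** qualify (phase is
#'   unconfirmed, so these are excluded from the diagnostic yield and
#'   reported separately);
#' * XLR: a hemizygous variant (males) or a hom variant qualifies.
#'
#' @param variants_in_gene `small_variants` rows sharing sample and gene
#' @param modes character vector of modes from `{AD, AR, XLD, XLR}`
#' @param sex `"male"`, `"female"` or `"unknown"`
#' @return list with `ok` (logical), `mode_used` (mode or `NA`), `flags`
#'   (character vector, possibly empty)
#' @export
inheritance_consistent <- function(variants_in_gene, modes, sex = "unknown") {
  modes <- unique(modes)
  assert_in(modes, .INH_MODES, "inheritance modes")
  flags <- character()
  if (length(modes) == 0L || nrow(variants_in_gene) == 0L) {
    return(list(ok = FALSE, mode_used = NA_character_, flags = flags))
  }
  gt <- variants_in_gene$genotype
  n_het_distinct <- length(unique(paste(
    variants_in_gene$chrom, variants_in_gene$pos,
    variants_in_gene$ref, variants_in_gene$alt
  )[gt == "het"]))

  for (m in intersect(c("AD", "XLD", "AR", "XLR"), modes)) {
    if (m %in% c("AD", "XLD")) {
      if (length(gt)) return(list(ok = TRUE, mode_used = m, flags = flags))
    } else if (m == "AR") {
      if (any(gt == "hom")) return(list(ok = TRUE, mode_used = m, flags = flags))
      if (n_het_distinct >= 2L) flags <- union(flags, "suspected_compound_het")
    } else if (m == "XLR") {
      if (any(gt == "hemi") || any(gt == "hom")) {
        return(list(ok = TRUE, mode_used = m, flags = flags))
      }
    }
  }
  list(ok = FALSE, mode_used = NA_character_, flags = flags)
}

#' Turn classified variants into per-sample gene-level etiologies
#'
#' Composition of the triage gates: keep variants that pass
#' [technical_filter_status()] and are classified Pathogenic or
#' LikelyPathogenic, group them per sample and gene, require
#' [inheritance_consistent()] zygosity, and assign the evidence class:
#' `definitive_panel` when the gene is in the curated panel,
#' `candidate_gene` when it is on the adjudicated candidate list (panel
#' membership wins when a gene is on both), otherwise the gene is dropped
#' and recorded in the `dropped` attribute (never silently).
#'
#' Candidate-list genes carry no curated inheritance mode; autosomal
#' dominant is assumed for them (the adjudication itself is expert curation
#' consumed as input, and every adjudicated gene in the motivating use case
#' is AD).
#'
#' @param variants `small_variants` with `tier` column (see
#'   [classify_variants()])
#' @param panel a `gene_panel`
#' @param candidate_list character vector of adjudicated candidate genes
#' @param meta a `sample_meta` (for sample sex)
#' @param cfg a [triage_config()]
#' @return a `gene_etiologies` data.frame: `sample_id`, `gene`,
#'   `evidence_class`, `inheritance_mode_used`, `n_variants`, `flags`.
#'   Attributes: `dropped` (passing P/LP gene hits in neither list),
#'   `flagged` (gene groups excluded with flags, e.g. suspected compound
#'   hets).
#' @export
assign_gene_etiologies <- function(variants, panel, candidate_list = character(),
                                   meta = NULL, cfg = triage_config()) {
  if (!"tier" %in% names(variants)) {
    abort("variants must carry a 'tier' column; run classify_variants() first")
  }
  st <- technical_filter_status(variants, cfg)
  keep <- st$pass & variants$tier %in% c("Pathogenic", "LikelyPathogenic")
  v <- variants[keep, , drop = FALSE]

  empty <- data.frame(
    sample_id = character(), gene = character(), evidence_class = character(),
    inheritance_mode_used = character(), n_variants = integer(),
    flags = character(), stringsAsFactors = FALSE
  )
  flagged <- dropped <- empty
  if (nrow(v) == 0L) {
    res <- empty
    class(res) <- c("gene_etiologies", "data.frame")
    attr(res, "dropped") <- dropped
    attr(res, "flagged") <- flagged
    return(res)
  }

  sex_of <- function(sid) {
    if (is.null(meta)) return("unknown")
    i <- match(sid, meta$sample_id)
    if (is.na(i)) "unknown" else meta$sex[i]
  }
  panel_modes <- strsplit(panel$inheritance_modes, ";", fixed = TRUE)
  names(panel_modes) <- panel$gene_symbol

  groups <- split(v, list(v$sample_id, v$gene), drop = TRUE)
  rows <- list()
  for (g in groups) {
    sid <- g$sample_id[1L]
    gene <- g$gene[1L]
    in_panel <- gene %in% panel$gene_symbol
    on_list <- gene %in% candidate_list
    modes <- if (in_panel) panel_modes[[gene]] else "AD"
    ic <- inheritance_consistent(g, modes, sex_of(sid))
    rec <- data.frame(
      sample_id = sid, gene = gene,
      evidence_class = if (in_panel) "definitive_panel"
        else if (on_list) "candidate_gene" else "unlisted",
      inheritance_mode_used = ic$mode_used,
      n_variants = nrow(g),
      flags = paste(ic$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
    if (!ic$ok) {
      if (length(ic$flags)) flagged <- rbind(flagged, rec)
      next
    }
    if (!in_panel && !on_list) {
      dropped <- rbind(dropped, rec)
      next
    }
    rows[[length(rows) + 1L]] <- rec
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  res <- res[order(res$sample_id, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gene_etiologies", "data.frame")
  attr(res, "dropped") <- dropped
  attr(res, "flagged") <- flagged
  res
}

#' Classify the variants of a cohort
#'
#' Adds `tier` and `matched_rule` columns by running the ACMG engine on
#' each variant's evidence-code set.
#'
#' @param variants a `small_variants` data.frame
#' @param rules optional `acmg_rules` table
#' @return `variants` with `tier` and `matched_rule` appended
#' @export
classify_variants <- function(variants, rules = NULL) {
  cl <- classify_evidence_strings(variants$evidence_codes, rules)
  variants$tier <- cl$tier
  variants$matched_rule <- cl$matched_rule
  variants
}

#' Tally variant consequences
#'
#' Counts variants per consequence class and renders proportions as
#' percentages to two decimals (half-up). Proportions sum to 1 over the
#' table.
#'
#' @param variants a `small_variants` data.frame (or anything with a
#'   `consequence` column)
#' @return data.frame `consequence, count, proportion, percent`, sorted by
#'   count descending then consequence
#' @examples
#' # 606 frameshift among 724 variants renders as 83.70
#' @export
tally_consequences <- function(variants) {
  if (nrow(variants) == 0L) {
    return(data.frame(consequence = character(), count = integer(),
                      proportion = numeric(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(variants$consequence)
  df <- data.frame(
    consequence = names(tab),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  df$proportion <- df$count / sum(df$count)
  df$percent <- round_half_up(100 * df$proportion, 2)
  df <- df[order(-df$count, df$consequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}
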