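#' Label a CNV or whole-chromosome event
#'
#' Coordinate-derived labels (`del(chr22:18900000-21500000)`) for segmental
#' events and karyotype-style labels for whole-chromosome events: `T<chr>`
#' for trisomy, `XO` for monosomy X, `M<chr>` otherwise. Recurrently
#' planted events share coordinates and therefore labels.
#'
#' @param chrom,start,end event interval (ignored for aneuploidies)
#' @param copy_state `"deletion"` or `"duplication"`
#' @param aneuploidy logical; whole-chromosome event
#' @return character label vector
#' @export
cnv_event_label <- function(chrom, start, end, copy_state, aneuploidy = FALSE) {
  chr_id <- sub("^chr", "", chrom)
  ifelse(aneuploidy,
         ifelse(copy_state == "duplication", paste0("T", chr_id),
                ifelse(chr_id == "X", "XO", paste0("M", chr_id))),
         paste0(ifelse(copy_state == "deletion", "del", "dup"),
                "(", chrom, ":",
                format(start, scientific = FALSE, trim = TRUE), "-",
                format(end, scientific = FALSE, trim = TRUE), ")"))
}

#' Promote a CNV to a whole-chromosome (aneuploidy) call
#'
#' A call spanning at least `cfg$aneuploidy_span_fraction` of its
#' chromosome is promoted: duplications become trisomies, deletions
#' monosomies. The mosaic fraction is propagated.
#'
#' @param cnv a single-row `cnv_calls` data.frame (or list with the same
#'   fields)
#' @param chrom_lengths named numeric vector of chromosome lengths
#' @param cfg a [triage_config()]
#' @return a one-row `aneuploidy_calls` data.frame, or `NULL` when the
#'   event stays segmental
#' @export
promote_aneuploidy <- function(cnv, chrom_lengths, cfg = triage_config()) {
  len <- unname(chrom_lengths[cnv$chrom])[1L]
  if (is.null(len) || is.na(len)) {
    abort("unknown chromosome in CNV call: ", cnv$chrom,
          class = "chdtriage_validation_error")
  }
  size <- cnv$end - cnv$start + 1
  if (size < cfg$aneuploidy_span_fraction * len) return(NULL)
  data.frame(
    sample_id = cnv$sample_id,
    chromosome = cnv$chrom,
    kind = if (cnv$copy_state == "duplication") "trisomy" else "monosomy",
    mosaic_fraction = if (is.null(cnv$mosaic_fraction)) NA_real_ else cnv$mosaic_fraction,
    label = cnv_event_label(cnv$chrom, cnv$start, cnv$end, cnv$copy_state,
                            aneuploidy = TRUE),
    stringsAsFactors = FALSE
  )
}

panel_intervals <- function(panel) {
  has_iv <- !is.na(panel$chrom) & !is.na(panel$start) & !is.na(panel$end)
  panel[has_iv, , drop = FALSE]
}

#' Panel genes overlapped by CNV intervals
#'
#' Maps each CNV to the curated panel genes whose intervals it overlaps
#' (any 1-bp overlap by default; full containment of the gene inside the
#' CNV with `cfg$cnv_gene_overlap = "containment"`). Interval arithmetic is
#' delegated to `GenomicRanges::findOverlaps`.
#'
#' @param cnvs a `cnv_calls` data.frame
#' @param panel a `gene_panel`
#' @param cfg a [triage_config()]
#' @return character vector (length `nrow(cnvs)`) of comma-separated panel
#'   gene symbols, `""` when none
#' @export
cnv_panel_genes <- function(cnvs, panel, cfg = triage_config()) {
  if (nrow(cnvs) == 0L) return(character())
  piv <- panel_intervals(panel)
  if (nrow(piv) == 0L) return(rep("", nrow(cnvs)))
  lev <- unique(c(cnvs$chrom, piv$chrom))
  cnv_gr <- GenomicRanges::GRanges(
    factor(cnvs$chrom, lev), IRanges::IRanges(cnvs$start, cnvs$end))
  gene_gr <- GenomicRanges::GRanges(
    factor(piv$chrom, lev), IRanges::IRanges(piv$start, piv$end))
  type <- if (cfg$cnv_gene_overlap == "containment") "within" else "any"
  hits <- GenomicRanges::findOverlaps(gene_gr, cnv_gr, type = type)
  out <- rep("", nrow(cnvs))
  if (length(hits)) {
    by_cnv <- split(piv$gene_symbol[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits))
    idx <- as.integer(names(by_cnv))
    out[idx] <- vapply(by_cnv, function(g) paste(sort(unique(g)), collapse = ","), "")
  }
  out
}

#' Triage one segmental CNV
#'
#' Applies the interpretation rule for size-passing segmental events:
#' tier P or LP is a definitive etiology (`pathogenic_cnv`); tier VUS
#' overlapping at least one curated panel gene is a candidate etiology
#' (`vus_cnv_panel_gene`); anything else (VUS without panel overlap, LB, B)
#' is non-causative. The mosaic fraction never gates any decision.
#'
#' @param cnv single-row `cnv_calls` data.frame; `size` must already meet
#'   `cfg$min_cnv_size` (smaller events are excluded upstream)
#' @param panel a `gene_panel`
#' @param cfg a [triage_config()]
#' @return one-row `cnv_etiologies` data.frame or `NULL`
#' @export
triage_cnv <- function(cnv, panel, cfg = triage_config()) {
  cnv <- as.data.frame(cnv, stringsAsFactors = FALSE)
  genes <- cnv_panel_genes(cnv, panel, cfg)
  cls <- if (cnv$tier %in% c("P", "LP")) "pathogenic_cnv"
    else if (cnv$tier == "VUS" && nzchar(genes)) "vus_cnv_panel_gene"
    else return(NULL)
  data.frame(
    sample_id = cnv$sample_id,
    evidence_class = cls,
    label = cnv_event_label(cnv$chrom, cnv$start, cnv$end, cnv$copy_state),
    chrom = cnv$chrom, start = cnv$start, end = cnv$end,
    copy_state = cnv$copy_state, tier = cnv$tier,
    mosaic_fraction = cnv$mosaic_fraction,
    panel_genes_hit = genes,
    stringsAsFactors = FALSE
  )
}

#' Triage a full CNV call set
#'
#' Partitions every input call into exactly one of five bins: below the
#' size threshold (`excluded-small`), promoted whole-chromosome event
#' (`aneuploidy`), `pathogenic_cnv`, `vus_cnv_panel_gene`, or
#' `non-causative`. The bin counts sum to the input count.
#'
#' @param cnvs a `cnv_calls` data.frame
#' @param panel a `gene_panel`
#' @param chrom_lengths named numeric vector
#' @param cfg a [triage_config()]
#' @return list with `etiologies` (a `cnv_etiologies` data.frame covering
#'   aneuploidies, pathogenic CNVs and VUS-over-panel CNVs),
#'   `aneuploidies` (the promoted calls), `partition` (named counts), and
#'   `excluded` (sub-threshold calls with reason)
#' @export
triage_cnvs <- function(cnvs, panel, chrom_lengths, cfg = triage_config()) {
  n <- nrow(cnvs)
  bin <- rep(NA_character_, n)

  small <- cnvs$size < cfg$min_cnv_size
  bin[small] <- "excluded-small"

  unknown <- setdiff(unique(cnvs$chrom[!small]), names(chrom_lengths))
  if (length(unknown)) {
    abort("unknown chromosome(s) in CNV calls: ", paste(unknown, collapse = ", "),
          class = "chdtriage_validation_error")
  }
  span <- cnvs$size / unname(chrom_lengths[cnvs$chrom])
  aneu <- !small & span >= cfg$aneuploidy_span_fraction
  bin[aneu] <- "aneuploidy"

  seg <- which(!small & !aneu)
  genes <- rep("", n)
  if (length(seg)) {
    genes[seg] <- cnv_panel_genes(cnvs[seg, , drop = FALSE], panel, cfg)
  }
  for (i in seg) {
    bin[i] <- if (cnvs$tier[i] %in% c("P", "LP")) "pathogenic_cnv"
      else if (cnvs$tier[i] == "VUS" && nzchar(genes[i])) "vus_cnv_panel_gene"
      else "non-causative"
  }

  aneu_df <- if (any(aneu)) {
    data.frame(
      sample_id = cnvs$sample_id[aneu],
      chromosome = cnvs$chrom[aneu],
      kind = ifelse(cnvs$copy_state[aneu] == "duplication", "trisomy", "monosomy"),
      mosaic_fraction = cnvs$mosaic_fraction[aneu],
      label = cnv_event_label(cnvs$chrom[aneu], cnvs$start[aneu],
                              cnvs$end[aneu], cnvs$copy_state[aneu],
                              aneuploidy = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sample_id = character(), chromosome = character(),
               kind = character(), mosaic_fraction = numeric(),
               label = character(), stringsAsFactors = FALSE)
  }

  causal <- which(bin %in% c("aneuploidy", "pathogenic_cnv", "vus_cnv_panel_gene"))
  etio <- if (length(causal)) {
    data.frame(
      sample_id = cnvs$sample_id[causal],
      evidence_class = bin[causal],
      label = cnv_event_label(cnvs$chrom[causal], cnvs$start[causal],
                              cnvs$end[causal], cnvs$copy_state[causal],
                              aneuploidy = bin[causal] == "aneuploidy"),
      chrom = cnvs$chrom[causal], start = cnvs$start[causal],
      end = cnvs$end[causal], copy_state = cnvs$copy_state[causal],
      tier = cnvs$tier[causal],
      mosaic_fraction = cnvs$mosaic_fraction[causal],
      panel_genes_hit = genes[causal],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(sample_id = character(), evidence_class = character(),
               label = character(), chrom = character(), start = numeric(),
               end = numeric(), copy_state = character(), tier = character(),
               mosaic_fraction = numeric(), panel_genes_hit = character(),
               stringsAsFactors = FALSE)
  }
  class(etio) <- c("cnv_etiologies", "data.frame")

  excluded <- cnvs[small, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "below-min-cnv-size"

  partition <- c(
    `excluded-small` = sum(bin == "excluded-small"),
    aneuploidy = sum(bin == "aneuploidy"),
    pathogenic_cnv = sum(bin == "pathogenic_cnv"),
    vus_cnv_panel_gene = sum(bin == "vus_cnv_panel_gene"),
    `non-causative` = sum(bin == "non-causative")
  )
  list(etiologies = etio, aneuploidies = aneu_df, partition = partition,
       excluded = excluded)
}

#' Sample-level recurrence table of event or gene labels
#'
#' Counts the number of distinct samples per label (an event recurring
#' twice in one sample counts once), sorted by count descending then label.
#'
#' @param labels data.frame with columns `sample_id` and `label`
#' @return data.frame `label, n_samples`
#' @export
recurrence_table <- function(labels) {
  if (nrow(labels) == 0L) {
    return(data.frame(label = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  u <- unique(labels[, c("sample_id", "label")])
  tab <- table(u$label)
  df <- data.frame(label = names(tab), n_samples = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_samples, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}
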