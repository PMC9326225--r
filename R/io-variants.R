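#' Read annotated small variants from a VCF file
#'
#' Parses a VCF 4.x subset in which each record carries its gene symbol,
#' consequence class and ACMG evidence codes in the INFO keys `GENE`,
#' `CSQCLASS` and `ACMG` (comma-separated codes), and per-sample genotypes
#' in `FORMAT` fields `GT` and `AD`. One row is emitted per ALT allele per
#' carrying sample; samples whose genotype does not include the ALT allele
#' contribute no row. Positions are 1-based as in VCF and the FILTER column
#' is preserved verbatim.
#'
#' @param path path to a plain-text VCF file
#' @param sample_map optional named character vector renaming VCF sample
#'   columns (`old = new`)
#' @return a `small_variants` data.frame with columns `sample_id`, `chrom`,
#'   `pos`, `id`, `ref`, `alt`, `gene`, `consequence`, `filter_status`,
#'   `genotype` (het/hom/hemi), `ref_depth`, `alt_depth`, `evidence_codes`
#'   (comma-separated string)
#' @export
read_small_variants <- function(path, sample_map = NULL) {
  if (!file.exists(path)) abort("VCF not found: ", path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_small_variants())

  chrom_v <- unname(fix[, "CHROM"])
  pos_v <- as.integer(fix[, "POS"])
  id_v <- unname(fix[, "ID"])
  ref_v <- unname(fix[, "REF"])
  alt_v <- unname(fix[, "ALT"])
  filt_v <- unname(fix[, "FILTER"])
  gene <- unname(vcfR::extract.info(vcf, element = "GENE"))
  csq <- unname(vcfR::extract.info(vcf, element = "CSQCLASS"))
  acmg <- unname(vcfR::extract.info(vcf, element = "ACMG"))
  acmg[is.na(acmg)] <- ""

  gt_mat <- vcf@gt
  samples <- colnames(gt_mat)[-1L]
  if (!is.null(sample_map)) {
    hit <- samples %in% names(sample_map)
    samples[hit] <- unname(sample_map[samples[hit]])
  }

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    rec_name <- paste0(chrom_v[i], ":", pos_v[i], " ", ref_v[i], ">", alt_v[i])
    fmt <- strsplit(gt_mat[i, 1L], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    ai <- match("AD", fmt)
    if (is.na(gi) || is.na(ai)) {
      abort("record ", rec_name, ": FORMAT must contain GT and AD",
            class = "chdtriage_validation_error")
    }
    codes <- strsplit(acmg[i], ",", fixed = TRUE)[[1]]
    codes <- codes[nzchar(codes)]
    validate_acmg_codes(codes)
    codes_str <- paste(codes, collapse = ",")
    alts <- strsplit(alt_v[i], ",", fixed = TRUE)[[1]]

    cells <- unname(gt_mat[i, -1L])
    live <- which(!is.na(cells) & cells != ".")
    if (!length(live)) next
    parts <- strsplit(cells[live], ":", fixed = TRUE)
    gts <- vapply(parts, `[`, "", gi)
    ads <- vapply(parts, `[`, "", ai)
    ok <- !is.na(gts) & !(gts %in% c(".", "./.", ".|."))
    live <- live[ok]; gts <- gts[ok]; ads <- ads[ok]
    if (!length(live)) next
    allele_l <- lapply(strsplit(gts, "[/|]"),
                       function(a) suppressWarnings(as.integer(a)))
    ad_l <- lapply(strsplit(ads, ",", fixed = TRUE),
                   function(a) suppressWarnings(as.integer(a)))
    called <- !vapply(allele_l, anyNA, TRUE)
    live <- live[called]; allele_l <- allele_l[called]; ad_l <- ad_l[called]
    if (!length(live)) next
    bad_ad <- vapply(ad_l, function(a) anyNA(a) || length(a) < length(alts) + 1L, TRUE)
    if (any(bad_ad)) {
      abort("record ", rec_name, " sample ", samples[live[which(bad_ad)[1L]]],
            ": AD must list ref and every alt depth",
            class = "chdtriage_validation_error")
    }

    blocks <- list()
    for (k in seq_along(alts)) {
      n_k <- vapply(allele_l, function(a) sum(a == k), 0L)
      n_tot <- lengths(allele_l)
      carrier <- n_k > 0L
      if (!any(carrier)) next
      genotype <- ifelse(n_tot == 1L, "hemi",
                  ifelse(n_k == n_tot, "hom", "het"))[carrier]
      blocks[[length(blocks) + 1L]] <- data.frame(
        sample_id = samples[live[carrier]],
        chrom = chrom_v[i],
        pos = pos_v[i],
        id = if (is.na(id_v[i])) "." else id_v[i],
        ref = ref_v[i],
        alt = alts[k],
        gene = if (is.na(gene[i])) NA_character_ else gene[i],
        consequence = if (is.na(csq[i])) "other" else csq[i],
        filter_status = if (is.na(filt_v[i])) "." else filt_v[i],
        genotype = genotype,
        ref_depth = vapply(ad_l, `[`, 0L, 1L)[carrier],
        alt_depth = vapply(ad_l, `[`, 0L, k + 1L)[carrier],
        evidence_codes = codes_str,
        stringsAsFactors = FALSE
      )
    }
    if (length(blocks)) out[[i]] <- do.call(rbind, blocks)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else empty_small_variants()
  rownames(res) <- NULL
  class(res) <- c("small_variants", "data.frame")
  res
}

empty_small_variants <- function() {
  res <- data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    id = character(), ref = character(), alt = character(),
    gene = character(), consequence = character(),
    filter_status = character(), genotype = character(),
    ref_depth = integer(), alt_depth = integer(),
    evidence_codes = character(), stringsAsFactors = FALSE
  )
  class(res) <- c("small_variants", "data.frame")
  res
}

#' Write small variants to a VCF file
#'
#' Inverse of [read_small_variants()]: emits a multi-sample VCF 4.2 file in
#' which carriers get `GT:AD` genotype cells and non-carriers `0/0`.
#' Variants sharing position but differing in annotation are written as
#' separate records (legal VCF). Round-trip through
#' [read_small_variants()] recovers the carrier rows exactly.
#'
#' @param variants a `small_variants` data.frame
#' @param path output path
#' @param samples optional character vector fixing the sample-column set and
#'   order; defaults to the samples present in `variants`
#' @return `path`, invisibly
#' @export
write_small_variants <- function(variants, path, samples = NULL) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(samples)) samples <- sort(unique(v$sample_id))
  key_cols <- c("chrom", "pos", "id", "ref", "alt", "gene", "consequence",
                "filter_status", "evidence_codes")
  if (nrow(v)) {
    key <- do.call(paste, c(v[key_cols], sep = "\r"))
    v$.key <- key
    recs <- v[!duplicated(key), key_cols, drop = FALSE]
    recs <- recs[order(recs$chrom, recs$pos, recs$ref, recs$alt), , drop = FALSE]
  } else {
    recs <- v[key_cols]
  }

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=chdtriage",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=ACMG,Number=.,Type=String,Description=\"ACMG evidence codes\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)

  if (nrow(recs)) {
    gt_for <- function(genotype) switch(genotype,
      het = "0/1", hom = "1/1", hemi = "1",
      abort("unknown genotype class: ", genotype))
    lines <- character(nrow(recs))
    for (i in seq_len(nrow(recs))) {
      r <- recs[i, ]
      rkey <- paste(unlist(r[key_cols]), collapse = "\r")
      carriers <- v[v$.key == rkey, , drop = FALSE]
      cells <- rep("0/0:0,0", length(samples))
      idx <- match(carriers$sample_id, samples)
      if (anyNA(idx)) abort("sample(s) not in the sample set: ",
                            paste(carriers$sample_id[is.na(idx)], collapse = ", "))
      cells[idx] <- paste0(
        vapply(carriers$genotype, gt_for, ""),
        ":", carriers$ref_depth, ",", carriers$alt_depth
      )
      info <- paste0(
        if (!is.na(r$gene)) paste0("GENE=", r$gene, ";") else "",
        "CSQCLASS=", r$consequence,
        if (nzchar(r$evidence_codes)) paste0(";ACMG=", r$evidence_codes) else ""
      )
      lines[i] <- paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".",
                          r$filter_status, info, "GT:AD", cells),
                        collapse = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}
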