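#' Tabular readers and writers
#'
#' Plain-TSV carriers for CNV calls, the curated gene panel, sample
#' metadata, interaction edges, chromosome lengths and flat gene lists.
#' Malformed rows are hard errors, never warnings: in a clinical-style
#' pipeline a silently dropped record corrupts every downstream yield.
#'
#' @name io_tables
NULL

.CNV_TIERS <- c("B", "LB", "VUS", "LP", "P")
.INH_MODES <- c("AD", "AR", "XLD", "XLR")
.SEXES <- c("male", "female", "unknown")
.SAMPLE_TYPES <- c("tissue", "cord_blood", "amniotic_fluid")
.US_PERIODS <- c("fetus", "neonate")
.PHENO_GROUPS <- c("isolated", "non_isolated", "unknown")

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(basename(path), ": missing column(s): ", paste(miss, collapse = ", "),
          class = "chdtriage_validation_error")
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a CNV call table
#'
#' @param path TSV with header `sample_id, chrom, start, end, copy_state,
#'   mosaic_fraction, tier`; `copy_state` in `{deletion, duplication}`,
#'   `mosaic_fraction` in `[0,1]` or empty, `tier` one of `B, LB, VUS, LP, P`.
#' @return a `cnv_calls` data.frame; intervals 1-based inclusive, `size`
#'   computed as `end - start + 1`
#' @export
read_cnv_table <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "chrom", "start", "end",
                                "copy_state", "mosaic_fraction", "tier"))
  if (nrow(df) == 0L) return(empty_cnv_calls())
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(start) || anyNA(end)) abort("CNV table: non-numeric start/end",
                                        class = "chdtriage_validation_error")
  bad <- which(start > end)
  if (length(bad)) {
    abort("CNV table row ", bad[1L], ": start > end (",
          start[bad[1L]], " > ", end[bad[1L]], ")",
          class = "chdtriage_validation_error")
  }
  assert_in(df$copy_state, c("deletion", "duplication"), "CNV copy_state")
  assert_in(df$tier, .CNV_TIERS, "CNV tier")
  mf <- suppressWarnings(as.numeric(df$mosaic_fraction))
  has_mf <- nzchar(df$mosaic_fraction)
  if (any(has_mf & (is.na(mf) | mf < 0 | mf > 1))) {
    abort("CNV table: mosaic_fraction must be in [0,1] or empty",
          class = "chdtriage_validation_error")
  }
  mf[!has_mf] <- NA_real_
  res <- data.frame(
    sample_id = df$sample_id, chrom = df$chrom,
    start = start, end = end, copy_state = df$copy_state,
    mosaic_fraction = mf, tier = df$tier,
    size = end - start + 1,
    stringsAsFactors = FALSE
  )
  class(res) <- c("cnv_calls", "data.frame")
  res
}

empty_cnv_calls <- function() {
  res <- data.frame(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), copy_state = character(), mosaic_fraction = numeric(),
    tier = character(), size = numeric(), stringsAsFactors = FALSE
  )
  class(res) <- c("cnv_calls", "data.frame")
  res
}

#' Write a CNV call table
#' @param cnvs a `cnv_calls` data.frame
#' @param path output TSV path
#' @export
write_cnv_table <- function(cnvs, path) {
  cols <- c("sample_id", "chrom", "start", "end", "copy_state",
            "mosaic_fraction", "tier")
  df <- as.data.frame(cnvs)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write_tsv(df, path)
}

#' Read the curated gene panel
#'
#' @param path TSV with header `gene_symbol, sources, inheritance_modes,
#'   chrom, start, end`. `sources` and `inheritance_modes` are
#'   semicolon-separated; modes are drawn from AD/AR/XLD/XLR (OMIM-style).
#'   `chrom/start/end` (1-based inclusive) may be empty when no interval is
#'   curated.
#' @return a `gene_panel` data.frame (one row per gene; modes kept as a
#'   semicolon-separated string)
#' @export
read_gene_panel <- function(path) {
  df <- read_tsv_strict(path, c("gene_symbol", "sources", "inheritance_modes",
                                "chrom", "start", "end"))
  if (anyDuplicated(df$gene_symbol)) {
    abort("gene panel: duplicate gene_symbol: ",
          df$gene_symbol[duplicated(df$gene_symbol)][1L],
          class = "chdtriage_validation_error")
  }
  modes <- strsplit(df$inheritance_modes, ";", fixed = TRUE)
  for (i in seq_along(modes)) {
    assert_in(modes[[i]], .INH_MODES, paste0("panel gene ", df$gene_symbol[i],
                                             " inheritance_modes"))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  has_iv <- nzchar(df$chrom)
  if (any(has_iv & (is.na(start) | is.na(end)))) {
    abort("gene panel: interval rows need numeric start and end",
          class = "chdtriage_validation_error")
  }
  if (any(has_iv & start > end)) {
    abort("gene panel: interval start > end",
          class = "chdtriage_validation_error")
  }
  res <- data.frame(
    gene_symbol = df$gene_symbol, sources = df$sources,
    inheritance_modes = df$inheritance_modes,
    chrom = ifelse(has_iv, df$chrom, NA_character_),
    start = ifelse(has_iv, start, NA_real_),
    end = ifelse(has_iv, end, NA_real_),
    stringsAsFactors = FALSE
  )
  class(res) <- c("gene_panel", "data.frame")
  res
}

#' Write a gene panel table
#' @param panel a `gene_panel` data.frame
#' @param path output TSV path
#' @export
write_gene_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, c("gene_symbol", "sources", "inheritance_modes",
                                 "chrom", "start", "end"), drop = FALSE]
  for (col in c("start", "end")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        format(df[[col]], scientific = FALSE, trim = TRUE))
  }
  df$chrom[is.na(df$chrom)] <- ""
  write_tsv(df, path)
}

#' Read sample metadata
#'
#' @param path TSV with header `sample_id, sex, sample_type,
#'   ultrasound_period, phenotype_group`; enums are validated strictly
#'   (`sex`: male/female/unknown; `sample_type`: tissue/cord_blood/
#'   amniotic_fluid; `ultrasound_period`: fetus/neonate; `phenotype_group`:
#'   isolated/non_isolated/unknown)
#' @return a `sample_meta` data.frame
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "sex", "sample_type",
                                "ultrasound_period", "phenotype_group"))
  if (anyDuplicated(df$sample_id)) {
    abort("sample metadata: duplicate sample_id",
          class = "chdtriage_validation_error")
  }
  assert_in(df$sex, .SEXES, "sex")
  assert_in(df$sample_type, .SAMPLE_TYPES, "sample_type")
  assert_in(df$ultrasound_period, .US_PERIODS, "ultrasound_period")
  assert_in(df$phenotype_group, .PHENO_GROUPS, "phenotype_group")
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Write sample metadata
#' @param meta a `sample_meta` data.frame
#' @param path output TSV path
#' @export
write_sample_meta <- function(meta, path) {
  write_tsv(as.data.frame(meta)[, c("sample_id", "sex", "sample_type",
                                    "ultrasound_period", "phenotype_group")],
            path)
}

#' Read a weighted gene-interaction edge list
#'
#' Undirected semantics: `(a,b)` and `(b,a)` collapse to one record keeping
#' the maximum confidence; self-edges are dropped. Confidence must lie in
#' `[0,1]`; inputs on the common 0-999 interaction-database scale (any value
#' `> 1`) are detected and divided by 1000 with a message.
#'
#' @param path TSV with header `gene_a, gene_b, confidence`
#' @return an `edge_list` data.frame with columns `gene_a, gene_b,
#'   confidence`, `gene_a < gene_b` lexicographically
#' @export
read_edges <- function(path) {
  df <- read_tsv_strict(path, c("gene_a", "gene_b", "confidence"))
  conf <- suppressWarnings(as.numeric(df$confidence))
  if (anyNA(conf) && nrow(df)) {
    abort("edge list: non-numeric confidence",
          class = "chdtriage_validation_error")
  }
  if (length(conf) && any(conf > 1)) {
    if (all(conf >= 0 & conf <= 1000)) {
      message("edge confidences > 1 detected; assuming 0-999 scale, dividing by 1000")
      conf <- conf / 1000
    }
  }
  if (length(conf) && any(conf < 0 | conf > 1)) {
    abort("edge list: confidence outside [0,1]",
          class = "chdtriage_validation_error")
  }
  normalize_edges(data.frame(gene_a = df$gene_a, gene_b = df$gene_b,
                             confidence = conf, stringsAsFactors = FALSE))
}

normalize_edges <- function(edges) {
  keep <- edges$gene_a != edges$gene_b
  edges <- edges[keep, , drop = FALSE]
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(edges$confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  res <- data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    confidence = as.numeric(conf),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("edge_list", "data.frame")
  res
}

#' Write an edge list
#' @param edges an `edge_list` data.frame
#' @param path output TSV path
#' @export
write_edges <- function(edges, path) {
  write_tsv(as.data.frame(edges)[, c("gene_a", "gene_b", "confidence")], path)
}

#' Read chromosome lengths
#' @param path TSV with header `chrom, length`
#' @return named numeric vector of lengths keyed by chromosome
#' @export
read_chrom_lengths <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "length"))
  len <- suppressWarnings(as.numeric(df$length))
  if (anyNA(len) && nrow(df)) abort("chromosome lengths: non-numeric length",
                                    class = "chdtriage_validation_error")
  stats::setNames(len, df$chrom)
}

#' Read a flat gene list
#' @param path TSV with a single `gene` column
#' @return character vector of unique gene symbols
#' @export
read_gene_list <- function(path) {
  df <- read_tsv_strict(path, "gene")
  unique(df$gene[nzchar(df$gene)])
}

#' Write a flat gene list
#' @param genes character vector
#' @param path output TSV path
#' @export
write_gene_list <- function(genes, path) {
  write_tsv(data.frame(gene = genes, stringsAsFactors = FALSE), path)
}
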