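.CATEGORIES <- c("PLP_definitive_gene", "PLP_candidate_gene", "aneuploidy",
                 "pathogenic_cnv", "vus_cnv_panel_gene")

#' The five etiology categories
#' @return character vector: P|LP variants in definitive panel genes, P|LP
#'   variants in candidate genes, aneuploidy, pathogenic/likely-pathogenic
#'   CNVs, VUS CNVs over panel genes
#' @export
etiology_categories <- function() .CATEGORIES

#' Assign the five etiology categories per sample
#'
#' Combines gene-level (WES channel) and CNV-level (low-coverage WGS
#' channel) etiologies into one call per sample, including all-negative
#' samples. A sample may carry several categories. The reporting channel is
#' `gene_only` / `chromosomal_only` / `both` / `none`, where the gene
#' channel covers the two variant categories and the chromosomal channel
#' the three CNV categories.
#'
#' @param gene_etiologies a `gene_etiologies` data.frame
#'   ([assign_gene_etiologies()])
#' @param cnv_etiologies a `cnv_etiologies` data.frame ([triage_cnvs()])
#' @param meta a `sample_meta` (defines the sample universe)
#' @return an `etiology_calls` data.frame: `sample_id`, one logical column
#'   per category, `n_categories`, `diagnosed`, `channel`
#' @export
assign_categories <- function(gene_etiologies, cnv_etiologies, meta) {
  ids <- meta$sample_id
  extra <- setdiff(unique(c(gene_etiologies$sample_id,
                            cnv_etiologies$sample_id)), ids)
  if (length(extra)) {
    abort("etiology for sample(s) absent from metadata: ",
          paste(extra, collapse = ", "),
          class = "chdtriage_validation_error")
  }
  res <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  res$PLP_definitive_gene <- ids %in%
    gene_etiologies$sample_id[gene_etiologies$evidence_class == "definitive_panel"]
  res$PLP_candidate_gene <- ids %in%
    gene_etiologies$sample_id[gene_etiologies$evidence_class == "candidate_gene"]
  res$aneuploidy <- ids %in%
    cnv_etiologies$sample_id[cnv_etiologies$evidence_class == "aneuploidy"]
  res$pathogenic_cnv <- ids %in%
    cnv_etiologies$sample_id[cnv_etiologies$evidence_class == "pathogenic_cnv"]
  res$vus_cnv_panel_gene <- ids %in%
    cnv_etiologies$sample_id[cnv_etiologies$evidence_class == "vus_cnv_panel_gene"]

  cat_mat <- as.matrix(res[, .CATEGORIES])
  res$n_categories <- rowSums(cat_mat)
  res$diagnosed <- res$n_categories > 0L
  gene_ch <- res$PLP_definitive_gene | res$PLP_candidate_gene
  chrom_ch <- res$aneuploidy | res$pathogenic_cnv | res$vus_cnv_panel_gene
  res$channel <- ifelse(gene_ch & chrom_ch, "both",
                 ifelse(gene_ch, "gene_only",
                 ifelse(chrom_ch, "chromosomal_only", "none")))
  class(res) <- c("etiology_calls", "data.frame")
  res
}

#' Agresti-Coull binomial confidence interval
#'
#' Adds \eqn{z^2/2} pseudo-successes and \eqn{z^2} pseudo-trials, then
#' applies a Wald-style interval around the adjusted centre
#' \eqn{\tilde p = (x + z^2/2)/(n + z^2)}: bounds
#' \eqn{\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}}, clamped to
#' `[0,1]`. This is the interval that reproduces every printed cohort CI
#' to two decimals (Wilson and Clopper-Pearson do not); both alternatives
#' are available via `method`.
#'
#' @param x successes (non-negative integer, `x <= n`)
#' @param n trials (positive integer)
#' @param alpha two-sided error rate (default 0.05)
#' @param method `"agresti-coull"` (default), `"wilson"` or
#'   `"clopper-pearson"`
#' @return a `proportion_ci` list: `x`, `n`, `percent` (point estimate
#'   `x/n` as a two-decimal percentage), `lower`/`upper` (two-decimal
#'   percentages), `p_lower`/`p_upper` (full-precision proportions),
#'   `alpha`, `z`, `method`
#' @examples
#' ci <- agresti_coull_ci(42, 121)
#' c(ci$percent, ci$lower, ci$upper)  # 34.71 26.80 43.56
#' @export
agresti_coull_ci <- function(x, n, alpha = 0.05,
                             method = c("agresti-coull", "wilson",
                                        "clopper-pearson")) {
  method <- match.arg(method)
  if (length(n) != 1L || is.na(n) || n <= 0) {
    abort("agresti_coull_ci: n must be a positive count",
          class = "chdtriage_validation_error")
  }
  if (x < 0 || x > n) abort("agresti_coull_ci: need 0 <= x <= n",
                            class = "chdtriage_validation_error")
  z <- stats::qnorm(1 - alpha / 2)
  if (method == "agresti-coull") {
    nt <- n + z^2
    pt <- (x + z^2 / 2) / nt
    half <- z * sqrt(pt * (1 - pt) / nt)
    lo <- pt - half
    hi <- pt + half
  } else if (method == "wilson") {
    p <- x / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- centre - half
    hi <- centre + half
  } else {
    bt <- stats::binom.test(x, n, conf.level = 1 - alpha)
    lo <- bt$conf.int[1L]
    hi <- bt$conf.int[2L]
  }
  lo <- max(0, lo)
  hi <- min(1, hi)
  structure(list(
    x = x, n = n,
    percent = round_half_up(100 * x / n, 2),
    lower = round_half_up(100 * lo, 2),
    upper = round_half_up(100 * hi, 2),
    p_lower = lo, p_upper = hi,
    alpha = alpha, z = z, method = method
  ), class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.2f%% [%d/%d, %d%%CI (%.2f%%-%.2f%%), %s]\n",
              x$percent, x$x, x$n, round((1 - x$alpha) * 100),
              x$lower, x$upper, x$method))
  invisible(x)
}

#' Fisher exact test with conditional-MLE odds ratio on a 2x2 table
#'
#' Table layout: rows are groups, columns diagnosed/undiagnosed, i.e.
#' `a`/`b` are group 1 diagnosed/undiagnosed and `c`/`d` group 2. The
#' odds-ratio estimate is the conditional maximum-likelihood estimate
#' under Fisher's noncentral hypergeometric distribution (the value
#' solving `E[A | margins, psi] = a`); the two-sided p sums the
#' conditional probabilities (at psi = 1) of all tables with fixed
#' margins whose probability does not exceed the observed table's. Both
#' are delegated to [stats::fisher.test()]. Tables with a zero cell give
#' an estimate of 0 or `Inf` and are flagged (`zero_cell = TRUE`); the
#' corresponding conditional-likelihood bound is one-sided.
#'
#' @param a,b,c,d non-negative integer counts
#' @param estimator `"cmle"` (default) or `"cross-product"` (`ad/bc`)
#' @return a `contingency_2x2` list: `a,b,c,d`, `or` (selected estimator),
#'   `or_cmle`, `or_cross`, `p_two_sided`, `zero_cell`, `estimator`
#' @examples
#' fisher_or(24, 28, 18, 51)$or_cmle  # ~2.41
#' @export
fisher_or <- function(a, b, c, d, estimator = c("cmle", "cross-product")) {
  estimator <- match.arg(estimator)
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cnt)) || any(cnt < 0)) {
    abort("fisher_or: counts must be non-negative",
          class = "chdtriage_validation_error")
  }
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("fisher_or: degenerate margin (an entire row or column is zero)",
          class = "chdtriage_validation_error")
  }
  ft <- stats::fisher.test(m)
  or_cmle <- unname(ft$estimate)
  or_cross <- if (b * c == 0) Inf else (a * d) / (b * c)
  if (a * d == 0 && b * c == 0) or_cross <- NaN
  structure(list(
    a = a, b = b, c = c, d = d,
    or = if (estimator == "cmle") or_cmle else or_cross,
    or_cmle = or_cmle,
    or_cross = or_cross,
    p_two_sided = ft$p.value,
    zero_cell = any(cnt == 0),
    estimator = estimator
  ), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 [%d %d; %d %d]  OR(%s) = %.3f, two-sided exact p = %.5g%s\n",
              x$a, x$b, x$c, x$d, x$estimator, x$or, x$p_two_sided,
              if (x$zero_cell) " [zero cell: one-sided bound behaviour]" else ""))
  invisible(x)
}

subgroup_or <- function(calls, meta, var, level1, level2) {
  g <- meta[[var]][match(calls$sample_id, meta$sample_id)]
  in1 <- g == level1
  in2 <- g == level2
  a <- sum(calls$diagnosed & in1)
  b <- sum(!calls$diagnosed & in1)
  cc <- sum(calls$diagnosed & in2)
  d <- sum(!calls$diagnosed & in2)
  if (min(a + b, cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
    return(NULL)  # degenerate margin; no OR computable
  }
  res <- fisher_or(a, b, cc, d)
  list(comparison = paste0(level1, "_vs_", level2),
       a = a, b = b, c = cc, d = d,
       or_cmle = res$or_cmle, or_cross = res$or_cross,
       p_two_sided = res$p_two_sided,
       rate1 = percent2(a, a + b), rate2 = percent2(cc, cc + d))
}

#' Cohort diagnostic-yield report
#'
#' Computes the overall diagnostic yield, per-channel yields
#' (chromosomal-only / gene-only / both), per-category sample counts (each
#' with its binomial CI), recurrence tables, and subgroup odds ratios for
#' sex (female vs male), ultrasound period (fetus vs neonate) and
#' phenotype group (isolated vs non-isolated), excluding `unknown` levels
#' from each comparison.
#'
#' @param calls an `etiology_calls` data.frame ([assign_categories()])
#' @param meta a `sample_meta`
#' @param cfg a [triage_config()]
#' @param gene_etiologies optional `gene_etiologies` for the gene
#'   recurrence table
#' @param cnv_etiologies optional `cnv_etiologies` for the event
#'   recurrence table
#' @return a `yield_report` list; see Details in the package vignette
#' @export
yield_report <- function(calls, meta, cfg = triage_config(),
                         gene_etiologies = NULL, cnv_etiologies = NULL) {
  n <- nrow(calls)
  ci <- function(x) agresti_coull_ci(x, n, cfg$ci_alpha, cfg$ci_method)

  n_diag <- sum(calls$diagnosed)
  channels <- c("chromosomal_only", "gene_only", "both")
  channel_counts <- vapply(channels, function(ch) sum(calls$channel == ch), 0L)
  category_counts <- vapply(.CATEGORIES, function(cat) sum(calls[[cat]]), 0L)

  multi <- c(two_categories = sum(calls$n_categories == 2L),
             three_or_more_categories = sum(calls$n_categories >= 3L))

  ors <- Filter(Negate(is.null), list(
    sex = subgroup_or(calls, meta, "sex", "female", "male"),
    ultrasound_period = subgroup_or(calls, meta, "ultrasound_period",
                                    "fetus", "neonate"),
    phenotype_group = subgroup_or(calls, meta, "phenotype_group",
                                  "isolated", "non_isolated")
  ))

  recurrence <- list()
  if (!is.null(gene_etiologies) && nrow(gene_etiologies)) {
    recurrence$genes <- recurrence_table(
      data.frame(sample_id = gene_etiologies$sample_id,
                 label = gene_etiologies$gene, stringsAsFactors = FALSE))
  }
  if (!is.null(cnv_etiologies) && nrow(cnv_etiologies)) {
    recurrence$events <- recurrence_table(
      cnv_etiologies[, c("sample_id", "label")])
  }

  structure(list(
    n_samples = n,
    n_diagnosed = n_diag,
    overall = ci(n_diag),
    channels = stats::setNames(lapply(channel_counts, ci), channels),
    channel_counts = channel_counts,
    categories = stats::setNames(lapply(category_counts, ci), .CATEGORIES),
    category_counts = category_counts,
    multi_category = multi,
    subgroup_or = ors,
    recurrence = recurrence,
    notes = c(
      "Subgroup denominators follow the cohort metadata; sentence-level and",
      "table-level denominators can disagree in published reports and the",
      "metadata is taken as authoritative."
    )
  ), class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat(sprintf("Cohort of %d samples; %d diagnosed\n", x$n_samples, x$n_diagnosed))
  cat("  overall:           "); print(x$overall)
  for (ch in names(x$channels)) {
    cat(sprintf("  %-18s ", paste0(ch, ":"))); print(x$channels[[ch]])
  }
  cat("  categories (samples):",
      paste(sprintf("%s=%d", names(x$category_counts), x$category_counts),
            collapse = ", "), "\n")
  cat("  multi-category:", paste(sprintf("%s=%d", names(x$multi_category),
                                         x$multi_category), collapse = ", "), "\n")
  for (nm in names(x$subgroup_or)) {
    o <- x$subgroup_or[[nm]]
    cat(sprintf("  OR %s (%s): %.2f, p = %.4g\n", nm, o$comparison,
                o$or_cmle, o$p_two_sided))
  }
  invisible(x)
}

#' Landscape matrix of etiologies and clinical features
#'
#' Builds the sample-by-feature matrix behind a cohort landscape plot: one
#' row per sample, binary indicator columns for the five etiology
#' categories plus the four metadata columns (sex, sample type, ultrasound
#' period, phenotype group). Rows are ordered diagnosed-first, then by
#' category count descending, then by sample id.
#'
#' @param calls an `etiology_calls` data.frame
#' @param meta a `sample_meta`
#' @return a `landscape_matrix` data.frame (5 indicator + 4 metadata
#'   columns)
#' @export
landscape_matrix <- function(calls, meta) {
  m <- merge(calls, as.data.frame(meta), by = "sample_id", sort = FALSE)
  out <- data.frame(sample_id = m$sample_id, stringsAsFactors = FALSE)
  for (cat in .CATEGORIES) out[[cat]] <- as.integer(m[[cat]])
  out$sex <- m$sex
  out$sample_type <- m$sample_type
  out$ultrasound_period <- m$ultrasound_period
  out$phenotype_group <- m$phenotype_group
  n_cat <- rowSums(out[, .CATEGORIES])
  out <- out[order(-(n_cat > 0), -n_cat, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("landscape_matrix", "data.frame")
  out
}

#' Write / read a landscape matrix TSV
#' @param mat a `landscape_matrix`
#' @param path TSV path
#' @export
write_landscape_matrix <- function(mat, path) {
  write_tsv(as.data.frame(mat), path)
}

#' @rdname write_landscape_matrix
#' @export
read_landscape_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("landscape_matrix", "data.frame")
  df
}

#' Render a landscape heatmap (optional)
#'
#' Draws the binary category block of a [landscape_matrix()] as a heatmap
#' PNG via the pheatmap package when it is installed; otherwise errors.
#'
#' @param mat a `landscape_matrix`
#' @param path output PNG path
#' @param width,height device size in pixels
#' @return `path`, invisibly
#' @export
plot_landscape <- function(mat, path, width = 900, height = 1200) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    abort("plot_landscape needs the 'pheatmap' package")
  }
  block <- as.matrix(mat[, .CATEGORIES])
  rownames(block) <- mat$sample_id
  ann <- data.frame(
    sex = mat$sex, sample_type = mat$sample_type,
    ultrasound_period = mat$ultrasound_period,
    phenotype_group = mat$phenotype_group,
    row.names = mat$sample_id, stringsAsFactors = FALSE
  )
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(block, cluster_rows = FALSE, cluster_cols = FALSE,
                     legend = FALSE, annotation_row = ann,
                     color = c("grey95", "firebrick"),
                     show_rownames = nrow(block) <= 60)
  invisible(path)
}
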