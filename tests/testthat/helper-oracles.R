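# Independent oracles used across test files. Each is a literal, brute-force
# transcription of the rule it checks, deliberately sharing no code with the
# package implementation.

# ACMG 2015 combining rules, written as explicit boolean clauses over
# strength-class counts (pathogenic side evaluated strongest-first, then
# benign; contradiction and no-rule both give VUS)
acmg_oracle <- function(pvs, ps, pm, pp, ba, bs, bp) {
  path_tier <- NA_character_
  if ((pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
      ps >= 2 ||
      (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))) {
    path_tier <- "Pathogenic"
  } else if ((pvs >= 1 && pm >= 1) ||
             (ps >= 1 && pm >= 1) ||
             (ps >= 1 && pp >= 2) ||
             pm >= 3 ||
             (pm >= 2 && pp >= 2) ||
             (pm >= 1 && pp >= 4)) {
    path_tier <- "LikelyPathogenic"
  }
  ben_tier <- NA_character_
  if (ba >= 1 || bs >= 2) {
    ben_tier <- "Benign"
  } else if ((bs >= 1 && bp >= 1) || bp >= 2) {
    ben_tier <- "LikelyBenign"
  }
  if (!is.na(path_tier) && !is.na(ben_tier)) return("VUS")
  if (!is.na(path_tier)) return(path_tier)
  if (!is.na(ben_tier)) return(ben_tier)
  "VUS"
}

# Fisher two-sided exact p by explicit enumeration of all tables with the
# observed margins: sum the null (central hypergeometric) probabilities of
# tables no more probable than the observed one
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # row-1 total ("white")
  n <- c + d          # row-2 total ("black")
  k <- a + c          # column-1 total (drawn)
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# conditional-MLE odds ratio: solve E[A | margins, psi] = a for psi under
# Fisher's noncentral hypergeometric distribution by bisection
fisher_cmle_oracle <- function(a, b, c, d, tol = 1e-10) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  lw <- lchoose(m, support) + lchoose(n, k - support)
  e_a <- function(log_psi) {
    lp <- lw + support * log_psi
    w <- exp(lp - max(lp))
    sum(support * w) / sum(w)
  }
  if (a <= min(support)) return(0)
  if (a >= max(support)) return(Inf)
  lo <- -50; hi <- 50
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (e_a(mid) < a) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# brute-force interval scan: which panel genes overlap each cnv row
overlap_oracle <- function(cnvs, panel, containment = FALSE) {
  vapply(seq_len(nrow(cnvs)), function(i) {
    hit <- vapply(seq_len(nrow(panel)), function(j) {
      if (is.na(panel$chrom[j]) || panel$chrom[j] != cnvs$chrom[i]) return(FALSE)
      if (containment) {
        panel$start[j] >= cnvs$start[i] && panel$end[j] <= cnvs$end[i]
      } else {
        panel$start[j] <= cnvs$end[i] && panel$end[j] >= cnvs$start[i]
      }
    }, TRUE)
    paste(sort(unique(panel$gene_symbol[hit])), collapse = ",")
  }, "")
}

# set-comprehension over (candidate x panel x edge) triples
expand_oracle <- function(candidates, panel, edges, min_conf = 0.9, min_nb = 2) {
  cand <- setdiff(unique(candidates), panel)
  res <- lapply(cand, function(g) {
    partners <- character()
    for (i in seq_len(nrow(edges))) {
      if (edges$confidence[i] < min_conf) next
      if (edges$gene_a[i] == g && edges$gene_b[i] %in% panel) {
        partners <- union(partners, edges$gene_b[i])
      } else if (edges$gene_b[i] == g && edges$gene_a[i] %in% panel) {
        partners <- union(partners, edges$gene_a[i])
      }
    }
    list(gene = g, nb = length(partners))
  })
  nb <- vapply(res, function(r) r$nb, 0L)
  names(nb) <- vapply(res, function(r) r$gene, "")
  nb
}

# random small-variant table used by round-trip tests
rand_small_variants <- function(n, n_samples = 5, seed = 1) {
  set.seed(seed)
  sites <- data.frame(
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T", "AT"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T", "AG"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  # a site is (chrom,pos); keep one allele pair per site to avoid colliding
  # records that differ only in annotation
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), , drop = FALSE]
  sites <- sites[sites$ref != sites$alt, , drop = FALSE]
  n <- nrow(sites)
  df <- data.frame(
    sample_id = sprintf("S%02d", sample.int(n_samples, n, replace = TRUE)),
    chrom = sites$chrom, pos = sites$pos, id = ".",
    ref = sites$ref, alt = sites$alt,
    gene = sample(c("GENEA", "GENEB", "GENEC"), n, replace = TRUE),
    consequence = sample(c("frameshift", "missense", "nonsense"), n,
                         replace = TRUE),
    filter_status = sample(c("PASS", "LowQual"), n, replace = TRUE),
    genotype = sample(c("het", "hom"), n, replace = TRUE),
    ref_depth = sample(0:60, n, replace = TRUE),
    alt_depth = sample(1:60, n, replace = TRUE),
    evidence_codes = sample(c("PVS1,PM2", "PM2,PP3", "BS1,BS2", ""), n,
                            replace = TRUE),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$pos, df$ref, df$alt, df$sample_id), ]
}

sort_variants <- function(v) {
  v <- as.data.frame(v)
  v <- v[order(v$chrom, v$pos, v$ref, v$alt, v$sample_id), ]
  rownames(v) <- NULL
  v
}

text_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
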