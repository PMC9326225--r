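#' ACMG/AMP evidence-combination engine
#'
#' Combines ACMG/AMP evidence codes (PVS1, PS1-4, PM1-6, PP1-5 on the
#' pathogenic side; BA1, BS1-4, BP1-7 on the benign side) into a five-tier
#' call (Pathogenic, LikelyPathogenic, VUS, LikelyBenign, Benign) using the
#' 2015 combining rules, which are shipped as a plain-TSV rule table so an
#' alternative rule set can be swapped in.
#'
#' @name acmg_engine
NULL

# canonical evidence-code vocabulary; strength class is the code prefix
.ACMG_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

.TIERS <- c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic", "Pathogenic")

#' The valid ACMG evidence-code vocabulary
#' @return character vector of the 28 recognised codes
#' @export
acmg_codes <- function() .ACMG_CODES

#' Strength class of an ACMG evidence code
#' @param code character vector of codes (e.g. `"PM2"`)
#' @return character vector in `{PVS, PS, PM, PP, BA, BS, BP}`
#' @export
code_strength <- function(code) {
  validate_acmg_codes(code)
  sub("[0-9]+$", "", code)
}

validate_acmg_codes <- function(codes) {
  bad <- setdiff(codes, .ACMG_CODES)
  if (length(bad)) {
    abort("unknown ACMG evidence code(s): ", paste(bad, collapse = ", "),
          "; valid codes are: ", paste(.ACMG_CODES, collapse = " "),
          class = "chdtriage_validation_error")
  }
  invisible(codes)
}

#' Load an ACMG combining-rule table
#'
#' Each row is one combining rule: a tier plus minimum counts per strength
#' class (`pvs_min`..`bp_min`). A rule fires when every minimum is met.
#' Pathogenic-side rows are evaluated before LikelyPathogenic rows (and
#' Benign before LikelyBenign), so the strongest firing tier wins within a
#' side.
#'
#' @param path TSV path; default is the table shipped with the package
#'   (the 2015 combining rules)
#' @return data.frame with class `acmg_rules`
#' @export
load_acmg_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "acmg_combining_rules.tsv",
                        package = "chdtriage", mustWork = TRUE)
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rule_id", "side", "tier", "pvs_min", "ps_min", "pm_min",
            "pp_min", "ba_min", "bs_min", "bp_min")
  miss <- setdiff(need, names(rules))
  if (length(miss)) abort("rule table missing column(s): ", paste(miss, collapse = ", "))
  assert_in(rules$side, c("pathogenic", "benign"), "rule table side")
  assert_in(rules$tier, .TIERS, "rule table tier")
  class(rules) <- c("acmg_rules", "data.frame")
  rules
}

.default_rules_cache <- new.env(parent = emptyenv())

default_acmg_rules <- function() {
  if (is.null(.default_rules_cache$rules)) {
    .default_rules_cache$rules <- load_acmg_rules()
  }
  .default_rules_cache$rules
}

#' Classify a strength-class count signature
#'
#' Lower-level entry point of the engine: takes counts per strength class
#' rather than codes. Both a pathogenic-side and a benign-side rule firing
#' is contradictory evidence and yields VUS (`matched_rule = "conflict-VUS"`);
#' no rule firing yields VUS (`"default-VUS"`).
#'
#' @param pvs,ps,pm,pp,ba,bs,bp non-negative counts of codes per strength
#'   class
#' @param rules an `acmg_rules` table; default the shipped 2015 table
#' @return list with `tier` (one of the five tiers) and `matched_rule`
#' @export
classify_signature <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                               ba = 0, bs = 0, bp = 0, rules = NULL) {
  if (is.null(rules)) rules <- default_acmg_rules()
  counts <- c(pvs = pvs, ps = ps, pm = pm, pp = pp, ba = ba, bs = bs, bp = bp)
  if (any(counts < 0)) abort("evidence counts must be non-negative")

  fires <- rules$pvs_min <= pvs & rules$ps_min <= ps & rules$pm_min <= pm &
    rules$pp_min <= pp & rules$ba_min <= ba & rules$bs_min <= bs &
    rules$bp_min <= bp

  path_hit <- which(fires & rules$side == "pathogenic")
  ben_hit <- which(fires & rules$side == "benign")

  if (length(path_hit) && length(ben_hit)) {
    return(list(tier = "VUS", matched_rule = "conflict-VUS"))
  }
  if (length(path_hit)) {
    i <- path_hit[1L]  # table ordered strongest-first within a side
    return(list(tier = rules$tier[i], matched_rule = rules$rule_id[i]))
  }
  if (length(ben_hit)) {
    i <- ben_hit[1L]
    return(list(tier = rules$tier[i], matched_rule = rules$rule_id[i]))
  }
  list(tier = "VUS", matched_rule = "default-VUS")
}

#' Classify a set of ACMG evidence codes
#'
#' @param codes character vector of evidence codes; duplicates collapse
#'   (classification is a function of the code *set*)
#' @param rules optional `acmg_rules` table
#' @return list with `tier` and `matched_rule`
#' @examples
#' classify_evidence(c("PVS1", "PM2", "PP3"))$tier   # "Pathogenic"
#' classify_evidence(c("PVS1", "PM2"))$tier          # "LikelyPathogenic"
#' classify_evidence(character())$tier               # "VUS"
#' @export
classify_evidence <- function(codes, rules = NULL) {
  codes <- unique(as.character(codes))
  validate_acmg_codes(codes)
  cls <- sub("[0-9]+$", "", codes)
  n <- function(k) sum(cls == k)
  classify_signature(pvs = n("PVS"), ps = n("PS"), pm = n("PM"), pp = n("PP"),
                     ba = n("BA"), bs = n("BS"), bp = n("BP"), rules = rules)
}

#' Classify many code sets at once
#'
#' Vectorised convenience over [classify_evidence()] for comma-separated
#' code strings as carried in the VCF `ACMG` INFO key.
#'
#' @param code_strings character vector; each element a comma-separated set
#'   of codes (empty string = no evidence)
#' @param rules optional `acmg_rules` table
#' @return data.frame with columns `tier` and `matched_rule`
#' @export
classify_evidence_strings <- function(code_strings, rules = NULL) {
  if (is.null(rules)) rules <- default_acmg_rules()
  sets <- strsplit(code_strings, ",", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  keys <- vapply(sets, function(s) paste(sort(unique(s)), collapse = ","), "")
  uk <- unique(keys)
  res <- lapply(uk, function(k) {
    classify_evidence(if (nzchar(k)) strsplit(k, ",")[[1]] else character(), rules)
  })
  idx <- match(keys, uk)
  data.frame(
    tier = vapply(res, `[[`, "", "tier")[idx],
    matched_rule = vapply(res, `[[`, "", "matched_rule")[idx],
    stringsAsFactors = FALSE
  )
}

#' Enumerate the engine's full decision table
#'
#' Exhaustively enumerates every strength-class count vector with at most
#' `max_codes` codes (respecting the vocabulary caps: one PVS code, four PS,
#' six PM, five PP, one BA, four BS, seven BP exist) and records the tier
#' assigned to each signature. Used to cross-check the rule-table engine
#' against an independent transcription of the combining rules, and to test
#' monotonicity over the whole decision surface.
#'
#' @param max_codes maximum total number of codes per signature (<= 6)
#' @param rules optional `acmg_rules` table
#' @return data.frame with the seven count columns plus `tier`
#' @export
enumerate_rule_table <- function(max_codes = 6L, rules = NULL) {
  if (max_codes > 6L) abort("enumerate_rule_table: max_codes must be <= 6")
  caps <- c(pvs = 1L, ps = 4L, pm = 6L, pp = 5L, ba = 1L, bs = 4L, bp = 7L)
  caps <- pmin(caps, max_codes)
  grid <- expand.grid(
    pvs = 0:caps["pvs"], ps = 0:caps["ps"], pm = 0:caps["pm"],
    pp = 0:caps["pp"], ba = 0:caps["ba"], bs = 0:caps["bs"],
    bp = 0:caps["bp"], KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[rowSums(grid) <= max_codes, , drop = FALSE]
  rownames(grid) <- NULL
  res <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    classify_signature(g$pvs, g$ps, g$pm, g$pp, g$ba, g$bs, g$bp, rules)$tier
  }, character(1))
  grid$tier <- res
  grid
}

#' Five-tier vocabulary in benign-to-pathogenic order
#' @return character vector `Benign < LikelyBenign < VUS < LikelyPathogenic < Pathogenic`
#' @export
classification_tiers <- function() .TIERS
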