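#' Triage configuration
#'
#' Bundles every tunable threshold of the pipeline. The defaults are the
#' published study thresholds: alternate-allele depth of at least 5 reads and
#' heterozygous allele fraction of at least 25% for small variants, a 100 kb
#' minimum CNV size, two-sided 95% confidence intervals, and the network
#' expansion rule (at least 2 panel neighbours at interaction confidence of
#' at least 0.9).
#'
#' @param min_alt_depth minimum alternate-allele read depth (reads; default 5)
#' @param min_het_allele_fraction minimum alternate-allele fraction for
#'   heterozygous calls, in `[0,1]` (default 0.25)
#' @param min_cnv_size minimum CNV size in base pairs (default 1e5; "larger
#'   than 100K" events only)
#' @param ci_alpha two-sided error rate of the binomial CIs (default 0.05)
#' @param ci_method `"agresti-coull"` (default), `"wilson"` or
#'   `"clopper-pearson"`
#' @param or_estimator `"cmle"` (conditional maximum likelihood, default) or
#'   `"cross-product"`
#' @param net_min_confidence minimum interaction confidence for a panel edge
#'   to count, in `[0,1]` (default 0.9, inclusive)
#' @param net_min_panel_neighbors minimum number of distinct panel neighbours
#'   for a candidate gene to be retained (default 2, inclusive)
#' @param aneuploidy_span_fraction fraction of the chromosome length a CNV
#'   must span to be promoted to a whole-chromosome event (default 0.9)
#' @param cnv_gene_overlap `"overlap"` (any 1-bp overlap counts, default) or
#'   `"containment"` (panel gene interval fully inside the CNV)
#' @param random_seed integer seed used by stochastic components (default 1)
#' @return an object of class `triage_config` (a validated named list)
#' @examples
#' cfg <- triage_config()
#' cfg$min_alt_depth
#' @export
triage_config <- function(min_alt_depth = 5L,
                          min_het_allele_fraction = 0.25,
                          min_cnv_size = 100000L,
                          ci_alpha = 0.05,
                          ci_method = c("agresti-coull", "wilson", "clopper-pearson"),
                          or_estimator = c("cmle", "cross-product"),
                          net_min_confidence = 0.9,
                          net_min_panel_neighbors = 2L,
                          aneuploidy_span_fraction = 0.9,
                          cnv_gene_overlap = c("overlap", "containment"),
                          random_seed = 1L) {
  cfg <- list(
    min_alt_depth = as.integer(min_alt_depth),
    min_het_allele_fraction = as.numeric(min_het_allele_fraction),
    min_cnv_size = as.numeric(min_cnv_size),
    ci_alpha = as.numeric(ci_alpha),
    ci_method = match.arg(ci_method),
    or_estimator = match.arg(or_estimator),
    net_min_confidence = as.numeric(net_min_confidence),
    net_min_panel_neighbors = as.integer(net_min_panel_neighbors),
    aneuploidy_span_fraction = as.numeric(aneuploidy_span_fraction),
    cnv_gene_overlap = match.arg(cnv_gene_overlap),
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "triage_config"
  validate_triage_config(cfg)
}

validate_triage_config <- function(cfg) {
  fracs <- c("min_het_allele_fraction", "ci_alpha", "net_min_confidence",
             "aneuploidy_span_fraction")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      abort("triage_config: ", f, " must be a fraction in [0,1], got ", v,
            class = "chdtriage_validation_error")
    }
  }
  if (cfg$min_alt_depth < 0L) {
    abort("triage_config: min_alt_depth must be >= 0",
          class = "chdtriage_validation_error")
  }
  if (!is.finite(cfg$min_cnv_size) || cfg$min_cnv_size <= 0) {
    abort("triage_config: min_cnv_size must be > 0",
          class = "chdtriage_validation_error")
  }
  if (cfg$net_min_panel_neighbors < 0L) {
    abort("triage_config: net_min_panel_neighbors must be >= 0",
          class = "chdtriage_validation_error")
  }
  cfg
}

#' Read a triage configuration from a YAML or JSON file
#'
#' Keys present in the file override the corresponding [triage_config()]
#' defaults; unknown keys are a hard error (a typo in a threshold name must
#' not silently fall back to a default).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a `triage_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config file must be .yaml/.yml or .json: ", path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(triage_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort("unknown config key(s): ", paste(bad, collapse = ", "),
          class = "chdtriage_validation_error")
  }
  do.call(triage_config, vals)
}

#' @export
print.triage_config <- function(x, ...) {
  cat("<triage_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
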