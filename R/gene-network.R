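#' Split a candidate set on panel membership
#'
#' Candidate genes predicted elsewhere (e.g. by rare disease-causal variant
#' prioritisation) may already be in the curated panel; these are removed
#' before network expansion.
#'
#' @param candidates character vector of candidate gene symbols
#' @param panel character vector of panel gene symbols, or a `gene_panel`
#' @return list with `in_panel` and `remaining` (disjoint;
#'   `|in_panel| + |remaining| = |unique(candidates)|`)
#' @export
panel_overlap_split <- function(candidates, panel) {
  if (is.data.frame(panel)) panel <- panel$gene_symbol
  candidates <- unique(candidates)
  inp <- intersect(candidates, panel)
  list(in_panel = inp, remaining = setdiff(candidates, inp))
}

#' Expand the curated panel with network-supported candidate genes
#'
#' Retains each candidate gene (outside the panel) that interacts with at
#' least `cfg$net_min_panel_neighbors` distinct curated panel genes at
#' interaction confidence of at least `cfg$net_min_confidence`. Both
#' thresholds are inclusive ("at least 2", "no less than 0.9").
#' "Interactions" counts distinct panel partners, not edges; parallel
#' edges collapse during normalisation ([read_edges()]).
#'
#' @param candidates character vector of candidate gene symbols
#' @param panel character vector of panel gene symbols, or a `gene_panel`
#' @param edges a normalised `edge_list` (`gene_a, gene_b, confidence`)
#' @param cfg a [triage_config()]
#' @return a `panel_expansion` data.frame ranked by
#'   (`panel_neighbors` desc, `gene` asc): `gene`, `panel_neighbors`
#'   (distinct panel partners at or above the confidence threshold),
#'   `max_confidence` (strongest panel edge at any confidence; 0 when
#'   none), `retained`, `rank`
#' @export
expand_panel <- function(candidates, panel, edges, cfg = triage_config()) {
  if (is.data.frame(panel)) panel <- panel$gene_symbol
  split <- panel_overlap_split(candidates, panel)
  cand <- split$remaining

  res <- data.frame(gene = cand, panel_neighbors = 0L, max_confidence = 0,
                    stringsAsFactors = FALSE)
  if (nrow(edges) && length(cand)) {
    # orient each edge both ways, keep candidate -> panel pairs
    pair <- rbind(
      data.frame(from = edges$gene_a, to = edges$gene_b,
                 confidence = edges$confidence, stringsAsFactors = FALSE),
      data.frame(from = edges$gene_b, to = edges$gene_a,
                 confidence = edges$confidence, stringsAsFactors = FALSE)
    )
    pair <- pair[pair$from %in% cand & pair$to %in% panel, , drop = FALSE]
    if (nrow(pair)) {
      mx <- tapply(pair$confidence, pair$from, max)
      res$max_confidence[match(names(mx), res$gene)] <- as.numeric(mx)
      qual <- pair[pair$confidence >= cfg$net_min_confidence, , drop = FALSE]
      if (nrow(qual)) {
        deg <- tapply(qual$to, qual$from, function(g) length(unique(g)))
        res$panel_neighbors[match(names(deg), res$gene)] <- as.integer(deg)
      }
    }
  }
  res$retained <- res$panel_neighbors >= cfg$net_min_panel_neighbors
  res <- res[order(-res$panel_neighbors, res$gene), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "in_panel") <- split$in_panel
  class(res) <- c("panel_expansion", "data.frame")
  res
}
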