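## Overlaying gene-level association signal on the PPI network.

#' Convert a gene-level P-value to a z-score
#'
#' \eqn{z = \Phi^{-1}(1 - p)}, where \eqn{\Phi} is the standard normal
#' CDF: smaller P-values map to larger z-scores. P-values are clamped
#' into [clamp, 1 - clamp] first so that z stays finite at the extremes.
#'
#' @param p numeric vector of probabilities in (0, 1].
#' @param clamp probability floor (default 1e-12).
#' @return numeric z-scores, strictly decreasing in p on the unclamped
#'   range.
#' @examples
#' pToZ(0.5)    # 0
#' pToZ(0.025)  # ~1.96
#' @export
pToZ <- function(p, clamp = 1e-12) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("P-values must lie in (0, 1]")
  }
  # evaluate in whichever tail is small, so extreme z stay accurate
  lo <- p <= 0.5
  z <- numeric(length(p))
  z[lo] <- -stats::qnorm(pmax(p[lo], clamp))
  z[!lo] <- stats::qnorm(pmax(1 - p[!lo], clamp))
  z
}

#' Build a scored PPI network from gene-level P-values
#'
#' Nodes are the genes present in both the gene score table and the PPI
#' edge list; edges are restricted to surviving nodes. Scored genes with
#' no surviving interaction are dropped (module scores need neighbours),
#' as are edges with an unscored endpoint; counts are reported.
#'
#' @param scores data.frame from [computeGenePvalues()] (columns
#'   \code{gene_id} and \code{corrected_p}).
#' @param ppi data.frame from [readPpi()].
#' @param clamp probability clamp passed to [pToZ()].
#' @return a [ScoredNetwork-class].
#' @export
buildScoredNetwork <- function(scores, ppi, clamp = 1e-12) {
  if (anyDuplicated(scores$gene_id)) stop("duplicate gene_id in scores")
  scored <- scores$gene_id
  keepEdge <- ppi$gene_a %in% scored & ppi$gene_b %in% scored
  nDropE <- sum(!keepEdge)
  e <- ppi[keepEdge, c("gene_a", "gene_b"), drop = FALSE]
  # collapse duplicates defensively (readPpi already canonicalizes)
  ga <- pmin(e$gene_a, e$gene_b)
  gb <- pmax(e$gene_a, e$gene_b)
  key <- paste(ga, gb, sep = "\r")
  dup <- duplicated(key) | ga == gb
  ga <- ga[!dup]; gb <- gb[!dup]
  nodes <- sort(unique(c(ga, gb)))
  if (length(nodes) == 0L) {
    stop("no scored gene participates in any PPI edge")
  }
  nDropN <- sum(!(scored %in% nodes))
  if (nDropE > 0L) {
    message(nDropE, " edge(s) dropped (unscored endpoint)")
  }
  if (nDropN > 0L) {
    message(nDropN, " scored gene(s) dropped (absent or isolated in PPI)")
  }
  o <- order(ga, gb)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ga[o], to = gb[o], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  z <- pToZ(scores$corrected_p[match(nodes, scores$gene_id)], clamp)
  names(z) <- nodes
  new("ScoredNetwork", graph = g, scores = z)
}
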