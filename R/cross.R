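## Cross-dataset module pairing, top-pair selection and the consensus
## (final) module.

#' All cross-dataset module pairs with their similarity
#'
#' Computes the similarity of every (module from dataset 1, module from
#' dataset 2) pair; exactly |set1| x |set2| pairs. The similarity is
#' the Dice coefficient 2|A∩B|/(|A|+|B|) by default — the same notion
#' used for within-dataset merging — or, as an alternative reading of
#' "proportion of shared genes", the overlap coefficient
#' |A∩B|/min(|A|,|B|).
#'
#' @param set1,set2 [ModuleSet-class] objects from the two datasets.
#' @param method \code{"dice"} (default) or \code{"overlap"}.
#' @return data.frame with columns \code{i} (index into set1), \code{j}
#'   (index into set2), \code{similarity}.
#' @export
crossPairs <- function(set1, set2, method = c("dice", "overlap")) {
  method <- match.arg(method)
  if (length(set1) == 0L || length(set2) == 0L) {
    stop("both module sets must be non-empty")
  }
  g1 <- lapply(modules(set1), moduleGenes)
  g2 <- lapply(modules(set2), moduleGenes)
  universe <- sort(unique(c(unlist(g1), unlist(g2))))
  M1 <- .incidence(g1, universe)
  M2 <- .incidence(g2, universe)
  inter <- as.matrix(Matrix::tcrossprod(M1, M2))
  s1 <- lengths(g1)
  s2 <- lengths(g2)
  sim <- switch(method,
    dice = 2 * inter / outer(s1, s2, `+`),
    overlap = inter / outer(s1, s2, pmin))
  data.frame(i = rep(seq_along(g1), times = length(g2)),
             j = rep(seq_along(g2), each = length(g1)),
             similarity = as.vector(sim))
}

#' Select the K most similar cross-dataset pairs
#'
#' Returns the K pairs of largest similarity. Ties at the selection
#' boundary are broken deterministically by the lexicographic order of
#' the sorted member gene lists (dataset 1 first), then pair indices,
#' and the tie-break is reported.
#'
#' @param pairs data.frame from [crossPairs()].
#' @param K number of pairs to select (default 10).
#' @param set1,set2 the [ModuleSet-class] objects the pair indices refer
#'   to (used for the deterministic tie-break; optional — without them
#'   ties fall back to index order).
#' @return the selected rows of \code{pairs}, ordered by decreasing
#'   similarity.
#' @export
selectTopPairs <- function(pairs, K = 10L, set1 = NULL, set2 = NULL) {
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(pairs)) {
    warning("K = ", K, " exceeds the ", nrow(pairs),
            " available pairs; taking all")
    K <- nrow(pairs)
  }
  key1 <- key2 <- rep("", nrow(pairs))
  if (!is.null(set1) && !is.null(set2)) {
    k1 <- vapply(modules(set1),
                 function(m) paste(moduleGenes(m), collapse = "\r"), "")
    k2 <- vapply(modules(set2),
                 function(m) paste(moduleGenes(m), collapse = "\r"), "")
    key1 <- k1[pairs$i]
    key2 <- k2[pairs$j]
  }
  o <- order(-pairs$similarity, key1, key2, pairs$i, pairs$j)
  sel <- pairs[o[seq_len(K)], , drop = FALSE]
  if (K < nrow(pairs) &&
      pairs$similarity[o[K]] == pairs$similarity[o[K + 1L]]) {
    message("similarity tie at the selection boundary broken ",
            "deterministically")
  }
  rownames(sel) <- NULL
  sel
}

#' Merge the selected modules of one dataset
#'
#' Union of the gene sets of the given modules, with the subgraph they
#' induce in the network; the number of connected components of the
#' union is reported.
#'
#' @param mods list of [GeneModule-class] objects (one dataset's members of
#'   the selected pairs).
#' @param network the [ScoredNetwork-class].
#' @return list with \code{genes} (sorted union), \code{edges}
#'   (two-column character matrix of induced edges), \code{nComponents}.
#' @export
unionSelected <- function(mods, network) {
  genes <- sort(unique(unlist(lapply(mods, moduleGenes))))
  sub <- igraph::induced_subgraph(networkGraph(network), genes)
  comp <- igraph::components(sub)
  if (comp$no > 1L) {
    message("merged gene set spans ", comp$no, " components")
  }
  list(genes = genes, edges = .edgeMatrix(sub),
       nComponents = comp$no)
}

.edgeMatrix <- function(g) {
  e <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(e) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  ga <- pmin(e[, 1L], e[, 2L])
  gb <- pmax(e[, 1L], e[, 2L])
  o <- order(ga, gb)
  matrix(c(ga[o], gb[o]), ncol = 2L,
         dimnames = list(NULL, c("gene_a", "gene_b")))
}

#' Build the final cross-dataset consensus module
#'
#' The final module is the set of genes shared by the two merged gene
#' sets, together with the PPI edges it induces; it may be disconnected
#' (components are reported, not pruned). Per-gene statistics from both
#' datasets (z, corrected gene P, nominal-significance flag at
#' \code{alpha}) are attached when score tables are supplied.
#'
#' @param merged1,merged2 character vectors: the merged gene sets of the
#'   two datasets.
#' @param network a [ScoredNetwork-class] providing the PPI topology.
#' @param scores1,scores2 optional data.frames from
#'   [computeGenePvalues()] for the two datasets.
#' @param z1,z2 optional named z-score vectors for the two datasets
#'   (defaults to [pToZ()] of the corrected P-values).
#' @param alpha nominal significance threshold on the corrected gene P
#'   (default 0.05).
#' @param datasets character(2), labels for the two datasets.
#' @return a [FinalModule-class].
#' @export
finalModule <- function(merged1, merged2, network,
                        scores1 = NULL, scores2 = NULL,
                        z1 = NULL, z2 = NULL, alpha = 0.05,
                        datasets = c("d1", "d2")) {
  if (length(merged1) == 0L || length(merged2) == 0L) {
    stop("merged gene sets must be non-empty")
  }
  genes <- sort(intersect(merged1, merged2))
  if (length(genes) == 0L) {
    stop("empty intersection: the merged sets (", length(merged1),
         " and ", length(merged2), " genes) share no gene")
  }
  sub <- igraph::induced_subgraph(networkGraph(network), genes)
  comp <- igraph::components(sub)
  if (comp$no > 1L) {
    message("final module has ", comp$no, " components")
  }
  st <- data.frame(gene = genes, stringsAsFactors = FALSE)
  attach1 <- function(scores, z, tag) {
    if (is.null(scores)) return(NULL)
    idx <- match(genes, scores$gene_id)
    p <- scores$corrected_p[idx]
    if (is.null(z)) zz <- pToZ(p) else zz <- unname(z[genes])
    out <- data.frame(z = zz, p = p, sig = !is.na(p) & p < alpha)
    names(out) <- paste0(c("z_", "p_", "sig_"), tag)
    out
  }
  s1 <- attach1(scores1, z1, datasets[1L])
  s2 <- attach1(scores2, z2, datasets[2L])
  if (!is.null(s1)) st <- cbind(st, s1)
  if (!is.null(s2)) st <- cbind(st, s2)
  new("FinalModule", genes = genes, edges = .edgeMatrix(sub), stats = st)
}
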