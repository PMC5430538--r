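## Module significance battery: circular-permutation association,
## topology-free and connected-random-module score nulls, enrichment in
## nominally significant genes, and connectivity permutation.

#' Permutation P-value
#'
#' The add-one permutation form \eqn{(x + 1)/(n + 1)}: with \eqn{x} the
#' number of null statistics at least as extreme as the observed one out
#' of \eqn{n} samples, the P-value is bounded in \eqn{[1/(n+1), 1]} and
#' can never be zero.
#'
#' @param countGE number of null samples >= observed.
#' @param n number of null samples.
#' @return numeric probability.
#' @export
permPvalue <- function(countGE, n) {
  if (any(n < 1)) stop("need at least one null sample")
  if (any(countGE < 0) || any(countGE > n)) stop("count must lie in 0..n")
  (countGE + 1) / (n + 1)
}

#' Module association P-value by circular genomic permutation
#'
#' Tests whether the module score is higher than expected under the CGP
#' null that preserves the LD structure of the SNP statistics. For each
#' rotation offset, the module genes' best-SNP P-values are recomputed
#' under the rotated circle, corrected exactly as in
#' [computeGenePvalues()] (for a window of fixed width m, the corrected
#' P of a rotated best-P t is 1 - #\{window minima > t\}/(L+1)),
#' converted to z and scored; the P-value is
#' \eqn{(\#\{Z_{m(s)} \ge Z_m\} + 1)/(n + 1)}.
#'
#' Offsets are sampled uniformly without replacement from the L-1
#' non-identity rotations; when \code{n >= L - 1} the computation is
#' exhaustive over all of them.
#'
#' @param moduleGenes character vector of module gene ids (all must have
#'   windows).
#' @param circle a [GenomicCircle-class].
#' @param windows data.frame from [mapGeneWindows()].
#' @param n requested number of permutations (default 100000).
#' @param seed RNG seed (used only when sampling a subset of offsets).
#' @param clamp z-score clamp, see [pToZ()].
#' @return numeric P-value with attributes \code{observed} (the observed
#'   module score) and \code{n} (offsets actually used).
#' @export
assocPvalue <- function(moduleGenes, circle, windows, n = 100000L,
                        seed = NULL, clamp = 1e-12) {
  if (n < 1L) stop("n must be >= 1")
  L <- circleLength(circle)
  vals <- circleValues(circle)
  w <- windows[match(moduleGenes, windows$gene_id), , drop = FALSE]
  if (anyNA(w$start_index)) {
    stop("module gene(s) without a mapped window: ",
         paste(moduleGenes[is.na(w$start_index)], collapse = ", "))
  }
  k <- nrow(w)
  if (n >= L - 1L) {
    offsets <- seq_len(L - 1L)
  } else {
    if (!is.null(seed)) set.seed(seed)
    offsets <- sample.int(L - 1L, n)
  }
  nOff <- length(offsets)
  zMat <- matrix(0, nrow = nOff, ncol = k)
  zObs <- numeric(k)
  for (gi in seq_len(k)) {
    m <- w$m[gi]
    s <- w$start_index[gi]
    sm <- .slidingMinCircular(vals, m)
    smSorted <- sort(sm)
    # corrected P as a function of the rotated best-P t:
    # l(t) = #{window minima > t} = L - #{<= t}
    tObs <- sm[s]
    lObs <- L - findInterval(tObs, smSorted)
    zObs[gi] <- pToZ(correctedP(lObs, L), clamp)
    tRot <- sm[((s - 1L - offsets) %% L) + 1L]
    lRot <- L - findInterval(tRot, smSorted)
    zMat[, gi] <- pToZ(correctedP(lRot, L), clamp)
  }
  zmObs <- sum(zObs) / sqrt(k)
  zmNull <- rowSums(zMat) / sqrt(k)
  p <- permPvalue(sum(zmNull >= zmObs), nOff)
  attr(p, "observed") <- zmObs
  attr(p, "n") <- nOff
  p
}

#' Topology-free null module scores
#'
#' Samples \code{n} modules of \code{k} distinct genes uniformly from
#' the scored network, ignoring connectivity, and records their scores.
#'
#' @param network a [ScoredNetwork-class].
#' @param k module size.
#' @param n number of samples (default 100000).
#' @param seed RNG seed.
#' @return list with \code{scores} (numeric of length n),
#'   \code{generator = "topology_free"}, \code{n}, \code{seed}.
#' @export
topologyFreeNull <- function(network, k, n = 100000L, seed = NULL) {
  z <- unname(nodeScores(network))
  N <- length(z)
  if (k > N) stop("module size k exceeds the ", N, " network genes")
  if (!is.null(seed)) set.seed(seed)
  sq <- sqrt(k)
  scores <- vapply(seq_len(n),
                   function(i) sum(z[sample.int(N, k)]) / sq, 0)
  list(scores = scores, generator = "topology_free", n = n, seed = seed)
}

#' Sample one connected random module by Metropolis-Hastings random walk
#'
#' Degree-corrected random walk: from the current node u a uniform
#' neighbour v is proposed and accepted with probability
#' min(1, deg(u)/deg(v)) (the Metropolis correction towards a uniform
#' node stationary distribution); distinct accepted nodes are collected
#' until \code{k} are gathered. The collected set is connected by
#' construction (every node enters via an edge from the walk).
#'
#' @param network a [ScoredNetwork-class].
#' @param k module size.
#' @param start starting gene id; its connected component must hold at
#'   least k nodes.
#' @param seed RNG seed.
#' @param adj,deg optional precomputed adjacency list and degree vector.
#' @return a [GeneModule-class] of exactly k genes containing \code{start}.
#' @export
mhrwRandomModule <- function(network, k, start, seed = NULL,
                             adj = NULL, deg = NULL) {
  z <- nodeScores(network)
  if (!(start %in% names(z))) stop("start gene not in network: ", start)
  if (is.null(adj)) adj <- .adjList(network)
  if (is.null(deg)) deg <- lengths(adj)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) {
    return(new("GeneModule", genes = start,
               score = unname(z[start]), seed = start))
  }
  comp <- igraph::components(networkGraph(network))
  cid <- comp$membership[start]
  if (comp$csize[cid] < k) {
    stop("component of ", start, " has only ", comp$csize[cid],
         " nodes; cannot sample a connected module of size ", k)
  }
  collected <- start
  u <- start
  while (length(collected) < k) {
    nb <- adj[[u]]
    v <- nb[sample.int(length(nb), 1L)]
    if (stats::runif(1) <= min(1, deg[[u]] / deg[[v]])) {
      u <- v
      if (!(v %in% collected)) collected <- c(collected, v)
    }
  }
  g <- sort(collected)
  new("GeneModule", genes = g, score = moduleScore(unname(z[g])),
      seed = start)
}

#' Connected random-module null via MHRW, one walk per network gene
#'
#' Generates one connected random module of size \code{k} per network
#' node used as walk start (so N = number of network genes), records
#' their scores and gene sets; starts whose component is smaller than k
#' are skipped and reported.
#'
#' @param network a [ScoredNetwork-class].
#' @param k module size.
#' @param seed RNG seed.
#' @return list with \code{scores}, \code{moduleGenes} (list of gene
#'   sets), \code{generator = "mhrw"}, \code{n} (modules generated),
#'   \code{seed}.
#' @export
mhrwNull <- function(network, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- .adjList(network)
  deg <- lengths(adj)
  comp <- igraph::components(networkGraph(network))
  starts <- sort(networkGenes(network))
  feasible <- comp$csize[comp$membership[starts]] >= k
  if (!any(feasible)) {
    stop("no component holds ", k, " nodes; MHRW null is infeasible")
  }
  if (any(!feasible)) {
    message(sum(!feasible), " start(s) skipped (component smaller than ",
            k, ")")
  }
  starts <- starts[feasible]
  mods <- lapply(starts, function(s) {
    mhrwRandomModule(network, k, s, adj = adj, deg = deg)
  })
  list(scores = vapply(mods, moduleScore, 0),
       moduleGenes = lapply(mods, moduleGenes),
       generator = "mhrw", n = length(mods), seed = seed)
}

#' Upper tail of the hypergeometric distribution
#'
#' Probability that a module of K genes drawn from a network of N genes
#' containing n nominally significant ones holds at least k significant
#' genes: \eqn{P[X \ge k]} for X ~ Hypergeometric(N, n, K) (inclusive
#' upper tail).
#'
#' @param k observed significant genes in the module.
#' @param K module size.
#' @param n significant genes in the network.
#' @param N network size.
#' @return numeric probability.
#' @examples
#' hypergeomTail(4, 4, 5, 10)  # 5/210
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (K > N || n > N || k < 0 || k > K) {
    stop("inconsistent counts: need 0 <= k <= K <= N and n <= N")
  }
  if (k == 0) return(1)
  if (k > n) return(0)
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Enrichment of a module in nominally significant genes
#'
#' Two complementary tests that the module holds more nominally
#' significant genes than expected: the hypergeometric tail against the
#' whole network, and a permutation comparison against connected random
#' modules (\eqn{(\#\{k(s) \ge k\}+1)/(N+1)}, with k(s) the significant
#' count in each MHRW null module).
#'
#' @param moduleGenes character vector of module gene ids.
#' @param network a [ScoredNetwork-class].
#' @param sigGenes character vector of nominally significant genes
#'   (must be network nodes).
#' @param mhrwNulls result of [mhrwNull()].
#' @return named list: \code{pSigHyper}, \code{pSigMhrw}, and the counts
#'   \code{k}, \code{K}, \code{n}, \code{N}.
#' @export
sigEnrichment <- function(moduleGenes, network, sigGenes, mhrwNulls) {
  nodes <- networkGenes(network)
  if (!all(sigGenes %in% nodes)) {
    stop("sigGenes must be a subset of the network genes")
  }
  k <- length(intersect(moduleGenes, sigGenes))
  K <- length(moduleGenes)
  n <- length(sigGenes)
  N <- length(nodes)
  pH <- hypergeomTail(k, K, n, N)
  ks <- vapply(mhrwNulls$moduleGenes,
               function(g) length(intersect(g, sigGenes)), 0L)
  pM <- permPvalue(sum(ks >= k), mhrwNulls$n)
  list(pSigHyper = pH, pSigMhrw = pM, k = k, K = K, n = n, N = N)
}

#' Connectivity permutation test for the module's significant genes
#'
#' Tests whether the nominally significant genes inside the module are
#' more interconnected than significant genes outside it: \code{e} is
#' the number of network edges between significant module genes; each of
#' \code{n} samples draws the same number of genes uniformly without
#' replacement from the unselected (outside-module) significant genes
#' and counts their induced edges; P = (#\{e(s) >= e\}+1)/(n+1).
#'
#' @param moduleGenes character vector of module gene ids.
#' @param network a [ScoredNetwork-class].
#' @param sigGenes character vector of nominally significant genes.
#' @param n number of permutation samples (default 100000).
#' @param seed RNG seed.
#' @return numeric P-value with attributes \code{e} (observed edge
#'   count) and \code{n}.
#' @export
connectivityP <- function(moduleGenes, network, sigGenes, n = 100000L,
                          seed = NULL) {
  g <- networkGraph(network)
  sigIn <- intersect(sigGenes, moduleGenes)
  sigOut <- setdiff(intersect(sigGenes, networkGenes(network)),
                    moduleGenes)
  if (length(sigIn) > length(sigOut)) {
    stop("only ", length(sigOut), " significant genes outside the ",
         "module; cannot draw samples of size ", length(sigIn))
  }
  e <- igraph::ecount(igraph::induced_subgraph(g, sigIn))
  if (!is.null(seed)) set.seed(seed)
  kIn <- length(sigIn)
  nOut <- length(sigOut)
  if (kIn == 0L) {
    cnt <- n                       # every sample has e(s) = 0 >= e = 0
  } else {
    sub <- igraph::induced_subgraph(g, sigOut)
    el <- igraph::as_edgelist(sub, names = FALSE)
    ea <- el[, 1L]; eb <- el[, 2L]
    cnt <- 0L
    memb <- logical(nOut)
    for (i in seq_len(n)) {
      s <- sample.int(nOut, kIn)
      memb[s] <- TRUE
      es <- sum(memb[ea] & memb[eb])
      memb[s] <- FALSE
      if (es >= e) cnt <- cnt + 1L
    }
  }
  p <- permPvalue(cnt, n)
  attr(p, "e") <- e
  attr(p, "n") <- n
  p
}

#' Run the full significance battery for a final module
#'
#' Computes, for the given consensus module: the per-dataset association
#' P by circular genomic permutation, per-dataset module-score P against
#' topology-free and connected (MHRW) random modules, hypergeometric and
#' MHRW enrichment in nominally significant genes (corrected gene P <
#' \code{alpha} in at least one dataset), and the connectivity
#' permutation P. Sub-seeds for each sampler are derived from
#' \code{seed}.
#'
#' @param final a [FinalModule-class].
#' @param network1,network2 per-dataset [ScoredNetwork-class] objects.
#' @param circle1,circle2 per-dataset [GenomicCircle-class] objects.
#' @param windows1,windows2 per-dataset window tables.
#' @param scores1,scores2 per-dataset gene score tables.
#' @param nPerm permutation count for CGP, topology-free and
#'   connectivity nulls (default 100000).
#' @param alpha nominal significance threshold (default 0.05).
#' @param seed master RNG seed.
#' @param clamp z clamp, see [pToZ()].
#' @param datasets labels of the two datasets.
#' @return an [AssessmentReport-class].
#' @export
assessModule <- function(final, network1, network2, circle1, circle2,
                         windows1, windows2, scores1, scores2,
                         nPerm = 100000L, alpha = 0.05, seed = 1L,
                         clamp = 1e-12, datasets = c("d1", "d2")) {
  genes <- moduleGenes(final)
  k <- length(genes)
  z1 <- nodeScores(network1)
  z2 <- nodeScores(network2)
  zm1 <- moduleScore(unname(z1[genes]))
  zm2 <- moduleScore(unname(z2[genes]))

  pA1 <- assocPvalue(genes, circle1, windows1, n = nPerm,
                     seed = seed + 11L, clamp = clamp)
  pA2 <- assocPvalue(genes, circle2, windows2, n = nPerm,
                     seed = seed + 12L, clamp = clamp)

  tf1 <- topologyFreeNull(network1, k, n = nPerm, seed = seed + 21L)
  tf2 <- topologyFreeNull(network2, k, n = nPerm, seed = seed + 22L)
  pZ1 <- permPvalue(sum(tf1$scores >= zm1), tf1$n)
  pZ2 <- permPvalue(sum(tf2$scores >= zm2), tf2$n)

  mh1 <- mhrwNull(network1, k, seed = seed + 31L)
  mh2 <- mhrwNull(network2, k, seed = seed + 32L)
  pM1 <- permPvalue(sum(mh1$scores >= zm1), mh1$n)
  pM2 <- permPvalue(sum(mh2$scores >= zm2), mh2$n)

  sig1 <- scores1$gene_id[scores1$corrected_p < alpha]
  sig2 <- scores2$gene_id[scores2$corrected_p < alpha]
  nodes <- networkGenes(network1)
  sigGenes <- intersect(union(sig1, sig2), nodes)

  enr <- sigEnrichment(genes, network1, sigGenes, mh1)
  pCon <- tryCatch(
    connectivityP(genes, network1, sigGenes, n = nPerm,
                  seed = seed + 41L),
    error = function(e) {
      message("connectivity test skipped: ", conditionMessage(e))
      structure(NA_real_, e = NA_integer_, n = nPerm)
    })

  names2 <- function(x1, x2) stats::setNames(c(x1, x2), datasets)
  new("AssessmentReport",
      pAssoc = names2(as.numeric(pA1), as.numeric(pA2)),
      pZm = names2(pZ1, pZ2),
      pZmMhrw = names2(pM1, pM2),
      pSigHyper = enr$pSigHyper,
      pSigMhrw = enr$pSigMhrw,
      pCon = as.numeric(pCon),
      counts = list(k = enr$k, K = enr$K, n = enr$n, N = enr$N,
                    e = attr(pCon, "e"),
                    z_m = as.list(names2(zm1, zm2)),
                    n_assoc = names2(attr(pA1, "n"), attr(pA2, "n")),
                    n_mhrw = names2(mh1$n, mh2$n)),
      params = list(n_perm = nPerm, alpha = alpha, seed = seed,
                    clamp = clamp, datasets = as.list(datasets)))
}
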