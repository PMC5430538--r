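## Greedy dense module search (seed-and-extend on the scored PPI) and
## Dice-similarity redundancy reduction.

#' Grow a score-dense module from a seed gene
#'
#' Seed-and-extend: starting from the seed, the neighbour of the current
#' module that yields the maximum new score
#' \eqn{Z_m = \sum z_i/\sqrt{k}} is added if and only if the increment
#' is at least \code{r} times the current score
#' (\eqn{Z_{new} - Z_{old} \ge r \cdot Z_{old}}); otherwise growth
#' terminates. For a fixed module, maximizing the new score is
#' equivalent to adding the highest-z neighbour; ties are broken by
#' lexicographic gene id, making growth independent of node enumeration
#' order. The termination rule is applied literally also when the
#' current score is non-positive (where the bar \eqn{r \cdot Z_{old}}
#' is itself non-positive and score decreases can be accepted).
#'
#' @param network a [ScoredNetwork-class].
#' @param seed a gene id present in the network.
#' @param r growth ratio (default 0.1).
#' @param d candidate neighbourhood distance (default 1, the literal
#'   "neighbouring gene"; \code{d = 2} also admits genes two steps from
#'   the module, in which case the gene set is connected only through
#'   its distance-2 closure).
#' @param adj optional precomputed adjacency list (names = genes) to
#'   speed up repeated calls.
#' @return a connected [GeneModule-class] containing the seed.
#' @export
growModule <- function(network, seed, r = 0.1, d = 1L, adj = NULL) {
  z <- nodeScores(network)
  if (!(seed %in% names(z))) stop("seed gene not in network: ", seed)
  if (!(d %in% 1:2)) stop("candidate distance d must be 1 or 2")
  if (is.null(adj)) adj <- .adjList(network)
  genes <- seed
  sumz <- unname(z[seed])
  zOld <- sumz
  candidates <- function(genes) {
    cand <- unique(unlist(adj[genes], use.names = FALSE))
    if (d == 2L) {
      cand <- unique(c(cand, unlist(adj[cand], use.names = FALSE)))
    }
    setdiff(cand, genes)
  }
  repeat {
    cand <- candidates(genes)
    if (length(cand) == 0L) break
    zc <- z[cand]
    best <- cand[zc == max(zc)]
    best <- min(best)                       # lexicographic tie-break
    zNew <- (sumz + z[[best]]) / sqrt(length(genes) + 1)
    if (zNew - zOld >= r * zOld) {
      genes <- c(genes, best)
      sumz <- sumz + z[[best]]
      zOld <- zNew
    } else break
  }
  new("GeneModule", genes = sort(genes), score = zOld, seed = seed)
}

.adjList <- function(network) {
  g <- networkGraph(network)
  nm <- igraph::V(g)$name
  al <- igraph::as_adj_list(g, mode = "all")
  out <- lapply(al, function(v) nm[as.integer(v)])
  names(out) <- nm
  out
}

#' Grow a module from every seed gene of the network
#'
#' Runs [growModule()] with every network gene as seed and collapses
#' duplicate gene sets, keeping as representative the module whose seed
#' is lexicographically smallest (order-free determinism).
#'
#' @param network a [ScoredNetwork-class].
#' @param r growth ratio (default 0.1).
#' @param dataset optional dataset tag recorded on the result.
#' @return a [ModuleSet-class].
#' @export
searchAllModules <- function(network, r = 0.1, dataset = NA_character_) {
  seeds <- sort(networkGenes(network))
  if (length(seeds) == 0L) stop("network is empty")
  adj <- .adjList(network)
  grown <- lapply(seeds, function(s) growModule(network, s, r, adj = adj))
  keys <- vapply(grown, function(m) paste(m@genes, collapse = "\r"), "")
  keep <- !duplicated(keys)       # seeds sorted, so first = smallest seed
  nDup <- sum(!keep)
  if (nDup > 0L) {
    message(nDup, " duplicate module(s) collapsed (", sum(keep),
            " unique gene sets from ", length(seeds), " seeds)")
  }
  mods <- grown[keep]
  mods <- lapply(mods, function(m) { m@dataset <- dataset; m })
  new("ModuleSet", modules = mods, dataset = dataset)
}

#' Dice similarity between two gene sets
#'
#' \eqn{s(A,B) = 2|A \cap B| / (|A| + |B|)}: a similarity of r means the
#' two modules share roughly 100r% of their genes.
#'
#' @param A,B non-empty character vectors of gene ids.
#' @return similarity in [0, 1].
#' @examples
#' dice(c("a", "b", "c"), c("b", "c", "d"))  # 2/3
#' @export
dice <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L) {
    stop("Dice similarity of an empty set is undefined")
  }
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# sparse pattern incidence matrix (modules x genes) over a gene universe
.incidence <- function(geneSets, universe) {
  i <- rep.int(seq_along(geneSets), lengths(geneSets))
  j <- match(unlist(geneSets, use.names = FALSE), universe)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(geneSets), length(universe)))
}

#' Merge redundant modules within a dataset
#'
#' Hierarchically merges the most similar pair of modules (greedy
#' max-Dice-first) into its union (score recomputed on the network)
#' until every pairwise Dice similarity is below \code{threshold}.
#' Ties on similarity are broken in favour of the larger union, then the
#' lexicographically smallest combined gene list. Each merge reduces the
#' module count by one, so the procedure always terminates.
#'
#' @param moduleSet a [ModuleSet-class].
#' @param network the [ScoredNetwork-class] the modules live on (for
#'   score recomputation).
#' @param threshold Dice threshold (default 0.5).
#' @return a [ModuleSet-class] with all pairwise Dice < threshold.
#' @export
mergeRedundant <- function(moduleSet, network, threshold = 0.5) {
  z <- nodeScores(network)
  sets <- lapply(modules(moduleSet), moduleGenes)
  if (length(sets) <= 1L) return(moduleSet)
  universe <- sort(unique(unlist(sets)))
  M <- .incidence(sets, universe)
  sizes <- Matrix::rowSums(M)
  inter <- as.matrix(Matrix::tcrossprod(M))
  simOf <- function() {
    D <- 2 * inter / outer(sizes, sizes, `+`)
    diag(D) <- -1
    D
  }
  D <- simOf()
  alive <- rep(TRUE, length(sets))
  repeat {
    mx <- max(D)
    if (mx < threshold) break
    idx <- which(D == mx, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    if (nrow(idx) > 1L) {
      us <- sizes[idx[, 1L]] + sizes[idx[, 2L]] -
        inter[cbind(idx[, 1L], idx[, 2L])]
      idx <- idx[us == max(us), , drop = FALSE]
      if (nrow(idx) > 1L) {
        keys <- apply(idx, 1L, function(ij) {
          paste(sort(union(sets[[ij[1L]]], sets[[ij[2L]]])),
                collapse = "\r")
        })
        idx <- idx[order(keys, idx[, 1L], idx[, 2L]), , drop = FALSE]
      }
    }
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
    alive[j] <- FALSE
    D[j, ] <- -1
    D[, j] <- -1
    # refresh row/column i
    M[i, ] <- as.numeric(universe %in% sets[[i]])
    sizes[i] <- length(sets[[i]])
    newInter <- as.vector(M %*% M[i, ])
    inter[i, ] <- newInter
    inter[, i] <- newInter
    Drow <- 2 * newInter / (sizes[i] + sizes)
    Drow[!alive] <- -1
    Drow[i] <- -1
    D[i, ] <- Drow
    D[, i] <- Drow
  }
  kept <- which(alive)
  mods <- lapply(kept, function(i) {
    g <- sets[[i]]
    new("GeneModule", genes = g, score = moduleScore(unname(z[g])),
        seed = NA_character_, dataset = moduleSet@dataset)
  })
  # drop duplicated gene sets that merging may have produced
  keys <- vapply(mods, function(m) paste(m@genes, collapse = "\r"), "")
  mods <- mods[!duplicated(keys)]
  new("ModuleSet", modules = mods, dataset = moduleSet@dataset)
}
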