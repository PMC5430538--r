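## Synthetic study generator: two parallel GWAS datasets with
## LD-blocked P-values, a tiling gene annotation, a scale-free PPI and a
## planted connected high-score module shared (noisily) by both
## datasets. This is what the package's end-to-end tests run on.

#' Simulation configuration
#'
#' Defaults describe the standard synthetic study: ~20,000 SNPs on 10
#' chromosomes, 500 genes tiling them in consecutive SNP intervals, a
#' 1,000-node preferential-attachment PPI, and a planted module of 12
#' connected genes whose best SNPs get a +4 shift of their latent
#' association score, with 20% of planted genes carrying signal in only
#' one of the two datasets. LD is modelled as block-equicorrelation of
#' the latent standard-normal scores (correlation \code{ldRho} within
#' blocks of \code{ldBlockSize} SNPs) — enough to create the gene-length
#' bias the circular-permutation correction removes.
#'
#' @param nSnpsPerChrom integer vector, SNPs per chromosome.
#' @param nGenes number of genes.
#' @param geneLengthRange integer(2), min/max gene length in SNPs.
#' @param geneGapRange integer(2), min/max intergenic gap in SNPs.
#' @param ldBlockSize SNPs per correlated block.
#' @param ldRho within-block correlation of latent scores, in [0, 1).
#' @param ppiNodes number of PPI nodes (>= nGenes; the excess are
#'   unannotated proteins that drop out of the scored network).
#' @param edgesPerNode preferential-attachment edges per added node.
#' @param plantedSize number of planted module genes (0 disables).
#' @param plantedEffect mean shift of the latent score of each planted
#'   gene's causal SNP.
#' @param overlapNoise fraction of planted genes carrying signal in only
#'   one dataset.
#' @param seed RNG seed.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nSnpsPerChrom = rep(2000L, 10L),
                             nGenes = 500L,
                             geneLengthRange = c(10L, 30L),
                             geneGapRange = c(0L, 5L),
                             ldBlockSize = 20L,
                             ldRho = 0.8,
                             ppiNodes = 1000L,
                             edgesPerNode = 10L,
                             plantedSize = 12L,
                             plantedEffect = 4,
                             overlapNoise = 0.2,
                             seed = 1L) {
  cfg <- list(nSnpsPerChrom = as.integer(nSnpsPerChrom),
              nGenes = as.integer(nGenes),
              geneLengthRange = as.integer(geneLengthRange),
              geneGapRange = as.integer(geneGapRange),
              ldBlockSize = as.integer(ldBlockSize),
              ldRho = ldRho,
              ppiNodes = as.integer(ppiNodes),
              edgesPerNode = as.integer(edgesPerNode),
              plantedSize = as.integer(plantedSize),
              plantedEffect = plantedEffect,
              overlapNoise = overlapNoise,
              seed = as.integer(seed))
  if (any(cfg$nSnpsPerChrom < 1L) || length(cfg$nSnpsPerChrom) > 22L) {
    stop("nSnpsPerChrom must be positive counts for at most 22 autosomes")
  }
  if (cfg$ldRho < 0 || cfg$ldRho >= 1) stop("ldRho must lie in [0, 1)")
  if (cfg$overlapNoise < 0 || cfg$overlapNoise > 1) {
    stop("overlapNoise must lie in [0, 1]")
  }
  if (cfg$plantedSize > cfg$nGenes || cfg$nGenes > cfg$ppiNodes) {
    stop("need plantedSize <= nGenes <= ppiNodes")
  }
  if (cfg$edgesPerNode < 1L || cfg$edgesPerNode + 1L > cfg$ppiNodes) {
    stop("edgesPerNode infeasible for ppiNodes")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a pair of parallel GWAS datasets with a planted module
#'
#' Per dataset, each SNP gets a latent standard-normal score with
#' block-equicorrelation (LD); the causal SNP of each planted gene is
#' shifted by \code{plantedEffect} in the datasets where that gene
#' carries signal; one-sided P-values are the upper-tail probabilities
#' of the latent scores. Genes tile the chromosomes in consecutive,
#' non-overlapping SNP intervals. Fully deterministic per seed.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{snps1}, \code{snps2} (SNP association
#'   data.frames sorted by (chrom, pos)), \code{genes} (annotation
#'   data.frame) and \code{truth} (list: \code{planted} gene ids,
#'   \code{signal1}, \code{signal2} named logical flags,
#'   \code{causalSnp} named indices).
#' @export
simulateGwasPair <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nChrom <- length(config$nSnpsPerChrom)
  L <- sum(config$nSnpsPerChrom)
  chrom <- rep(seq_len(nChrom), config$nSnpsPerChrom)
  posIn <- unlist(lapply(config$nSnpsPerChrom, seq_len))
  pos <- posIn * 1000L
  snpId <- paste0("rs", chrom, "_", posIn)

  # tile genes into consecutive SNP intervals, never crossing chromosomes
  gl <- sample(config$geneLengthRange[1L]:config$geneLengthRange[2L],
               config$nGenes, replace = TRUE)
  gaps <- sample(config$geneGapRange[1L]:config$geneGapRange[2L],
                 config$nGenes, replace = TRUE)
  chromEnd <- cumsum(config$nSnpsPerChrom)
  chromOf <- function(i) findInterval(i - 1L, chromEnd) + 1L
  starts <- integer(config$nGenes)
  ends <- integer(config$nGenes)
  cur <- 1L
  for (i in seq_len(config$nGenes)) {
    cur <- cur + gaps[i]
    # move to next chromosome if the gene would cross the boundary
    while (cur <= L && chromOf(cur) != chromOf(min(cur + gl[i] - 1L, L))) {
      cur <- chromEnd[chromOf(cur)] + 1L
    }
    if (cur + gl[i] - 1L > L) {
      stop("infeasible config: ran out of SNPs while placing gene ", i)
    }
    starts[i] <- cur
    ends[i] <- cur + gl[i] - 1L
    cur <- ends[i] + 1L
  }
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(config$nGenes)),
                      chrom = chrom[starts],
                      start = pos[starts], end = pos[ends],
                      stringsAsFactors = FALSE)

  # planted truth
  if (config$plantedSize > 0L) {
    planted <- sort(sample(genes$gene_id, config$plantedSize))
    oneOnly <- stats::runif(config$plantedSize) < config$overlapNoise
    which1 <- stats::runif(config$plantedSize) < 0.5
    signal1 <- !oneOnly | which1
    signal2 <- !oneOnly | !which1
    names(signal1) <- names(signal2) <- planted
    pi <- match(planted, genes$gene_id)
    causal <- starts[pi] + floor(stats::runif(config$plantedSize) *
                                 (ends[pi] - starts[pi] + 1L))
    names(causal) <- planted
  } else {
    planted <- character()
    signal1 <- signal2 <- logical()
    causal <- integer()
  }

  latent <- function(signalFlags) {
    bs <- config$ldBlockSize
    block <- rep(seq_len(ceiling(L / bs)), each = bs)[seq_len(L)]
    # blocks are nested within chromosomes in index order; a block that
    # straddles a chromosome boundary only correlates neighbouring
    # statistics, which is all the LD model needs
    shared <- stats::rnorm(max(block))
    x <- sqrt(config$ldRho) * shared[block] +
      sqrt(1 - config$ldRho) * stats::rnorm(L)
    on <- names(signalFlags)[signalFlags]
    x[causal[on]] <- x[causal[on]] + config$plantedEffect
    x
  }
  mkSnps <- function(x) {
    data.frame(snp_id = snpId, chrom = chrom, pos = pos,
               p = stats::pnorm(x, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  snps1 <- mkSnps(latent(signal1))
  snps2 <- mkSnps(latent(signal2))
  list(snps1 = snps1, snps2 = snps2, genes = genes,
       truth = list(planted = planted, signal1 = signal1,
                    signal2 = signal2, causalSnp = causal))
}

#' Simulate a scale-free PPI with a connected planted subgraph
#'
#' Preferential-attachment (Barabasi-Albert) graph over
#' \code{ppiNodes} identifiers, seeded from a clique of
#' \code{edgesPerNode + 1} nodes, so the base graph has exactly
#' \code{(ppiNodes - m0) * edgesPerNode + choose(m0, 2)} edges
#' (m0 = clique size). Node labels are a random permutation of the gene
#' ids plus unannotated protein ids. The planted genes are then
#' connected by adding a random spanning tree among them, guaranteeing
#' they induce a connected subgraph. Deterministic per seed (uses
#' \code{config$seed + 1}).
#'
#' @param config a [simulationConfig()].
#' @param genes gene annotation data.frame from [simulateGwasPair()].
#' @param truth planted-truth list from [simulateGwasPair()].
#' @return a PPI edge data.frame (\code{gene_a}, \code{gene_b},
#'   \code{evidence = "exp"}), canonicalized.
#' @export
simulatePpi <- function(config, genes, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  n <- config$ppiNodes
  m0 <- config$edgesPerNode + 1L
  g <- igraph::sample_pa(n, power = 1, m = config$edgesPerNode,
                         directed = FALSE,
                         start.graph = igraph::make_full_graph(m0))
  ids <- c(genes$gene_id,
           sprintf("X%04d", seq_len(n - nrow(genes))))
  igraph::V(g)$name <- sample(ids)
  planted <- truth$planted
  if (length(planted) > 1L) {
    ord <- sample(planted)
    newFrom <- ord[-1L]
    newTo <- vapply(seq_along(newFrom), function(i) {
      ord[sample.int(i, 1L)]       # random recursive tree
    }, "")
    g <- igraph::add_edges(g, rbind(newFrom, newTo))
    g <- igraph::simplify(g)
  }
  e <- igraph::as_edgelist(g, names = TRUE)
  ga <- pmin(e[, 1L], e[, 2L])
  gb <- pmax(e[, 1L], e[, 2L])
  o <- order(ga, gb)
  data.frame(gene_a = ga[o], gene_b = gb[o], evidence = "exp",
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper around [simulateGwasPair()] and [simulatePpi()].
#'
#' @param config a [simulationConfig()].
#' @return list with \code{snps1}, \code{snps2}, \code{genes},
#'   \code{ppi}, \code{truth}.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  sim <- simulateGwasPair(config)
  sim$ppi <- simulatePpi(config, sim$genes, sim$truth)
  sim
}
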