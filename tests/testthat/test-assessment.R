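test_that("permutation P-values keep the add-one form and bounds", {
  expect_equal(permPvalue(0, 9), 0.1)
  expect_equal(permPvalue(9, 9), 1)
  expect_error(permPvalue(10, 9), "0..n")
  expect_error(permPvalue(0, 0), "at least one")
  set.seed(1)
  n <- sample(1:1000, 20)
  x <- vapply(n, function(m) sample(0:m, 1), 0L)
  p <- permPvalue(x, n)
  expect_true(all(p >= 1 / (n + 1) & p <= 1))
})

test_that("association P matches the exhaustive rotation oracle", {
  set.seed(21)
  L <- 12L
  vals <- round(runif(L), 2)
  snps <- data.frame(snp_id = sprintf("s%d", 1:L), chrom = 1L,
                     pos = (1:L) * 100L, p = vals)
  circ <- buildCircle(snps)
  w <- data.frame(gene_id = c("g1", "g2"), chrom = 1L,
                  start_index = c(1L, 6L), m = c(3L, 4L),
                  best_p = c(min(vals[1:3]), min(vals[6:9])))
  # independent oracle: enumerate every non-identity rotation explicitly
  zm <- function(d) {
    zs <- vapply(1:2, function(gi) {
      idx <- ((w$start_index[gi] - 1L + 0:(w$m[gi] - 1L) - d) %% L) + 1L
      pb <- min(vals[idx])
      l <- bruteRotationCount(vals, w$m[gi], pb)
      pToZ(correctedP(l, L))
    }, 0)
    sum(zs) / sqrt(2)
  }
  obs <- zm(0L)
  nullScores <- vapply(1:(L - 1L), zm, 0)
  pRef <- (sum(nullScores >= obs) + 1) / L
  p <- assocPvalue(c("g1", "g2"), circ, w, n = 100000L)
  expect_equal(as.numeric(p), pRef)
  expect_equal(attr(p, "n"), L - 1L)
  expect_equal(attr(p, "observed"), obs)

  # flat P-values: every rotation gives the same score, P = 1
  flat <- buildCircle(transform(snps, p = 0.5))
  wf <- transform(w, best_p = 0.5)
  expect_equal(as.numeric(assocPvalue(c("g1", "g2"), flat, wf,
                                      n = 1000L)), 1)
  expect_error(assocPvalue("g1", circ, w, n = 0L), ">= 1")
  expect_error(assocPvalue("absent", circ, w), "without a mapped window")
})

test_that("subsampled association offsets are reproducible by seed", {
  set.seed(31)
  L <- 200L
  vals <- runif(L)
  snps <- data.frame(snp_id = sprintf("s%d", 1:L), chrom = 1L,
                     pos = (1:L) * 10L, p = vals)
  circ <- buildCircle(snps)
  w <- data.frame(gene_id = "g1", chrom = 1L, start_index = 5L, m = 10L,
                  best_p = min(vals[5:14]))
  p1 <- assocPvalue("g1", circ, w, n = 50L, seed = 7L)
  p2 <- assocPvalue("g1", circ, w, n = 50L, seed = 7L)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "n"), 50L)
})

test_that("topology-free nulls sample uniformly and bound their P", {
  net <- toyNetwork(rbind(c("a", "b")), c(a = 1, b = 3))
  # k = node count: every sample is the whole network
  tf <- topologyFreeNull(net, 2, n = 50, seed = 1)
  expect_true(all(tf$scores == moduleScore(c(1, 3))))
  # k = 1 on two nodes: each node drawn with frequency ~ 1/2
  tf1 <- topologyFreeNull(net, 1, n = 10000, seed = 2)
  fa <- mean(tf1$scores == 1)
  expect_lt(abs(fa - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(topologyFreeNull(net, 3, n = 10), "exceeds")
  # P formula bounds for an arbitrary observation
  p <- permPvalue(sum(tf1$scores >= 2), tf1$n)
  expect_gte(p, 1 / (tf1$n + 1))
  expect_lte(p, 1)
})

test_that("MHRW modules are connected, sized and feasibility-checked", {
  edges <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("x", "y"))
  net <- toyNetwork(edges, c(a = 1, b = 1, c = 1, d = 1, x = 1, y = 1))
  m1 <- mhrwRandomModule(net, 1, "a", seed = 1)
  expect_equal(moduleGenes(m1), "a")
  # whole component is the only connected 4-set on the path
  m4 <- mhrwRandomModule(net, 4, "a", seed = 1)
  expect_equal(moduleGenes(m4), c("a", "b", "c", "d"))
  expect_error(mhrwRandomModule(net, 3, "x", seed = 1), "component")
  set.seed(5)
  for (i in 1:20) {
    m <- mhrwRandomModule(net, 3, "b")
    expect_equal(length(m), 3L)
    sub <- igraph::induced_subgraph(networkGraph(net), moduleGenes(m))
    expect_equal(igraph::components(sub)$no, 1L)
  }
})

test_that("the MHRW null uses one start per node and floors its P", {
  set.seed(8)
  g <- igraph::sample_gnp(50, 0.12)
  igraph::V(g)$name <- sprintf("v%02d", 1:50)
  g <- igraph::simplify(g)
  keep <- igraph::components(g)$membership ==
    which.max(igraph::components(g)$csize)
  g <- igraph::induced_subgraph(g, which(keep))
  z <- setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  net <- new("ScoredNetwork", graph = g, scores = z)
  nn <- igraph::vcount(g)
  mh <- mhrwNull(net, 4, seed = 3)
  expect_equal(mh$n, nn)
  # all z equal: every null score equals any observed module score
  expect_true(all(mh$scores == moduleScore(rep(1, 4))))
  expect_equal(permPvalue(sum(mh$scores >= moduleScore(rep(1, 4))), mh$n), 1)
  expect_equal(permPvalue(0, mh$n), 1 / (mh$n + 1))
})

test_that("the hypergeometric tail matches draw enumeration", {
  expect_equal(hypergeomTail(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeomTail(0, 4, 5, 10), 1)
  expect_equal(hypergeomTail(3, 4, 2, 10), 0)   # k > n impossible
  expect_error(hypergeomTail(5, 4, 5, 10), "inconsistent")

  # enumeration oracle over all C(N, K) draws on small instances
  set.seed(13)
  for (i in 1:10) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:K, 1)
    draws <- utils::combn(N, K)
    tail <- mean(colSums(draws <= n) >= k)   # items 1..n are "significant"
    expect_equal(hypergeomTail(k, K, n, N), tail,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    # inclusive tail and lower CDF partition exactly
    if (k >= 1) {
      expect_equal(hypergeomTail(k, K, n, N) +
                     phyper(k - 1, n, N - n, K), 1)
    }
  }
})

test_that("significance enrichment combines both null families", {
  edges <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"))
  net <- toyNetwork(edges, c(a = 3, b = 3, c = 0, d = 0, e = 0))
  mh <- mhrwNull(net, 2, seed = 4)
  # module holding every significant gene while no null module does
  mhNone <- list(moduleGenes = list(c("c", "d"), c("d", "e")), n = 2)
  enr <- sigEnrichment(c("a", "b"), net, c("a", "b"), mhNone)
  expect_equal(enr$pSigMhrw, 1 / 3)
  expect_equal(enr$k, 2L)
  expect_equal(enr$pSigHyper, hypergeomTail(2, 2, 2, 5))
  # no significant genes at all: k = 0, hypergeometric tail is 1
  enr0 <- sigEnrichment(c("a", "b"), net, character(), mh)
  expect_equal(enr0$pSigHyper, 1)
  expect_error(sigEnrichment("a", net, "zz", mh), "subset")
})

test_that("connectivity permutation matches subset enumeration", {
  # 8-node toy: module genes m1-m2 adjacent; outside significant genes
  # o1..o4 with edges o1-o2, o2-o3
  edges <- rbind(c("m1", "m2"), c("o1", "o2"), c("o2", "o3"),
                 c("m1", "o4"), c("m2", "o1"))
  z <- setNames(rep(1, 8), c("m1", "m2", "o1", "o2", "o3", "o4", "u1", "u2"))
  net <- toyNetwork(rbind(edges, c("u1", "u2")), z)
  modGenes <- c("m1", "m2")
  sig <- c("m1", "m2", "o1", "o2", "o3", "o4")
  # exact tail: choose 2 of 4 outside genes, count pairs with >= 1 edge
  subs <- utils::combn(c("o1", "o2", "o3", "o4"), 2)
  eobs <- 1L
  tailExact <- mean(apply(subs, 2, function(s) {
    sum(paste(pmin(s[1], s[2]), pmax(s[1], s[2])) %in%
          c("o1 o2", "o2 o3")) >= eobs
  }))
  p <- connectivityP(modGenes, net, sig, n = 20000L, seed = 6)
  expect_equal(attr(p, "e"), 1L)
  phat <- (as.numeric(p) * 20001 - 1) / 20000
  expect_lt(abs(phat - tailExact),
            3 * sqrt(tailExact * (1 - tailExact) / 20000))

  # e = 0: every sample qualifies
  p0 <- connectivityP("u1", net, c("u1", "o1", "o3", "o4"), n = 100L)
  expect_equal(as.numeric(p0), 1)
  # pairwise non-adjacent outside genes with e >= 1: minimum P
  pMin <- connectivityP(modGenes, net, c("m1", "m2", "o3", "o4", "u1"),
                        n = 200L, seed = 6)
  expect_equal(as.numeric(pMin), 1 / 201)
  expect_error(connectivityP(modGenes, net, c("m1", "m2", "o1")),
               "outside")
})

test_that("the full battery returns coherent bounded statistics", {
  set.seed(15)
  sim <- simulateStudy(simulationConfig(
    nSnpsPerChrom = rep(400L, 4L), nGenes = 60L, ppiNodes = 120L,
    geneLengthRange = c(5L, 12L), plantedSize = 6L, seed = 2L))
  fc1 <- suppressMessages(fastCGP(sim$snps1, sim$genes))
  fc2 <- suppressMessages(fastCGP(sim$snps2, sim$genes))
  net1 <- suppressMessages(buildScoredNetwork(fc1$scores, sim$ppi))
  net2 <- suppressMessages(buildScoredNetwork(fc2$scores, sim$ppi))
  common <- intersect(networkGenes(net1), networkGenes(net2))
  gsub <- igraph::induced_subgraph(networkGraph(net1), common)
  cmp <- igraph::components(gsub)
  big <- names(cmp$membership)[cmp$membership == which.max(cmp$csize)]
  genes <- sort(big[1:4])
  fin <- suppressMessages(
    finalModule(genes, genes, net1, scores1 = fc1$scores,
                scores2 = fc2$scores))
  rep <- suppressMessages(
    assessModule(fin, net1, net2, fc1$circle, fc2$circle, fc1$windows,
                 fc2$windows, fc1$scores, fc2$scores, nPerm = 500L,
                 seed = 42L))
  expect_s4_class(rep, "AssessmentReport")
  for (p in c(rep@pAssoc, rep@pZm, rep@pZmMhrw, rep@pSigHyper,
              rep@pSigMhrw, rep@pCon)) {
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  expect_equal(rep@counts$K, 4L)
  expect_gte(min(rep@pZmMhrw), 1 / (min(unlist(rep@counts$n_mhrw)) + 1))
})
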