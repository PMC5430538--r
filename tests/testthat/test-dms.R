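test_that("the module score is the z sum over root module size", {
  expect_equal(moduleScore(2.0), 2.0)
  expect_equal(moduleScore(c(1, 1, 1, 1)), 2.0)
  expect_equal(moduleScore(c(3, 1)), 4 / sqrt(2))
  expect_error(moduleScore(numeric()), "empty")
})

test_that("growth accepts and rejects by the 10% increment rule", {
  # seed z=2 with neighbours 1.0 and 0.5: best new score (2+1)/sqrt(2)
  # = 2.1213, increment 0.1213 < 0.2 -> stays a singleton
  net <- toyNetwork(rbind(c("s", "n1"), c("s", "n2")),
                    c(s = 2, n1 = 1, n2 = 0.5))
  m <- growModule(net, "s", r = 0.1)
  expect_equal(moduleGenes(m), "s")
  expect_equal(moduleScore(m), 2)

  # seed z=1 with sole neighbour z=3: 4/sqrt(2) = 2.83 >= 1.1 -> joins
  net2 <- toyNetwork(rbind(c("s", "n1")), c(s = 1, n1 = 3))
  m2 <- growModule(net2, "s", r = 0.1)
  expect_setequal(moduleGenes(m2), c("s", "n1"))
  expect_equal(moduleScore(m2), 4 / sqrt(2))

  # isolated seed
  net3 <- toyNetwork(rbind(c("a", "b")), c(a = 1, b = 1, iso = 0.7))
  m3 <- growModule(net3, "iso")
  expect_equal(moduleGenes(m3), "iso")
  expect_equal(moduleScore(m3), 0.7)

  expect_error(growModule(net3, "nope"), "not in network")
})

test_that("distance-2 candidates reach genes one hop beyond the module", {
  # strong gene g2 sits two steps from the seed behind a weak bridge:
  # unreachable at d = 1, collected at d = 2
  net <- toyNetwork(rbind(c("s", "w"), c("w", "g2")),
                    c(s = 2, w = -3, g2 = 5))
  m1 <- growModule(net, "s", r = 0.1, d = 1L)
  expect_equal(moduleGenes(m1), "s")
  m2 <- growModule(net, "s", r = 0.1, d = 2L)
  expect_true("g2" %in% moduleGenes(m2))
  expect_error(growModule(net, "s", d = 3L), "d must be")
})

test_that("accepted growth steps respect the increment bound", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    g <- igraph::sample_gnp(n, 0.15)
    igraph::V(g)$name <- sprintf("v%02d", 1:n)
    z <- setNames(rnorm(n), igraph::V(g)$name)
    net <- new("ScoredNetwork", graph = igraph::simplify(g), scores = z)
    for (s in sample(names(z), 5)) {
      m <- growModule(net, s, r = 0.1)
      expect_true(s %in% moduleGenes(m))
      sub <- igraph::induced_subgraph(networkGraph(net), moduleGenes(m))
      expect_equal(igraph::components(sub)$no, 1L)
      expect_equal(moduleScore(m),
                   moduleScore(unname(z[moduleGenes(m)])))
    }
  }
})

test_that("all-seed search enumerates deterministically and dedupes", {
  # path a-b-c with z = (3, -5, 3): a and c stay singletons (adding b
  # loses too much); b grows by the literal rule on negative scores:
  # (-5+3)/sqrt(2) = -1.41 >= -5.5 -> accepted, then (-2+3)/sqrt(3) =
  # 0.577 >= 1.1*(-1.41) -> accepted: module {a,b,c}
  net <- toyNetwork(rbind(c("a", "b"), c("b", "c")),
                    c(a = 3, b = -5, c = 3))
  ms <- searchAllModules(net, r = 0.1)
  keys <- sort(vapply(modules(ms),
                      function(m) paste(moduleGenes(m), collapse = ","), ""))
  expect_equal(keys, c("a", "a,b,c", "c"))

  # all-negative star: every growth stops immediately
  star <- toyNetwork(rbind(c("h", "l1"), c("h", "l2"), c("h", "l3")),
                     c(h = -1, l1 = -1, l2 = -1, l3 = -1))
  mstar <- searchAllModules(star, r = 0.1)
  expect_equal(sort(vapply(modules(mstar), length, 0L)), rep(1L, 4))

  # identical outcomes from two seeds collapse to one module
  pair <- toyNetwork(rbind(c("x", "y")), c(x = 2, y = 2))
  expect_message(mp <- searchAllModules(pair, r = 0.1), "collapsed")
  expect_equal(length(mp), 1L)
  expect_equal(moduleGenes(modules(mp)[[1]]), c("x", "y"))
})

test_that("Dice similarity is the exact overlap ratio", {
  expect_equal(dice(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(dice(c("a", "b"), c("a", "b")), 1)
  expect_equal(dice("a", "b"), 0)
  expect_error(dice(character(), "a"), "empty")
})

test_that("redundancy merging reaches the all-pairs threshold", {
  net <- toyNetwork(rbind(c("a", "b"), c("b", "c"), c("c", "d")),
                    c(a = 1, b = 1, c = 1, d = 1))
  mk <- function(g) new("GeneModule", genes = sort(g),
                        score = moduleScore(rep(1, length(g))),
                        seed = NA_character_)
  ms <- new("ModuleSet", modules = list(mk(c("a", "b", "c")),
                                        mk(c("a", "b", "d"))))
  merged <- mergeRedundant(ms, net, threshold = 0.5)
  expect_equal(length(merged), 1L)
  expect_equal(moduleGenes(modules(merged)[[1]]), c("a", "b", "c", "d"))

  # disjoint modules are untouched
  ms2 <- new("ModuleSet", modules = list(mk(c("a", "b")), mk(c("c", "d"))))
  m2 <- mergeRedundant(ms2, net, threshold = 0.5)
  expect_equal(length(m2), 2L)

  # overlapping chain: converges with all pairwise Dice < 0.5
  ms3 <- new("ModuleSet", modules = list(mk(c("a", "b")), mk(c("b", "c")),
                                         mk(c("c", "d"))))
  m3 <- mergeRedundant(ms3, net, threshold = 0.5)
  gs <- lapply(modules(m3), moduleGenes)
  if (length(gs) > 1L) {
    for (i in seq_along(gs)) for (j in seq_len(i - 1L)) {
      expect_lt(dice(gs[[i]], gs[[j]]), 0.5)
    }
  }
  expect_lt(length(m3), 3L)   # at least one merge happened (Dice 0.5)
})

test_that("merging random module collections satisfies the contract", {
  set.seed(77)
  n <- 40
  g <- igraph::sample_gnp(n, 0.2)
  igraph::V(g)$name <- sprintf("v%02d", 1:n)
  z <- setNames(rnorm(n), igraph::V(g)$name)
  net <- new("ScoredNetwork", graph = igraph::simplify(g), scores = z)
  raw <- suppressMessages(searchAllModules(net, r = 0.1))
  merged <- mergeRedundant(raw, net, threshold = 0.5)
  gs <- lapply(modules(merged), moduleGenes)
  if (length(gs) > 1L) {
    for (i in seq_along(gs)) for (j in seq_len(i - 1L)) {
      expect_lt(dice(gs[[i]], gs[[j]]), 0.5)
    }
  }
  # unions of overlapping connected modules stay connected
  for (m in modules(merged)) {
    sub <- igraph::induced_subgraph(networkGraph(net), moduleGenes(m))
    expect_equal(igraph::components(sub)$no, 1L)
    expect_equal(moduleScore(m), moduleScore(unname(z[moduleGenes(m)])))
  }
})
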