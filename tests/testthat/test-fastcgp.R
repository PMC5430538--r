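test_that("the circle preserves genome order and rejects bad input", {
  circ <- buildCircle(tinySnps())
  expect_equal(circleValues(circ), c(.9, .1, .5))
  expect_equal(circleLength(circ), 3L)
  one <- buildCircle(tinySnps()[1, ])
  expect_equal(circleLength(one), 1L)
  expect_error(buildCircle(tinySnps()[c(2, 1, 3), ]), "sorted")
  expect_error(buildCircle(tinySnps()[0, ]), "zero SNPs")
})

test_that("gene windows are consecutive intervals with the best P", {
  circ <- buildCircle(tinySnps())
  genes <- data.frame(gene_id = c("G1", "G2", "G3"),
                      chrom = c(1L, 1L, 3L),
                      start = c(50L, 50L, 1L),
                      end = c(150L, 250L, 1000000L))
  expect_message(w <- mapGeneWindows(circ, genes), "1 gene")
  expect_equal(nrow(w), 2L)
  expect_equal(w$start_index, c(1L, 1L))
  expect_equal(w$m, c(1L, 2L))
  expect_equal(w$best_p, c(.9, .1))
})

test_that("analytical rotation count equals brute-force enumeration", {
  v <- c(.9, .8, .05, .5, .7, .6, .95, .4)
  expect_equal(countValidRotations(v, 2, .05), 6L)
  expect_equal(countValidRotations(v, 2, .05), bruteRotationCount(v, 2, .05))
  # threshold at the maximum: no window can exceed it
  expect_equal(countValidRotations(v, 3, max(v)), 0L)
  # m = 1 below the minimum: every rotation qualifies
  expect_equal(countValidRotations(v, 1, min(v) / 2), 8L)
  expect_error(countValidRotations(v, 9, .5), "m must satisfy")

  set.seed(101)
  for (i in 1:60) {
    L <- sample(4:80, 1)
    vals <- round(runif(L), 3)      # rounding forces frequent ties
    m <- sample(1:L, 1)
    thr <- if (runif(1) < .5) vals[sample(L, 1)] else runif(1)
    expect_equal(countValidRotations(vals, m, thr),
                 bruteRotationCount(vals, m, thr),
                 info = sprintf("L=%d m=%d thr=%g", L, m, thr))
  }
})

test_that("multi-interval rotation count matches its brute-force oracle", {
  set.seed(11)
  for (i in 1:30) {
    L <- sample(10:60, 1)
    vals <- round(runif(L), 2)
    idx <- sort(sample(L, sample(2:min(8, L), 1)))
    thr <- vals[sample(L, 1)]
    expect_equal(countValidRotationsGeneric(vals, idx, thr),
                 bruteRotationCountGeneric(vals, idx, thr))
  }
  # consecutive index sets agree with the contiguous-window count
  vals <- runif(20)
  expect_equal(countValidRotationsGeneric(vals, 4:9, 0.3),
               countValidRotations(vals, 6, 0.3))
})

test_that("the corrected P formula is exact and bounded", {
  expect_equal(correctedP(6, 8), 1 / 3)
  expect_equal(correctedP(0, 8), 1)
  expect_equal(correctedP(8, 8), 1 / 9)
  expect_error(correctedP(9, 8), "0..L")
})

test_that("batch gene P-values equal the per-gene analytical path", {
  set.seed(202)
  L <- 300L
  vals <- round(runif(L), 3)
  snps <- data.frame(snp_id = sprintf("s%d", 1:L), chrom = 1L,
                     pos = (1:L) * 10L, p = vals)
  circ <- buildCircle(snps)
  G <- 30L
  st <- sample(1:L, G)
  m <- pmin(sample(1:40, G, replace = TRUE), L - st + 1L)
  w <- data.frame(gene_id = sprintf("g%02d", 1:G), chrom = 1L,
                  start_index = st, m = m,
                  best_p = vapply(1:G, function(i) {
                    min(vals[st[i]:(st[i] + m[i] - 1L)])
                  }, 0))
  res <- computeGenePvalues(circ, w)
  for (i in 1:G) {
    lRef <- bruteRotationCount(vals, w$m[i], w$best_p[i], w$start_index[i])
    expect_equal(res$l[i], lRef, info = paste("gene", i))
  }
  expect_equal(res$corrected_p, correctedP(res$l, L))
})

test_that("a gene holding the unique global minimum has P = (m+1)/(L+1)", {
  set.seed(303)
  for (i in 1:20) {
    L <- sample(30:200, 1)
    vals <- runif(L, 0.1, 1)
    m <- sample(1:10, 1)
    s <- sample(1:(L - m + 1L), 1)
    hit <- s + sample(0:(m - 1L), 1)
    vals[hit] <- 0.01              # unique global minimum inside window
    l <- countValidRotations(vals, m, vals[hit])
    expect_equal(correctedP(l, L), (m + 1) / (L + 1))
  }
})

test_that("rotation counts are monotone in window size and threshold", {
  set.seed(404)
  vals <- runif(60)
  thr <- 0.2
  ls <- vapply(1:60, function(m) countValidRotations(vals, m, thr), 0L)
  expect_true(all(diff(ls) <= 0))
  expect_true(all(diff(correctedP(ls, 60)) >= 0))
  thrs <- sort(runif(15))
  lt <- vapply(thrs, function(t) countValidRotations(vals, 5, t), 0L)
  expect_true(all(diff(lt) <= 0))  # larger threshold, fewer windows
  expect_true(all(diff(correctedP(lt, 60)) >= 0))
})

test_that("corrected P is bounded and window self-containment caps l", {
  set.seed(505)
  L <- 100L
  vals <- runif(L)
  for (i in 1:20) {
    m <- sample(1:30, 1)
    s <- sample(1:(L - m + 1L), 1)
    pg <- min(vals[s:(s + m - 1L)])
    l <- countValidRotations(vals, m, pg)
    p <- correctedP(l, L)
    expect_gte(p, 1 / (L + 1))
    expect_lte(p, 1)
    # the m rotations placing the window's own best inside it all fail
    expect_lte(l, L - m)
  }
})
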