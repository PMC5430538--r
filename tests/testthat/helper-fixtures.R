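# Shared fixtures and independent oracles (brute-force reference
# implementations kept free of the code paths they check).

# Brute-force rotation count: enumerate all L cyclic shifts explicitly
# and test whether the window minimum strictly exceeds the threshold.
bruteRotationCount <- function(values, m, thr, startIdx = 1L) {
  L <- length(values)
  sum(vapply(0:(L - 1L), function(d) {
    idx <- ((startIdx - 1L + 0:(m - 1L) - d) %% L) + 1L
    min(values[idx]) > thr
  }, TRUE))
}

# Brute-force rotation count for an arbitrary index set.
bruteRotationCountGeneric <- function(values, indices, thr) {
  L <- length(values)
  sum(vapply(0:(L - 1L), function(d) {
    idx <- ((indices - 1L - d) %% L) + 1L
    min(values[idx]) > thr
  }, TRUE))
}

# Construct a ScoredNetwork directly from an edge list and named
# z-scores (bypassing the p-value route, for score-controlled tests).
toyNetwork <- function(edges, z) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  miss <- setdiff(names(z), igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  g <- igraph::simplify(g)
  new("ScoredNetwork", graph = g, scores = z[igraph::V(g)$name])
}

# A small circle fixture: 3 SNPs on two chromosomes.
tinySnps <- function() {
  data.frame(snp_id = c("a", "b", "c"),
             chrom = c(1L, 1L, 2L), pos = c(100L, 200L, 50L),
             p = c(.9, .1, .5), stringsAsFactors = FALSE)
}

writeTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
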