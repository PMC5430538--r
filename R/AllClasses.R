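#' @import methods
NULL

#' GenomicCircle: genome-ordered SNP P-values on a circle
#'
#' All autosomal SNP association P-values arranged in genome order
#' (chromosome-major, position-minor) on a circle of length \code{L}, the
#' total number of SNPs. Rotating the values around this circle preserves
#' the local correlation (LD) structure of neighbouring statistics, which
#' is what the circular genomic permutation (CGP) null exploits.
#'
#' Circle indices are 1-based throughout.
#'
#' @slot snpId character, SNP identifiers.
#' @slot chrom integer, chromosome codes (autosomes 1-22).
#' @slot pos integer, base-pair positions (1-based).
#' @slot values numeric, association P-values in (0, 1], circle order.
#'
#' @seealso [buildCircle()], [mapGeneWindows()], [computeGenePvalues()]
#' @export
setClass("GenomicCircle",
  representation(
    snpId = "character",
    chrom = "integer",
    pos = "integer",
    values = "numeric"
  )
)

setValidity("GenomicCircle", function(object) {
  L <- length(object@values)
  if (L < 1L) return("circle must contain at least one SNP")
  if (length(object@chrom) != L || length(object@pos) != L ||
      length(object@snpId) != L) {
    return("snpId, chrom, pos and values must have equal length")
  }
  if (anyNA(object@values) || any(object@values <= 0) ||
      any(object@values > 1)) {
    return("P-values must lie in (0, 1]")
  }
  if (any(object@chrom < 1L) || any(object@chrom > 22L)) {
    return("chromosomes must be autosomal (1-22)")
  }
  o <- order(object@chrom, object@pos)
  if (!identical(o, seq_len(L))) {
    return("SNPs must be sorted by (chromosome, position)")
  }
  if (anyDuplicated(paste(object@chrom, object@pos))) {
    return("(chromosome, position) must be unique")
  }
  TRUE
})

#' ScoredNetwork: a PPI network with gene z-scores on its nodes
#'
#' A simple undirected protein-protein interaction graph whose nodes are
#' genes carrying a finite z-score, z = Phi^-1(1 - p), derived from the
#' gene-level corrected P-value p.
#'
#' @slot graph an \pkg{igraph} graph; simple, undirected, named vertices.
#' @slot scores named numeric, z-score per node (names match vertices).
#'
#' @seealso [buildScoredNetwork()], [nodeScores()], [networkGenes()]
#' @export
setClass("ScoredNetwork",
  representation(graph = "ANY", scores = "numeric")
)

setValidity("ScoredNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    return("graph must be simple (no self-loops, no parallel edges)")
  }
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyDuplicated(nm)) {
    return("vertices must carry unique names")
  }
  z <- object@scores
  if (!setequal(names(z), nm) || length(z) != length(nm)) {
    return("scores must be named exactly by the vertex names")
  }
  if (anyNA(z) || any(!is.finite(z))) return("every node needs a finite z")
  TRUE
})

#' Module: a scored gene set grown on a ScoredNetwork
#'
#' A non-empty set of genes with module score
#' \eqn{Z_m = \sum_i z_i / \sqrt{k}} (k = number of genes). Raw modules
#' produced by the dense module search are connected in their network and
#' remember their seed gene; merged modules have no single seed.
#'
#' @slot genes character, the member genes (stored sorted).
#' @slot score numeric scalar, \eqn{Z_m}.
#' @slot seed character scalar, originating seed gene (NA for merged).
#' @slot dataset character scalar, tag of the dataset that produced it.
#'
#' @seealso [growModule()], [searchAllModules()], [moduleScore()]
#' @export
setClass("GeneModule",
  representation(
    genes = "character",
    score = "numeric",
    seed = "character",
    dataset = "character"
  ),
  prototype(seed = NA_character_, dataset = NA_character_)
)

setValidity("GeneModule", function(object) {
  if (length(object@genes) < 1L) return("module must contain >= 1 gene")
  if (anyDuplicated(object@genes)) return("module genes must be unique")
  if (length(object@score) != 1L || is.na(object@score)) {
    return("score must be a single non-NA number")
  }
  if (length(object@seed) != 1L || length(object@dataset) != 1L) {
    return("seed and dataset must be scalars")
  }
  TRUE
})

#' ModuleSet: a collection of modules on one network
#'
#' @slot modules list of [GeneModule-class] objects, no two with identical
#'   gene sets.
#' @slot dataset character scalar, dataset tag.
#'
#' @seealso [searchAllModules()], [mergeRedundant()]
#' @export
setClass("ModuleSet",
  representation(modules = "list", dataset = "character"),
  prototype(dataset = NA_character_)
)

setValidity("ModuleSet", function(object) {
  if (!all(vapply(object@modules, is, TRUE, class2 = "GeneModule"))) {
    return("all elements must be Module objects")
  }
  keys <- vapply(object@modules,
                 function(m) paste(sort(m@genes), collapse = "\r"), "")
  if (anyDuplicated(keys)) return("duplicate gene sets are not allowed")
  TRUE
})

#' FinalModule: the cross-dataset consensus module
#'
#' Gene set obtained by intersecting the merged top-pair modules of the
#' two datasets, together with its induced PPI edges and per-dataset gene
#' statistics (z-score, corrected P, nominal-significance flag).
#'
#' @slot genes character, the consensus genes (sorted).
#' @slot edges two-column character matrix of induced PPI edges.
#' @slot stats data.frame of per-gene, per-dataset statistics.
#'
#' @seealso [finalModule()], [assessModule()], [writeModuleReport()]
#' @export
setClass("FinalModule",
  representation(genes = "character", edges = "matrix",
                 stats = "data.frame")
)

setValidity("FinalModule", function(object) {
  if (length(object@genes) < 1L) return("final module must be non-empty")
  if (anyDuplicated(object@genes)) return("genes must be unique")
  e <- object@edges
  if (ncol(e) != 2L) return("edges must be a two-column matrix")
  if (nrow(e) > 0L && !all(e %in% object@genes)) {
    return("edge endpoints must be module genes")
  }
  TRUE
})

#' AssessmentReport: the module significance battery
#'
#' Holds the six significance statistics computed for a final module:
#' per-dataset association P by circular genomic permutation
#' (\code{pAssoc}), per-dataset module-score P against topology-free
#' (\code{pZm}) and connected random modules (\code{pZmMhrw}),
#' hypergeometric and random-module enrichment in nominally significant
#' genes (\code{pSigHyper}, \code{pSigMhrw}), and the connectivity
#' permutation P (\code{pCon}), with the counts and sampler parameters
#' behind them.
#'
#' @slot pAssoc named numeric, per dataset.
#' @slot pZm named numeric, per dataset.
#' @slot pZmMhrw named numeric, per dataset.
#' @slot pSigHyper numeric scalar.
#' @slot pSigMhrw numeric scalar.
#' @slot pCon numeric scalar.
#' @slot counts list: k, K, n, N, e.
#' @slot params list of sampler parameters and seeds.
#'
#' @seealso [assessModule()]
#' @export
setClass("AssessmentReport",
  representation(
    pAssoc = "numeric", pZm = "numeric", pZmMhrw = "numeric",
    pSigHyper = "numeric", pSigMhrw = "numeric", pCon = "numeric",
    counts = "list", params = "list"
  )
)

setValidity("AssessmentReport", function(object) {
  ok <- function(p) all(p >= 0 & p <= 1, na.rm = TRUE)
  if (!ok(object@pAssoc) || !ok(object@pZm) || !ok(object@pZmMhrw) ||
      !ok(object@pSigHyper) || !ok(object@pSigMhrw) || !ok(object@pCon)) {
    return("all P-values must lie in [0, 1]")
  }
  TRUE
})
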