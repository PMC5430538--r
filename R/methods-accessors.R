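#' @rdname GenomicCircle-class
#' @export
setMethod("circleLength", "GenomicCircle", function(x) length(x@values))

#' @rdname GenomicCircle-class
#' @export
setMethod("circleValues", "GenomicCircle", function(x) x@values)

#' @describeIn GenomicCircle-class number of SNPs on the circle
#' @export
setMethod("length", "GenomicCircle", function(x) length(x@values))

#' @rdname GenomicCircle-class
#' @export
setMethod("show", "GenomicCircle", function(object) {
  cat("GenomicCircle with", length(object@values), "SNPs on",
      length(unique(object@chrom)), "chromosomes\n")
  cat("  P-value range: [", format(min(object@values), digits = 3), ", ",
      format(max(object@values), digits = 3), "]\n", sep = "")
})

#' @rdname ScoredNetwork-class
#' @export
setMethod("networkGraph", "ScoredNetwork", function(x) x@graph)

#' @rdname ScoredNetwork-class
#' @export
setMethod("networkGenes", "ScoredNetwork",
          function(x) igraph::V(x@graph)$name)

#' @rdname ScoredNetwork-class
#' @export
setMethod("nodeScores", "ScoredNetwork", function(x) x@scores)

#' @rdname ScoredNetwork-class
#' @export
setMethod("show", "ScoredNetwork", function(object) {
  cat("ScoredNetwork with", igraph::vcount(object@graph), "genes and",
      igraph::ecount(object@graph), "interactions\n")
  cat("  z-score range: [", format(min(object@scores), digits = 3), ", ",
      format(max(object@scores), digits = 3), "]\n", sep = "")
})

#' @rdname GeneModule-class
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)

#' @rdname GeneModule-class
#' @export
setMethod("moduleScore", "GeneModule", function(x) x@score)

#' @rdname moduleScore
#' @export
setMethod("moduleScore", "numeric", function(x) {
  if (length(x) == 0L) stop("module score of an empty set is undefined")
  sum(x) / sqrt(length(x))
})

#' @rdname GeneModule-class
#' @export
setMethod("moduleSeed", "GeneModule", function(x) x@seed)

#' @rdname GeneModule-class
#' @export
setMethod("length", "GeneModule", function(x) length(x@genes))

#' @rdname GeneModule-class
#' @export
setMethod("show", "GeneModule", function(object) {
  cat("Module of", length(object@genes), "genes, Z_m =",
      format(object@score, digits = 4))
  if (!is.na(object@seed)) cat(", seed", object@seed)
  if (!is.na(object@dataset)) cat(" [", object@dataset, "]", sep = "")
  cat("\n")
})

#' @rdname ModuleSet-class
#' @export
setMethod("modules", "ModuleSet", function(x) x@modules)

#' @rdname ModuleSet-class
#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

#' @rdname ModuleSet-class
#' @export
setMethod("show", "ModuleSet", function(object) {
  k <- vapply(object@modules, function(m) length(m@genes), 0L)
  cat("ModuleSet of", length(object@modules), "modules")
  if (!is.na(object@dataset)) cat(" [", object@dataset, "]", sep = "")
  if (length(k)) {
    cat("; sizes ", min(k), "-", max(k), sep = "")
  }
  cat("\n")
})

#' @rdname FinalModule-class
#' @export
setMethod("moduleGenes", "FinalModule", function(x) x@genes)

#' @rdname FinalModule-class
#' @export
setMethod("moduleEdges", "FinalModule", function(x) x@edges)

#' @rdname FinalModule-class
#' @export
setMethod("geneStats", "FinalModule", function(x) x@stats)

#' @rdname FinalModule-class
#' @export
setMethod("length", "FinalModule", function(x) length(x@genes))

#' @rdname FinalModule-class
#' @export
setMethod("show", "FinalModule", function(object) {
  cat("FinalModule of", length(object@genes), "genes with",
      nrow(object@edges), "interactions\n")
})

#' @rdname AssessmentReport-class
#' @export
setMethod("show", "AssessmentReport", function(object) {
  fmt <- function(p) paste(format(p, digits = 3), collapse = " / ")
  cat("AssessmentReport\n")
  cat("  P_assoc      :", fmt(object@pAssoc), "\n")
  cat("  P_zm         :", fmt(object@pZm), "\n")
  cat("  P_zm (MHRW)  :", fmt(object@pZmMhrw), "\n")
  cat("  P_sig (hyper):", fmt(object@pSigHyper), "\n")
  cat("  P_sig (MHRW) :", fmt(object@pSigMhrw), "\n")
  cat("  P_con        :", fmt(object@pCon), "\n")
})
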