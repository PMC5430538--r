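#' @rdname GenomicCircle-class
#' @param x,object a \code{GenomicCircle}
#' @export
setGeneric("circleLength", function(x) standardGeneric("circleLength"))

#' @rdname GenomicCircle-class
#' @export
setGeneric("circleValues", function(x) standardGeneric("circleValues"))

#' @rdname ScoredNetwork-class
#' @param x,object a \code{ScoredNetwork}
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname ScoredNetwork-class
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @rdname ScoredNetwork-class
#' @export
setGeneric("nodeScores", function(x) standardGeneric("nodeScores"))

#' Module score
#'
#' The score of a module of \eqn{k} genes is
#' \eqn{Z_m = \sum_{i} z_i / \sqrt{k}}: a high score means the member
#' genes carry jointly strong association signal. Applied to a bare
#' numeric vector of z-scores it computes the score; applied to a
#' [GeneModule-class] it returns the stored score.
#'
#' @param x numeric vector of z-scores, or a \code{Module}.
#' @return a single numeric score.
#' @examples
#' moduleScore(c(1, 1, 1, 1))  # 2
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' @rdname GeneModule-class
#' @param x,object a \code{Module}
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname GeneModule-class
#' @export
setGeneric("moduleSeed", function(x) standardGeneric("moduleSeed"))

#' @rdname ModuleSet-class
#' @param x,object a \code{ModuleSet}
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname FinalModule-class
#' @param x,object a \code{FinalModule}
#' @export
setGeneric("moduleEdges", function(x) standardGeneric("moduleEdges"))

#' @rdname FinalModule-class
#' @export
setGeneric("geneStats", function(x) standardGeneric("geneStats"))
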