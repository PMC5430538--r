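## End-to-end orchestration: gene P-values -> scored networks -> dense
## module search -> cross-dataset selection -> significance battery.

#' Pipeline configuration
#'
#' Defaults are the method's standard operating parameters: growth ratio
#' 0.1, merge threshold 0.5, top 10 cross-dataset pairs, 100,000
#' permutations, nominal alpha 0.05.
#'
#' @param r dense-module-search growth ratio.
#' @param mergeThreshold Dice threshold for within-dataset merging.
#' @param topK number of cross-dataset pairs selected.
#' @param minModuleSize smallest merged module admitted to cross-dataset
#'   pairing (default 4). Stalled growths leave size-1 to size-3
#'   remnants whose cross-dataset Dice trivially saturates at 1 whenever
#'   the same remnant arises in both datasets, which would crowd every
#'   genuine pair out of the top-K selection; module-pair similarity is
#'   only meaningful for modules large enough that perfect overlap is
#'   non-trivial.
#' @param nPerm permutation count for the assessment samplers.
#' @param alpha nominal significance threshold on corrected gene P.
#' @param zClamp probability clamp for the z transform.
#' @param seed master RNG seed.
#' @param datasets labels for the two datasets.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(r = 0.1, mergeThreshold = 0.5, topK = 10L,
                           minModuleSize = 4L,
                           nPerm = 100000L, alpha = 0.05,
                           zClamp = 1e-12, seed = 1L,
                           datasets = c("d1", "d2")) {
  cfg <- list(r = r, mergeThreshold = mergeThreshold,
              topK = as.integer(topK),
              minModuleSize = as.integer(minModuleSize),
              nPerm = as.integer(nPerm),
              alpha = alpha, zClamp = zClamp, seed = as.integer(seed),
              datasets = datasets)
  if (cfg$r < 0 || cfg$mergeThreshold <= 0 || cfg$mergeThreshold > 1 ||
      cfg$topK < 1L || cfg$nPerm < 1L || cfg$alpha <= 0 ||
      cfg$alpha >= 1) {
    stop("invalid pipeline configuration")
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full network-assisted analysis
#'
#' Executes, for two parallel GWAS datasets sharing one gene annotation
#' and one PPI: exact circular-permutation gene P-values, z-scored
#' networks, per-dataset dense module search with redundancy merging,
#' cross-dataset pairing and top-pair selection, the consensus module,
#' and the significance battery. Fully reproducible given the seed.
#'
#' @param snps1,snps2 SNP association data.frames (as from
#'   [readSnpAssociations()]).
#' @param genes gene annotation data.frame.
#' @param ppi PPI edge data.frame (as from [readPpi()]).
#' @param config a [pipelineConfig()].
#' @param outdir optional directory; when given, intermediate artifacts
#'   (gene scores, merged modules, the module report and a provenance
#'   record) are written there.
#' @return list with \code{final} ([FinalModule-class]), \code{report}
#'   ([AssessmentReport-class]), per-dataset \code{scores},
#'   \code{networks}, \code{mergedModules}, the selected \code{pairs}
#'   and a \code{provenance} list.
#' @export
runPipeline <- function(snps1, snps2, genes, ppi,
                        config = pipelineConfig(), outdir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  ds <- config$datasets

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fc1 <- stage("fastcgp", fastCGP(snps1, genes))
  fc2 <- stage("fastcgp", fastCGP(snps2, genes))

  net1 <- stage("score-network",
                buildScoredNetwork(fc1$scores, ppi, config$zClamp))
  net2 <- stage("score-network",
                buildScoredNetwork(fc2$scores, ppi, config$zClamp))

  raw1 <- stage("dms", searchAllModules(net1, config$r, dataset = ds[1L]))
  raw2 <- stage("dms", searchAllModules(net2, config$r, dataset = ds[2L]))
  mg1 <- stage("dms", mergeRedundant(raw1, net1, config$mergeThreshold))
  mg2 <- stage("dms", mergeRedundant(raw2, net2, config$mergeThreshold))

  bigEnough <- function(ms) {
    keep <- Filter(function(m) length(m) >= config$minModuleSize,
                   modules(ms))
    if (length(keep) == 0L) {
      warning("no merged module reaches minModuleSize = ",
              config$minModuleSize, "; pairing all modules")
      return(ms)
    }
    new("ModuleSet", modules = keep, dataset = ms@dataset)
  }
  pg1 <- bigEnough(mg1)
  pg2 <- bigEnough(mg2)
  pairs <- stage("cross-select", crossPairs(pg1, pg2))
  sel <- stage("cross-select",
               selectTopPairs(pairs, config$topK, pg1, pg2))
  u1 <- stage("cross-select",
              unionSelected(modules(pg1)[unique(sel$i)], net1))
  u2 <- stage("cross-select",
              unionSelected(modules(pg2)[unique(sel$j)], net2))
  fin <- stage("cross-select",
               finalModule(u1$genes, u2$genes, net1,
                           scores1 = fc1$scores, scores2 = fc2$scores,
                           z1 = nodeScores(net1), z2 = nodeScores(net2),
                           alpha = config$alpha, datasets = ds))

  report <- stage("assess",
                  assessModule(fin, net1, net2, fc1$circle, fc2$circle,
                               fc1$windows, fc2$windows,
                               fc1$scores, fc2$scores,
                               nPerm = config$nPerm,
                               alpha = config$alpha,
                               seed = config$seed, clamp = config$zClamp,
                               datasets = ds))

  provenance <- list(
    package = "cgpnet",
    version = as.character(utils::packageVersion("cgpnet")),
    config = unclass(config),
    inputs = list(n_snps = c(nrow(snps1), nrow(snps2)),
                  n_genes = nrow(genes), n_ppi_edges = nrow(ppi)),
    n_raw_modules = c(length(raw1), length(raw2)),
    n_merged_modules = c(length(mg1), length(mg2)),
    n_cross_pairs = nrow(pairs),
    selected_similarities = sel$similarity
  )

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    wScore <- function(s, tag) {
      utils::write.table(s, file.path(outdir,
                                      paste0("gene_pvalues_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wScore(fc1$scores, ds[1L])
    wScore(fc2$scores, ds[2L])
    wMods <- function(ms, tag) {
      df <- data.frame(
        module_id = seq_along(modules(ms)),
        genes = vapply(modules(ms),
                       function(m) paste(moduleGenes(m), collapse = ","),
                       ""),
        z_m = vapply(modules(ms), moduleScore, 0))
      utils::write.table(df, file.path(outdir,
                                       paste0("modules_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wMods(mg1, ds[1L])
    wMods(mg2, ds[2L])
    writeModuleReport(fin, net1, report, outdir)
    jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(final = fin, report = report,
       scores = stats::setNames(list(fc1$scores, fc2$scores), ds),
       networks = stats::setNames(list(net1, net2), ds),
       mergedModules = stats::setNames(list(mg1, mg2), ds),
       pairs = sel, provenance = provenance)
}
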