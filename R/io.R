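## Reading and writing of GWAS summary statistics, gene annotations and
## PPI edge lists; all coordinates are 1-based inclusive, autosomes only.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read GWAS SNP-level summary statistics
#'
#' Reads a table of SNP association results (identifier, chromosome,
#' position, P-value), validates it and returns it sorted in genome order
#' (chromosome-major, position-minor) — the order in which the SNPs are
#' later placed on the genomic circle.
#'
#' @param path path to a delimited text file with a header line.
#'   Tab-, comma- or whitespace-separated files are auto-detected.
#' @param dialect named character vector mapping the canonical column
#'   names \code{snp}, \code{chr}, \code{pos}, \code{p} to the column
#'   names used in the file.
#' @return a \code{data.frame} with columns \code{snp_id}, \code{chrom}
#'   (integer 1-22), \code{pos} (integer), \code{p} (numeric in (0, 1]),
#'   sorted by (chrom, pos).
#' @details Rows with non-autosomal chromosome codes, P-values outside
#'   (0, 1], or duplicated (chromosome, position) coordinates are
#'   rejected with an informative error; the rotation logic is positional
#'   so coordinates are the primary key.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tchr\tpos\tp", "rs1\t1\t100\t0.5"), f)
#' readSnpAssociations(f)
#' @export
readSnpAssociations <- function(path,
                                dialect = c(snp = "snp", chr = "chr",
                                            pos = "pos", p = "p")) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("snp", "chr", "pos", "p")
  if (!all(need %in% names(dialect))) {
    stop("dialect must map all of: ", paste(need, collapse = ", "))
  }
  sep <- .detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(dialect[need]), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    snp_id = as.character(df[[dialect[["snp"]]]]),
    chrom = suppressWarnings(as.integer(df[[dialect[["chr"]]]])),
    pos = suppressWarnings(as.integer(df[[dialect[["pos"]]]])),
    p = as.numeric(df[[dialect[["p"]]]]),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$chrom) | out$chrom < 1L | out$chrom > 22L)
  if (length(bad)) {
    stop("non-autosomal or unparseable chromosome code at row ", bad[1L],
         " (chromosomes must be 1-22)")
  }
  bad <- which(is.na(out$p) | out$p <= 0 | out$p > 1)
  if (length(bad)) {
    stop("P-value outside (0, 1] at row ", bad[1L])
  }
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (chromosome, position) coordinate: ", d)
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write GWAS SNP-level summary statistics
#'
#' @param snps data.frame as returned by [readSnpAssociations()].
#' @param path output path (tab-separated, canonical header).
#' @return invisibly, the path.
#' @export
writeSnpAssociations <- function(snps, path) {
  out <- data.frame(snp = snps$snp_id, chr = snps$chrom, pos = snps$pos,
                    p = snps$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene annotations
#'
#' Reads gene intervals used to map SNPs to genes. Two dialects are
#' supported: a header-named table with columns \code{gene}, \code{chr},
#' \code{start}, \code{end}, or a headerless BED-like four-column file
#' (\code{chr start end gene}) whose basedness is declared by
#' \code{zeroBased}.
#'
#' @param path path to the annotation file.
#' @param format \code{"tsv"} (header with named columns) or \code{"bed"}
#'   (headerless chr/start/end/gene).
#' @param zeroBased logical; for \code{format = "bed"}, whether starts are
#'   0-based half-open (converted to 1-based inclusive on read).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive).
#' @export
readGeneAnnotations <- function(path, format = c("tsv", "bed"),
                                zeroBased = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (length(readLines(path, n = 1L)) == 0L) {
    warning("empty gene annotation file: ", path)
    return(data.frame(gene_id = character(), chrom = integer(),
                      start = integer(), end = integer()))
  }
  if (format == "tsv") {
    sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    need <- c("gene", "chr", "start", "end")
    if (!all(need %in% names(df))) {
      stop("annotation must have columns: ", paste(need, collapse = ", "))
    }
    out <- data.frame(gene_id = as.character(df$gene),
                      chrom = as.integer(df$chr),
                      start = as.integer(df$start),
                      end = as.integer(df$end),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED-like annotation needs 4 columns")
    out <- data.frame(gene_id = as.character(df[[4L]]),
                      chrom = as.integer(df[[1L]]),
                      start = as.integer(df[[2L]]) + as.integer(zeroBased),
                      end = as.integer(df[[3L]]),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id: ", out$gene_id[duplicated(out$gene_id)][1L])
  }
  bad <- which(out$start > out$end)
  if (length(bad)) {
    stop("start > end for gene ", out$gene_id[bad[1L]])
  }
  out
}

#' Write gene annotations (canonical header dialect)
#' @param genes data.frame as returned by [readGeneAnnotations()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGeneAnnotations <- function(genes, path) {
  out <- data.frame(gene = genes$gene_id, chr = genes$chrom,
                    start = genes$start, end = genes$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Reads an undirected PPI edge list with two identifier columns and an
#' optional evidence tag. Edges are canonicalized (unordered pairs),
#' self-loops are dropped, parallel edges collapsed, and — when an
#' evidence filter is supplied — only edges whose tag belongs to the
#' filter survive (e.g. keeping experimentally supported interactions
#' only).
#'
#' @param path path to a 2-3 column whitespace/tab file (no header), or a
#'   SIF file (\code{A relation B}) when \code{format = "sif"}.
#' @param evidenceFilter optional character vector of evidence tags to
#'   keep; \code{NULL} keeps all edges.
#' @param format \code{"tsv"} (gene_a gene_b [evidence]) or \code{"sif"}.
#' @return data.frame with columns \code{gene_a}, \code{gene_b} (ordered
#'   so that \code{gene_a < gene_b}) and \code{evidence}.
#' @export
readPpi <- function(path, evidenceFilter = NULL,
                    format = c("tsv", "sif")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      evidence = character()))
  }
  toks <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(toks)
  if (format == "sif") {
    bad <- which(nf != 3L)
    if (length(bad)) stop("unparseable SIF line ", bad[1L], " in ", path)
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 3L)
    ev <- vapply(toks, `[[`, "", 2L)
  } else {
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad)) stop("unparseable line ", bad[1L], " in ", path)
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 2L)
    ev <- vapply(toks, function(t) if (length(t) >= 3L) t[[3L]] else NA_character_, "")
  }
  if (!is.null(evidenceFilter)) {
    keep <- !is.na(ev) & ev %in% evidenceFilter
    a <- a[keep]; b <- b[keep]; ev <- ev[keep]
  }
  loops <- a == b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]; b <- b[!loops]; ev <- ev[!loops]
  }
  ga <- pmin(a, b)
  gb <- pmax(a, b)
  key <- paste(ga, gb, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " parallel edge(s) collapsed")
  data.frame(gene_a = ga[!dup], gene_b = gb[!dup],
             evidence = ev[!dup], stringsAsFactors = FALSE)
}

#' Write a PPI edge list
#' @param ppi data.frame as returned by [readPpi()].
#' @param path output path (tab-separated, no header).
#' @return invisibly, the path.
#' @export
writePpi <- function(ppi, path) {
  ev <- ppi$evidence
  ev[is.na(ev)] <- ""
  lines <- ifelse(nzchar(ev),
                  paste(ppi$gene_a, ppi$gene_b, ev, sep = "\t"),
                  paste(ppi$gene_a, ppi$gene_b, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the final-module report
#'
#' Writes three files into \code{outdir}: \code{module_genes.tsv} (per
#' gene: z-score, corrected gene P and nominal-significance flag in each
#' dataset), \code{module_edges.tsv} (the PPI edges induced by the module)
#' and \code{module_report.json} (all significance statistics, counts and
#' sampler parameters). Output ordering is deterministic, so a rerun with
#' identical inputs produces byte-identical files.
#'
#' @param module a [FinalModule-class].
#' @param network a [ScoredNetwork-class] the module lives on.
#' @param report an [AssessmentReport-class].
#' @param outdir output directory (created if missing).
#' @return invisibly, a character vector of the files written.
#' @export
writeModuleReport <- function(module, network, report, outdir) {
  stopifnot(is(module, "FinalModule"), is(network, "ScoredNetwork"),
            is(report, "AssessmentReport"))
  genes <- moduleGenes(module)
  if (length(genes) == 0L) stop("nothing to report: module is empty")
  if (!all(genes %in% networkGenes(network))) {
    stop("module genes must be nodes of the network")
  }
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  geneFile <- file.path(outdir, "module_genes.tsv")
  edgeFile <- file.path(outdir, "module_edges.tsv")
  jsonFile <- file.path(outdir, "module_report.json")

  st <- geneStats(module)
  st <- st[order(st$gene), , drop = FALSE]
  utils::write.table(st, geneFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  e <- moduleEdges(module)
  ed <- data.frame(gene_a = e[, 1L], gene_b = e[, 2L],
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  utils::write.table(ed, edgeFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  payload <- list(
    n_genes = length(genes),
    n_edges = nrow(ed),
    statistics = list(
      p_assoc = as.list(report@pAssoc),
      p_zm = as.list(report@pZm),
      p_zm_mhrw = as.list(report@pZmMhrw),
      p_sig_hyper = report@pSigHyper,
      p_sig_mhrw = report@pSigMhrw,
      p_con = report@pCon
    ),
    counts = report@counts,
    params = report@params
  )
  jsonlite::write_json(payload, jsonFile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(geneFile, edgeFile, jsonFile))
}
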