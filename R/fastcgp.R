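## Exact gene-level P-values by circular genomic permutation (CGP).
##
## The genome is treated as a circle of the L genome-ordered SNP
## P-values. A CGP sample rotates all values by an offset d; the
## corrected gene-level P-value is
##     P_corrected = 1 - l / (L + 1),
## where l counts the rotations whose best (minimum) P-value inside the
## gene's window strictly exceeds the observed best P_g. Considering all
## L non-repeating rotations makes the permutation test exact, and l is
## computed analytically: a rotation qualifies iff the corresponding
## circular window of width m_g contains no value <= P_g, so l is a
## function of the maximal circular runs of values above the threshold.

#' Build the genomic circle from sorted SNP associations
#'
#' @param snps data.frame from [readSnpAssociations()] (must already be
#'   sorted by (chromosome, position); the reader guarantees this).
#' @return a [GenomicCircle-class].
#' @examples
#' snps <- data.frame(snp_id = c("a", "b", "c"),
#'                    chrom = c(1L, 1L, 2L), pos = c(100L, 200L, 50L),
#'                    p = c(.9, .1, .5))
#' buildCircle(snps)
#' @export
buildCircle <- function(snps) {
  if (nrow(snps) == 0L) stop("cannot build a circle from zero SNPs")
  o <- order(snps$chrom, snps$pos)
  if (!identical(o, seq_len(nrow(snps)))) {
    stop("SNP table must be sorted by (chromosome, position)")
  }
  new("GenomicCircle",
      snpId = as.character(snps$snp_id),
      chrom = as.integer(snps$chrom),
      pos = as.integer(snps$pos),
      values = as.numeric(snps$p))
}

#' Map genes to contiguous SNP windows on the circle
#'
#' A gene's window is the run of circle indices of the SNPs lying within
#' its interval (chromosome match, start <= position <= end). Because the
#' circle is sorted genome-order and a gene lies on one chromosome, the
#' window is always a consecutive index interval that never wraps the
#' chromosome-22/chromosome-1 seam. Genes with no mapped SNP are omitted
#' (a message reports how many).
#'
#' @param circle a [GenomicCircle-class].
#' @param genes data.frame from [readGeneAnnotations()].
#' @return data.frame with one row per mapped gene: \code{gene_id},
#'   \code{chrom}, \code{start_index} (1-based circle index), \code{m}
#'   (number of mapped SNPs), \code{best_p} (minimum P in the window).
#' @export
mapGeneWindows <- function(circle, genes) {
  stopifnot(is(circle, "GenomicCircle"))
  L <- circleLength(circle)
  chrom <- circle@chrom
  pos <- circle@pos
  vals <- circle@values
  # offset of each chromosome's first SNP on the circle
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ci <- genes$chrom[i]
    idx <- which(chrom == ci)
    if (length(idx) == 0L) next
    p0 <- pos[idx]
    lo <- findInterval(genes$start[i] - 1L, p0) + 1L
    hi <- findInterval(genes$end[i], p0)
    if (hi < lo) next
    a <- idx[lo]; b <- idx[hi]
    res[[i]] <- data.frame(gene_id = genes$gene_id[i], chrom = ci,
                           start_index = a, m = b - a + 1L,
                           best_p = min(vals[a:b]),
                           stringsAsFactors = FALSE)
  }
  dropped <- sum(vapply(res, is.null, TRUE))
  if (dropped > 0L) {
    message(dropped, " gene(s) with no mapped SNP omitted")
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = integer(),
                      start_index = integer(), m = integer(),
                      best_p = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Count qualifying circular rotations analytically
#'
#' Counts the rotations d in 0..L-1 for which the minimum of the m values
#' falling in a window of width \code{m} strictly exceeds
#' \code{threshold}; equivalently, the number of length-\code{m} circular
#' windows of \code{values} whose minimum is > \code{threshold}. Computed
#' without enumerating rotations, from the maximal circular runs of
#' values above the threshold: each run of length r contributes
#' max(0, r - m + 1) windows (and if no value is at or below the
#' threshold every one of the L rotations qualifies).
#'
#' @param values numeric vector of circle values.
#' @param m window size, 1 <= m <= length(values).
#' @param threshold the comparison threshold (the gene's best P_g);
#'   values tied with the threshold count against the window.
#' @return integer l, the number of qualifying rotations.
#' @examples
#' countValidRotations(c(.9, .8, .05, .5, .7, .6, .95, .4), 2, .05)  # 6
#' @export
countValidRotations <- function(values, m, threshold) {
  L <- length(values)
  if (m < 1L || m > L) stop("window size m must satisfy 1 <= m <= L")
  ok <- values > threshold
  if (all(ok)) return(L)
  if (!any(ok)) return(0L)
  r <- rle(ok)
  len <- r$lengths[r$values]
  # merge the run that wraps the seam
  if (ok[1L] && ok[L]) {
    first <- r$lengths[1L]
    last <- r$lengths[length(r$lengths)]
    len <- c(len[-c(1L, length(len))], first + last)
  }
  as.integer(sum(pmax(0, len - m + 1)))
}

#' Qualifying-rotation count for a non-contiguous SNP set
#'
#' Generic fallback for gene windows that are not a single consecutive
#' interval (e.g. exon-only annotations): a rotation qualifies iff every
#' rotated position of the index set carries a value above the threshold.
#' Each maximal consecutive sub-interval contributes a boolean
#' qualifying mask over the L offsets (via its circular sliding-window
#' minimum); the count is the size of the conjunction.
#'
#' @param values numeric circle values.
#' @param indices integer vector of 1-based circle indices (distinct).
#' @param threshold comparison threshold.
#' @return integer l.
#' @export
countValidRotationsGeneric <- function(values, indices, threshold) {
  L <- length(values)
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1L || indices[1L] < 1L || indices[length(indices)] > L) {
    stop("indices must be distinct integers in 1..L")
  }
  # split into maximal consecutive intervals
  brk <- c(0L, which(diff(indices) != 1L), length(indices))
  okAll <- rep(TRUE, L)
  d <- 0:(L - 1L)
  for (j in seq_len(length(brk) - 1L)) {
    iv <- indices[(brk[j] + 1L):brk[j + 1L]]
    s <- iv[1L]; m <- length(iv)
    sm <- .slidingMinCircular(values, m)
    # rotated min of interval [s, s+m-1] under offset d is sm[(s-1-d) mod L + 1]
    okAll <- okAll & (sm[((s - 1L - d) %% L) + 1L] > threshold)
  }
  sum(okAll)
}

#' Corrected gene-level P-value from the rotation count
#'
#' @param l number of qualifying rotations, 0 <= l <= L.
#' @param L total number of SNPs on the circle.
#' @return P_corrected = 1 - l/(L+1), in [1/(L+1), 1].
#' @examples
#' correctedP(6, 8)  # 1/3
#' @export
correctedP <- function(l, L) {
  if (any(l < 0) || any(l > L)) stop("l must lie in 0..L")
  1 - l / (L + 1)
}

# Circular sliding-window minimum of width m over x (length L), returned
# for every start index 1..L. O(L) via the block prefix/suffix-min trick.
.slidingMinCircular <- function(x, m) {
  n <- length(x)
  if (m == 1L) return(x)
  ext <- c(x, x[seq_len(m - 1L)])
  N <- length(ext)
  nb <- ceiling(N / m)
  pad <- nb * m - N
  if (pad > 0L) ext <- c(ext, rep(Inf, pad))
  mat <- matrix(ext, nrow = m)
  pref <- apply(mat, 2L, cummin)
  suf <- apply(mat[m:1, , drop = FALSE], 2L, cummin)[m:1, , drop = FALSE]
  pref <- as.vector(pref)
  suf <- as.vector(suf)
  i <- seq_len(n)
  pmin(suf[i], pref[i + m - 1L])
}

#' Exact corrected P-values for all mapped genes
#'
#' Batch computation of the CGP-corrected gene-level P-value for every
#' gene window. Genes are processed in decreasing order of their best
#' P-value while "blocker" positions (SNPs whose value exceeds the
#' current threshold) are deleted from a circular doubly linked list of
#' positions; the maximal runs of above-threshold values are then exactly
#' the gaps between surviving blockers, and their lengths are maintained
#' in a Fenwick tree keyed by length so that for a window of size m,
#' l = (sum of gap lengths >= m) - (m-1) x (number of gaps >= m).
#' Results are identical to applying [countValidRotations()] and
#' [correctedP()] gene by gene (strict ">" comparison; ties count
#' against the gene).
#'
#' @param circle a [GenomicCircle-class].
#' @param windows data.frame from [mapGeneWindows()] built on the same
#'   circle.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{m}, \code{best_p}, \code{l}, \code{corrected_p}.
#' @export
computeGenePvalues <- function(circle, windows) {
  stopifnot(is(circle, "GenomicCircle"))
  L <- circleLength(circle)
  G <- nrow(windows)
  if (G == 0L) {
    return(data.frame(gene_id = character(), chrom = integer(),
                      m = integer(), best_p = numeric(), l = numeric(),
                      corrected_p = numeric()))
  }
  if (any(windows$m < 1L) || any(windows$m > L)) {
    stop("window sizes must lie in 1..L")
  }
  vals <- circleValues(circle)

  # Fenwick trees over gap length 1..L (counts and sums)
  fwCnt <- numeric(L)
  fwSum <- numeric(L)
  totCnt <- 0; totSum <- 0
  gapAddTracked <- function(len, w) {
    if (len < 1L) return(invisible())
    i <- as.integer(len)
    while (i <= L) {
      fwCnt[i] <<- fwCnt[i] + w
      fwSum[i] <<- fwSum[i] + w * len
      i <- i + bitwAnd(i, -i)
    }
    totCnt <<- totCnt + w
    totSum <<- totSum + w * len
  }
  fwPrefix <- function(i) {
    c0 <- 0; s0 <- 0
    i <- as.integer(i)
    while (i > 0L) {
      c0 <- c0 + fwCnt[i]
      s0 <- s0 + fwSum[i]
      i <- i - bitwAnd(i, -i)
    }
    c(c0, s0)
  }

  # circular doubly linked list over all positions (all start as blockers)
  nxt <- c(seq_len(L)[-1L], 1L)
  prv <- c(L, seq_len(L)[-L])
  gapAfter <- numeric(L)        # non-blocker run length to next blocker
  alive <- rep(TRUE, L)
  nBlockers <- L

  ord <- order(vals, decreasing = TRUE)   # removal order: largest first
  gord <- order(windows$best_p, decreasing = TRUE)

  lRes <- numeric(G)
  ri <- 1L
  for (gi in gord) {
    t <- windows$best_p[gi]
    m <- windows$m[gi]
    # remove blockers with value > t
    while (ri <= L && vals[ord[ri]] > t) {
      p <- ord[ri]
      ri <- ri + 1L
      if (nBlockers == 1L) {
        alive[p] <- FALSE
        nBlockers <- 0L
        gapAddTracked(gapAfter[p], -1)
        gapAfter[p] <- 0
        next
      }
      a <- prv[p]; b <- nxt[p]
      gapAddTracked(gapAfter[a], -1)
      gapAddTracked(gapAfter[p], -1)
      newGap <- gapAfter[a] + 1 + gapAfter[p]
      gapAfter[a] <- newGap
      gapAddTracked(newGap, 1)
      nxt[a] <- b
      prv[b] <- a
      alive[p] <- FALSE
      nBlockers <- nBlockers - 1L
    }
    if (nBlockers == 0L) {
      lRes[gi] <- L
    } else {
      # gaps >= m: suffix of the Fenwick range
      if (m > 1L) {
        pre <- fwPrefix(m - 1L)
        cgt <- totCnt - pre[1L]
        sgt <- totSum - pre[2L]
      } else {
        cgt <- totCnt
        sgt <- totSum
      }
      lRes[gi] <- sgt - (m - 1) * cgt
    }
  }

  data.frame(gene_id = windows$gene_id, chrom = windows$chrom,
             m = windows$m, best_p = windows$best_p, l = lRes,
             corrected_p = correctedP(lRes, L),
             stringsAsFactors = FALSE)
}

#' One-call fastCGP: SNP table + annotation to gene-level P-values
#'
#' Convenience wrapper: builds the circle, maps gene windows and computes
#' the exact corrected P-values.
#'
#' @param snps sorted SNP association data.frame.
#' @param genes gene annotation data.frame.
#' @return list with elements \code{circle}, \code{windows},
#'   \code{scores} (the data.frame of [computeGenePvalues()]).
#' @export
fastCGP <- function(snps, genes) {
  circle <- buildCircle(snps)
  windows <- mapGeneWindows(circle, genes)
  scores <- computeGenePvalues(circle, windows)
  list(circle = circle, windows = windows, scores = scores)
}
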