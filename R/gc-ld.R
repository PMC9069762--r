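## Intergenic-SNP genomic control and greedy LD pruning.

#' Estimate the genomic inflation factor from intergenic SNPs
#'
#' Intergenic SNPs are treated as an empirical null: the inflation factor is
#' the median of their chi-square statistics divided by the theoretical
#' median of a 1-df chi-square (0.4549364).
#'
#' @param x a [SummaryStats-class] table.
#' @param intergenic either a logical vector parallel to the table's rows, a
#'   named logical vector keyed by snp id, or a character vector of
#'   intergenic snp ids.
#' @return a [GCResult-class]; extract the factor with [lambdaHat()].
#' @export
estimateLambda <- function(x, intergenic) {
  d <- x@snps
  if (is.character(intergenic)) {
    mask <- d$snp %in% intergenic
  } else if (!is.null(names(intergenic))) {
    mask <- d$snp %in% names(intergenic)[as.logical(intergenic)]
  } else {
    stopifnot(length(intergenic) == nrow(d))
    mask <- as.logical(intergenic)
  }
  nUsed <- sum(mask, na.rm = TRUE)
  if (nUsed < 100)
    stop("need at least 100 flagged intergenic SNPs, got ", nUsed)
  lam <- median(d$z[mask]^2, na.rm = TRUE) / .CHISQ1_MEDIAN
  new("GCResult", lambdaHat = lam, nIntergenic = as.integer(nUsed))
}

#' Apply a genomic-control correction
#'
#' Divides z by `sqrt(lambdaHat)` and recomputes two-sided p-values;
#' beta and se are left untouched (they remain on the pre-correction scale,
#' flagged in the provenance).
#'
#' @param x a [SummaryStats-class] table.
#' @param lambdaHat inflation factor (> 0), or a [GCResult-class].
#' @return corrected [SummaryStats-class].
#' @export
applyGenomicControl <- function(x, lambdaHat) {
  if (is(lambdaHat, "GCResult")) lambdaHat <- lambdaHat@lambdaHat
  stopifnot(lambdaHat > 0)
  d <- x@snps
  d$z <- d$z / sqrt(lambdaHat)
  d$pvalue <- pmax(.pFromZ(d$z), .Machine$double.xmin)
  new("SummaryStats", snps = d, trait = x@trait, dropLog = x@dropLog,
      provenance = c(x@provenance,
                     list(genomicControl = lambdaHat, betaPreGC = TRUE)))
}

## per-block correlation cache for a panel; blocks = runs of SNPs whose gaps
## never exceed the window (the simulator's 1 Mb gaps split blocks cleanly)
.panelBlocks <- function(ldref, windowBp) {
  o <- order(.chromRank(ldref@chrom), ldref@pos)
  brk <- c(TRUE, diff(.chromRank(ldref@chrom)[o]) != 0 |
                 diff(ldref@pos[o]) > windowBp)
  split(o, cumsum(brk))
}

#' Greedy LD pruning of summary statistics
#'
#' plink-clump convention: SNPs are visited in order of ascending p-value
#' (ties broken by chromosome and position); each visited SNP not already
#' removed is kept, and every not-yet-kept SNP within `windowBp` whose
#' panel r-squared with it exceeds `r2Max` is removed. The result contains
#' no retained pair with r-squared above `r2Max` within the window. SNPs
#' absent from the panel are retained and reported via the `uncovered`
#' attribute (conservative).
#'
#' @param x a [SummaryStats-class] table.
#' @param ldref an [LDReference-class] covering (most of) the table.
#' @param r2Max prune threshold on r-squared (default 0.2).
#' @param windowBp pruning window in base pairs (default 250 kb).
#' @return character vector of retained snp ids, attribute `uncovered`
#'   listing the ids that the panel did not cover.
#' @export
ldPrune <- function(x, ldref, r2Max = 0.2, windowBp = 250000) {
  d <- x@snps
  idx <- match(d$snp, ldref@snp)
  uncovered <- d$snp[is.na(idx)]
  dd <- d[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!nrow(dd)) {
    out <- uncovered
    attr(out, "uncovered") <- uncovered
    return(out)
  }
  g <- ldref@genotypes
  ord <- order(dd$pvalue, .chromRank(dd$chrom), dd$pos)
  state <- integer(nrow(dd))           # 0 = free, 1 = kept, -1 = removed
  pos <- dd$pos
  chrom <- .chromRank(dd$chrom)
  ## rows are (chrom, pos)-sorted, so the window around i is a contiguous
  ## index range found by binary search within i's chromosome segment
  segStart <- which(c(TRUE, diff(chrom) != 0))
  segEnd <- c(segStart[-1] - 1L, length(chrom))
  segOf <- rep(seq_along(segStart), segEnd - segStart + 1L)
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    s <- segStart[segOf[i]]; e <- segEnd[segOf[i]]
    seg <- pos[s:e]
    lo <- s + findInterval(pos[i] - windowBp - 0.5, seg)
    hi <- s - 1L + findInterval(pos[i] + windowBp + 0.5, seg)
    nb <- lo:hi
    nb <- nb[state[nb] == 0L]
    if (!length(nb)) next
    r <- as.vector(cor(g[, idx[i]], g[, idx[nb], drop = FALSE]))
    state[nb[r^2 > r2Max]] <- -1L
  }
  out <- c(dd$snp[state == 1L], uncovered)
  out <- d$snp[d$snp %in% out]   # restore (chrom, pos) order
  attr(out, "uncovered") <- uncovered
  out
}

#' Subset a SummaryStats table to a set of SNP ids
#'
#' @param x a [SummaryStats-class] or [HarmonizedPair-class].
#' @param ids snp ids to keep.
#' @param reason drop-log reason code for the removed records.
#' @return same class as `x`.
#' @export
keepSnps <- function(x, ids, reason = "pruned") {
  if (is(x, "HarmonizedPair")) {
    return(new("HarmonizedPair", a = keepSnps(x@a, ids, reason),
               b = keepSnps(x@b, ids, reason), counts = x@counts))
  }
  d <- x@snps
  drop <- !(d$snp %in% ids)
  log <- x@dropLog
  if (any(drop))
    log <- rbind(log, data.frame(snp = d$snp[drop], reason = reason,
                                 stringsAsFactors = FALSE))
  new("SummaryStats", snps = `rownames<-`(d[!drop, , drop = FALSE], NULL),
      trait = x@trait, dropLog = log, provenance = x@provenance)
}
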