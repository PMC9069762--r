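## Conditional and conjunctional FDR, and locus calling -- the discovery
## statistic at the heart of the pipeline.

#' Conditional FDR of trait A given trait B
#'
#' The conditional FDR of SNP i is the conservative empirical-Bayes
#' estimate of the posterior probability that the SNP is null for trait A
#' given that both traits' p-values are at least as extreme as observed:
#' `cfdr_i = p1_i * #\{j: p2_j <= p2_i\} / #\{j: p1_j <= p1_i & p2_j <= p2_i\}`,
#' i.e. p1 divided by the empirical conditional cdf of p1 given P2 <= p2,
#' with the null proportion taken as 1 (conservative). Values are clipped
#' to (0, 1]; `cfdr_i >= p1_i` always (the empirical cdf is at most 1).
#'
#' The default `"exact"` method counts 2-D dominance exactly (Fenwick tree,
#' `O(n log n)`); `"grid"` evaluates the counts on a 101 x 101 grid in
#' -log10 space with bilinear interpolation, a cheaper approximation meant
#' for panels beyond ~1e6 SNPs.
#'
#' An optional lookup set (`refP1`/`refP2`) supports assign-back scoring:
#' the empirical cdfs are built from the lookup SNPs (typically the
#' LD-pruned set) while the query SNPs are scored against them.
#'
#' @param p1 p-values of the trait of interest.
#' @param p2 aligned p-values of the conditioning trait.
#' @param refP1,refP2 lookup p-values defining the empirical cdfs (default:
#'   the query vectors themselves).
#' @param method `"exact"` or `"grid"`.
#' @return numeric vector of conditional FDR values in (0, 1].
#' @export
conditionalFDR <- function(p1, p2, refP1 = p1, refP2 = p2,
                           method = c("exact", "grid")) {
  method <- match.arg(method)
  stopifnot(length(p1) == length(p2), length(refP1) == length(refP2))
  if (method == "grid") return(.conditionalFDRGrid(p1, p2, refP1, refP2))
  both <- dominance_count(p1, p2, refP1, refP2)
  sr2 <- sort(refP2)
  marg <- findInterval(p2, sr2)   # #{ refP2 <= p2_i }
  cfdr <- ifelse(both > 0, p1 * marg / both, 1)
  pmin(cfdr, 1)
}

## grid approximation: dominance counts at 101x101 -log10(p) knots,
## bilinear interpolation in between
.conditionalFDRGrid <- function(p1, p2, refP1, refP2, nKnots = 101L) {
  l1 <- -log10(p1); l2 <- -log10(p2)
  r1 <- -log10(refP1); r2 <- -log10(refP2)
  g1 <- seq(0, max(l1, r1), length.out = nKnots)
  g2 <- seq(0, max(l2, r2), length.out = nKnots)
  ## counts[a, b] = #{ ref: r1 >= g1[a] & r2 >= g2[b] } (<= on p scale)
  s1 <- sort(r1)
  cnt <- matrix(0L, nKnots, nKnots)
  o2 <- order(r2, decreasing = TRUE)
  ptr <- 0L
  inTail <- numeric(0)
  for (b in nKnots:1) {
    while (ptr < length(o2) && r2[o2[ptr + 1L]] >= g2[b]) {
      ptr <- ptr + 1L
      inTail <- c(inTail, r1[o2[ptr]])
    }
    st <- sort(inTail)
    cnt[, b] <- length(st) - findInterval(g1 - 1e-12, st)
  }
  marg2 <- vapply(g2, function(t) sum(r2 >= t - 1e-12), numeric(1))
  interp <- function(grid, v) {
    i <- findInterval(v, grid, all.inside = TRUE)
    w <- (v - grid[i]) / (grid[i + 1] - grid[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  a <- interp(g1, l1); b <- interp(g2, l2)
  bil <- function(M) {
    (1 - a$w) * (1 - b$w) * M[cbind(a$i, b$i)] +
      a$w * (1 - b$w) * M[cbind(a$i + 1L, b$i)] +
      (1 - a$w) * b$w * M[cbind(a$i, b$i + 1L)] +
      a$w * b$w * M[cbind(a$i + 1L, b$i + 1L)]
  }
  both <- bil(cnt)
  marg <- (1 - b$w) * marg2[b$i] + b$w * marg2[b$i + 1L]
  pmin(ifelse(both > 0, p1 * marg / both, 1), 1)
}

#' Conjunctional FDR
#'
#' The maximum of the two directional conditional FDRs; small values flag a
#' SNP associated with both traits.
#'
#' @param cfdr12,cfdr21 the two conditional-FDR vectors over the same SNPs.
#' @return `pmax(cfdr12, cfdr21)`.
#' @export
conjunctionalFDR <- function(cfdr12, cfdr21) {
  if (length(cfdr12) != length(cfdr21))
    stop("conditional FDR vectors differ in length")
  pmax(cfdr12, cfdr21)
}

#' Per-SNP conditional and conjunctional FDR for a harmonized pair
#'
#' Computes both conditional directions and their maximum over the pair's
#' SNPs (conventionally the LD-pruned set).
#'
#' @param pair a [HarmonizedPair-class].
#' @param method passed to [conditionalFDR()].
#' @return a [CFDRTable-class].
#' @export
cfdrTable <- function(pair, method = c("exact", "grid")) {
  stopifnot(is(pair, "HarmonizedPair"))
  da <- pair@a@snps; db <- pair@b@snps
  c12 <- conditionalFDR(da$pvalue, db$pvalue, method = method)
  c21 <- conditionalFDR(db$pvalue, da$pvalue, method = method)
  new("CFDRTable",
      stats = data.frame(snp = da$snp, chrom = da$chrom, pos = da$pos,
                         p1 = da$pvalue, p2 = db$pvalue, cfdr12 = c12,
                         cfdr21 = c21, conjfdr = conjunctionalFDR(c12, c21),
                         stringsAsFactors = FALSE),
      traits = c(pair@a@trait, pair@b@trait))
}

#' Expected false positives at an FDR reporting threshold
#'
#' Plain FDR semantics: reporting associations at FDR < `threshold` implies
#' `threshold * nReported` expected false positives among them (one per
#' hundred at the conventional 0.01 cutoff).
#'
#' @param threshold FDR reporting threshold.
#' @param nReported number of reported associations.
#' @return expected number of false positives.
#' @export
expectedFalsePositives <- function(threshold, nReported = 100) {
  stopifnot(threshold > 0, threshold <= 1, nReported >= 0)
  threshold * nReported
}

#' Group FDR-significant SNPs into independent loci
#'
#' SNPs with `fdr < fdrThreshold` (strict) are merged by single linkage:
#' two significant SNPs belong to the same locus when they lie within
#' `mergeKb` kilobases on the same chromosome OR their panel r-squared
#' exceeds `r2Merge`. The index SNP of a locus is its lowest-FDR member
#' (ties broken by smaller p1, then position).
#'
#' @param x a [CFDRTable-class].
#' @param ldref optional [LDReference-class] for the LD linkage rule; with
#'   NULL only the distance rule applies.
#' @param fdrColumn which FDR column drives the calling (default
#'   `"conjfdr"`; `"cfdr12"`/`"cfdr21"` give conditional loci).
#' @param fdrThreshold reporting threshold (default 0.01, strict `<`).
#' @param mergeKb distance linkage rule in kb (default 250).
#' @param r2Merge LD linkage rule on r-squared (default 0.6).
#' @return a `GRanges` of loci (one range per locus, member span) with
#'   metadata columns indexSnp, indexPos, fdr, p1, nSnps, members.
#' @export
callLoci <- function(x, ldref = NULL, fdrColumn = "conjfdr",
                     fdrThreshold = 0.01, mergeKb = 250, r2Merge = 0.6) {
  d <- x@stats
  stopifnot(fdrColumn %in% names(d))
  fdr <- d[[fdrColumn]]
  sig <- which(fdr < fdrThreshold)
  empty <- GRanges(character(), IRanges(),
                   indexSnp = character(), indexPos = integer(),
                   fdr = numeric(), p1 = numeric(), nSnps = integer())
  if (!length(sig)) return(empty)
  s <- d[sig, , drop = FALSE]
  s$fdr <- fdr[sig]
  o <- order(.chromRank(s$chrom), s$pos)
  s <- s[o, , drop = FALSE]
  n <- nrow(s)

  ## union-find over significant SNPs
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  idx <- if (!is.null(ldref)) match(s$snp, ldref@snp) else rep(NA_integer_, n)
  maxBp <- mergeKb * 1000
  ldWindow <- if (!is.null(ldref)) ldref@windowBp else 0
  for (i in seq_len(n)[-1]) {
    for (j in (i - 1):1) {
      if (.chromRank(s$chrom[j]) != .chromRank(s$chrom[i])) break
      gap <- s$pos[i] - s$pos[j]
      if (gap > max(maxBp, ldWindow)) break
      linked <- gap <= maxBp
      if (!linked && !is.na(idx[i]) && !is.na(idx[j]) && gap <= ldWindow) {
        r <- cor(ldref@genotypes[, idx[i]], ldref@genotypes[, idx[j]])
        linked <- r^2 > r2Merge
      }
      if (linked) union(i, j)
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  groups <- split(seq_len(n), root)
  loci <- lapply(groups, function(g) {
    gs <- s[g, , drop = FALSE]
    lead <- gs[order(gs$fdr, gs$p1, gs$pos), , drop = FALSE][1, ]
    data.frame(chrom = gs$chrom[1], start = min(gs$pos), end = max(gs$pos),
               indexSnp = lead$snp, indexPos = lead$pos, fdr = lead$fdr,
               p1 = lead$p1, nSnps = nrow(gs),
               members = paste(gs$snp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  loci <- loci[order(.chromRank(loci$chrom), loci$start), , drop = FALSE]
  GRanges(loci$chrom, IRanges(loci$start, loci$end),
          indexSnp = loci$indexSnp, indexPos = loci$indexPos,
          fdr = loci$fdr, p1 = loci$p1, nSnps = loci$nSnps,
          members = loci$members)
}
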