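## Summary-statistics genetic covariance and correlation: single-annotation
## method of moments with delete-one block-jackknife uncertainty.

#' Per-SNP LD scores from a reference panel
#'
#' `l_j` is the sum of r-squared between SNP j and every panel SNP within
#' `windowBp` of it (including the self term, so `l_j >= 1` up to the
#' small-sample adjustment). Estimated r-squared from a finite panel is
#' biased upward by `(1 - r^2) / (nRef - 2)`; the standard adjustment
#' `r2_adj = r2 - (1 - r2) / (nRef - 2)` is applied to the off-diagonal
#' terms so the score is unbiased for the population quantity.
#'
#' @param ldref an [LDReference-class].
#' @param windowBp base-pair window (default: the panel's own, 1 Mb).
#' @param adjusted apply the small-sample bias adjustment (default TRUE).
#' @return named numeric vector of LD scores, parallel to the panel SNPs.
#' @export
ldScores <- function(ldref, windowBp = ldref@windowBp, adjusted = TRUE) {
  g <- ldref@genotypes
  nRef <- nrow(g)
  m <- ncol(g)
  l <- rep(1, m)
  blocks <- .panelBlocks(ldref, windowBp)
  for (blk in blocks) {
    if (length(blk) == 1) next
    pos <- ldref@pos[blk]
    r2 <- cor(g[, blk, drop = FALSE])^2
    if (adjusted && nRef > 2) r2 <- r2 - (1 - r2) / (nRef - 2)
    inWin <- abs(outer(pos, pos, "-")) <= windowBp
    diag(r2) <- 1
    r2[!inWin] <- 0
    l[blk] <- rowSums(r2)
  }
  setNames(l, ldref@snp)
}

#' Method-of-moments SNP heritability
#'
#' One-parameter moment estimator without an intercept term:
#' `h2 = m (mean(z^2) - 1) / (n mean(l))`. Under the polygenic model the
#' expected chi-square statistic is `1 + n h2 l_j / m`, so the average
#' excess over 1, scaled by sample size and mean LD score, identifies h2.
#' A nonpositive estimate is reported raw with a `"nonpositive_h2"`
#' attribute rather than truncated.
#'
#' @param z signed z scores.
#' @param n sample size (scalar, or per-SNP vector averaged).
#' @param l LD scores aligned with `z`.
#' @param m number of SNPs the heritability refers to (default length(z)).
#' @return heritability estimate (attribute `flag` when nonpositive).
#' @export
momH2 <- function(z, n, l, m = length(z)) {
  stopifnot(length(z) == length(l))
  n <- mean(n)
  h2 <- m * (mean(z^2) - 1) / (n * mean(l))
  if (!is.na(h2) && h2 <= 0) attr(h2, "flag") <- "nonpositive_h2"
  h2
}

#' Method-of-moments genetic covariance
#'
#' `rho_g = m mean(z1 z2) / (sqrt(n1 n2) mean(l))`. The cross moment has no
#' null offset under the stated no-sample-overlap assumption, hence no -1
#' term (unlike [momH2()]).
#'
#' @param z1,z2 aligned signed z scores of the two traits.
#' @param n1,n2 sample sizes.
#' @param l LD scores aligned with the z vectors.
#' @param m number of SNPs.
#' @return genetic covariance estimate.
#' @export
momGencov <- function(z1, z2, n1, n2, l, m = length(z1)) {
  stopifnot(length(z1) == length(z2), length(z1) == length(l))
  m * mean(z1 * z2) / (sqrt(mean(n1) * mean(n2)) * mean(l))
}

#' Genetic correlation between two traits with jackknife uncertainty
#'
#' Point estimates via [momH2()] and [momGencov()];
#' `r_g = rho_g / sqrt(h2_1 h2_2)`, clipped to \[-1, 1\] with the raw value
#' retained. The standard error comes from a delete-one jackknife over
#' `nBlocks` contiguous position-ordered SNP blocks, applied to the full
#' r_g pipeline; p is two-sided normal. The MHC should be excluded
#' upstream ([excludeRegion()]); sample overlap between the two studies is
#' assumed absent.
#'
#' @param pair a [HarmonizedPair-class] (MHC excluded upstream).
#' @param ldref an [LDReference-class] covering the pair (SNPs missing from
#'   the panel are dropped from the estimator).
#' @param nBlocks jackknife block count (default 100).
#' @return a [GencorrResult-class].
#' @export
geneticCorrelation <- function(pair, ldref, nBlocks = 100L) {
  stopifnot(is(pair, "HarmonizedPair"), is(ldref, "LDReference"))
  da <- pair@a@snps; db <- pair@b@snps
  idx <- match(da$snp, ldref@snp)
  keep <- !is.na(idx)
  da <- da[keep, , drop = FALSE]; db <- db[keep, , drop = FALSE]
  idx <- idx[keep]
  m <- nrow(da)
  if (nBlocks > m) stop("more jackknife blocks than SNPs")
  l <- ldScores(ldref)[idx]
  z1 <- da$z; z2 <- db$z
  n1 <- mean(da$n); n2 <- mean(db$n)

  pipeline <- function(s11, s22, s12, sl, mm) {
    h21 <- mm * (s11 / mm - 1) / (n1 * (sl / mm))
    h22 <- mm * (s22 / mm - 1) / (n2 * (sl / mm))
    rho <- mm * (s12 / mm) / (sqrt(n1 * n2) * (sl / mm))
    rg <- if (h21 > 0 && h22 > 0) rho / sqrt(h21 * h22) else NA_real_
    c(h21 = h21, h22 = h22, rho = rho, rg = rg)
  }
  s11 <- sum(z1^2); s22 <- sum(z2^2); s12 <- sum(z1 * z2); sl <- sum(l)
  full <- pipeline(s11, s22, s12, sl, m)

  ## contiguous equal-SNP blocks in (chrom, pos) order (the table order)
  bid <- factor(ceiling(seq_len(m) / (m / nBlocks)),
                levels = seq_len(nBlocks))
  b11 <- unname(tapply(z1^2, bid, sum))
  b22 <- unname(tapply(z2^2, bid, sum))
  b12 <- unname(tapply(z1 * z2, bid, sum))
  bl <- unname(tapply(l, bid, sum))
  bn <- tabulate(bid, nBlocks)
  jk <- vapply(seq_len(nBlocks), function(b)
    pipeline(s11 - b11[b], s22 - b22[b], s12 - b12[b], sl - bl[b],
             m - bn[b])["rg"], numeric(1))
  flags <- character()
  if (anyNA(jk) || is.na(full["rg"])) {
    flags <- c(flags, "nonpositive_h2_in_jackknife")
    jkOK <- jk[!is.na(jk)]
  } else jkOK <- jk
  B <- length(jkOK)
  se <- if (B > 1) sqrt((B - 1) / B * sum((jkOK - mean(jkOK))^2)) else NA_real_
  rgRaw <- unname(full["rg"])
  rg <- if (is.na(rgRaw)) NA_real_ else max(-1, min(1, rgRaw))
  if (!is.na(rgRaw) && abs(rgRaw) > 1) flags <- c(flags, "rg_clipped")
  if (is.na(rgRaw)) flags <- c(flags, "nonpositive_h2")
  p <- if (!is.na(rg) && !is.na(se)) {
    if (se == 0) as.numeric(rg != 0) * 0 else 2 * pnorm(-abs(rg / se))
  } else NA_real_
  new("GencorrResult", h2 = unname(full[c("h21", "h22")]),
      rhoG = unname(full["rho"]), rG = rg, rGRaw = rgRaw, se = se, p = p,
      mSnps = as.integer(m), nBlocks = as.integer(nBlocks), flags = flags)
}
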