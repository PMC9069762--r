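## Two-sample Mendelian randomization: instrument selection and clumping,
## IVW, Egger regression, Cochran's Q, leave-one-out, F statistics,
## PRESSO-style outlier detection, and analytic power.

.Z975 <- qnorm(0.975)

#' Select genome-wide-significant, LD-independent instruments
#'
#' Candidates are SNPs with `p < pThreshold`; when the candidates collapse
#' to at most one independent locus the selection is rerun at the relaxed
#' threshold (recorded in the metadata). Candidates are clumped greedily by
#' ascending p: an index SNP is kept only if its panel r-squared with every
#' already-kept SNP within `clumpWindowBp` stays below `clumpR2`.
#'
#' @param exposure a [SummaryStats-class] table.
#' @param ldref an [LDReference-class]; candidates absent from the panel
#'   are treated as independent (kept, logged).
#' @param pThreshold genome-wide threshold (default 5e-8).
#' @param relaxed fallback threshold (default 1e-6) used when <= 1 locus
#'   survives at `pThreshold`.
#' @param clumpR2 clump r-squared bound (default 0.001).
#' @param clumpWindowBp clump window (default 1e7, i.e. 10 Mb).
#' @return character vector of instrument snp ids (possibly empty, never an
#'   error), with attributes `thresholdUsed` and `relaxedApplied`.
#' @export
selectInstruments <- function(exposure, ldref, pThreshold = 5e-8,
                              relaxed = 1e-6, clumpR2 = 0.001,
                              clumpWindowBp = 1e7) {
  clumpAt <- function(thr) {
    d <- exposure@snps
    d <- d[d$pvalue < thr, , drop = FALSE]
    if (!nrow(d)) return(character())
    d <- d[order(d$pvalue, .chromRank(d$chrom), d$pos), , drop = FALSE]
    idx <- match(d$snp, ldref@snp)
    kept <- integer()
    for (i in seq_len(nrow(d))) {
      ok <- TRUE
      for (j in kept) {
        if (d$chrom[j] != d$chrom[i]) next
        if (abs(d$pos[j] - d$pos[i]) > clumpWindowBp) next
        if (is.na(idx[i]) || is.na(idx[j])) next
        r <- cor(ldref@genotypes[, idx[i]], ldref@genotypes[, idx[j]])
        if (r^2 >= clumpR2) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, i)
    }
    d$snp[kept]
  }
  ids <- clumpAt(pThreshold)
  relaxedApplied <- FALSE
  if (length(ids) <= 1) {
    ids <- clumpAt(relaxed)
    relaxedApplied <- TRUE
  }
  attr(ids, "thresholdUsed") <- if (relaxedApplied) relaxed else pThreshold
  attr(ids, "relaxedApplied") <- relaxedApplied
  ids
}

#' Harmonize instruments across the exposure and outcome studies
#'
#' Restricts both tables to the instrument ids, delegates allele alignment
#' to [harmonizePair()], and computes Wald ratios
#' (`theta_j = betaY_j / betaX_j`), first-order ratio standard errors
#' (`seY_j / |betaX_j|`) and instrument F statistics
#' (`(betaX_j / seX_j)^2`). Instruments missing from either table or with
#' `betaX = 0` (undefined ratio) are dropped with a reason.
#'
#' @param exposure,outcome [SummaryStats-class] tables.
#' @param ids instrument snp ids from [selectInstruments()].
#' @return an [MRInstruments-class]; zero rows means "no instruments".
#' @export
harmonizeInstruments <- function(exposure, outcome, ids) {
  meta <- list(requested = length(ids),
               thresholdUsed = attr(ids, "thresholdUsed"),
               relaxedApplied = isTRUE(attr(ids, "relaxedApplied")))
  missA <- setdiff(ids, exposure@snps$snp)
  missB <- setdiff(ids, outcome@snps$snp)
  ids2 <- setdiff(ids, union(missA, missB))
  meta$missingDropped <- length(union(missA, missB))
  if (!length(ids2))
    return(new("MRInstruments",
               data = data.frame(snp = character(), betaX = numeric(),
                                 seX = numeric(), betaY = numeric(),
                                 seY = numeric(), ratio = numeric(),
                                 ratioSE = numeric(), F = numeric(),
                                 stringsAsFactors = FALSE),
               meta = meta))
  pr <- harmonizePair(keepSnps(exposure, ids2, "not_instrument"),
                      keepSnps(outcome, ids2, "not_instrument"))
  dx <- pr@a@snps; dy <- pr@b@snps
  zero <- !is.na(dx$beta) & dx$beta == 0
  meta$zeroBetaXDropped <- sum(zero)
  dx <- dx[!zero, , drop = FALSE]; dy <- dy[!zero, , drop = FALSE]
  d <- data.frame(snp = dx$snp, betaX = dx$beta, seX = dx$se,
                  betaY = dy$beta, seY = dy$se,
                  ratio = dy$beta / dx$beta,
                  ratioSE = dy$se / abs(dx$beta),
                  F = (dx$beta / dx$se)^2, stringsAsFactors = FALSE)
  new("MRInstruments", data = d, meta = meta)
}

.mrResult <- function(method, k, estimate, se, p, ...) {
  new("MRResult", method = method, k = as.integer(k), estimate = estimate,
      se = se, ciLow = estimate - .Z975 * se, ciHigh = estimate + .Z975 * se,
      p = p, ...)
}

.noInstruments <- function(method) {
  new("MRResult", method = method, k = 0L, estimate = NA_real_,
      se = NA_real_, ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
      details = list(noInstruments = TRUE))
}

#' Random-effects inverse-variance-weighted estimate
#'
#' Wald ratios are combined with weights `w_j = 1 / ratioSE_j^2`. The
#' fixed-effect standard error `1 / sqrt(sum w)` is inflated by the
#' multiplicative overdispersion factor `max(1, sqrt(Q / (k - 1)))`
#' (random-effects with a floor at no underdispersion). With a single
#' instrument the Wald ratio itself is returned and Q is undefined.
#'
#' @param instr an [MRInstruments-class].
#' @return an [MRResult-class] carrying Q, its df and p alongside the
#'   estimate.
#' @export
mrIVW <- function(instr) {
  d <- instr@data
  k <- nrow(d)
  if (k == 0) return(.noInstruments("IVW"))
  if (k == 1) {
    est <- d$ratio; se <- d$ratioSE
    return(.mrResult("Wald ratio", 1L, est, se, .pFromZ(est / se)))
  }
  w <- 1 / d$ratioSE^2
  est <- sum(w * d$ratio) / sum(w)
  seFE <- 1 / sqrt(sum(w))
  Q <- sum(w * (d$ratio - est)^2)
  se <- seFE * max(1, sqrt(Q / (k - 1)))
  .mrResult("IVW (random effects)", k, est, se, .pFromZ(est / se),
            Q = Q, QDf = k - 1, QP = pchisq(Q, k - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' unconstrained intercept, after orienting all exposure effects
#' nonnegative; weights `1 / seY^2`. The slope is the causal estimate and
#' the intercept measures directional horizontal pleiotropy. Inference uses
#' the t distribution with k - 2 df and a residual-sd floor of 1 on the
#' standard errors (no underdispersion), the convention of the established
#' two-sample MR tooling.
#'
#' @param instr an [MRInstruments-class] with at least 3 instruments.
#' @return an [MRResult-class]; the intercept test sits in the intercept
#'   slots.
#' @export
mrEgger <- function(instr) {
  d <- instr@data
  k <- nrow(d)
  if (k < 3)
    stop("MR-Egger needs at least 3 instruments (zero residual df otherwise)")
  flip <- d$betaX < 0
  bx <- abs(d$betaX)
  by <- ifelse(flip, -d$betaY, d$betaY)
  w <- 1 / d$seY^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  slope <- co["bx", "Estimate"]
  slopeSE <- co["bx", "Std. Error"] / min(1, sm$sigma)
  int <- co["(Intercept)", "Estimate"]
  intSE <- co["(Intercept)", "Std. Error"] / min(1, sm$sigma)
  pSlope <- 2 * pt(-abs(slope / slopeSE), df = k - 2)
  pInt <- 2 * pt(-abs(int / intSE), df = k - 2)
  .mrResult("MR-Egger", k, slope, slopeSE, pSlope,
            intercept = int, interceptSE = intSE, interceptP = pInt)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (theta_j - estimate)^2` with IVW weights; chi-square with
#' k - 1 df. By default the estimate is the IVW point estimate, making this
#' identical to the Q reported by [mrIVW()].
#'
#' @param instr an [MRInstruments-class] with k >= 2.
#' @param estimate pooled estimate to test around (default: IVW).
#' @return list(Q, df, p).
#' @export
cochranQ <- function(instr, estimate = NULL) {
  d <- instr@data
  k <- nrow(d)
  if (k < 2) stop("Cochran's Q needs at least 2 instruments")
  w <- 1 / d$ratioSE^2
  if (is.null(estimate)) estimate <- sum(w * d$ratio) / sum(w)
  Q <- sum(w * (d$ratio - estimate)^2)
  list(Q = Q, df = k - 1, p = pchisq(Q, k - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect k times, omitting one instrument each
#' time; a dominant instrument shows up as a large deviation when dropped.
#'
#' @param instr an [MRInstruments-class].
#' @param allowPairs permit k = 2 (each omission leaves a single-instrument
#'   Wald ratio); disallowed by default.
#' @return data.frame (omitted, estimate, se, p) with attribute `maxDev`,
#'   the largest absolute deviation from the full estimate.
#' @export
leaveOneOut <- function(instr, allowPairs = FALSE) {
  d <- instr@data
  k <- nrow(d)
  if (k < 3 && !(allowPairs && k == 2))
    stop("leave-one-out needs at least 3 instruments")
  full <- mrIVW(instr)@estimate
  res <- lapply(seq_len(k), function(j) {
    sub <- new("MRInstruments", data = d[-j, , drop = FALSE],
               meta = instr@meta)
    r <- mrIVW(sub)
    data.frame(omitted = d$snp[j], estimate = r@estimate, se = r@se,
               p = r@p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "fullEstimate") <- full
  attr(out, "maxDev") <- max(abs(out$estimate - full))
  out
}

#' Instrument F statistics and weak-instrument flags
#'
#' `F_j = (betaX_j / seX_j)^2`; the conventional weakness bound is 10.
#'
#' @param instr an [MRInstruments-class].
#' @param weakThreshold flag bound (default 10).
#' @return data.frame (snp, F, weak) with attribute `range`, the
#'   (min, max) F across instruments.
#' @export
fStatistics <- function(instr, weakThreshold = 10) {
  d <- instr@data
  out <- data.frame(snp = d$snp, F = d$F, weak = d$F < weakThreshold,
                    stringsAsFactors = FALSE)
  attr(out, "range") <- if (nrow(d)) range(d$F) else c(NA_real_, NA_real_)
  out
}

## leave-one-out IVW estimates for every column of a ratio/weight matrix
## (rows = instruments, cols = replicates); returns a k x nrep matrix
.looMatrix <- function(theta, w) {
  sw <- colSums(w)
  swt <- colSums(w * theta)
  (matrix(swt, nrow(theta), ncol(theta), byrow = TRUE) - w * theta) /
    (matrix(sw, nrow(theta), ncol(theta), byrow = TRUE) - w)
}

#' PRESSO-style pleiotropy residual sum of squares and outlier test
#'
#' The observed residual sum of squares is
#' `RSS = sum_j (betaY_j - theta_(-j) betaX_j)^2` with `theta_(-j)` the
#' leave-one-out IVW estimate. Its null distribution is simulated by a
#' parametric bootstrap under no pleiotropy: `betaX* ~ N(betaX, seX)`,
#' `betaY* ~ N(theta_(-j) betaX, seY)`. The global p is the fraction of
#' simulated RSS at or above the observed. Each instrument's observed
#' squared residual is compared with its simulated distribution for a
#' per-SNP empirical p, Bonferroni-adjusted over k; significant outliers
#' are removed one at a time (worst first) with IVW re-estimation until
#' none remain or only 4 instruments are left.
#'
#' @param instr an [MRInstruments-class] with k >= 4.
#' @param nSim parametric-bootstrap replicates (default 1000).
#' @param outlierAlpha significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @param seed optional integer seed for the bootstrap.
#' @return list: `globalRSS`, `globalP`, `outliers` (data.frame snp, rss,
#'   p, pAdj, flagged), `corrected` ([MRResult-class] after removals; the
#'   uncorrected IVW when nothing was removed), `removed` (character trace
#'   in removal order), `nSim`.
#' @export
mrPresso <- function(instr, nSim = 1000, outlierAlpha = 0.05, seed = NULL) {
  d0 <- instr@data
  if (nrow(d0) < 4) stop("MR-PRESSO needs at least 4 instruments")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  testOnce <- function(d) {
    k <- nrow(d)
    w <- 1 / d$ratioSE^2
    thetaLoo <- (sum(w * d$ratio) - w * d$ratio) / (sum(w) - w)
    obsRes2 <- (d$betaY - thetaLoo * d$betaX)^2
    obsRSS <- sum(obsRes2)

    bx <- matrix(rnorm(k * nSim, d$betaX, d$seX), k, nSim)
    by <- matrix(rnorm(k * nSim, thetaLoo * d$betaX, d$seY), k, nSim)
    thetaStar <- by / bx
    wStar <- (abs(bx) / d$seY)^2            # 1 / ratioSE*^2
    looStar <- .looMatrix(thetaStar, wStar)
    simRes2 <- (by - looStar * bx)^2
    simRSS <- colSums(simRes2)

    globalP <- mean(simRSS >= obsRSS)
    pSnp <- rowMeans(simRes2 >= obsRes2)
    list(globalRSS = obsRSS, globalP = globalP, pSnp = pSnp,
         obsRes2 = obsRes2)
  }

  first <- testOnce(d0)
  pAdj <- pmin(first$pSnp * nrow(d0), 1)
  outliers <- data.frame(snp = d0$snp, rss = first$obsRes2, p = first$pSnp,
                         pAdj = pAdj, flagged = pAdj < outlierAlpha,
                         stringsAsFactors = FALSE)

  removed <- character()
  d <- d0
  res <- first
  while (nrow(d) > 4) {
    pA <- pmin(res$pSnp * nrow(d), 1)
    if (!any(pA < outlierAlpha)) break
    worst <- which.min(res$pSnp)
    removed <- c(removed, d$snp[worst])
    d <- d[-worst, , drop = FALSE]
    res <- testOnce(d)
  }
  corrected <- mrIVW(new("MRInstruments", data = d, meta = instr@meta))
  list(globalRSS = first$globalRSS, globalP = first$globalP,
       outliers = outliers, corrected = corrected, removed = removed,
       nSim = nSim)
}

#' Analytic power of a two-sample MR test with a binary outcome
#'
#' Linear-approximation power of the two-sided Wald test: the
#' non-centrality parameter is
#' `NCP = n r2_xz K (1 - K) log(OR)^2`, where `r2_xz` is the variance of
#' the exposure explained by the instruments, K the outcome case fraction
#' and OR the hypothesized odds ratio per SD of exposure; power is the
#' upper tail of a noncentral chi-square(1) beyond the alpha critical
#' value. At OR = 1 this returns exactly alpha (two-sided size).
#'
#' @param nOutcome total outcome-study sample size.
#' @param caseFraction outcome case fraction K, in (0, 1).
#' @param r2xz variance of the exposure explained by the instruments.
#' @param orPerSd hypothesized odds ratio per SD of exposure.
#' @param alpha test size (default 0.05).
#' @return power in \[0, 1\].
#' @export
mrPower <- function(nOutcome, caseFraction, r2xz, orPerSd, alpha = 0.05) {
  if (caseFraction <= 0 || caseFraction >= 1)
    stop("caseFraction must lie strictly inside (0, 1)")
  stopifnot(nOutcome > 0, r2xz >= 0, r2xz <= 1, orPerSd > 0,
            alpha > 0, alpha < 1)
  ncp <- nOutcome * r2xz * caseFraction * (1 - caseFraction) *
    log(orPerSd)^2
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
}
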