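## Paired-GWAS simulator: block AR(1) LD, four-component bivariate
## causal-effect mixture, multivariate-normal summary statistics, optional
## genomic inflation and allele-coding perturbations.

#' Build a simulation configuration
#'
#' Defines the generative model for a pair of GWAS over a shared SNP panel:
#' SNPs fall into contiguous LD blocks with AR(1) correlation `ar1Rho^|i-j|`
#' (blocks separated by 1 Mb gaps so they are independent loci for pruning
#' and clumping), causal effects follow a four-component mixture (null /
#' trait-1-only / trait-2-only / shared with correlation `rhoShared`), and
#' z scores are drawn from the standard multivariate-normal summary-statistic
#' model per block, optionally inflated by `lambdaInflation`.
#'
#' @param mSnps total SNP count.
#' @param nBlocks number of LD blocks.
#' @param ar1Rho within-block AR(1) correlation, in \[0, 1).
#' @param n1,n2 GWAS sample sizes.
#' @param pi10,pi01,pi11 causal mixture proportions (trait-1-only,
#'   trait-2-only, shared); the null proportion is the remainder.
#' @param h2 length-2 target SNP heritabilities, each in \[0, 1).
#' @param rhoShared correlation of shared causal effects, in \[-1, 1\].
#' @param lambdaInflation multiplicative variance inflation of z (>= 1).
#' @param intergenicFraction fraction of SNPs labelled intergenic (labels
#'   are assigned to causal-free SNPs first).
#' @param palindromicFraction fraction of SNPs given A/T or C/G alleles.
#' @param strandFlipFraction fraction of second-table records reported on
#'   the opposite strand.
#' @param swapFraction fraction of second-table records with effect/other
#'   allele swapped (and the effect sign negated accordingly).
#' @param seed integer seed consumed by [simulatePair()].
#' @return a validated [SimulationConfig-class] object.
#' @export
simConfig <- function(mSnps = 10000L, nBlocks = 50L, ar1Rho = 0.8,
                      n1 = 50000, n2 = 50000,
                      pi10 = 0.004, pi01 = 0.004, pi11 = 0.002,
                      h2 = c(0.3, 0.3), rhoShared = 0.5,
                      lambdaInflation = 1, intergenicFraction = 0.5,
                      palindromicFraction = 0, strandFlipFraction = 0,
                      swapFraction = 0, seed = 1L) {
  pi00 <- 1 - pi10 - pi01 - pi11
  new("SimulationConfig", mSnps = as.integer(mSnps),
      nBlocks = as.integer(nBlocks), ar1Rho = ar1Rho, n1 = n1, n2 = n2,
      pi = c(pi00 = pi00, pi10 = pi10, pi01 = pi01, pi11 = pi11),
      h2 = rep_len(h2, 2), rhoShared = rhoShared,
      lambdaInflation = lambdaInflation,
      intergenicFraction = intergenicFraction,
      palindromicFraction = palindromicFraction,
      strandFlipFraction = strandFlipFraction, swapFraction = swapFraction,
      seed = as.integer(seed))
}

## block sizes and 1-based start/end column indices
.blockLayout <- function(m, nBlocks) {
  sizes <- rep(m %/% nBlocks, nBlocks)
  extra <- m %% nBlocks
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  data.frame(size = sizes, from = c(1L, head(ends, -1) + 1L), to = ends)
}

## coordinates: 1 kb spacing within a block, 1 Mb gaps between blocks, all
## on chromosome 1
.blockPositions <- function(layout) {
  gap <- 1e6
  spacing <- 1000
  pos <- integer(0)
  offset <- 1
  for (i in seq_len(nrow(layout))) {
    pos <- c(pos, offset + spacing * (seq_len(layout$size[i]) - 1L))
    offset <- offset + spacing * layout$size[i] + gap
  }
  as.integer(pos)
}

## x[, j] = rho x[, j-1] + sqrt(1-rho^2) eps gives exact AR(1) columns
.ar1Matrix <- function(n, m, rho) {
  x <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) x[, j] <- rho * x[, j - 1] + s * x[, j]
  }
  x
}

## AR(1)-correlated unit-variance noise vector
.ar1Noise <- function(m, rho) {
  z <- rnorm(m)
  if (rho == 0 || m == 1) return(z)
  as.numeric(stats::filter(c(z[1], sqrt(1 - rho^2) * z[-1]), rho,
                           method = "recursive"))
}

## (R %*% beta) for AR(1) correlation via forward/backward recursions, O(m)
.ar1Rbeta <- function(beta, rho) {
  m <- length(beta)
  if (rho == 0 || m == 1) return(beta)
  f <- as.numeric(stats::filter(beta, rho, method = "recursive"))
  g <- as.numeric(stats::filter(rev(beta), rho, method = "recursive"))
  f + rev(g) - beta
}

#' Simulate an LD reference panel
#'
#' Draws `nRef` standardized-Gaussian genotype vectors with the
#' configuration's block AR(1) correlation; columns are standardized so the
#' empirical within-panel r-squared is exact at the diagonal.
#'
#' @param cfg a [SimulationConfig-class].
#' @param nRef number of reference individuals (>= 50).
#' @return an [LDReference-class] with a 1 Mb default query window.
#' @export
simulateLDReference <- function(cfg, nRef = 200L) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (nRef < 50) stop("nRef must be at least 50")
  layout <- .blockLayout(cfg@mSnps, cfg@nBlocks)
  blocks <- lapply(seq_len(nrow(layout)), function(i)
    .ar1Matrix(nRef, layout$size[i], cfg@ar1Rho))
  x <- do.call(cbind, blocks)
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  new("LDReference", genotypes = x,
      snp = paste0("rs", seq_len(cfg@mSnps)),
      chrom = rep("1", cfg@mSnps), pos = .blockPositions(layout),
      windowBp = 1e6)
}

#' Draw per-SNP causal effects from the four-component mixture
#'
#' Each SNP is assigned to null / trait-1-only / trait-2-only / shared with
#' the configured proportions. Causal effects are zero-mean normal with
#' variance `h2_t / m_causal_t` so that the expected summed squared effect
#' equals the target heritability; shared-component pairs are bivariate
#' normal with correlation `rhoShared`. Nulls are exactly zero.
#'
#' @param cfg a [SimulationConfig-class].
#' @return data.frame (component, beta1, beta2) with attribute `trueRg`,
#'   the implied genetic correlation
#'   `rhoShared * pi11 / sqrt((pi10 + pi11) (pi01 + pi11))`.
#' @export
simulateEffects <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  m <- cfg@mSnps
  labels <- c("null", "c1", "c2", "shared")
  for (try in 1:20) {
    comp <- sample(labels, m, replace = TRUE, prob = cfg@pi)
    if (all(labels[cfg@pi > 0] %in% comp)) break
    if (try == 20) stop("could not populate all mixture components; increase mSnps")
    warning("empty mixture component; resampling assignment")
  }
  beta1 <- numeric(m); beta2 <- numeric(m)
  mC1 <- sum(comp %in% c("c1", "shared"))
  mC2 <- sum(comp %in% c("c2", "shared"))
  s1 <- if (mC1) sqrt(cfg@h2[1] / mC1) else 0
  s2 <- if (mC2) sqrt(cfg@h2[2] / mC2) else 0
  i1 <- comp == "c1"; i2 <- comp == "c2"; ish <- comp == "shared"
  beta1[i1] <- rnorm(sum(i1), sd = s1)
  beta2[i2] <- rnorm(sum(i2), sd = s2)
  if (any(ish)) {
    u <- rnorm(sum(ish)); v <- rnorm(sum(ish))
    rho <- cfg@rhoShared
    beta1[ish] <- s1 * u
    beta2[ish] <- s2 * (rho * u + sqrt(1 - rho^2) * v)
  }
  out <- data.frame(component = comp, beta1 = beta1, beta2 = beta2,
                    stringsAsFactors = FALSE)
  piC <- cfg@pi
  denom <- sqrt((piC[["pi10"]] + piC[["pi11"]]) * (piC[["pi01"]] + piC[["pi11"]]))
  attr(out, "trueRg") <- if (denom > 0) cfg@rhoShared * piC[["pi11"]] / denom else NA_real_
  out
}

.randomAlleles <- function(m, palindromicFraction) {
  bases <- names(.complement)
  a1 <- sample(bases, m, replace = TRUE)
  ## a non-palindromic partner: anything except self and complement
  a2 <- vapply(a1, function(b)
    sample(setdiff(bases, c(b, .complement[[b]])), 1), character(1))
  nP <- round(palindromicFraction * m)
  if (nP > 0) {
    idx <- sample.int(m, nP)
    a2[idx] <- unname(.complement[a1[idx]])
  }
  list(a1 = unname(a1), a2 = unname(a2))
}

#' Simulate paired GWAS summary statistics
#'
#' Per LD block draws `z_t = sqrt(n_t) R beta_t + e_t` with
#' `e_t ~ N(0, R)` (noise independent between traits), scales by
#' `sqrt(lambdaInflation)`, and converts to two-sided normal p-values.
#' Effect sizes are reported per standardized genotype
#' (`beta = z / sqrt(n)`, `se = 1 / sqrt(n)`). Alleles are assigned at
#' random (with configurable palindromic fraction); in the second table a
#' configurable fraction of records is strand-flipped or allele-swapped to
#' exercise harmonization. Intergenic labels are given to causal-free SNPs
#' first.
#'
#' @param cfg a [SimulationConfig-class].
#' @param effects output of [simulateEffects()]; drawn fresh when NULL.
#' @return list with elements `a`, `b` ([SummaryStats-class]), `intergenic`
#'   (named logical), `effects`, and `trueRg`.
#' @export
simulateSumstats <- function(cfg, effects = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (is.null(effects)) effects <- simulateEffects(cfg)
  stopifnot(nrow(effects) == cfg@mSnps)
  m <- cfg@mSnps
  layout <- .blockLayout(m, cfg@nBlocks)
  pos <- .blockPositions(layout)
  snp <- paste0("rs", seq_len(m))

  drawZ <- function(beta, n) {
    z <- numeric(m)
    for (i in seq_len(nrow(layout))) {
      j <- layout$from[i]:layout$to[i]
      z[j] <- sqrt(n) * .ar1Rbeta(beta[j], cfg@ar1Rho) +
        .ar1Noise(length(j), cfg@ar1Rho)
    }
    z * sqrt(cfg@lambdaInflation)
  }
  z1 <- drawZ(effects$beta1, cfg@n1)
  z2 <- drawZ(effects$beta2, cfg@n2)

  al <- .randomAlleles(m, cfg@palindromicFraction)
  mk <- function(z, n, trait, a1, a2) {
    p <- pmax(.pFromZ(z), .Machine$double.xmin)
    df <- data.frame(snp = snp, chrom = "1", pos = pos, a1 = a1, a2 = a2,
                     beta = z / sqrt(n), se = 1 / sqrt(n), pvalue = p,
                     n = n, z = z, stringsAsFactors = FALSE)
    new("SummaryStats", snps = df, trait = trait,
        dropLog = data.frame(snp = character(), reason = character(),
                             stringsAsFactors = FALSE),
        provenance = list(source = "simulateSumstats"))
  }
  a <- mk(z1, cfg@n1, "traitA", al$a1, al$a2)

  ## perturb the second table's allele coding on non-palindromic SNPs
  b1 <- al$a1; b2 <- al$a2
  beta2Rep <- z2 / sqrt(cfg@n2); z2Rep <- z2
  palin <- .isPalindromic(al$a1, al$a2)
  perturbable <- which(!palin)
  nFlip <- round(cfg@strandFlipFraction * m)
  nSwap <- round(cfg@swapFraction * m)
  chosen <- sample(perturbable, min(nFlip + nSwap, length(perturbable)))
  doFlip <- chosen[seq_len(min(nFlip, length(chosen)))]
  doSwap <- setdiff(chosen, doFlip)
  if (length(doFlip)) {
    b1[doFlip] <- unname(.complement[b1[doFlip]])
    b2[doFlip] <- unname(.complement[b2[doFlip]])
  }
  if (length(doSwap)) {
    tmp <- b1[doSwap]; b1[doSwap] <- b2[doSwap]; b2[doSwap] <- tmp
    beta2Rep[doSwap] <- -beta2Rep[doSwap]
    z2Rep[doSwap] <- -z2Rep[doSwap]
  }
  b <- mk(z2Rep, cfg@n2, "traitB", b1, b2)
  b@snps$beta <- beta2Rep

  ## intergenic mask: causal-free SNPs first
  nInter <- round(cfg@intergenicFraction * m)
  isNull <- effects$component == "null"
  ord <- order(!isNull, runif(m))   # nulls first, random within group
  intergenic <- setNames(rep(FALSE, m), snp)
  intergenic[ord[seq_len(nInter)]] <- TRUE

  list(a = a, b = b, intergenic = intergenic, effects = effects,
       trueRg = attr(effects, "trueRg"))
}

#' One-call simulation of a harmonization-ready dataset
#'
#' Seeds the RNG from `cfg@seed`, draws effects, summary statistics and
#' (optionally) an LD reference panel, and harmonizes the pair.
#'
#' @param cfg a [SimulationConfig-class].
#' @param nRef reference-panel size; 0 skips the panel.
#' @return list: `pair` ([HarmonizedPair-class]), `ldref` (or NULL),
#'   `intergenic`, `effects`, `trueRg`, `cfg`.
#' @export
simulatePair <- function(cfg, nRef = 200L) {
  stopifnot(is(cfg, "SimulationConfig"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg@seed)
  sim <- simulateSumstats(cfg)
  ldref <- if (nRef > 0) simulateLDReference(cfg, nRef) else NULL
  pair <- harmonizePair(sim$a, sim$b)
  list(pair = pair, ldref = ldref,
       intergenic = sim$intergenic, effects = sim$effects,
       trueRg = sim$trueRg, cfg = cfg)
}

#' Simulate a two-sample MR instrument table
#'
#' True instrument-exposure effects are drawn uniformly from `betaXRange`
#' (random sign); observed effects add normal noise at the stated standard
#' errors, and outcome effects follow `theta * betaX_true + pleio_j`.
#'
#' @param theta true causal effect (log-odds per exposure unit).
#' @param k number of instruments (>= 2).
#' @param pleio per-instrument pleiotropic intercepts (recycled; default 0).
#' @param seX,seY observed standard errors (recycled).
#' @param betaXRange range of |true instrument effect|.
#' @param seed optional integer seed.
#' @return an [MRInstruments-class]; true effects and theta are kept in
#'   `meta` for calibration studies.
#' @export
simulateMRDataset <- function(theta, k, pleio = 0, seX = 0.01, seY = 0.05,
                              betaXRange = c(0.05, 0.2), seed = NULL) {
  if (k < 2) stop("need at least 2 instruments")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  pleio <- rep_len(pleio, k)
  seX <- rep_len(seX, k)
  seY <- rep_len(seY, k)
  bxTrue <- sample(c(-1, 1), k, replace = TRUE) *
    runif(k, betaXRange[1], betaXRange[2])
  bx <- rnorm(k, bxTrue, seX)
  by <- rnorm(k, theta * bxTrue + pleio, seY)
  d <- data.frame(snp = paste0("iv", seq_len(k)), betaX = bx, seX = seX,
                  betaY = by, seY = seY, stringsAsFactors = FALSE)
  d$ratio <- d$betaY / d$betaX
  d$ratioSE <- d$seY / abs(d$betaX)
  d$F <- (d$betaX / d$seX)^2
  new("MRInstruments", data = d,
      meta = list(simulated = TRUE, theta = theta, betaXTrue = bxTrue,
                  pleio = pleio))
}
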