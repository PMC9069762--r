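test_that("instrument harmonization computes ratios, SEs and F", {
  exp <- makeSumstats(3, beta = c(0.1, 0.2, -0.1), se = 0.02)
  out <- makeSumstats(3, beta = c(0.01, 0.03, 0.02), se = 0.05)
  instr <- harmonizeInstruments(exp, out, c("rs1", "rs2", "rs3"))
  d <- instrumentData(instr)
  expect_equal(d$ratio, c(0.01 / 0.1, 0.03 / 0.2, 0.02 / -0.1))
  expect_equal(d$ratioSE, 0.05 / abs(c(0.1, 0.2, -0.1)))
  expect_equal(d$F, (c(0.1, 0.2, -0.1) / 0.02)^2)
})

test_that("outcome allele swaps are corrected before the ratio", {
  exp <- makeSumstats(1, a1 = "A", a2 = "G", beta = 0.1, se = 0.02)
  out <- makeSumstats(1, a1 = "G", a2 = "A", beta = 0.05, se = 0.05)
  instr <- harmonizeInstruments(exp, out, "rs1")
  expect_equal(instrumentData(instr)$betaY, -0.05)
  expect_equal(instrumentData(instr)$ratio, -0.5)
})

test_that("zero-betaX and missing instruments are dropped with reasons", {
  exp <- makeSumstats(3, beta = c(0.1, 0, 0.2), se = 0.02)
  out <- makeSumstats(2, beta = c(0.01, 0.02), se = 0.05)
  instr <- harmonizeInstruments(exp, out, c("rs1", "rs2", "rs3"))
  expect_equal(nrow(instrumentData(instr)), 1)
  expect_equal(instr@meta$zeroBetaXDropped, 1L)
  expect_equal(instr@meta$missingDropped, 1L)
  # nothing left is a result, not an exception
  none <- harmonizeInstruments(exp, out, "rs99")
  expect_equal(nrow(instrumentData(none)), 0)
  expect_s4_class(mrIVW(none), "MRResult")
  expect_true(mrIVW(none)@details$noInstruments)
})

test_that("IVW reduces correctly in the homogeneous and k = 1 cases", {
  instr <- makeInstruments(betaX = c(0.1, 0.2, 0.4),
                           betaY = 0.07 * c(0.1, 0.2, 0.4))
  r <- mrIVW(instr)
  expect_equal(r@estimate, 0.07, tolerance = 1e-12)
  expect_equal(r@Q, 0, tolerance = 1e-20)
  w <- 1 / instrumentData(instr)$ratioSE^2
  expect_equal(r@se, 1 / sqrt(sum(w)))   # RE floor leaves FE se at Q = 0
  one <- makeInstruments(0.1, 0.005)
  r1 <- mrIVW(one)
  expect_equal(r1@method, "Wald ratio")
  expect_equal(r1@estimate, 0.05)
  expect_equal(r1@se, 0.05 / 0.1)
  expect_true(is.na(r1@Q))
})

test_that("IVW equals the closed-form weighted mean on a fixture", {
  bx <- c(0.12, 0.08, 0.2, 0.15)
  by <- c(0.015, 0.004, 0.03, 0.01)
  instr <- makeInstruments(bx, by, seY = c(0.04, 0.05, 0.03, 0.06))
  r <- mrIVW(instr)
  theta <- by / bx
  w <- (bx / c(0.04, 0.05, 0.03, 0.06))^2
  est <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - est)^2)
  expect_equal(r@estimate, est, tolerance = 1e-12)
  expect_equal(r@Q, Q, tolerance = 1e-12)
  expect_equal(r@se, max(1, sqrt(Q / 3)) / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(r@ciHigh - r@estimate, qnorm(0.975) * r@se, tolerance = 1e-9)
  # standalone Cochran Q is the identical quantity
  q <- cochranQ(instr)
  expect_equal(q$Q, r@Q)
  expect_equal(q$df, 3)
  expect_equal(q$p, r@QP)
})

test_that("Egger matches an independent weighted regression oracle", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  by <- c(0.02, 0.025, 0.035, 0.05)
  seY <- c(0.01, 0.012, 0.009, 0.011)
  instr <- makeInstruments(bx, by, seY = seY)
  r <- mrEgger(instr)
  # normal-equations oracle for weighted least squares with intercept
  w <- 1 / seY^2
  X <- cbind(1, bx)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * by))
  expect_equal(r@intercept, beta[1], tolerance = 1e-10)
  expect_equal(r@estimate, beta[2], tolerance = 1e-10)
  expect_error(mrEgger(makeInstruments(c(0.1, 0.2), c(0.01, 0.02))),
               "at least 3")
})

test_that("Egger orientation flips negative exposure effects", {
  bx <- c(0.1, -0.15, 0.2, -0.3)
  by <- 0.1 * bx + 0.01
  instr <- makeInstruments(bx, by)
  r <- mrEgger(instr)
  instr2 <- makeInstruments(abs(bx), ifelse(bx < 0, -by, by))
  r2 <- mrEgger(instr2)
  expect_equal(r@estimate, r2@estimate)
  expect_equal(r@intercept, r2@intercept)
})

test_that("IVW and Egger recover a simulated causal effect", {
  ests <- eggs <- ses <- numeric(10)
  for (s in 1:10) {
    iv <- simulateMRDataset(0.1, 50, seed = 100 + s)
    ests[s] <- mrIVW(iv)@estimate
    eggs[s] <- mrEgger(iv)@estimate
    ses[s] <- mrIVW(iv)@se
  }
  expect_lt(abs(mean(ests) - 0.1), 3 * sd(ests) / sqrt(10) + 0.005)
  expect_lt(abs(mean(eggs) - 0.1), 3 * sd(eggs) / sqrt(10) + 0.02)
  # zero-pleiotropy data: Egger intercept consistent with 0
  iv <- simulateMRDataset(0.1, 50, seed = 200)
  eg <- mrEgger(iv)
  expect_lt(abs(eg@intercept), 3 * eg@interceptSE)
})

test_that("a displaced ratio drives Cochran's Q above its null quantile", {
  bx <- rep(0.2, 5)
  by <- 0.1 * bx
  seY <- rep(0.02, 5)
  by[5] <- by[5] + 10 * seY[5]      # 10 ratio-SE displacement
  instr <- makeInstruments(bx, by, seY = seY)
  q <- cochranQ(instr)
  expect_equal(q$df, 4)
  expect_gt(q$Q, qchisq(0.99, 4))
  # two instruments: df = 1
  expect_equal(cochranQ(makeInstruments(c(0.1, 0.2), c(0.01, 0.01)))$df, 1)
})

test_that("leave-one-out isolates a planted outlier", {
  bx <- rep(0.2, 6)
  by <- 0.1 * bx
  by[3] <- by[3] + 0.2
  instr <- makeInstruments(bx, by)
  loo <- leaveOneOut(instr)
  expect_equal(nrow(loo), 6)
  dev <- abs(loo$estimate - attr(loo, "fullEstimate"))
  expect_equal(loo$omitted[which.max(dev)], "iv3")
  # homogeneous ratios: every LOO estimate equals the full estimate
  hom <- makeInstruments(c(0.1, 0.2, 0.3), 0.05 * c(0.1, 0.2, 0.3))
  looH <- leaveOneOut(hom)
  expect_equal(looH$estimate, rep(0.05, 3), tolerance = 1e-12)
  expect_error(leaveOneOut(makeInstruments(c(0.1, 0.2), c(0.01, 0.01))),
               "at least 3")
  expect_silent(leaveOneOut(makeInstruments(c(0.1, 0.2), c(0.01, 0.01)),
                            allowPairs = TRUE))
})

test_that("F statistics flag weak instruments", {
  instr <- makeInstruments(c(0.1, 0, 0.05), c(0.01, 0.001, 0.002),
                           seX = 0.02)
  instr@data$betaX[2] <- 1e-9      # effectively zero strength
  instr@data$F <- (instr@data$betaX / instr@data$seX)^2
  f <- fStatistics(instr)
  expect_equal(f$F[1], 25)
  expect_false(f$weak[1])
  expect_true(f$weak[2])
  expect_equal(f$F[3], 6.25)
  expect_true(f$weak[3])
})

test_that("PRESSO flags a planted outlier and reduces bias", {
  theta <- 0.1
  iv <- simulateMRDataset(theta, 15, pleio = c(rep(0, 14), 10 * 0.05),
                          seed = 42)
  pr <- mrPresso(iv, nSim = 600, seed = 7)
  expect_lt(pr$globalP, 0.05)
  expect_true(pr$outliers$flagged[15])
  expect_true("iv15" %in% pr$removed)
  raw <- mrIVW(iv)@estimate
  expect_lt(abs(pr$corrected@estimate - theta), abs(raw - theta))
  expect_error(mrPresso(simulateMRDataset(0.1, 3, seed = 1)), "at least 4")
})

test_that("PRESSO stays quiet on clean data", {
  flagged <- integer(8)
  for (s in 1:8) {
    iv <- simulateMRDataset(0.1, 12, seed = 500 + s)
    pr <- mrPresso(iv, nSim = 300, seed = 600 + s)
    flagged[s] <- sum(pr$outliers$flagged)
  }
  # Bonferroni-controlled outlier test: false flags are rare
  expect_lte(sum(flagged), 2)
})

test_that("orientation invariance: flipping a reported allele changes nothing", {
  exp <- makeSumstats(4, beta = c(0.1, 0.15, 0.2, 0.12), se = 0.02)
  out <- makeSumstats(4, beta = c(0.011, 0.014, 0.022, 0.013), se = 0.03)
  base <- mrIVW(harmonizeInstruments(exp, out, paste0("rs", 1:4)))
  # flip instrument 2's coding in both studies
  flipBoth <- function(t, i) {
    d <- snpData(t)
    tmp <- d$a1[i]; d$a1[i] <- d$a2[i]; d$a2[i] <- tmp
    d$beta[i] <- -d$beta[i]; d$z[i] <- -d$z[i]
    new("SummaryStats", snps = d, trait = t@trait, dropLog = t@dropLog,
        provenance = t@provenance)
  }
  alt <- mrIVW(harmonizeInstruments(flipBoth(exp, 2), flipBoth(out, 2),
                                    paste0("rs", 1:4)))
  expect_equal(alt@estimate, base@estimate, tolerance = 1e-12)
  expect_equal(alt@Q, base@Q, tolerance = 1e-12)
})

test_that("instrument selection applies the relaxed-threshold rule", {
  set.seed(91)
  # two strong loci in different blocks: no relaxation
  cfg <- simConfig(mSnps = 400, nBlocks = 4, seed = 91)
  ref <- simulateLDReference(cfg, nRef = 500)
  p <- rep(0.5, 400)
  p[c(10, 150)] <- 1e-9            # separate blocks
  p[c(11, 12)] <- c(1e-8 / 2, 1e-8 / 3)  # same clump as SNP 10
  t <- summaryStats(data.frame(snp = ref@snp, chrom = ref@chrom,
                               pos = ref@pos, a1 = "A", a2 = "G",
                               beta = NA, se = NA, pvalue = p, n = 1e4))
  ids <- selectInstruments(t, ref, clumpR2 = 0.05)
  expect_false(attr(ids, "relaxedApplied"))
  expect_equal(attr(ids, "thresholdUsed"), 5e-8)
  # clumped: one index SNP per locus, the minimum-p member
  expect_setequal(as.character(ids), c("rs10", "rs150"))
  # one locus only: relaxed threshold kicks in and recruits 1e-6 SNPs
  p2 <- rep(0.5, 400)
  p2[10] <- 1e-9
  p2[250] <- 5e-7
  t2 <- summaryStats(data.frame(snp = ref@snp, chrom = ref@chrom,
                                pos = ref@pos, a1 = "A", a2 = "G",
                                beta = NA, se = NA, pvalue = p2, n = 1e4))
  ids2 <- selectInstruments(t2, ref, clumpR2 = 0.05)
  expect_true(attr(ids2, "relaxedApplied"))
  expect_equal(attr(ids2, "thresholdUsed"), 1e-6)
  expect_setequal(as.character(ids2), c("rs10", "rs250"))
  # nothing even at the relaxed threshold: empty result, no exception
  t3 <- summaryStats(data.frame(snp = ref@snp, chrom = ref@chrom,
                                pos = ref@pos, a1 = "A", a2 = "G",
                                beta = NA, se = NA, pvalue = 0.5, n = 1e4))
  ids3 <- selectInstruments(t3, ref, clumpR2 = 0.05)
  expect_length(ids3, 0)
})

test_that("MR power has the required size, monotonicity and MC agreement", {
  expect_equal(mrPower(50000, 0.3, 0.02, 1), 0.05, tolerance = 1e-12)
  ns <- c(1e4, 5e4, 1e5, 5e5)
  pw <- sapply(ns, function(n) mrPower(n, 0.3, 0.02, 1.1))
  expect_true(all(diff(pw) > 0))
  r2s <- c(0.005, 0.01, 0.05, 0.1)
  pw2 <- sapply(r2s, function(r) mrPower(50000, 0.3, r, 1.1))
  expect_true(all(diff(pw2) > 0))
  expect_error(mrPower(1e4, 1.2, 0.02, 1.1), "caseFraction")

  # Monte-Carlo oracle: summary-level two-sample MR with a binary outcome.
  # k instruments explain r2 of the standardized exposure; the outcome
  # log-odds SE per standardized allele is 1/sqrt(n K (1-K)).
  set.seed(92)
  n <- 50000; K <- 0.3; r2 <- 0.02; or <- 1.15; alpha <- 0.05
  k <- 10
  bx <- rep(sqrt(r2 / k), k)
  seY <- 1 / sqrt(n * K * (1 - K))
  nsim <- 400
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    by <- rnorm(k, log(or) * bx, seY)
    iv <- makeInstruments(bx, by, seX = 1e-4, seY = seY)
    w <- 1 / iv@data$ratioSE^2
    est <- sum(w * iv@data$ratio) / sum(w)
    rej[i] <- abs(est) / (1 / sqrt(sum(w))) > qnorm(0.975)
  }
  analytic <- mrPower(n, K, r2, or, alpha)
  mcse <- sqrt(analytic * (1 - analytic) / nsim)
  expect_equal(mean(rej), analytic, tolerance = 2 * mcse + 0.01)
})
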