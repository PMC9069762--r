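test_that("simulation configs validate their parameter ranges", {
  expect_s4_class(simConfig(), "SimulationConfig")
  expect_error(simConfig(pi11 = 1.5), "pi")
  expect_error(simConfig(ar1Rho = 1), "ar1Rho")
  expect_error(simConfig(h2 = c(1.2, 0.3)), "h2")
  expect_error(simConfig(lambdaInflation = 0.5), "lambdaInflation")
  expect_error(simConfig(n1 = 0), "sample sizes")
})

test_that("LD reference reproduces the AR(1) correlation structure", {
  set.seed(5)
  cfg <- simConfig(mSnps = 400, nBlocks = 4, ar1Rho = 0.9)
  ref <- simulateLDReference(cfg, nRef = 2000)
  g <- ref@genotypes
  # adjacent within-block r^2 ~ rho^2 = 0.81
  adj <- sapply(seq(2, 100), function(j) cor(g[, j - 1], g[, j])^2)
  expect_equal(mean(adj), 0.81, tolerance = 0.03)
  # rho = 0: off-diagonal r^2 at sampling-noise level ~ 1/nRef
  cfg0 <- simConfig(mSnps = 200, nBlocks = 2, ar1Rho = 0)
  ref0 <- simulateLDReference(cfg0, nRef = 2000)
  off <- cor(ref0@genotypes[, 1:50])
  expect_lt(mean(off[upper.tri(off)]^2), 3 / 2000)
  # inter-block gap exceeds the pruning window
  gap <- ref@pos[101] - ref@pos[100]
  expect_gt(gap, 250000)
  expect_error(simulateLDReference(cfg, nRef = 10), "at least 50")
})

test_that("simulation is deterministic given the seed", {
  cfg <- simConfig(mSnps = 300, nBlocks = 3, seed = 99)
  s1 <- suppressWarnings(simulatePair(cfg, nRef = 60))
  s2 <- suppressWarnings(simulatePair(cfg, nRef = 60))
  expect_identical(s1$ldref@genotypes, s2$ldref@genotypes)
  expect_identical(snpData(s1$pair@a), snpData(s2$pair@a))
  expect_identical(s1$effects, s2$effects)
  iv1 <- simulateMRDataset(0.1, 10, seed = 3)
  iv2 <- simulateMRDataset(0.1, 10, seed = 3)
  expect_identical(instrumentData(iv1), instrumentData(iv2))
})

test_that("effect mixture matches its configured structure", {
  set.seed(7)
  # no shared component: causal effects uncorrelated
  e0 <- simulateEffects(simConfig(mSnps = 20000, pi10 = 0.02, pi01 = 0.02,
                                  pi11 = 0))
  causal <- e0$beta1 != 0 | e0$beta2 != 0
  expect_lt(abs(cor(e0$beta1[causal], e0$beta2[causal])), 0.05)
  expect_true(all(e0$beta1[e0$component == "null"] == 0))
  # degenerate correlation: shared effects proportional
  e1 <- simulateEffects(simConfig(mSnps = 5000, pi10 = 0, pi01 = 0,
                                  pi11 = 0.02, rhoShared = 1))
  sh <- e1$component == "shared"
  expect_equal(cor(e1$beta1[sh], e1$beta2[sh]), 1, tolerance = 1e-12)
  # configured correlation recovered empirically at large m
  e2 <- simulateEffects(simConfig(mSnps = 10000, pi10 = 0, pi01 = 0,
                                  pi11 = 0.01, rhoShared = 0.5))
  sh2 <- e2$component == "shared"
  expect_equal(cor(e2$beta1[sh2], e2$beta2[sh2]), 0.5, tolerance = 0.2)
  # expected summed squared effects hit the heritability target
  expect_equal(sum(e2$beta1^2), 0.3, tolerance = 0.15)
  expect_equal(attr(e2, "trueRg"), 0.5)
})

test_that("null summary statistics have unit chi-square and uniform p", {
  set.seed(21)
  cfg <- simConfig(mSnps = 50000, nBlocks = 100, pi10 = 0, pi01 = 0,
                   pi11 = 0)
  sim <- simulateSumstats(cfg)
  z <- snpData(sim$a)$z
  expect_equal(mean(z^2), 1, tolerance = 0.05)
  p <- snpData(sim$a)$pvalue
  # LD shrinks the effective sample: for AR(1) at rho = 0.8 roughly by
  # (1 + rho) / (1 - rho) = 9
  for (t in c(0.1, 0.01))
    expect_lt(abs(mean(p < t) - t), 4 * sqrt(t * (1 - t) / (50000 / 9)))
})

test_that("inflation scales the median chi-square as configured", {
  set.seed(22)
  cfg <- simConfig(mSnps = 50000, nBlocks = 100, pi10 = 0, pi01 = 0,
                   pi11 = 0, lambdaInflation = 1.5)
  sim <- simulateSumstats(cfg)
  z <- snpData(sim$a)$z
  expect_equal(median(z^2) / qchisq(0.5, 1), 1.5, tolerance = 0.05)
})

test_that("clean generated pairs validate with zero drops", {
  set.seed(23)
  cfg <- simConfig(mSnps = 300, nBlocks = 3)
  sim <- suppressWarnings(simulateSumstats(cfg))
  ta <- summaryStats(snpData(sim$a))    # revalidate from scratch
  expect_equal(nrow(dropLog(ta)), 0)
  hp <- harmonizePair(sim$a, sim$b)
  expect_equal(hp@counts[["shared"]], 300L)
  expect_equal(hp@counts[["palindromicDropped"]] +
               hp@counts[["unresolvedDropped"]], 0L)
})

test_that("intergenic labels go to causal-free SNPs first", {
  set.seed(24)
  cfg <- simConfig(mSnps = 2000, nBlocks = 10, pi10 = 0.05, pi01 = 0.05,
                   pi11 = 0.05, intergenicFraction = 0.5)
  sim <- simulateSumstats(cfg)
  causal <- sim$effects$component != "null"
  # nulls outnumber the intergenic quota, so no causal SNP is intergenic
  expect_equal(sum(sim$intergenic & causal), 0)
  expect_equal(sum(sim$intergenic), 1000)
})

test_that("MR scenario generator plants the requested structure", {
  iv <- simulateMRDataset(0.25, 30, seX = 1e-6, seY = 1e-6, seed = 8)
  # noiseless limit: every Wald ratio equals theta
  expect_equal(instrumentData(iv)$ratio, rep(0.25, 30), tolerance = 1e-3)
  # planted outlier construction
  pl <- c(rep(0, 9), 10 * 0.05)
  iv2 <- simulateMRDataset(0.1, 10, pleio = pl, seY = 0.05, seed = 9)
  expect_equal(iv2@meta$pleio, pl)
  expect_error(simulateMRDataset(0.1, 1), "at least 2")
})
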