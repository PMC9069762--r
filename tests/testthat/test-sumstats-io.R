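test_that("a well-formed file loads with an empty filter log", {
  df <- makeSnpTable(3)
  path <- writeSumstatsFile(data.frame(SNP = df$snp, CHR = df$chrom,
                                       BP = df$pos, A1 = df$a1, A2 = df$a2,
                                       BETA = df$beta, SE = df$se,
                                       N = df$n))
  t <- loadSumstats(path, trait = "toy")
  expect_s4_class(t, "SummaryStats")
  expect_equal(length(t), 3)
  expect_equal(nrow(dropLog(t)), 0)
  expect_equal(traitLabel(t), "toy")
})

test_that("invalid rows are dropped with reason codes and counts balance", {
  df <- makeSnpTable(5)
  df$se[2] <- 0          # invalid
  df$pvalue <- c(NA, NA, 1.5, NA, NA)  # row 3 invalid
  path <- writeSumstatsFile(data.frame(SNP = df$snp, CHR = df$chrom,
                                       BP = df$pos, A1 = df$a1, A2 = df$a2,
                                       BETA = df$beta, SE = df$se,
                                       P = df$pvalue, N = df$n))
  t <- loadSumstats(path)
  expect_equal(length(t), 3)
  log <- dropLog(t)
  expect_equal(nrow(log), 2)
  expect_setequal(log$reason, c("nonpositive_se", "pvalue_above_1"))
  expect_equal(length(t) + nrow(log), 5)
})

test_that("odds ratios convert to log scale with the right z", {
  path <- writeSumstatsFile(data.frame(SNP = "rs1", CHR = "1", BP = 100,
                                       A1 = "A", A2 = "G", OR = 1.105,
                                       SE = 0.05, N = 1000))
  t <- loadSumstats(path)
  expect_equal(snpData(t)$beta, log(1.105), tolerance = 1e-12)
  expect_equal(snpData(t)$z, log(1.105) / 0.05, tolerance = 1e-12)
  expect_equal(snpData(t)$z, 1.997, tolerance = 1e-3)
})

test_that("column mapping and missing mandatory columns behave as specified", {
  df <- makeSnpTable(3)
  path <- writeSumstatsFile(data.frame(marker = df$snp, chromosome = df$chrom,
                                       position = df$pos, ea = df$a1,
                                       oa = df$a2, b = df$beta, s = df$se))
  t <- loadSumstats(path, columnMap = c(snp = "marker", chrom = "chromosome",
                                        pos = "position", a1 = "ea",
                                        a2 = "oa", beta = "b", se = "s"))
  expect_equal(length(t), 3)
  expect_error(loadSumstats(path), "mandatory")
  expect_error(loadSumstats(writeSumstatsFile(df[0, ])), "empty")
})

test_that("deriveZ implements every policy", {
  expect_equal(deriveZ(0.10, 0.05, NA), 2.0, ignore_attr = TRUE)
  expect_equal(deriveZ(0, 0.05, NA), 0, ignore_attr = TRUE)
  expect_equal(as.numeric(deriveZ(0.1, NA, 0.05, policy = "from_p")),
               1.959964, tolerance = 1e-6)
  expect_equal(as.numeric(deriveZ(-0.1, NA, 0.05, policy = "from_p")),
               -1.959964, tolerance = 1e-6)
  # reconcile prefers beta/se and flags the discrepancy
  z <- deriveZ(0.10, 0.05, 0.9)
  expect_equal(as.numeric(z), 2.0)
  expect_true(attr(z, "mismatch"))
  z2 <- deriveZ(0.10, 0.05, 2 * pnorm(-2))
  expect_false(attr(z2, "mismatch"))
  expect_true(is.na(deriveZ(NA, NA, NA)))
})

test_that("duplicate snp ids keep the smallest-se record", {
  df <- makeSnpTable(3)
  df$snp <- c("rs1", "rs1", "rs2")
  df$se <- c(0.5, 0.1, 0.2)
  t <- summaryStats(df)
  expect_equal(length(t), 2)
  expect_equal(snpData(t)$se[snpData(t)$snp == "rs1"], 0.1)
  expect_true("duplicate_snp_id" %in% dropLog(t)$reason)
})

test_that("p = 0 underflow is clamped to the smallest positive double", {
  df <- makeSnpTable(2, beta = NA_real_, se = NA_real_,
                     pvalue = c(0, 0.5))
  t <- summaryStats(df)
  expect_equal(length(t), 2)
  expect_equal(min(snpData(t)$pvalue), .Machine$double.xmin)
  expect_true("pvalue_underflow_clamped" %in% dropLog(t)$reason)
})

test_that("harmonization aligns swapped and strand-flipped alleles", {
  a <- makeSumstats(4, a1 = c("A", "C", "G", "T"), a2 = c("G", "A", "T", "C"),
                    beta = c(0.1, 0.2, 0.3, 0.4))
  bdf <- makeSnpTable(4, a1 = c("G", "C", "C", "T"),
                      a2 = c("A", "A", "A", "C"),
                      beta = c(0.2, 0.2, 0.3, 0.4))
  # rs1: swapped -> negate; rs2: identical; rs3: complement (G/T -> C/A)
  b <- summaryStats(bdf)
  hp <- harmonizePair(a, b)
  da <- snpData(hp@a); db <- snpData(hp@b)
  expect_identical(da$snp, db$snp)
  expect_identical(da$a1, db$a1)
  expect_equal(db$beta[db$snp == "rs1"], -0.2)
  expect_equal(db$beta[db$snp == "rs2"], 0.2)
  expect_equal(db$beta[db$snp == "rs3"], 0.3)   # strand relabel, no sign change
  expect_equal(hp@counts[["flipped"]], 1L)
  expect_equal(hp@counts[["strandCorrected"]], 1L)
})

test_that("palindromic SNPs are dropped and counted under the default policy", {
  a <- makeSumstats(3, a1 = c("A", "A", "C"), a2 = c("T", "G", "G"))
  b <- makeSumstats(3, a1 = c("A", "A", "C"), a2 = c("T", "G", "G"))
  hp <- harmonizePair(a, b)
  expect_equal(length(hp@a), 1)            # only rs2 (A/G) survives
  expect_equal(hp@counts[["palindromicDropped"]], 2L)
  expect_false(any(c("rs1", "rs3") %in% snpData(hp@a)$snp))
})

test_that("unresolvable allele pairs are dropped and logged", {
  a <- makeSumstats(2, a1 = c("A", "C"), a2 = c("G", "T"))
  b <- makeSumstats(2, a1 = c("A", "C"), a2 = c("C", "T"))
  hp <- harmonizePair(a, b)
  expect_equal(length(hp@a), 1)
  expect_equal(hp@counts[["unresolvedDropped"]], 1L)
  expect_true("allele_mismatch" %in% dropLog(hp@b)$reason)
})

test_that("harmonization is idempotent and preserves |z|", {
  set.seed(42)
  cfg <- simConfig(mSnps = 500, nBlocks = 5, palindromicFraction = 0.05,
                   strandFlipFraction = 0.1, swapFraction = 0.1, seed = 42)
  sim <- suppressWarnings(simulateSumstats(cfg))
  hp <- harmonizePair(sim$a, sim$b)
  expect_gt(hp@counts[["flipped"]], 0)
  expect_gt(hp@counts[["strandCorrected"]], 0)
  # |z| of every retained SNP unchanged by alignment
  orig <- setNames(abs(snpData(sim$b)$z), snpData(sim$b)$snp)
  expect_equal(abs(snpData(hp@b)$z), unname(orig[snpData(hp@b)$snp]))
  # applying harmonization to its own output changes nothing
  hp2 <- harmonizePair(hp@a, hp@b)
  expect_identical(snpData(hp2@a), snpData(hp@a))
  expect_identical(snpData(hp2@b)$beta, snpData(hp@b)$beta)
  expect_equal(hp2@counts[["flipped"]], 0L)
  expect_equal(hp2@counts[["palindromicDropped"]], 0L)
})

test_that("MHC exclusion uses a closed interval on the right chromosome", {
  df <- makeSnpTable(3, chrom = c("6", "6", "7"),
                     pos = c(30000000L, 23999999L, 30000000L))
  t <- summaryStats(df)
  out <- excludeRegion(t)   # default MHC 6:24e6-35e6
  kept <- snpData(out)
  expect_false(any(kept$chrom == "6" & kept$pos == 30000000))
  expect_true(any(kept$chrom == "6" & kept$pos == 23999999))
  expect_true(any(kept$chrom == "7" & kept$pos == 30000000))
  expect_true("region_excluded" %in% dropLog(out)$reason)
  # boundary SNPs at exactly 24e6 and 35e6 are removed (closed interval)
  t2 <- summaryStats(makeSnpTable(2, chrom = "6", pos = c(24000000L, 35000000L)))
  expect_equal(length(excludeRegion(t2)), 0)
})

test_that("canonical TSV round-trips through writeSumstats", {
  t <- makeSumstats(4)
  path <- tempfile(fileext = ".tsv")
  writeSumstats(t, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(hdr, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE",
                          "P", "N", "Z"))
  t2 <- loadSumstats(path)
  expect_equal(snpData(t2)$z, snpData(t)$z, tolerance = 1e-10)
})
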