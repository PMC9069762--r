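# In-code fixtures shared across the suite.

# a minimal valid record table; override fields via ...
makeSnpTable <- function(n = 5, chrom = "1", ...) {
  df <- data.frame(snp = paste0("rs", seq_len(n)),
                   chrom = chrom,
                   pos = seq_len(n) * 1000L,
                   a1 = rep(c("A", "C", "G", "T", "A"), length.out = n),
                   a2 = rep(c("C", "A", "T", "G", "G"), length.out = n),
                   beta = seq(0.01, by = 0.01, length.out = n),
                   se = 0.05,
                   pvalue = NA_real_,
                   n = 10000,
                   stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

makeSumstats <- function(n = 5, trait = "t", ...) {
  summaryStats(makeSnpTable(n, ...), trait = trait)
}

writeSumstatsFile <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force O(n^2) conditional-FDR oracle (independent of the package path)
cfdrOracle <- function(p1, p2) {
  n <- length(p1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    marg <- sum(p2 <= p2[i])
    both <- sum(p1 <= p1[i] & p2 <= p2[i])
    out[i] <- min(1, p1[i] * marg / both)
  }
  out
}

# an LDReference built directly from a genotype matrix
makeLDRef <- function(g, pos = NULL, chrom = "1", window = 1e6) {
  g <- scale(g)
  attr(g, "scaled:center") <- NULL
  attr(g, "scaled:scale") <- NULL
  m <- ncol(g)
  new("LDReference", genotypes = g, snp = paste0("rs", seq_len(m)),
      chrom = rep(chrom, m),
      pos = if (is.null(pos)) seq_len(m) * 1000L else as.integer(pos),
      windowBp = window)
}

# instruments with fully specified effects (no sampling noise)
makeInstruments <- function(betaX, betaY, seX = 0.01, seY = 0.05) {
  k <- length(betaX)
  d <- data.frame(snp = paste0("iv", seq_len(k)), betaX = betaX,
                  seX = rep_len(seX, k), betaY = betaY,
                  seY = rep_len(seY, k), stringsAsFactors = FALSE)
  d$ratio <- d$betaY / d$betaX
  d$ratioSE <- d$seY / abs(d$betaX)
  d$F <- (d$betaX / d$seX)^2
  new("MRInstruments", data = d, meta = list())
}
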