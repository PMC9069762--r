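## Central S4 containers. Slots are not part of the public contract; use the
## accessor functions.

#' SummaryStats: per-SNP association records for one trait
#'
#' Ordered (chrom, pos) table of validated GWAS summary statistics with a
#' reason-coded log of every dropped record. Build with [loadSumstats()] or
#' [summaryStats()].
#'
#' @slot snps data.frame with columns snp, chrom, pos, a1, a2, beta, se,
#'   pvalue, n, z (and optionally eaf).
#' @slot trait trait label.
#' @slot dropLog data.frame (snp, reason) of records removed during
#'   validation or filtering.
#' @slot provenance list of free-form processing notes (source path, applied
#'   filters, genomic-control state).
#' @export
setClass("SummaryStats",
  representation(snps = "data.frame", trait = "character",
                 dropLog = "data.frame", provenance = "list"),
  prototype(snps = data.frame(), trait = "trait",
            dropLog = data.frame(snp = character(), reason = character(),
                                 stringsAsFactors = FALSE),
            provenance = list()))

.validSummaryStats <- function(object) {
  d <- object@snps
  msg <- character()
  need <- c("snp", "chrom", "pos", "a1", "a2", "beta", "se", "pvalue", "n", "z")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d)) {
    if (anyDuplicated(d$snp)) msg <- c(msg, "duplicated snp ids")
    if (any(!is.na(d$pvalue) & (d$pvalue <= 0 | d$pvalue > 1)))
      msg <- c(msg, "pvalue outside (0, 1]")
    if (any(!is.na(d$se) & d$se <= 0)) msg <- c(msg, "non-positive se")
    o <- order(.chromRank(d$chrom), d$pos)
    if (!identical(o, seq_len(nrow(d)))) msg <- c(msg, "not sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SummaryStats", .validSummaryStats)

#' HarmonizedPair: two allele-aligned summary-statistic tables
#'
#' Both tables are restricted to the shared SNP panel and aligned so that the
#' effect allele is identical in the two studies; the counts of swapped,
#' strand-corrected, palindromic and unresolvable records are retained.
#'
#' @slot a,b [SummaryStats-class] objects over an identical snp sequence.
#' @slot counts named integer vector: flipped, strandCorrected,
#'   palindromicDropped, unresolvedDropped, shared.
#' @export
setClass("HarmonizedPair",
  representation(a = "SummaryStats", b = "SummaryStats", counts = "integer"))

setValidity("HarmonizedPair", function(object) {
  if (!identical(object@a@snps$snp, object@b@snps$snp))
    return("snp sequences of the two tables differ")
  if (nrow(object@a@snps) &&
      (!identical(object@a@snps$a1, object@b@snps$a1) ||
       !identical(object@a@snps$a2, object@b@snps$a2)))
    return("allele labels not aligned between tables")
  TRUE
})

#' LDReference: a standardized genotype panel for LD queries
#'
#' @slot genotypes numeric matrix, individuals x SNPs, columns standardized
#'   to zero mean and unit variance.
#' @slot snp,chrom,pos SNP identity and coordinates (parallel to columns).
#' @slot windowBp default base-pair window for r-squared and LD-score queries.
#' @export
setClass("LDReference",
  representation(genotypes = "matrix", snp = "character", chrom = "character",
                 pos = "integer", windowBp = "numeric"))

setValidity("LDReference", function(object) {
  m <- ncol(object@genotypes)
  if (length(object@snp) != m || length(object@pos) != m ||
      length(object@chrom) != m)
    return("coordinate vectors must parallel genotype columns")
  if (anyDuplicated(object@snp)) return("duplicated snp ids")
  TRUE
})

#' SimulationConfig: parameters of the paired-GWAS generator
#'
#' See [simConfig()] for field semantics and defaults.
#' @export
setClass("SimulationConfig",
  representation(mSnps = "integer", nBlocks = "integer", ar1Rho = "numeric",
                 n1 = "numeric", n2 = "numeric", pi = "numeric",
                 h2 = "numeric", rhoShared = "numeric",
                 lambdaInflation = "numeric", intergenicFraction = "numeric",
                 palindromicFraction = "numeric", strandFlipFraction = "numeric",
                 swapFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (abs(sum(object@pi) - 1) > 1e-8) msg <- c(msg, "pi must sum to 1")
  if (any(object@pi < 0)) msg <- c(msg, "pi components must be nonnegative")
  if (object@ar1Rho < 0 || object@ar1Rho >= 1) msg <- c(msg, "ar1Rho in [0,1)")
  if (any(object@h2 < 0 | object@h2 >= 1)) msg <- c(msg, "h2 in [0,1)")
  if (abs(object@rhoShared) > 1) msg <- c(msg, "rhoShared in [-1,1]")
  if (object@lambdaInflation < 1) msg <- c(msg, "lambdaInflation >= 1")
  if (object@n1 <= 0 || object@n2 <= 0) msg <- c(msg, "sample sizes must be positive")
  if (length(msg)) msg else TRUE
})

#' GCResult: an intergenic genomic-control fit
#' @slot lambdaHat estimated inflation factor (median chi-square ratio).
#' @slot nIntergenic number of intergenic SNPs used.
#' @export
setClass("GCResult",
  representation(lambdaHat = "numeric", nIntergenic = "integer"))

#' EnrichmentResult: conditional Q-Q and fold-enrichment curves
#'
#' @slot thresholds -log10(p) cutoffs of the conditioning trait.
#' @slot qq long data.frame (threshold, n, expected, observed) of conditional
#'   Q-Q curves; empty when only fold enrichment was computed.
#' @slot fe long data.frame (threshold, x, fe, nTail) of fold-enrichment
#'   curves on the x grid; NA fe marks an undefined (empty-tail) point.
#' @slot strata named integer vector of per-stratum SNP counts.
#' @export
setClass("EnrichmentResult",
  representation(thresholds = "numeric", qq = "data.frame",
                 fe = "data.frame", strata = "integer"))

#' CFDRTable: per-SNP conditional and conjunctional FDR
#'
#' @slot stats data.frame with snp, chrom, pos, p1, p2, cfdr12 (trait A given
#'   B), cfdr21, conjfdr.
#' @slot traits labels of the two traits (A, B).
#' @export
setClass("CFDRTable",
  representation(stats = "data.frame", traits = "character"))

setValidity("CFDRTable", function(object) {
  d <- object@stats
  need <- c("snp", "p1", "p2", "cfdr12", "cfdr21", "conjfdr")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  TRUE
})

#' GencorrResult: method-of-moments genetic covariance / correlation
#'
#' @slot h2 length-2 per-trait SNP-heritability estimates.
#' @slot rhoG genetic covariance.
#' @slot rG genetic correlation, clipped to [-1, 1] (raw value in rGRaw).
#' @slot rGRaw unclipped correlation (NA when either h2 <= 0).
#' @slot se,p block-jackknife standard error of rG and two-sided normal p.
#' @slot mSnps,nBlocks problem size used.
#' @slot flags character vector of degeneracy notes (e.g. nonpositive h2).
#' @export
setClass("GencorrResult",
  representation(h2 = "numeric", rhoG = "numeric", rG = "numeric",
                 rGRaw = "numeric", se = "numeric", p = "numeric",
                 mSnps = "integer", nBlocks = "integer", flags = "character"))

#' MRInstruments: harmonized instrument-level effects for two-sample MR
#'
#' @slot data data.frame with snp, betaX, seX, betaY, seY, ratio (Wald ratio),
#'   ratioSE (first-order), F (instrument strength).
#' @slot meta list of selection metadata (p threshold used, relaxed switch,
#'   clump parameters, drops).
#' @export
setClass("MRInstruments",
  representation(data = "data.frame", meta = "list"))

setValidity("MRInstruments", function(object) {
  d <- object@data
  need <- c("snp", "betaX", "seX", "betaY", "seY", "ratio", "ratioSE", "F")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) && any(d$seX <= 0 | d$seY <= 0)) return("standard errors must be positive")
  TRUE
})

#' MRResult: one causal estimate with its uncertainty and diagnostics
#'
#' Log-odds scale estimate with normal (or t, for Egger) inference, odds
#' ratio with 95 percent CI, and, where defined, Cochran's Q and the Egger
#' intercept test.
#' @export
setClass("MRResult",
  representation(method = "character", k = "integer", estimate = "numeric",
                 se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 p = "numeric", Q = "numeric", QDf = "numeric", QP = "numeric",
                 intercept = "numeric", interceptSE = "numeric",
                 interceptP = "numeric", details = "list"),
  prototype(Q = NA_real_, QDf = NA_real_, QP = NA_real_,
            intercept = NA_real_, interceptSE = NA_real_,
            interceptP = NA_real_, details = list()))

#' ScreenConfig: configuration of a full pairwise screen
#'
#' Built with [screenConfig()]; all referenced paths are checked at
#' construction time.
#' @export
setClass("ScreenConfig",
  representation(primary = "character", primaryLabel = "character",
                 comparisons = "character", ldPanel = "character",
                 annotation = "character", outDir = "character",
                 params = "list", seed = "integer"))

setValidity("ScreenConfig", function(object) {
  if (!length(object@comparisons)) return("at least one comparison trait required")
  if (is.null(names(object@comparisons)) || any(!nzchar(names(object@comparisons))))
    return("comparison paths must be named by trait label")
  paths <- c(object@primary, object@comparisons,
             if (nzchar(object@ldPanel)) object@ldPanel,
             if (nzchar(object@annotation)) object@annotation)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    return(paste("missing input file(s):", paste(missing, collapse = ", ")))
  TRUE
})
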