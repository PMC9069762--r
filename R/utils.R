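## Shared helpers and accessors.

.chromLevels <- c(as.character(1:22), "X")

.chromRank <- function(chrom) match(as.character(chrom), .chromLevels)

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

## Two-sided p from a z score, and back.  p = 0 underflow is replaced by the
## smallest positive double downstream, never here.
.pFromZ <- function(z) 2 * pnorm(-abs(z))
.zFromP <- function(p) qnorm(p / 2, lower.tail = FALSE)

## Median of the chi-square distribution with 1 df, the genomic-control
## denominator.
.CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' Construct a SummaryStats object from a data frame
#'
#' Lower-level companion of [loadSumstats()]: takes an already-parsed data
#' frame with canonical column names (snp, chrom, pos, a1, a2 and at least
#' one of beta+se / z / pvalue), validates each record against the field
#' invariants, derives the missing members of (beta, se, z, pvalue), drops
#' invalid rows with a reason code and sorts by (chrom, pos).
#'
#' @param df data.frame with canonical columns.
#' @param trait trait label.
#' @param source free-form provenance note (e.g. the file path).
#' @return a validated [SummaryStats-class] object.
#' @export
summaryStats <- function(df, trait = "trait", source = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("snp", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(df)))
    stop("missing mandatory column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  hasEffect <- ("beta" %in% names(df) && "se" %in% names(df)) ||
    "z" %in% names(df) || "pvalue" %in% names(df)
  if (!hasEffect)
    stop("need one of beta+se, z, or pvalue columns")
  for (col in c("beta", "se", "pvalue", "n", "z"))
    if (!col %in% names(df)) df[[col]] <- NA_real_

  df$snp <- as.character(df$snp)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$pos <- as.integer(df$pos)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  for (col in c("beta", "se", "pvalue", "n", "z"))
    df[[col]] <- as.numeric(df[[col]])

  drops <- data.frame(snp = character(), reason = character(),
                      stringsAsFactors = FALSE)
  note <- function(idx, reason) {
    if (any(idx)) drops <<- rbind(drops, data.frame(snp = df$snp[idx],
                                                    reason = reason,
                                                    stringsAsFactors = FALSE))
    idx
  }

  bad <- is.na(df$snp) | !nzchar(df$snp)
  note(bad, "missing_snp_id")
  bad <- bad | note(!bad & (is.na(df$chrom) | is.na(.chromRank(df$chrom))),
                    "bad_chromosome")
  bad <- bad | note(!bad & (is.na(df$pos) | df$pos < 1), "bad_position")
  okAllele <- df$a1 %in% names(.complement) & df$a2 %in% names(.complement) &
    df$a1 != df$a2
  okAllele[is.na(okAllele)] <- FALSE
  bad <- bad | note(!bad & !okAllele, "bad_alleles")
  bad <- bad | note(!bad & !is.na(df$se) & df$se <= 0, "nonpositive_se")
  bad <- bad | note(!bad & !is.na(df$pvalue) & df$pvalue > 1, "pvalue_above_1")
  bad <- bad | note(!bad & !is.na(df$pvalue) & df$pvalue < 0, "negative_pvalue")
  bad <- bad | note(!bad & !is.na(df$n) & df$n <= 0, "nonpositive_n")

  df <- df[!bad, , drop = FALSE]

  ## p = 0 underflow: replace by smallest positive double, log it
  uf <- !is.na(df$pvalue) & df$pvalue == 0
  if (any(uf)) {
    drops <- rbind(drops, data.frame(snp = df$snp[uf],
                                     reason = "pvalue_underflow_clamped",
                                     stringsAsFactors = FALSE))
    df$pvalue[uf] <- .Machine$double.xmin
  }

  ## derive z, then fill p / se / beta where recoverable
  z <- deriveZ(df$beta, df$se, df$pvalue, policy = "reconcile")
  df$z <- ifelse(is.na(df$z), z, df$z)
  unusable <- is.na(df$z)
  if (any(unusable)) {
    drops <- rbind(drops, data.frame(snp = df$snp[unusable],
                                     reason = "no_usable_effect",
                                     stringsAsFactors = FALSE))
    df <- df[!unusable, , drop = FALSE]
  }
  df$pvalue[is.na(df$pvalue)] <- .pFromZ(df$z[is.na(df$pvalue)])
  fixSe <- is.na(df$se) & !is.na(df$beta) & df$z != 0
  df$se[fixSe] <- abs(df$beta[fixSe] / df$z[fixSe])

  ## duplicate snp ids: keep the record with the smallest se
  if (anyDuplicated(df$snp)) {
    o <- order(df$snp, ifelse(is.na(df$se), Inf, df$se))
    dup <- duplicated(df$snp[o])
    lost <- df$snp[o][dup]
    drops <- rbind(drops, data.frame(snp = lost, reason = "duplicate_snp_id",
                                     stringsAsFactors = FALSE))
    df <- df[o, , drop = FALSE][!dup, , drop = FALSE]
  }

  df <- df[order(.chromRank(df$chrom), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  new("SummaryStats", snps = df, trait = trait, dropLog = drops,
      provenance = list(source = source))
}

#' @describeIn summaryStats number of retained records.
#' @param x,object a SummaryStats object.
#' @export
setMethod("length", "SummaryStats", function(x) nrow(x@snps))

#' Accessors for SummaryStats
#'
#' `snpData()` returns the per-SNP record table, `traitLabel()` the trait
#' name, `dropLog()` the reason-coded log of removed records, and
#' `snpRanges()` the coordinates as a `GRanges`.
#'
#' @param x a [SummaryStats-class] object.
#' @return a data.frame, character scalar, data.frame, or `GRanges`.
#' @export
snpData <- function(x) x@snps

#' @rdname snpData
#' @export
traitLabel <- function(x) x@trait

#' @rdname snpData
#' @export
dropLog <- function(x) x@dropLog

#' @rdname snpData
#' @export
snpRanges <- function(x) {
  d <- x@snps
  GRanges(seqnames = d$chrom, ranges = IRanges(start = d$pos, width = 1),
          snp = d$snp)
}

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats '", object@trait, "': ", nrow(object@snps), " SNPs",
      sep = "")
  if (nrow(object@snps))
    cat(" on chromosome(s) ",
        paste(unique(object@snps$chrom), collapse = ","), sep = "")
  cat("; ", nrow(object@dropLog), " logged drop(s)\n", sep = "")
})

setMethod("show", "HarmonizedPair", function(object) {
  cat("HarmonizedPair: ", length(object@a), " shared SNPs (",
      object@a@trait, " / ", object@b@trait, ")\n", sep = "")
  cat("  flipped ", object@counts[["flipped"]],
      ", strand-corrected ", object@counts[["strandCorrected"]],
      ", palindromic dropped ", object@counts[["palindromicDropped"]],
      ", unresolved dropped ", object@counts[["unresolvedDropped"]], "\n",
      sep = "")
})

setMethod("show", "LDReference", function(object) {
  cat("LDReference: ", nrow(object@genotypes), " individuals x ",
      ncol(object@genotypes), " SNPs, r2 window ", object@windowBp, " bp\n",
      sep = "")
})

setMethod("show", "GCResult", function(object) {
  cat(sprintf("Genomic control: lambda = %.4f from %d intergenic SNPs\n",
              object@lambdaHat, object@nIntergenic))
})

setMethod("show", "GencorrResult", function(object) {
  cat(sprintf("Genetic correlation: r_g = %.4f (se %.4f, p %.3g)\n",
              object@rG, object@se, object@p))
  cat(sprintf("  h2: %.4f / %.4f, rho_g = %.5f, %d SNPs, %d jackknife blocks\n",
              object@h2[1], object@h2[2], object@rhoG, object@mSnps,
              object@nBlocks))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MR %s (k = %d): estimate %.4f (se %.4f), OR %.3f [%.3f, %.3f], p = %.3g\n",
              object@method, object@k, object@estimate, object@se,
              exp(object@estimate), exp(object@ciLow), exp(object@ciHigh),
              object@p))
  if (!is.na(object@Q))
    cat(sprintf("  Cochran Q = %.3f (df %d, p %.3g)\n", object@Q,
                as.integer(object@QDf), object@QP))
  if (!is.na(object@intercept))
    cat(sprintf("  Egger intercept %.4f (se %.4f, p %.3g)\n",
                object@intercept, object@interceptSE, object@interceptP))
})

setMethod("show", "MRInstruments", function(object) {
  cat("MRInstruments: ", nrow(object@data), " harmonized instruments\n",
      sep = "")
})

setMethod("show", "CFDRTable", function(object) {
  d <- object@stats
  cat("CFDRTable (", object@traits[1], " vs ", object@traits[2], "): ",
      nrow(d), " SNPs, min conjFDR ",
      if (nrow(d)) format(min(d$conjfdr), digits = 3) else "NA", "\n",
      sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult: strata at -log10(p) thresholds ",
      paste(object@thresholds, collapse = ", "), "\n  counts: ",
      paste(sprintf("%s=%d", names(object@strata), object@strata),
            collapse = ", "), "\n", sep = "")
})

#' Accessors for analysis results
#'
#' `lambdaHat()` extracts the genomic-control inflation factor,
#' `cfdrStats()` the per-SNP FDR table, `enrichmentCurves()` the long-format
#' Q-Q and fold-enrichment tables, `instrumentData()` the instrument-level
#' MR table, and `mrEstimate()` the named estimate vector of an MR fit.
#'
#' @param x a result object.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
lambdaHat <- function(x) x@lambdaHat

#' @rdname result-accessors
#' @export
cfdrStats <- function(x) x@stats

#' @rdname result-accessors
#' @export
enrichmentCurves <- function(x) list(qq = x@qq, fe = x@fe, strata = x@strata)

#' @rdname result-accessors
#' @export
instrumentData <- function(x) x@data

#' @rdname result-accessors
#' @export
mrEstimate <- function(x)
  c(estimate = x@estimate, se = x@se, or = exp(x@estimate),
    orLow = exp(x@ciLow), orHigh = exp(x@ciHigh), p = x@p)

#' Bonferroni-adjusted per-test significance threshold
#'
#' The exact fraction `alpha / m`; callers that print it are responsible for
#' rounding, and verdicts must always compare against the exact value.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 9)       # nine-disorder screen
#' bonferroniThreshold(0.05, 292000)  # probe-level eQTL screen
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
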