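## Reading, validating, harmonizing and filtering GWAS summary statistics.

.defaultColumnMap <- c(snp = "SNP", chrom = "CHR", pos = "BP", a1 = "A1",
                       a2 = "A2", beta = "BETA", se = "SE", pvalue = "P",
                       n = "N", z = "Z", or = "OR", eaf = "EAF")

#' Load GWAS summary statistics from delimited text
#'
#' Reads a (possibly gzip-compressed) delimited file with a header, maps the
#' file's column names onto the canonical schema, converts odds ratios to
#' log scale, derives the signed z score (from beta/se when available,
#' otherwise from the p-value and effect direction), validates every record
#' and drops invalid rows with a reason code.
#'
#' @param path file path; tab, comma or whitespace delimited, gz accepted.
#' @param columnMap named character vector mapping canonical names (`snp`,
#'   `chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `pvalue`, `n`, `z`, `or`,
#'   `eaf`) to the file's column names; entries missing from the map fall
#'   back to the conventional names (SNP, CHR, BP, A1, A2, BETA, SE, P, N,
#'   Z, OR, EAF).
#' @param trait trait label attached to the table.
#' @return a [SummaryStats-class] object.
#' @seealso [summaryStats()] for in-memory data, [writeSumstats()] for the
#'   canonical TSV output.
#' @export
loadSumstats <- function(path, columnMap = NULL, trait = "trait") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  if (!nrow(raw)) stop("empty summary-statistics file: ", path)
  map <- .defaultColumnMap
  if (length(columnMap)) {
    unknown <- setdiff(names(columnMap), names(map))
    if (length(unknown))
      stop("unknown canonical column name(s) in columnMap: ",
           paste(unknown, collapse = ", "))
    map[names(columnMap)] <- columnMap
  }
  present <- map[map %in% names(raw)]
  df <- raw[, present, drop = FALSE]
  names(df) <- names(present)

  mandatory <- c("snp", "chrom", "pos", "a1", "a2")
  if (!all(mandatory %in% names(df)))
    stop("mandatory column(s) not found in ", path, ": ",
         paste(map[setdiff(mandatory, names(df))], collapse = ", "))
  if (!(("beta" %in% names(df) || "or" %in% names(df)) &&
        "se" %in% names(df)) &&
      !"z" %in% names(df) && !"pvalue" %in% names(df))
    stop("no usable effect columns found (need beta/OR + se, z, or p)")

  if ("or" %in% names(df)) {
    orv <- as.numeric(df$or)
    if (!"beta" %in% names(df) || all(is.na(df$beta)))
      df$beta <- log(orv)
    df$or <- NULL
  }
  summaryStats(df, trait = trait, source = path)
}

#' Derive a signed z score from effect estimates and/or a p-value
#'
#' @param beta,se effect and standard error (may be NA).
#' @param pvalue two-sided p (may be NA).
#' @param policy `"from_beta"` uses beta/se only; `"from_p"` takes the
#'   magnitude from the two-sided normal quantile of p with the sign of
#'   beta; `"reconcile"` (default) prefers beta/se, falls back to the
#'   p-derived value, and flags records where the two disagree by more than
#'   `tol` (the beta-derived value wins).
#' @param tol reconciliation tolerance on |z_beta - z_p|.
#' @return numeric z vector (NA where no usable input); under
#'   `"reconcile"` an attribute `"mismatch"` marks flagged records.
#' @examples
#' deriveZ(0.10, 0.05, NA)                       # 2
#' deriveZ(NA, NA, 0.05, policy = "from_p")      # 1.959964 (sign unknown -> +)
#' @export
deriveZ <- function(beta, se, pvalue,
                    policy = c("reconcile", "from_beta", "from_p"),
                    tol = 0.1) {
  policy <- match.arg(policy)
  k <- max(length(beta), length(se), length(pvalue))
  beta <- rep_len(as.numeric(beta), k)
  se <- rep_len(as.numeric(se), k)
  pvalue <- rep_len(as.numeric(pvalue), k)

  zBeta <- ifelse(!is.na(beta) & !is.na(se) & se > 0, beta / se, NA_real_)
  sgn <- ifelse(is.na(beta) | beta >= 0, 1, -1)
  zP <- ifelse(!is.na(pvalue) & pvalue > 0 & pvalue <= 1,
               sgn * .zFromP(pvalue), NA_real_)

  z <- switch(policy,
    from_beta = zBeta,
    from_p = zP,
    reconcile = ifelse(is.na(zBeta), zP, zBeta))
  if (policy == "reconcile") {
    mism <- !is.na(zBeta) & !is.na(zP) & abs(zBeta - zP) > tol
    attr(z, "mismatch") <- mism
  }
  z
}

#' Harmonize two summary-statistic tables onto a shared effect allele
#'
#' Intersects the two tables on SNP id and aligns the second table's alleles
#' to the first: swapped allele labels negate the effect, strand complements
#' are relabelled, and palindromic (A/T, C/G) SNPs are handled per policy
#' (dropped by default, or inferred from allele frequency when `eaf` is
#' present in both tables and the frequency is informative). Allele pairs
#' that match under none of these transformations are dropped and counted.
#'
#' @param a,b [SummaryStats-class] tables.
#' @param palindromePolicy `"drop"` (default) or `"maf_infer"`.
#' @param mafInformative frequency bound: under `maf_infer` a palindromic
#'   SNP is kept only if both studies' effect-allele frequencies are below
#'   `mafInformative` or both above `1 - mafInformative`.
#' @return a [HarmonizedPair-class]; identical snp sequence and allele
#'   labels in both member tables.
#' @export
harmonizePair <- function(a, b, palindromePolicy = c("drop", "maf_infer"),
                          mafInformative = 0.42) {
  palindromePolicy <- match.arg(palindromePolicy)
  da <- a@snps; db <- b@snps
  shared <- intersect(da$snp, db$snp)
  if (!length(shared)) stop("no shared SNPs between the two tables")
  da <- da[match(shared, da$snp), , drop = FALSE]
  db <- db[match(shared, db$snp), , drop = FALSE]

  same <- db$a1 == da$a1 & db$a2 == da$a2
  swapped <- db$a1 == da$a2 & db$a2 == da$a1
  comp <- unname(.complement[db$a1]) == da$a1 &
          unname(.complement[db$a2]) == da$a2
  compSwapped <- unname(.complement[db$a1]) == da$a2 &
                 unname(.complement[db$a2]) == da$a1
  palin <- .isPalindromic(da$a1, da$a2) | .isPalindromic(db$a1, db$a2)

  keep <- rep(TRUE, length(shared))
  flip <- rep(FALSE, length(shared))
  strand <- rep(FALSE, length(shared))
  nPalinDrop <- 0L

  if (any(palin)) {
    if (palindromePolicy == "drop" ||
        !("eaf" %in% names(da)) || !("eaf" %in% names(db))) {
      keep[palin] <- FALSE
      nPalinDrop <- sum(palin)
    } else {
      fa <- da$eaf[palin]; fb <- db$eaf[palin]
      inform <- !is.na(fa) & !is.na(fb) &
        (pmin(fa, 1 - fa) < mafInformative) &
        (pmin(fb, 1 - fb) < mafInformative)
      ## frequencies agree -> same orientation; disagree -> flipped
      agree <- (fa < 0.5) == (fb < 0.5)
      idx <- which(palin)
      keep[idx[!inform]] <- FALSE
      nPalinDrop <- sum(!inform)
      flip[idx[inform & !agree]] <- TRUE
    }
  }

  plain <- keep & !palin
  flip[plain & (swapped | compSwapped)] <- TRUE
  strand[plain & (comp | compSwapped)] <- TRUE
  unresolved <- plain & !(same | swapped | comp | compSwapped)
  keep[unresolved] <- FALSE

  if (any(flip & keep)) {
    i <- flip & keep
    db$beta[i] <- -db$beta[i]
    db$z[i] <- -db$z[i]
    if ("eaf" %in% names(db)) db$eaf[i] <- 1 - db$eaf[i]
  }
  ## after flip/strand handling the second table adopts the first's labels
  db$a1[keep] <- da$a1[keep]
  db$a2[keep] <- da$a2[keep]

  droppedIds <- shared[!keep]
  da <- da[keep, , drop = FALSE]
  db <- db[keep, , drop = FALSE]
  if (!nrow(da)) stop("no SNPs left after allele harmonization")

  mkDrop <- function(base, ids, reason) {
    if (!length(ids)) return(base)
    rbind(base, data.frame(snp = ids, reason = reason,
                           stringsAsFactors = FALSE))
  }
  logA <- a@dropLog; logB <- b@dropLog
  if (length(droppedIds)) {
    palinIds <- shared[!keep & palin]
    unresIds <- setdiff(droppedIds, palinIds)
    logB <- mkDrop(logB, palinIds, "palindromic_dropped")
    logB <- mkDrop(logB, unresIds, "allele_mismatch")
  }

  newA <- new("SummaryStats", snps = `rownames<-`(da, NULL), trait = a@trait,
              dropLog = logA,
              provenance = c(a@provenance, list(harmonized = TRUE)))
  newB <- new("SummaryStats", snps = `rownames<-`(db, NULL), trait = b@trait,
              dropLog = logB,
              provenance = c(b@provenance, list(harmonized = TRUE)))
  new("HarmonizedPair", a = newA, b = newB,
      counts = c(flipped = sum(flip & keep),
                 strandCorrected = sum(strand & keep),
                 palindromicDropped = as.integer(nPalinDrop),
                 unresolvedDropped = sum(unresolved),
                 shared = nrow(da)))
}

#' Remove SNPs inside a genomic region (default: the MHC)
#'
#' Drops records whose position lies in the closed interval
#' `[start, end]` on `chrom`. The default removes the extended major
#' histocompatibility complex, chr6:24,000,000-35,000,000 (GRCh37), whose
#' complex LD structure breaks the downstream moment and FDR estimators.
#'
#' @param x a [SummaryStats-class] or [HarmonizedPair-class] object.
#' @param chrom chromosome (character, no "chr" prefix).
#' @param start,end closed 1-based interval bounds in base pairs.
#' @return object of the same class with the region removed; removed SNPs
#'   are appended to the drop log with reason `region_excluded`.
#' @export
excludeRegion <- function(x, chrom = "6", start = 24e6, end = 35e6) {
  stopifnot(start < end)
  if (is(x, "HarmonizedPair")) {
    a <- excludeRegion(x@a, chrom, start, end)
    b <- excludeRegion(x@b, chrom, start, end)
    return(new("HarmonizedPair", a = a, b = b, counts = x@counts))
  }
  stopifnot(is(x, "SummaryStats"))
  d <- x@snps
  if (!nrow(d) || !any(d$chrom == chrom)) return(x)
  hit <- !is.na(findOverlaps(snpRanges(x),
                             GRanges(chrom, IRanges(start, end)),
                             select = "first"))
  if (!any(hit)) return(x)
  log <- rbind(x@dropLog,
               data.frame(snp = d$snp[hit], reason = "region_excluded",
                          stringsAsFactors = FALSE))
  new("SummaryStats", snps = `rownames<-`(d[!hit, , drop = FALSE], NULL),
      trait = x@trait, dropLog = log,
      provenance = c(x@provenance,
                     list(excludedRegion = sprintf("%s:%d-%d", chrom,
                                                   as.integer(start),
                                                   as.integer(end)))))
}

#' Write summary statistics as canonical TSV
#'
#' Fixed column order SNP, CHR, BP, A1, A2, BETA, SE, P, N, Z.
#'
#' @param x a [SummaryStats-class] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSumstats <- function(x, path) {
  d <- x@snps
  out <- data.frame(SNP = d$snp, CHR = d$chrom, BP = d$pos, A1 = d$a1,
                    A2 = d$a2, BETA = d$beta, SE = d$se, P = d$pvalue,
                    N = d$n, Z = d$z, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
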