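## Orchestration of the full pairwise screen: one primary trait against a
## panel of comparison traits with a family-wise Bonferroni policy.

#' Save / load an LD reference panel as plain TSV
#'
#' Row-per-SNP layout: snp, chrom, pos, then one column per reference
#' individual. A plain-text round trip keeps the workflow self-contained.
#'
#' @param ldref an [LDReference-class].
#' @param path TSV path (gz accepted on read and write).
#' @return `saveLDReference` the path invisibly; `loadLDReference` an
#'   [LDReference-class] (default 1 Mb query window).
#' @export
saveLDReference <- function(ldref, path) {
  out <- data.frame(snp = ldref@snp, chrom = ldref@chrom, pos = ldref@pos,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(t(ldref@genotypes)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname saveLDReference
#' @export
loadLDReference <- function(path) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  g <- t(as.matrix(raw[, -(1:3), drop = FALSE]))
  dimnames(g) <- NULL
  new("LDReference", genotypes = g, snp = as.character(raw$snp),
      chrom = as.character(raw$chrom), pos = as.integer(raw$pos),
      windowBp = 1e6)
}

#' Read a two-column intergenic annotation
#'
#' TSV with columns `snp` and `intergenic` (0/1).
#'
#' @param path annotation path.
#' @return named logical vector keyed by snp id.
#' @export
loadAnnotation <- function(path) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  setNames(as.logical(raw[[2]]), as.character(raw[[1]]))
}

.defaultScreenParams <- function() {
  list(gc = TRUE, r2Prune = 0.2, pruneWindowBp = 250000,
       fdrThreshold = 0.01, mergeKb = 250, r2Merge = 0.6,
       qqThresholds = c(0, 1, 2, 3), nBlocks = 100L,
       pThreshold = 5e-8, relaxed = 1e-6, clumpR2 = 0.001,
       clumpWindowBp = 1e7, pressoSims = 1000L, alpha = 0.05)
}

#' Build a screen configuration
#'
#' @param primary path to the primary trait's summary statistics.
#' @param comparisons named character vector of comparison-trait paths
#'   (names are the trait labels).
#' @param ldPanel path to an LD panel written by [saveLDReference()].
#' @param annotation path to the intergenic annotation TSV ("" disables
#'   genomic control).
#' @param outDir output directory (created on demand).
#' @param primaryLabel label of the primary trait.
#' @param params named list overriding the stage defaults (prune window,
#'   FDR threshold, MR thresholds, jackknife blocks, PRESSO replicates,
#'   family-wise alpha).
#' @param seed master seed; each stage derives its own stream from it.
#' @return a validated [ScreenConfig-class].
#' @export
screenConfig <- function(primary, comparisons, ldPanel, annotation = "",
                         outDir = tempfile("screen"), primaryLabel = "primary",
                         params = list(), seed = 1L) {
  new("ScreenConfig", primary = primary, primaryLabel = primaryLabel,
      comparisons = comparisons, ldPanel = ldPanel, annotation = annotation,
      outDir = outDir,
      params = modifyList(.defaultScreenParams(), params),
      seed = as.integer(seed))
}

## per-stage deterministic seed stream derived from the master seed
.stageSeed <- function(seed, stage) {
  (seed * 10007L + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

.mrResultJSON <- function(res) {
  list(method = res@method, k = res@k, estimate = res@estimate, se = res@se,
       or = exp(res@estimate), orLow = exp(res@ciLow),
       orHigh = exp(res@ciHigh), p = res@p)
}

.mrDirection <- function(exposure, outcome, ldref, params, seed) {
  ids <- selectInstruments(exposure, ldref, pThreshold = params$pThreshold,
                           relaxed = params$relaxed,
                           clumpR2 = params$clumpR2,
                           clumpWindowBp = params$clumpWindowBp)
  instr <- harmonizeInstruments(exposure, outcome, ids)
  k <- nrow(instr@data)
  out <- list(exposure = exposure@trait, outcome = outcome@trait, k = k,
              thresholdUsed = attr(ids, "thresholdUsed"),
              relaxedApplied = isTRUE(attr(ids, "relaxedApplied")))
  if (k == 0) { out$noInstruments <- TRUE; return(out) }
  ivw <- mrIVW(instr)
  out$ivw <- .mrResultJSON(ivw)
  out$Q <- ivw@Q; out$QDf <- ivw@QDf; out$QP <- ivw@QP
  out$F <- attr(fStatistics(instr), "range")
  if (k >= 3) {
    eg <- mrEgger(instr)
    out$egger <- .mrResultJSON(eg)
    out$eggerIntercept <- list(estimate = eg@intercept, se = eg@interceptSE,
                               p = eg@interceptP)
    loo <- leaveOneOut(instr)
    out$looMaxDev <- attr(loo, "maxDev")
  }
  if (k >= 4) {
    pr <- mrPresso(instr, nSim = params$pressoSims, seed = seed)
    out$presso <- list(globalP = pr$globalP,
                       nOutliers = sum(pr$outliers$flagged),
                       removed = pr$removed,
                       corrected = .mrResultJSON(pr$corrected))
  }
  out
}

#' Run the full analysis for one trait pair
#'
#' Executes the fixed stage order: load and validate, MHC exclusion,
#' per-GWAS intergenic genomic control, harmonization, LD pruning (greedy
#' by the primary trait's p-value), conditional Q-Q / fold enrichment,
#' conditional + conjunctional FDR with locus calling, method-of-moments
#' genetic correlation, and bidirectional MR. Every artifact is written
#' under `outDir/<label>/` together with a manifest of inputs, parameters
#' and seeds; outputs are deterministic given the configuration.
#'
#' @param cfg a [ScreenConfig-class].
#' @param label which comparison trait to analyse (must name an entry of
#'   the configuration's comparisons).
#' @return invisibly, a list bundle: `pair`, `lambda` (per-trait GC
#'   results), `pruned` (ids), `enrichment` (per direction), `cfdr`
#'   ([CFDRTable-class]), `loci` (`GRanges`), `gencorr`
#'   ([GencorrResult-class]), `mr` (per direction), `outDir`.
#' @export
runPair <- function(cfg, label) {
  stopifnot(is(cfg, "ScreenConfig"))
  validObject(cfg)
  if (!label %in% names(cfg@comparisons))
    stop("unknown comparison label: ", label)
  params <- cfg@params
  dir <- file.path(cfg@outDir, label)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for pair ", cfg@primaryLabel, " vs ",
           label, ": ", conditionMessage(e), call. = FALSE))
  }

  a <- stage("load", loadSumstats(cfg@primary, trait = cfg@primaryLabel))
  b <- stage("load", loadSumstats(cfg@comparisons[[label]], trait = label))
  a <- excludeRegion(a); b <- excludeRegion(b)

  lambda <- list()
  if (params$gc && nzchar(cfg@annotation)) {
    annot <- loadAnnotation(cfg@annotation)
    inter <- names(annot)[annot]
    lambda$a <- stage("genomic_control", estimateLambda(a, inter))
    lambda$b <- stage("genomic_control", estimateLambda(b, inter))
    a <- applyGenomicControl(a, lambda$a)
    b <- applyGenomicControl(b, lambda$b)
  }

  pair <- stage("harmonize", harmonizePair(a, b))
  ldref <- stage("ld_panel", loadLDReference(cfg@ldPanel))
  kept <- stage("ld_prune", ldPrune(pair@a, ldref, r2Max = params$r2Prune,
                                    windowBp = params$pruneWindowBp))
  pruned <- keepSnps(pair, kept)

  pa <- pruned@a@snps$pvalue; pb <- pruned@b@snps$pvalue
  enr <- stage("enrichment", list(
    qqAB = conditionalQQ(pa, pb, params$qqThresholds),
    qqBA = conditionalQQ(pb, pa, params$qqThresholds),
    feAB = foldEnrichment(pa, pb, params$qqThresholds),
    feBA = foldEnrichment(pb, pa, params$qqThresholds)))

  cf <- stage("cfdr", cfdrTable(pruned))
  loci <- stage("loci", callLoci(cf, ldref, fdrThreshold = params$fdrThreshold,
                                 mergeKb = params$mergeKb,
                                 r2Merge = params$r2Merge))
  gc <- stage("gencorr", geneticCorrelation(pair, ldref,
                                            nBlocks = params$nBlocks))
  mrAB <- stage("mr", .mrDirection(pair@a, pair@b, ldref, params,
                                   .stageSeed(cfg@seed, paste0("mrAB", label))))
  mrBA <- stage("mr", .mrDirection(pair@b, pair@a, ldref, params,
                                   .stageSeed(cfg@seed, paste0("mrBA", label))))

  ## artifacts
  feLong <- rbind(cbind(direction = "AgivenB", enr$feAB@fe),
                  cbind(direction = "BgivenA", enr$feBA@fe))
  data.table::fwrite(feLong, file.path(dir, "fold_enrichment.tsv"),
                     sep = "\t", quote = FALSE)
  qqLong <- rbind(cbind(direction = "AgivenB", enr$qqAB@qq),
                  cbind(direction = "BgivenA", enr$qqBA@qq))
  data.table::fwrite(qqLong, file.path(dir, "conditional_qq.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cf@stats, file.path(dir, "cfdr.tsv"), sep = "\t",
                     quote = FALSE)
  lociDf <- if (length(loci)) {
    data.frame(indexSnp = mcols(loci)$indexSnp,
               position = sprintf("%s:%d", as.character(seqnames(loci)),
                                  mcols(loci)$indexPos),
               fdr = mcols(loci)$fdr, nSnps = mcols(loci)$nSnps,
               stringsAsFactors = FALSE)
  } else data.frame(indexSnp = character(), position = character(),
                    fdr = numeric(), nSnps = integer())
  data.table::fwrite(lociDf, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE)
  gcJson <- list(h2 = gc@h2, rhoG = gc@rhoG, rG = gc@rG, se = gc@se,
                 p = gc@p, mSnps = gc@mSnps, flags = gc@flags)
  jsonlite::write_json(gcJson, file.path(dir, "gencorr.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(mrAB, file.path(dir, "mr_primary_to_comparison.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(mrBA, file.path(dir, "mr_comparison_to_primary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(primary = cfg@primary, comparison = cfg@comparisons[[label]],
                   label = label, ldPanel = cfg@ldPanel,
                   annotation = cfg@annotation, params = params,
                   seed = cfg@seed,
                   lambda = lapply(lambda, function(g) g@lambdaHat),
                   nShared = length(pair@a), nPruned = length(kept),
                   version = as.character(utils::packageVersion("pleioscan")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(pair = pair, lambda = lambda, pruned = kept,
                 enrichment = enr, cfdr = cf, loci = loci, gencorr = gc,
                 mr = list(primaryToComparison = mrAB,
                           comparisonToPrimary = mrBA),
                 outDir = dir))
}

#' Run the pairwise screen over all comparison traits
#'
#' Runs [runPair()] for every configured comparison and applies the
#' family-wise Bonferroni policy: with d comparison traits the per-test
#' threshold is the exact fraction `alpha / d` (never its rounded display
#' form), applied to the genetic-correlation p-value and to each MR
#' direction.
#'
#' @param cfg a [ScreenConfig-class].
#' @return data.frame summary (one row per comparison trait) with
#'   attribute `alphaPerTest`; also written to `outDir/screen_summary.tsv`.
#' @export
runScreen <- function(cfg) {
  stopifnot(is(cfg, "ScreenConfig"))
  d <- length(cfg@comparisons)
  alphaPerTest <- bonferroniThreshold(cfg@params$alpha, d)
  rows <- lapply(names(cfg@comparisons), function(label) {
    bundle <- runPair(cfg, label)
    gc <- bundle$gencorr
    getMR <- function(mr, what) if (!is.null(mr$ivw)) mr$ivw[[what]] else NA_real_
    mrAB <- bundle$mr$primaryToComparison
    mrBA <- bundle$mr$comparisonToPrimary
    data.frame(trait = label, rG = gc@rG, rGSe = gc@se, rGP = gc@p,
               rGSignificant = !is.na(gc@p) & gc@p < alphaPerTest,
               nLoci = length(bundle$loci),
               orPrimaryToComparison = getMR(mrAB, "or"),
               pPrimaryToComparison = getMR(mrAB, "p"),
               mrABSignificant = !is.na(getMR(mrAB, "p")) &
                 getMR(mrAB, "p") < alphaPerTest,
               orComparisonToPrimary = getMR(mrBA, "or"),
               pComparisonToPrimary = getMR(mrBA, "p"),
               mrBASignificant = !is.na(getMR(mrBA, "p")) &
                 getMR(mrBA, "p") < alphaPerTest,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  attr(summary, "alphaPerTest") <- alphaPerTest
  dir.create(cfg@outDir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cbind(summary, alphaPerTest = alphaPerTest),
                     file.path(cfg@outDir, "screen_summary.tsv"),
                     sep = "\t", quote = FALSE)
  summary
}
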