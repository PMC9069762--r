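## Conditional Q-Q and fold-enrichment stratification: association strength
## in one trait conditioned on association strength in the other.

.strata <- function(p2, thresholds, inclusive) {
  nl2 <- -log10(p2)
  lapply(thresholds, function(c)
    if (inclusive) which(nl2 >= c) else which(nl2 > c))
}

#' Conditional Q-Q curves of one trait stratified by the other
#'
#' For each conditioning threshold `c` the stratum is the set of SNPs with
#' `-log10(p2) > c` (strict, the convention of conditional Q-Q displays).
#' Within a stratum the curve pairs the empirical quantile
#' `-log10(i / (n_s + 1))` with the observed `-log10(p1)` order statistic;
#' leftward deflection from the identity line with increasing threshold is
#' the signature of pleiotropic enrichment.
#'
#' @param p1 p-values of the trait of interest.
#' @param p2 aligned p-values of the conditioning trait.
#' @param thresholds -log10(p) cutoffs (default 0, 1, 2, 3, i.e. p2 < 1,
#'   0.1, 0.01, 0.001).
#' @return an [EnrichmentResult-class] with the `qq` slot populated.
#' @export
conditionalQQ <- function(p1, p2, thresholds = c(0, 1, 2, 3)) {
  stopifnot(length(p1) == length(p2))
  strata <- .strata(p2, thresholds, inclusive = FALSE)
  qq <- list()
  counts <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    idx <- strata[[k]]
    counts[k] <- length(idx)
    if (!length(idx)) {
      warning("empty stratum at threshold ", thresholds[k], "; omitted")
      next
    }
    ns <- length(idx)
    obs <- sort(-log10(p1[idx]), decreasing = FALSE)
    expd <- -log10(seq_len(ns) / (ns + 1))
    ## pair ascending-sorted p1 (largest -log10 last) with its quantile
    qq[[k]] <- data.frame(threshold = thresholds[k], n = ns,
                          expected = rev(expd), observed = obs)
  }
  new("EnrichmentResult", thresholds = thresholds,
      qq = do.call(rbind, qq),
      fe = data.frame(threshold = numeric(), x = numeric(), fe = numeric(),
                      nTail = integer()),
      strata = setNames(counts, paste0("gt", thresholds)))
}

#' Fold-enrichment curves of one trait stratified by the other
#'
#' For each conditioning threshold `c` the stratum is the set of SNPs with
#' `-log10(p2) >= c` (inclusive, so the threshold-0 stratum is all SNPs and
#' its curve is identically 1). At each grid point x,
#' `FE(x) = tail fraction of the stratum at -log10(p1) >= x` divided by the
#' same tail fraction over all SNPs; points where the overall tail is empty
#' are reported as NA.
#'
#' @inheritParams conditionalQQ
#' @param xGrid grid of nominal -log10(p1) values; default 200 evenly
#'   spaced points from 0 to the maximum observed.
#' @return an [EnrichmentResult-class] with the `fe` slot populated.
#' @export
foldEnrichment <- function(p1, p2, thresholds = c(0, 1, 2, 3), xGrid = NULL) {
  stopifnot(length(p1) == length(p2))
  nl1 <- -log10(p1)
  if (is.null(xGrid)) xGrid <- seq(0, max(nl1), length.out = 200)
  strata <- .strata(p2, thresholds, inclusive = TRUE)
  nAll <- length(p1)
  ## tail count via sorted -log10(p1): #{ >= x }
  sAll <- sort(nl1)
  tailCount <- function(sorted, x)
    length(sorted) - findInterval(x - 1e-12, sorted)
  fe <- list()
  counts <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    idx <- strata[[k]]
    counts[k] <- length(idx)
    if (!length(idx)) next
    sk <- sort(nl1[idx])
    cntK <- vapply(xGrid, function(x) tailCount(sk, x), numeric(1))
    cntAll <- vapply(xGrid, function(x) tailCount(sAll, x), numeric(1))
    val <- ifelse(cntAll > 0, (cntK / length(idx)) / (cntAll / nAll),
                  NA_real_)
    fe[[k]] <- data.frame(threshold = thresholds[k], x = xGrid, fe = val,
                          nTail = as.integer(cntK))
  }
  new("EnrichmentResult", thresholds = thresholds,
      qq = data.frame(threshold = numeric(), n = integer(),
                      expected = numeric(), observed = numeric()),
      fe = do.call(rbind, fe),
      strata = setNames(counts, paste0("ge", thresholds)))
}

#' Plot enrichment curves
#'
#' Conditional Q-Q curves (with the dotted null diagonal) or fold-enrichment
#' curves (with the horizontal unity line), one line per conditioning
#' stratum.
#'
#' @param x an [EnrichmentResult-class].
#' @param which `"qq"` or `"fe"`, defaulting to whichever part is present.
#' @param main plot title.
#' @return invisibly, `x`.
#' @export
plotEnrichment <- function(x, which = c("auto", "qq", "fe"), main = "") {
  which <- match.arg(which)
  if (which == "auto") which <- if (nrow(x@qq)) "qq" else "fe"
  cols <- seq_along(x@thresholds)
  if (which == "qq") {
    d <- x@qq
    if (!nrow(d)) stop("no Q-Q curves in this result")
    plot(range(d$expected), range(d$observed), type = "n",
         xlab = expression(Empirical ~ -log[10](p)),
         ylab = expression(Nominal ~ -log[10](p)), main = main)
    abline(0, 1, lty = 3)
    for (k in seq_along(x@thresholds)) {
      dk <- d[d$threshold == x@thresholds[k], ]
      if (nrow(dk)) lines(sort(dk$expected), sort(dk$observed), col = cols[k])
    }
  } else {
    d <- x@fe
    if (!nrow(d)) stop("no fold-enrichment curves in this result")
    plot(range(d$x), range(d$fe, na.rm = TRUE), type = "n",
         xlab = expression(Nominal ~ -log[10](p)), ylab = "Fold enrichment",
         main = main)
    abline(h = 1, lty = 1, col = "grey")
    for (k in seq_along(x@thresholds)) {
      dk <- d[d$threshold == x@thresholds[k], ]
      if (nrow(dk)) lines(dk$x, dk$fe, col = cols[k])
    }
  }
  legend("topleft", bty = "n", col = cols, lty = 1,
         legend = paste0("-log10(p2) ",
                         if (which == "qq") "> " else ">= ", x@thresholds))
  invisible(x)
}
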