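#' Estimate the bisulfite conversion rate from the spike-in control
#'
#' The unmethylated control (lambda-phage style spike-in) carries no true
#' methylation, so every methylated read on it is a non-conversion event.
#' The conversion rate is the pooled maximum-likelihood estimate
#' `1 - sum(cCount) / sum(totalCount)` over all covered control cytosines.
#'
#' @param x A [CytosineReport] containing the control sequence.
#' @param controlChrom Name of the control sequence.
#' @return A [ConversionEstimate][fruitMethyl-classes].
#' @examples
#' rep <- CytosineReport(rep("lambda_control", 2), c(5, 9), c("+", "+"),
#'                       c("CG", "CHH"), c(1, 0), c(60, 40))
#' conversionRate(estimateConversion(rep))
#' @export
estimateConversion <- function(x, controlChrom = "lambda_control") {
  sel <- as.character(GenomicRanges::seqnames(x)) == controlChrom
  if (!any(sel))
    stop("no cytosines on control sequence '", controlChrom, "'")
  n <- totalCount(x)[sel]
  cc <- cCount(x)[sel]
  covered <- n > 0
  if (sum(n) == 0) stop("control cytosines carry zero total coverage")
  new("ConversionEstimate",
      rate = 1 - sum(cc) / sum(n),
      nSites = sum(covered), nReads = sum(n))
}

#' Call methylcytosines with an exact binomial test
#'
#' For each covered cytosine, tests whether the methylated read count
#' exceeds what bisulfite non-conversion alone would produce: one-sided
#' upper-tail exact binomial `p = P(X >= cCount | n = totalCount,
#' p0 = 1 - conversion rate)`. A site is a methylcytosine when `p < alpha`
#' (raw p, no multiple-testing correction: `alpha` is exposed so callers
#' can tighten it). Records with zero coverage are skipped and counted.
#'
#' @param x A [CytosineReport].
#' @param conversion A [ConversionEstimate][fruitMethyl-classes], or a
#'   plain conversion rate in `[0,1]`.
#' @param alpha Significance cutoff (strict `<`).
#' @return A `CytosineReport`-shaped `GRanges` (class `CytosineReport`)
#'   with extra metadata columns `pValue` and `isMc`; skipped-record count
#'   in `metadata(x)$nSkipped`.
#' @examples
#' rep <- CytosineReport("chr1", 1:3, "+", "CHH", c(0, 5, 1), c(10, 10, 10))
#' calls <- callMethylcytosines(rep, 0.99)
#' S4Vectors::mcols(calls)
#' @export
callMethylcytosines <- function(x, conversion, alpha = 0.05) {
  if (is(conversion, "ConversionEstimate"))
    conversion <- conversionRate(conversion)
  stopifnot(conversion >= 0, conversion <= 1, alpha > 0, alpha < 1)
  p0 <- 1 - conversion
  covered <- totalCount(x) > 0
  nSkipped <- sum(!covered)
  out <- x[covered]
  n <- totalCount(out)
  cc <- cCount(out)
  p <- stats::pbinom(cc - 1L, n, p0, lower.tail = FALSE)
  S4Vectors::mcols(out)$pValue <- p
  S4Vectors::mcols(out)$isMc <- p < alpha
  S4Vectors::metadata(out)$nSkipped <- nSkipped
  S4Vectors::metadata(out)$alpha <- alpha
  if (nSkipped > 0)
    message(nSkipped, " record(s) with zero coverage skipped")
  out
}

#' Weighted methylation level of a set of cytosines
#'
#' The weighted level is `sum(cCount) / sum(totalCount)` (the #C/(#C+#T)
#' estimator), which pools reads rather than averaging per-site ratios and
#' is therefore invariant under partitioning. A subset with no covering
#' reads has no defined level and raises an error rather than returning 0.
#'
#' @param x A [CytosineReport] (optionally subset, e.g. by context or
#'   overlap with a region).
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`).
#' @param ... Unused.
#' @return A single proportion.
#' @examples
#' rep <- CytosineReport("chr1", 1:2, "+", "CHH", c(3, 7), c(10, 10))
#' weightedLevel(rep)  # 0.5
#' @export
setMethod("weightedLevel", "GRanges", function(x, context = NULL, ...) {
  if (!is.null(context)) {
    checkContext(context)
    x <- x[as.character(S4Vectors::mcols(x)$context) %in% context]
  }
  if (length(x) == 0)
    stop("no cytosine records in the requested subset: level undefined")
  n <- sum(as.numeric(totalCount(x)))
  if (n == 0)
    stop("zero total coverage in the requested subset: level undefined")
  sum(as.numeric(cCount(x))) / n
})

#' Proportion of methylcytosines in a context
#'
#' Fraction of covered cytosines of a context called methylated by
#' [callMethylcytosines()].
#'
#' @param calls Output of [callMethylcytosines()].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @return A proportion.
#' @export
mcProportion <- function(calls, context) {
  checkContext(context)
  sel <- as.character(S4Vectors::mcols(calls)$context) == context &
    totalCount(calls) > 0
  if (!any(sel))
    stop("no covered cytosines in context ", context, ": proportion undefined")
  mean(S4Vectors::mcols(calls)$isMc[sel])
}

#' Per-context methylation summary of a methylome
#'
#' @param x A [CytosineReport].
#' @param calls Optional output of [callMethylcytosines()] to add
#'   methylcytosine proportions.
#' @return A data.frame with one row per context: weighted level, covered
#'   sites, and (when calls are given) the methylcytosine proportion.
#' @export
contextSummary <- function(x, calls = NULL) {
  rows <- lapply(METH_CONTEXTS, function(cx) {
    sel <- context(x) == cx & totalCount(x) > 0
    lvl <- if (any(sel)) weightedLevel(x[sel]) else NA_real_
    prop <- if (!is.null(calls)) {
      tryCatch(mcProportion(calls, cx), error = function(e) NA_real_)
    } else NA_real_
    data.frame(context = cx, nCovered = sum(sel), level = lvl,
               mcProportion = prop)
  })
  do.call(rbind, rows)
}
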