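#' Construct a CytosineReport
#'
#' @param chrom Chromosome names.
#' @param pos 1-based cytosine positions.
#' @param strand `"+"` or `"-"` per cytosine (the strand carrying the C).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param cCount Methylated (unconverted) read counts.
#' @param totalCount Covering read counts.
#' @param seqlengths Optional named chromosome lengths.
#' @return A [CytosineReport][fruitMethyl-classes].
#' @examples
#' CytosineReport("chr1", c(3, 9), c("+", "-"), c("CG", "CHH"), c(2, 0), c(10, 7))
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
CytosineReport <- function(chrom, pos, strand, context, cCount, totalCount,
                           seqlengths = NULL) {
  checkContext(context)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    strand = strand,
    context = factor(as.character(context), levels = METH_CONTEXTS),
    cCount = as.integer(cCount),
    totalCount = as.integer(totalCount)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  new("CytosineReport", gr)
}

#' @describeIn CytosineReport Sequence context accessor.
#' @param x A `CytosineReport`, `McCalls` or `MethylWindows` object.
#' @param ... Unused.
#' @export
setMethod("context", "GRanges", function(x, ...) {
  as.character(S4Vectors::mcols(x)$context)
})

#' @describeIn CytosineReport Methylated read counts.
#' @export
setMethod("cCount", "GRanges", function(x, ...) S4Vectors::mcols(x)$cCount)

#' @describeIn CytosineReport Covering read counts.
#' @export
setMethod("totalCount", "GRanges", function(x, ...) S4Vectors::mcols(x)$totalCount)

setMethod("show", "CytosineReport", function(object) {
  cat("CytosineReport with", length(object), "cytosines on",
      length(GenomeInfoDb::seqlevels(object)), "sequence(s)\n")
  if (length(object) > 0) {
    tab <- table(context(object))
    cat("  contexts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    cov <- totalCount(object)
    cat(sprintf("  mean coverage: %.1f; covered sites: %d\n",
                mean(cov), sum(cov > 0)))
  }
  invisible(NULL)
})

#' @describeIn ConversionEstimate-utils Estimated conversion rate.
#' @export
setMethod("conversionRate", "ConversionEstimate", function(x, ...) x@rate)

#' Conversion estimate utilities
#'
#' @param x A `ConversionEstimate`.
#' @param ... Unused.
#' @name ConversionEstimate-utils
NULL

setMethod("show", "ConversionEstimate", function(object) {
  cat(sprintf(
    "ConversionEstimate: %.4f (%d spike-in cytosines, %d reads)\n",
    object@rate, as.integer(object@nSites), as.integer(object@nReads)))
  invisible(NULL)
})

setMethod("show", "DmrParams", function(object) {
  cat("DmrParams:\n")
  cat(sprintf("  window %d bp; |delta| > %s\n", object@windowSize,
              paste(sprintf("%s:%.2g", names(object@deltaThresholds),
                            object@deltaThresholds), collapse = " ")))
  cat(sprintf("  p < %g (Fisher), q < %g (BH); >= %g reads and >= %g sites/sample\n",
              object@pAlpha, object@qAlpha, object@minCoverage, object@minSites))
  invisible(NULL)
})

setMethod("show", "DmrSet", function(object) {
  cat("DmrSet with", length(object), "DMRs\n")
  if (length(object) > 0) {
    tab <- table(context(object), as.character(S4Vectors::mcols(object)$direction))
    print(tab)
  }
  invisible(NULL)
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:\n")
  cat(sprintf("  genome %g bp over %d chromosome(s), GC %.2f, control %g bp\n",
              object@genomeLength, object@nChromosomes, object@gcFraction,
              object@controlLength))
  cat(sprintf("  %d genes, %d TEs; stages: %s\n", object@nGenes, object@nTes,
              paste(object@stageNames, collapse = ", ")))
  cat(sprintf("  coverage ~Pois(%g), non-conversion %.3g, seed %d\n",
              object@coverageMean, object@nonConversionRate, object@seed))
  cat(sprintf("  %.0f%% of %d-bp windows truly shifted (%s)\n",
              100 * object@diffWindowFraction, object@windowSize,
              paste(sprintf("%s:%+.2f", names(object@diffEffect),
                            object@diffEffect), collapse = " ")))
  invisible(NULL)
})

#' @describeIn MetaProfile-utils Ordered weighted levels, 5' flank first.
#' @export
setMethod("binLevels", "MetaProfile", function(x, ...) x@binLevels)

#' Metagene profile utilities
#'
#' @param x A `MetaProfile`.
#' @param ... Unused.
#' @name MetaProfile-utils
NULL

setMethod("show", "MetaProfile", function(object) {
  cat(sprintf(
    "MetaProfile (%s): %d+%d+%d bins over %d features (%d skipped)\n",
    object@context, object@nBinsFlank, object@nBinsBody, object@nBinsFlank,
    object@nFeatures, object@nSkipped))
  lv <- object@binLevels
  cat(sprintf("  level range: %.4f..%.4f (%d empty bins)\n",
              suppressWarnings(min(lv, na.rm = TRUE)),
              suppressWarnings(max(lv, na.rm = TRUE)), sum(is.na(lv))))
  invisible(NULL)
})

#' Coerce a MetaProfile to a data.frame
#'
#' One row per bin with the segment label (`upstream`, `body`,
#' `downstream`), 5'-oriented bin index, pooled counts and weighted level.
#'
#' @param x A `MetaProfile`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
setMethod("as.data.frame", "MetaProfile", function(x, ...) {
  nf <- x@nBinsFlank; nb <- x@nBinsBody
  segment <- rep(c("upstream", "body", "downstream"), times = c(nf, nb, nf))
  data.frame(
    bin = seq_len(2L * nf + nb) - 1L,
    segment = segment,
    cSum = x@binC,
    nSum = x@binN,
    level = x@binLevels
  )
})

#' @describeIn DmrDensity-utils One-sided empirical enrichment p-value.
#' @export
setMethod("empiricalP", "DmrDensity", function(x, ...) x@empiricalP)

#' DMR density utilities
#'
#' @param x A `DmrDensity`.
#' @param ... Unused.
#' @name DmrDensity-utils
NULL

setMethod("show", "DmrDensity", function(object) {
  cat(sprintf(
    "DmrDensity: observed %g midpoints in anchor windows; background %.2f +/- %.2f (%d permutations)\n",
    object@observedTotal, mean(object@backgroundTotals),
    stats::sd(object@backgroundTotals), object@nPermutations))
  cat(sprintf("  empirical enrichment p = %.4g\n", object@empiricalP))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d true differential windows; %d true DMGs; %d true DEGs\n",
    length(object@trueDiffWindows), length(object@trueDmgIds),
    length(object@trueDegIds)))
  invisible(NULL)
})

#' Ground-truth accessors
#'
#' @param truth A `GroundTruth` object.
#' @return `trueDiffWindows()` a `GRanges` with `context` and `direction`;
#'   the id accessors character vectors.
#' @export
trueDiffWindows <- function(truth) truth@trueDiffWindows

#' @rdname trueDiffWindows
#' @export
trueDmgIds <- function(truth) truth@trueDmgIds

#' @rdname trueDiffWindows
#' @export
trueDegIds <- function(truth) truth@trueDegIds
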