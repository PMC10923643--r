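#' Container classes
#'
#' `fruitMethyl` represents per-cytosine bisulfite counts, window-level
#' differential tests and simulation metadata as S4 classes built on
#' [GenomicRanges::GRanges], so the usual range machinery (subsetting,
#' `findOverlaps`, seqinfo) applies throughout.
#'
#' @details
#' * `CytosineReport`: one strand-specific cytosine per row; width-1
#'   ranges with `context` (CG/CHG/CHH), `cCount`, `totalCount`.
#' * `MethylWindows`: fixed-width genome windows with pooled counts for
#'   two samples, one row per (window, context).
#' * `DmrSet`: windows passing the DMR definition, with `delta`
#'   (level B minus A), `pValue`, `qValue`, `direction` (hyper/hypo in B).
#' * `DmrParams`: window size, per-context delta thresholds, p/q cutoffs
#'   and per-sample testability floors (see [dmrParams()]).
#' * `ConversionEstimate`: pooled conversion rate from the spike-in.
#' * `SimulationSpec` / `GroundTruth`: generator parameterization and the
#'   true differential windows / DMG ids / DEG ids it implants.
#' * `MetaProfile`: strand-aware binned methylation curve, bin 0 5'-most.
#' * `DmrDensity`: observed DMR density near TSS/TES with its
#'   permutation background and one-sided empirical enrichment p.
#'
#' @name fruitMethyl-classes
#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
NULL

## ---- CytosineReport --------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass CytosineReport
setClass("CytosineReport", contains = "GRanges")

setValidity("CytosineReport", function(object) {
  mc <- S4Vectors::mcols(object)
  need <- c("context", "cCount", "totalCount")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata column(s):",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(object) == 0) return(TRUE)
  if (any(BiocGenerics::width(object) != 1))
    return("all cytosine ranges must have width 1")
  ctx <- as.character(mc$context)
  if (!all(ctx %in% METH_CONTEXTS))
    return("context must be one of CG, CHG, CHH")
  cc <- mc$cCount; nn <- mc$totalCount
  if (any(cc < 0) || any(nn < 0) || any(cc > nn))
    return("counts must satisfy 0 <= cCount <= totalCount")
  if (any(as.character(BiocGenerics::strand(object)) == "*"))
    return("strand must be + or -")
  TRUE
})

## ---- MethylWindows ---------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass MethylWindows
setClass("MethylWindows", contains = "GRanges")

setValidity("MethylWindows", function(object) {
  mc <- S4Vectors::mcols(object)
  need <- c("context", "cA", "nA", "cB", "nB",
            "nSitesA", "nSitesB", "levelA", "levelB", "testable")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata column(s):",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(object) > 0) {
    if (any(mc$cA > mc$nA) || any(mc$cB > mc$nB))
      return("window counts must satisfy c <= n")
  }
  TRUE
})

## ---- DmrSet ----------------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass DmrSet
setClass("DmrSet", contains = "GRanges")

setValidity("DmrSet", function(object) {
  mc <- S4Vectors::mcols(object)
  need <- c("context", "delta", "pValue", "qValue", "direction")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata column(s):",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(object) > 0) {
    if (!all(as.character(mc$direction) %in% c("hyper", "hypo")))
      return("direction must be hyper or hypo")
    ok <- (mc$delta > 0) == (as.character(mc$direction) == "hyper")
    if (!all(ok)) return("direction must equal the sign of delta")
  }
  TRUE
})

## ---- DmrParams -------------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass DmrParams
setClass("DmrParams", representation(
  windowSize      = "integer",
  deltaThresholds = "numeric",
  pAlpha          = "numeric",
  qAlpha          = "numeric",
  minCoverage     = "numeric",
  minSites        = "numeric"
))

setValidity("DmrParams", function(object) {
  if (object@windowSize < 1) return("windowSize must be >= 1")
  dt <- object@deltaThresholds
  if (!all(METH_CONTEXTS %in% names(dt)))
    return("deltaThresholds must be named for CG, CHG and CHH")
  if (any(dt <= 0) || any(dt > 1)) return("deltaThresholds must lie in (0,1]")
  for (a in c(object@pAlpha, object@qAlpha))
    if (a <= 0 || a >= 1) return("alphas must lie in (0,1)")
  TRUE
})

#' DMR caller parameters
#'
#' Defaults follow the windowed definition used throughout the package: the
#' genome is tiled in 200-bp windows and a window is differentially
#' methylated when the absolute weighted-level difference exceeds 0.4 (CG),
#' 0.2 (CHG) or 0.1 (CHH), with two-sided Fisher's exact `p < 0.05` and
#' Benjamini-Hochberg `q < 0.05`. The coverage and site floors are quality
#' gates: windows with fewer pooled reads or covered context cytosines in
#' either sample are reported untestable rather than tested.
#'
#' @param windowSize Window width in bp.
#' @param deltaThresholds Named numeric, minimum |level difference| per context.
#' @param pAlpha,qAlpha Fisher p-value and BH q-value cutoffs (strict `<`).
#' @param minCoverage Minimum pooled reads per window per sample.
#' @param minSites Minimum covered cytosines of the context per window per sample.
#' @return A `DmrParams` object.
#' @examples
#' dmrParams(windowSize = 100)
#' @export
dmrParams <- function(windowSize = 200L,
                      deltaThresholds = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                      pAlpha = 0.05, qAlpha = 0.05,
                      minCoverage = 10, minSites = 3) {
  new("DmrParams", windowSize = as.integer(windowSize),
      deltaThresholds = deltaThresholds, pAlpha = pAlpha, qAlpha = qAlpha,
      minCoverage = minCoverage, minSites = minSites)
}

## ---- ConversionEstimate ----------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass ConversionEstimate
setClass("ConversionEstimate", representation(
  rate   = "numeric",
  nSites = "numeric",
  nReads = "numeric"
))

setValidity("ConversionEstimate", function(object) {
  if (object@rate < 0 || object@rate > 1) return("rate must lie in [0,1]")
  TRUE
})

## ---- SimulationSpec --------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass SimulationSpec
setClass("SimulationSpec", representation(
  genomeLength      = "numeric",
  nChromosomes      = "integer",
  gcFraction        = "numeric",
  nGenes            = "integer",
  nTes              = "integer",
  geneLengthRange   = "numeric",
  teLengthRange     = "numeric",
  stageNames        = "character",
  contextLevelMeans = "matrix",
  diffWindowFraction = "numeric",
  diffEffect        = "numeric",
  windowSize        = "integer",
  betaConcentration = "numeric",
  coverageMean      = "numeric",
  nonConversionRate = "numeric",
  controlLength     = "numeric",
  couplingProb      = "numeric",
  backgroundDegRate = "numeric",
  effectLfc         = "numeric",
  effectAdjP        = "numeric",
  nullLfcSd         = "numeric",
  seed              = "integer"
))

setValidity("SimulationSpec", function(object) {
  pr <- c(gc = object@gcFraction, diff = object@diffWindowFraction,
          nonconv = object@nonConversionRate, coupling = object@couplingProb,
          bg = object@backgroundDegRate)
  if (any(pr < 0) || any(pr > 1))
    return("all proportion parameters must lie in [0,1]")
  if (object@coverageMean <= 0) return("coverageMean must be > 0")
  if (object@genomeLength < 1) return("genomeLength must be positive")
  if (length(object@stageNames) < 1) return("at least one stage is required")
  clm <- object@contextLevelMeans
  if (!all(METH_CONTEXTS %in% colnames(clm)))
    return("contextLevelMeans must have columns CG, CHG, CHH")
  if (!all(object@stageNames %in% rownames(clm)))
    return("contextLevelMeans must have one row per stage")
  if (any(clm < 0) || any(clm > 1))
    return("contextLevelMeans must lie in [0,1]")
  if (!all(METH_CONTEXTS %in% names(object@diffEffect)))
    return("diffEffect must be named for CG, CHG and CHH")
  if (object@nGenes > 0 &&
      object@genomeLength < object@nGenes * min(object@geneLengthRange))
    return("genome too short to hold nGenes at the minimum gene footprint")
  TRUE
})

## ---- GroundTruth -----------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  trueDiffWindows = "GRanges",
  trueDmgIds      = "character",
  trueDegIds      = "character"
))

## ---- MetaProfile -----------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass MetaProfile
setClass("MetaProfile", representation(
  context    = "character",
  binLevels  = "numeric",
  binC       = "numeric",
  binN       = "numeric",
  nBinsFlank = "integer",
  nBinsBody  = "integer",
  flank      = "numeric",
  nFeatures  = "integer",
  nSkipped   = "integer"
))

setValidity("MetaProfile", function(object) {
  expected <- 2L * object@nBinsFlank + object@nBinsBody
  if (length(object@binLevels) != expected)
    return("binLevels must have length 2*nBinsFlank + nBinsBody")
  lv <- object@binLevels[!is.na(object@binLevels)]
  if (any(lv < 0) || any(lv > 1)) return("bin levels must lie in [0,1]")
  TRUE
})

## ---- DmrDensity ------------------------------------------------------

#' @rdname fruitMethyl-classes
#' @exportClass DmrDensity
setClass("DmrDensity", representation(
  bins            = "data.frame",
  observedTotal   = "numeric",
  backgroundTotals = "numeric",
  empiricalP      = "numeric",
  nPermutations   = "integer",
  seed            = "integer"
))

setValidity("DmrDensity", function(object) {
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must lie in (0,1]")
  TRUE
})
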