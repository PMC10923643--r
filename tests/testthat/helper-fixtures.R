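## Small fixture builders; everything is generated in code at test time.

## Quick CytosineReport from parallel vectors with convenient defaults.
makeReport <- function(pos, cCount, totalCount, chrom = "chr1",
                       strand = "+", context = "CHH", seqlengths = NULL) {
  n <- length(pos)
  CytosineReport(rep_len(chrom, n), pos, rep_len(strand, n),
                 rep_len(context, n), cCount, totalCount,
                 seqlengths = seqlengths)
}

## Stage-constant level matrix: no background change between stages, so
## implanted differential windows are the only true signal.
equalMeansMatrix <- function(stages = c("YF", "EF", "MF"),
                             cg = 0.65, chg = 0.45, chh = 0.066) {
  matrix(rep(c(cg, chg, chh), each = length(stages)),
         nrow = length(stages),
         dimnames = list(stages, c("CG", "CHG", "CHH")))
}

## Study conditions for the DMR power check: CHH shift +0.15 implanted in
## 10% of 200-bp windows, ~40x coverage, shared across later stages.
recoverySpec <- function(seed = 101L, genomeLength = 2e5) {
  simulationSpec(
    genomeLength = genomeLength, nChromosomes = 2L,
    nGenes = 40L, nTes = 20L, controlLength = 10000,
    contextLevelMeans = equalMeansMatrix(),
    diffWindowFraction = 0.10,
    diffEffect = c(CG = -0.45, CHG = -0.25, CHH = 0.15),
    coverageMean = 40, nonConversionRate = 0.01, seed = seed)
}

## Null conditions: no implanted shifts, stage means equal.
nullSpec <- function(seed = 77L, genomeLength = 1.5e5) {
  simulationSpec(
    genomeLength = genomeLength, nChromosomes = 2L,
    nGenes = 20L, nTes = 10L, controlLength = 10000,
    stageNames = c("YF", "EF"),
    contextLevelMeans = equalMeansMatrix(stages = c("YF", "EF")),
    diffWindowFraction = 0, coverageMean = 40,
    nonConversionRate = 0.01, seed = seed)
}

## Level-recovery conditions: stage-wise CHH targets 0.066 -> 0.153 with
## no implanted windows, so the genome-wide level equals the target.
levelsSpec <- function(seed = 55L, genomeLength = 2e5) {
  m <- matrix(c(0.65, 0.60,
                0.45, 0.40,
                0.066, 0.153),
              nrow = 2, dimnames = list(c("YF", "EF"), c("CG", "CHG", "CHH")))
  simulationSpec(
    genomeLength = genomeLength, nChromosomes = 2L,
    nGenes = 20L, nTes = 10L, controlLength = 10000,
    stageNames = c("YF", "EF"), contextLevelMeans = m,
    diffWindowFraction = 0, coverageMean = 40,
    nonConversionRate = 0.01, seed = seed)
}

dropControl <- function(report, chrom = "lambda_control") {
  report[as.character(GenomicRanges::seqnames(report)) != chrom]
}
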