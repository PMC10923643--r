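#' Strand-aware metagene methylation profile
#'
#' Computes the binned weighted-methylation curve over the upstream flank,
#' scaled body, and downstream flank of a feature set (genes or TEs). Each
#' feature's 2-kb flanks are cut into `nBinsFlank` equal bins and its body
#' into `nBinsBody` proportional bins, minus-strand features are reversed
#' so bin 0 is always 5'-most, and each bin's level is the weighted level
#' pooled over all cytosines of the context falling in that bin across all
#' features. Bins never touched by a covered cytosine are `NA`. Features
#' shorter than `nBinsBody` bp cannot be split into that many bins and are
#' skipped (the count is reported in the result).
#'
#' @param features `GRanges` of gene/TE models with strand (unstranded
#'   features are treated as plus).
#' @param records A [CytosineReport].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank Flank length in bp.
#' @param nBinsFlank Bins per flank.
#' @param nBinsBody Bins over the feature body.
#' @return A [MetaProfile][fruitMethyl-classes].
#' @export
computeMetaprofile <- function(features, records, context,
                               flank = 2000, nBinsFlank = 20L,
                               nBinsBody = 40L) {
  checkContext(context)
  if (length(features) == 0) stop("no features supplied")
  nBinsFlank <- as.integer(nBinsFlank); nBinsBody <- as.integer(nBinsBody)
  keep <- BiocGenerics::width(features) >= nBinsBody
  nSkipped <- sum(!keep)
  features <- features[keep]
  if (length(features) == 0)
    stop("all features shorter than nBinsBody bp; nothing to profile")

  sel <- as.character(S4Vectors::mcols(records)$context) == context &
    totalCount(records) > 0
  rec <- records[sel]
  nBins <- 2L * nBinsFlank + nBinsBody

  bins <- metageneBins(features, flank, nBinsFlank, nBinsBody)
  cSum <- numeric(nBins); nSum <- numeric(nBins)
  if (length(rec) > 0 && length(bins) > 0) {
    hits <- GenomicRanges::findOverlaps(rec, bins, ignore.strand = TRUE)
    if (length(hits) > 0) {
      bi <- S4Vectors::mcols(bins)$binIdx[S4Vectors::subjectHits(hits)]
      cc <- cCount(rec)[S4Vectors::queryHits(hits)]
      nn <- totalCount(rec)[S4Vectors::queryHits(hits)]
      cSum <- as.numeric(tapply(cc, factor(bi, levels = seq_len(nBins) - 1L),
                                sum, default = 0))
      nSum <- as.numeric(tapply(nn, factor(bi, levels = seq_len(nBins) - 1L),
                                sum, default = 0))
    }
  }
  levels <- ifelse(nSum > 0, cSum / nSum, NA_real_)
  new("MetaProfile", context = context, binLevels = levels,
      binC = cSum, binN = nSum, nBinsFlank = nBinsFlank,
      nBinsBody = nBinsBody, flank = flank,
      nFeatures = length(features), nSkipped = as.integer(nSkipped))
}

## One GRanges of all (feature x bin) intervals, binIdx 0-based and
## 5'-oriented: bins [0, nFlank) upstream, [nFlank, nFlank+nBody) body,
## [nFlank+nBody, 2*nFlank+nBody) downstream.
metageneBins <- function(features, flank, nBinsFlank, nBinsBody) {
  sl <- GenomeInfoDb::seqlengths(features)
  parts <- lapply(seq_along(features), function(i) {
    f <- features[i]
    ch <- as.character(GenomicRanges::seqnames(f))
    minus <- as.character(BiocGenerics::strand(f)) == "-"
    s <- BiocGenerics::start(f); e <- BiocGenerics::end(f)
    ## genomic-coordinate breakpoints, left to right
    upBreaks <- round(seq(s - flank, s, length.out = nBinsFlank + 1))
    bodyBreaks <- round(seq(s, e + 1, length.out = nBinsBody + 1))
    dnBreaks <- round(seq(e + 1, e + 1 + flank, length.out = nBinsFlank + 1))
    mk <- function(br) {
      data.frame(start = br[-length(br)], end = br[-1] - 1)
    }
    df <- rbind(mk(upBreaks), mk(bodyBreaks), mk(dnBreaks))
    ## left-to-right genomic order; orient so index 0 is 5'-most
    df$binIdx <- if (minus) rev(seq_len(nrow(df)) - 1L) else seq_len(nrow(df)) - 1L
    ## clip at chromosome bounds; drop bins fully outside
    L <- if (!is.null(sl) && !is.na(sl[ch])) sl[ch] else Inf
    df$start <- pmax(df$start, 1)
    df$end <- pmin(df$end, L)
    df <- df[df$start <= df$end, , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    df$chrom <- ch
    df
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$binIdx <- df$binIdx
  gr
}

#' DMR density near TSS/TES versus a random-placement background
#'
#' Counts DMR midpoints in strand-oriented windows of +/- `flank` bp
#' around every feature's transcription start and end site, expressed as
#' DMRs per feature per kb in `binWidth`-bp bins. The background is built
#' by permutation: in each permutation an equal number of length-matched
#' regions is placed uniformly at random on the genome (control excluded
#' by omitting it from `seqlengths`) and the same counting is applied. The
#' one-sided empirical enrichment p-value is
#' `(1 + #permutations with total >= observed) / (1 + nPermutations)`.
#'
#' @param dmrs A [DmrSet][fruitMethyl-classes] (already filtered to the
#'   context/direction of interest, e.g. CHH hyper).
#' @param features `GRanges` of gene models with strand.
#' @param seqlengths Named chromosome lengths available for random
#'   placement.
#' @param flank Window half-width around TSS/TES (bp).
#' @param binWidth Bin width (bp); must divide `2 * flank`.
#' @param nPermutations Number of background permutations.
#' @param seed Seed for the background placements.
#' @return A [DmrDensity][fruitMethyl-classes]; `@bins` holds one row per
#'   (anchor, bin) with the observed density and background mean/sd.
#' @export
dmrDensityVsRandom <- function(dmrs, features, seqlengths, flank = 2000,
                               binWidth = 200L, nPermutations = 1000L,
                               seed = 1L) {
  if (length(features) == 0) stop("no features supplied")
  if (nPermutations < 100)
    warning("fewer than 100 permutations gives a coarse empirical p-value")
  stopifnot((2 * flank) %% binWidth == 0)
  nBins <- as.integer(2 * flank / binWidth)

  mids <- midpoints(dmrs)
  widths <- BiocGenerics::width(dmrs)
  anchors <- anchorTable(features)

  countBins <- function(midChrom, midPos) {
    counts <- matrix(0, nrow = 2, ncol = nBins,
                     dimnames = list(c("TSS", "TES"), NULL))
    if (length(midPos) == 0) return(counts)
    for (a in c("TSS", "TES")) {
      at <- anchors[anchors$anchor == a, ]
      for (k in seq_len(nrow(at))) {
        sel <- midChrom == at$chrom[k]
        if (!any(sel)) next
        off <- (midPos[sel] - at$pos[k]) * at$orient[k]
        inWin <- off >= -flank & off < flank
        if (!any(inWin)) next
        bi <- (off[inWin] + flank) %/% binWidth
        tab <- tabulate(bi + 1L, nbins = nBins)
        counts[a, ] <- counts[a, ] + tab
      }
    }
    counts
  }

  obs <- countBins(as.character(GenomicRanges::seqnames(dmrs)), mids)
  obsTotal <- sum(obs)
  nFeat <- length(features)
  dens <- function(counts) counts / nFeat / (binWidth / 1000)

  permTotals <- numeric(nPermutations)
  permSum <- matrix(0, 2, nBins); permSumSq <- matrix(0, 2, nBins)
  if (length(widths) > 0) {
    withSeed(seed, {
      chroms <- names(seqlengths)
      for (p in seq_len(nPermutations)) {
        ch <- sample(chroms, length(widths), replace = TRUE,
                     prob = seqlengths / sum(seqlengths))
        maxStart <- pmax(1, seqlengths[ch] - widths + 1)
        st <- floor(stats::runif(length(widths), 1, maxStart + 1))
        pm <- st + (widths - 1L) %/% 2L
        cnt <- countBins(ch, pm)
        permTotals[p] <- sum(cnt)
        d <- dens(cnt)
        permSum <- permSum + d
        permSumSq <- permSumSq + d^2
      }
    })
  }
  bgMean <- permSum / nPermutations
  bgVar <- permSumSq / nPermutations - bgMean^2
  bgVar[bgVar < 0] <- 0
  bgSd <- sqrt(bgVar)
  obsD <- dens(obs)
  offsets <- seq(-flank, flank - binWidth, by = binWidth)
  bins <- data.frame(
    anchor = rep(c("TSS", "TES"), each = nBins),
    offset = rep(offsets, 2),
    observedDensity = c(obsD["TSS", ], obsD["TES", ]),
    backgroundMean = c(bgMean[1, ], bgMean[2, ]),
    backgroundSd = c(bgSd[1, ], bgSd[2, ]))
  new("DmrDensity",
      bins = bins, observedTotal = obsTotal,
      backgroundTotals = permTotals,
      empiricalP = (1 + sum(permTotals >= obsTotal)) / (1 + nPermutations),
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

midpoints <- function(gr) {
  BiocGenerics::start(gr) + (BiocGenerics::width(gr) - 1L) %/% 2L
}

## TSS/TES genomic positions with 5'->3' orientation sign per feature.
anchorTable <- function(features) {
  minus <- as.character(BiocGenerics::strand(features)) == "-"
  s <- BiocGenerics::start(features); e <- BiocGenerics::end(features)
  data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(features)), 2),
    anchor = rep(c("TSS", "TES"), each = length(features)),
    pos = c(ifelse(minus, e, s), ifelse(minus, s, e)),
    orient = rep(ifelse(minus, -1L, 1L), 2))
}
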