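#' @importFrom data.table data.table setkey .N .SD :=
NULL

## Non-overlapping tiling [1,w], [w+1,2w], ...; last window truncated at
## the chromosome end.
tileWindows <- function(seqlengths, windowSize) {
  parts <- lapply(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    starts <- seq.int(1L, L, by = windowSize)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + windowSize - 1L, L))
  })
  df <- do.call(rbind, parts)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         seqlengths = seqlengths)
}

#' Aggregate two methylomes into fixed windows
#'
#' Tiles every chromosome in non-overlapping `windowSize`-bp windows (the
#' final window of a chromosome is truncated) and, per window and context,
#' pools methylated and total read counts over all strand-specific
#' cytosines of the two samples. A (window, context) pair is testable when
#' both samples reach `minCoverage` pooled reads and `minSites` covered
#' context cytosines in it.
#'
#' @param a,b [CytosineReport]s for samples A and B (same reference).
#' @param params A [dmrParams()].
#' @param seqlengths Named chromosome lengths; inferred from the reports'
#'   seqinfo (or observed maxima) when missing.
#' @param excludeChrom Chromosomes to leave out of the tiling (default the
#'   spike-in control).
#' @return A [MethylWindows][fruitMethyl-classes] with one row per
#'   (window, context) having at least one covered cytosine in either
#'   sample.
#' @export
binWindows <- function(a, b, params = dmrParams(), seqlengths = NULL,
                       excludeChrom = "lambda_control") {
  chromsA <- unique(as.character(GenomicRanges::seqnames(a)))
  chromsB <- unique(as.character(GenomicRanges::seqnames(b)))
  onlyA <- setdiff(chromsA, chromsB); onlyB <- setdiff(chromsB, chromsA)
  if (length(onlyA) || length(onlyB)) {
    stop("methylomes cover different chromosome sets; only in A: {",
         paste(onlyA, collapse = ","), "}, only in B: {",
         paste(onlyB, collapse = ","), "}")
  }
  if (is.null(seqlengths)) seqlengths <- inferSeqlengths(a, b)
  seqlengths <- seqlengths[!(names(seqlengths) %in% excludeChrom)]
  w <- params@windowSize

  agg <- function(x) {
    keep <- !(as.character(GenomicRanges::seqnames(x)) %in% excludeChrom)
    x <- x[keep]
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(x)),
      widx = (BiocGenerics::start(x) - 1L) %/% w,
      context = context(x),
      cc = cCount(x), nn = totalCount(x))
    dt[, list(c = sum(cc), n = sum(nn), sites = sum(nn > 0)),
       by = c("chrom", "widx", "context")]
  }
  da <- agg(a); db <- agg(b)
  m <- merge(da, db, by = c("chrom", "widx", "context"), all = TRUE,
             suffixes = c("A", "B"))
  for (col in c("cA", "nA", "sitesA", "cB", "nB", "sitesB"))
    m[[col]][is.na(m[[col]])] <- 0
  m <- m[order(match(m$chrom, names(seqlengths)), m$widx,
               match(m$context, METH_CONTEXTS)), ]
  starts <- m$widx * w + 1L
  ends <- pmin(starts + w - 1L, seqlengths[m$chrom])
  gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(starts, ends),
                               seqlengths = seqlengths)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = m$context,
    cA = m$cA, nA = m$nA, cB = m$cB, nB = m$nB,
    nSitesA = m$sitesA, nSitesB = m$sitesB,
    levelA = ifelse(m$nA > 0, m$cA / m$nA, NA_real_),
    levelB = ifelse(m$nB > 0, m$cB / m$nB, NA_real_),
    testable = m$nA >= params@minCoverage & m$nB >= params@minCoverage &
      m$sitesA >= params@minSites & m$sitesB >= params@minSites,
    truncated = (ends - starts + 1L) < w
  )
  out <- new("MethylWindows", gr)
  S4Vectors::metadata(out)$windowSize <- w
  out
}

#' Two-sided Fisher's exact test for window counts
#'
#' Tests independence of methylation and sample in the 2x2 table
#' `[[cA, nA - cA], [cB, nB - cB]]`. The two-sided p-value is the
#' conventional point-probability definition: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one, matching `stats::fisher.test`. Vectorized over
#' windows.
#'
#' @param cA,nA Methylated and total counts in sample A.
#' @param cB,nB Methylated and total counts in sample B.
#' @return Numeric vector of p-values (`NA` where a sample total is 0).
#' @examples
#' fisherWindowTest(10, 10, 0, 10)  # 2 / choose(20, 10)
#' @export
fisherWindowTest <- function(cA, nA, cB, nB) {
  n <- length(cA)
  stopifnot(length(nA) == n, length(cB) == n, length(nB) == n)
  vapply(seq_len(n), function(i) {
    if (nA[i] == 0 || nB[i] == 0) return(NA_real_)
    K <- cA[i] + cB[i]
    N <- nA[i] + nB[i]
    supp <- max(0, K - nB[i]):min(K, nA[i])
    d <- stats::dhyper(supp, K, N - K, nA[i])
    dObs <- stats::dhyper(cA[i], K, N - K, nA[i])
    min(1, sum(d[d <= dObs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Call differentially methylated regions
#'
#' Applies the windowed DMR definition to binned counts: a testable
#' (window, context) is a DMR when the absolute weighted-level difference
#' exceeds the context threshold, the two-sided Fisher's exact p-value is
#' below `pAlpha`, and its Benjamini-Hochberg q-value - computed per
#' context over all testable windows of that context - is below `qAlpha`.
#' `delta = levelB - levelA`; DMRs with positive delta are `hyper` in
#' sample B.
#'
#' @param windows A [MethylWindows][fruitMethyl-classes] from
#'   [binWindows()].
#' @param params A [dmrParams()].
#' @return A [DmrSet][fruitMethyl-classes]. The tested windows with their
#'   p and q values are attached as `metadata(result)$tested`.
#' @export
callDmrs <- function(windows, params = dmrParams()) {
  mc <- S4Vectors::mcols(windows)
  testable <- which(mc$testable)
  if (length(testable) == 0) {
    warning("no testable windows; empty DMR set returned")
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
      context = character(), delta = numeric(), pValue = numeric(),
      qValue = numeric(), direction = character())
    out <- new("DmrSet", empty)
    S4Vectors::metadata(out)$windowSize <- S4Vectors::metadata(windows)$windowSize
    return(out)
  }
  tw <- windows[testable]
  mct <- S4Vectors::mcols(tw)
  p <- fisherWindowTest(mct$cA, mct$nA, mct$cB, mct$nB)
  q <- rep(NA_real_, length(p))
  for (cx in unique(as.character(mct$context))) {
    sel <- as.character(mct$context) == cx
    q[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  delta <- mct$levelB - mct$levelA
  thr <- params@deltaThresholds[as.character(mct$context)]
  isDmr <- abs(delta) > thr & p < params@pAlpha & q < params@qAlpha
  dmr <- GenomicRanges::granges(tw[isDmr])
  S4Vectors::mcols(dmr) <- S4Vectors::DataFrame(
    context = as.character(mct$context)[isDmr],
    delta = delta[isDmr],
    pValue = p[isDmr],
    qValue = q[isDmr],
    direction = ifelse(delta[isDmr] > 0, "hyper", "hypo"))
  out <- new("DmrSet", dmr)
  tested <- GenomicRanges::granges(tw)
  S4Vectors::mcols(tested) <- S4Vectors::DataFrame(
    context = as.character(mct$context), delta = delta, pValue = p, qValue = q)
  S4Vectors::metadata(out)$tested <- tested
  S4Vectors::metadata(out)$windowSize <- S4Vectors::metadata(windows)$windowSize
  out
}

#' Compare two DMR sets called on the same window tiling
#'
#' A DMR is shared when a window with identical coordinates and context is
#' present in both sets (the fixed tiling makes window identity
#' well-defined). Reports, per context, the counts unique to each set, the
#' shared count, and the direction concordance among shared DMRs (`NA`
#' when nothing is shared).
#'
#' @param d1,d2 [DmrSet][fruitMethyl-classes]s from [callDmrs()] runs on
#'   the same tiling.
#' @return A data.frame with one row per context.
#' @export
sharedDmrs <- function(d1, d2) {
  w1 <- S4Vectors::metadata(d1)$windowSize
  w2 <- S4Vectors::metadata(d2)$windowSize
  if (!is.null(w1) && !is.null(w2) && !identical(w1, w2))
    stop("DMR sets were called with different window sizes (", w1, " vs ",
         w2, ")")
  key <- function(d) paste(as.character(GenomicRanges::seqnames(d)),
                           BiocGenerics::start(d), BiocGenerics::end(d),
                           context(d))
  k1 <- key(d1); k2 <- key(d2)
  dir1 <- as.character(S4Vectors::mcols(d1)$direction)
  dir2 <- as.character(S4Vectors::mcols(d2)$direction)
  rows <- lapply(METH_CONTEXTS, function(cx) {
    s1 <- context(d1) == cx; s2 <- context(d2) == cx
    shared <- intersect(k1[s1], k2[s2])
    conc <- if (length(shared) > 0) {
      mean(dir1[match(shared, k1)] == dir2[match(shared, k2)])
    } else NA_real_
    data.frame(context = cx,
               nOnly1 = sum(s1) - length(shared),
               nOnly2 = sum(s2) - length(shared),
               nShared = length(shared),
               concordance = conc)
  })
  do.call(rbind, rows)
}

#' Fraction of the genome covered by DMRs
#'
#' Union of DMR window intervals in bp divided by total genome length
#' (spike-in control excluded by leaving it out of `seqlengths`).
#'
#' @param dmrs A [DmrSet][fruitMethyl-classes].
#' @param seqlengths Named chromosome lengths of the genome proper.
#' @return Named proportions, one per context plus `"all"`.
#' @export
genomeDmrCoverage <- function(dmrs, seqlengths) {
  total <- sum(as.numeric(seqlengths))
  stopifnot(total > 0)
  cov1 <- function(gr) {
    if (length(gr) == 0) return(0)
    sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(
      GenomicRanges::granges(gr))))) / total
  }
  out <- vapply(METH_CONTEXTS, function(cx) cov1(dmrs[context(dmrs) == cx]),
                numeric(1))
  c(out, all = cov1(dmrs))
}

#' Write a DMR set as BED6+
#'
#' Columns: chrom, 0-based start, end, name (context), score
#' (`-log10(q)`, capped at 1000), strand `"."`, then delta, p, q and
#' direction.
#'
#' @param dmrs A [DmrSet][fruitMethyl-classes].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
  mc <- S4Vectors::mcols(dmrs)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    start = BiocGenerics::start(dmrs) - 1L,
    end = BiocGenerics::end(dmrs),
    name = as.character(mc$context),
    score = round(pmin(1000, -log10(pmax(mc$qValue, 1e-300))), 3),
    strand = ".",
    delta = mc$delta, p = mc$pValue, q = mc$qValue,
    direction = as.character(mc$direction))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
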