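#' Classify differentially expressed genes from supplied statistics
#'
#' Applies the thresholding rule `|log2FC| > lfcThreshold` and
#' `adj_p < alpha` (both strict, so boundary values are `ns`) to a table
#' of per-gene differential-expression statistics. The model fit itself
#' is out of scope: the inputs are the statistics another tool produced.
#'
#' @param stats data.frame with columns `gene_id`, `log2_fc`, `adj_p`.
#' @param lfcThreshold Minimum absolute log2 fold change.
#' @param alpha Maximum adjusted p-value.
#' @return The input with an added `direction` factor (`up`/`down`/`ns`).
#' @examples
#' classifyDegs(data.frame(gene_id = c("g1", "g2"),
#'                         log2_fc = c(3, 2), adj_p = c(1e-4, 1e-4)))
#' @export
classifyDegs <- function(stats, lfcThreshold = 2, alpha = 0.05) {
  need <- c("gene_id", "log2_fc", "adj_p")
  if (!all(need %in% colnames(stats)))
    stop("stats table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(stats$gene_id))
    stop("duplicate gene ids in the statistics table")
  if (any(!is.finite(stats$log2_fc)))
    stop("non-finite log2 fold changes")
  if (any(is.na(stats$adj_p)) || any(stats$adj_p < 0) || any(stats$adj_p > 1))
    stop("adjusted p-values must lie in [0,1]")
  sig <- stats$adj_p < alpha
  direction <- ifelse(sig & stats$log2_fc > lfcThreshold, "up",
                      ifelse(sig & stats$log2_fc < -lfcThreshold, "down", "ns"))
  stats$direction <- factor(direction, levels = c("up", "down", "ns"))
  stats
}

## Strand-aware promoter/body/downstream regions of one gene set.
geneRegions <- function(genes, flank) {
  minus <- as.character(BiocGenerics::strand(genes)) == "-"
  s <- BiocGenerics::start(genes); e <- BiocGenerics::end(genes)
  ch <- as.character(GenomicRanges::seqnames(genes))
  sl <- GenomeInfoDb::seqlengths(genes)
  mk <- function(start, end, region) {
    start <- pmax(start, 1)
    if (!is.null(sl) && !all(is.na(sl))) {
      lim <- sl[ch]
      end <- ifelse(is.na(lim), end, pmin(end, lim))
    }
    keep <- start <= end
    gr <- GenomicRanges::GRanges(ch[keep],
                                 IRanges::IRanges(start[keep], end[keep]))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneIdx = which(keep), region = region)
    gr
  }
  prom <- mk(ifelse(minus, e + 1, s - flank), ifelse(minus, e + flank, s - 1),
             "promoter_flank")
  body <- mk(s, e, "body")
  down <- mk(ifelse(minus, s - flank, e + 1), ifelse(minus, s - 1, e + flank),
             "downstream_flank")
  c(prom, body, down)
}

#' Annotate differentially methylated genes
#'
#' A gene is a DMG when its body or +/- `flank` bp neighbourhood
#' intersects at least one DMR by any base-pair overlap. The regions hit
#' are reported strand-aware: `promoter_flank` is the `flank` bp 5' of the
#' TSS (downstream in genome coordinates for minus-strand genes), `body`
#' the gene interval, `downstream_flank` the `flank` bp 3' of the TES.
#'
#' @param genes `GRanges` of gene models with `id` and strand.
#' @param dmrs A [DmrSet][fruitMethyl-classes] (filter to a context or
#'   direction first if desired).
#' @param flank Flank width (bp).
#' @return A data.frame with one row per gene: `gene_id`, `isDmg`,
#'   `nDmrs` (distinct DMRs hitting the gene neighbourhood), per-region
#'   counts and a comma-separated `regionsHit`.
#' @export
annotateDmgs <- function(genes, dmrs, flank = 2000) {
  ids <- S4Vectors::mcols(genes)$id
  n <- length(genes)
  regions <- geneRegions(genes, flank)
  counts <- matrix(0L, nrow = n, ncol = 3,
                   dimnames = list(NULL, c("promoter_flank", "body",
                                           "downstream_flank")))
  nDistinct <- integer(n)
  if (length(dmrs) > 0 && length(regions) > 0) {
    hits <- GenomicRanges::findOverlaps(regions, dmrs, ignore.strand = TRUE)
    if (length(hits) > 0) {
      gi <- S4Vectors::mcols(regions)$geneIdx[S4Vectors::queryHits(hits)]
      rg <- S4Vectors::mcols(regions)$region[S4Vectors::queryHits(hits)]
      dj <- S4Vectors::subjectHits(hits)
      tab <- table(factor(gi, levels = seq_len(n)),
                   factor(rg, levels = colnames(counts)))
      counts <- matrix(as.integer(tab), nrow = n,
                       dimnames = dimnames(counts))
      nDistinct <- vapply(seq_len(n), function(i) {
        length(unique(dj[gi == i]))
      }, integer(1))
    }
  }
  regionsHit <- apply(counts, 1, function(r) {
    paste(colnames(counts)[r > 0], collapse = ",")
  })
  data.frame(gene_id = ids, isDmg = nDistinct > 0, nDmrs = nDistinct,
             nPromoter = counts[, "promoter_flank"],
             nBody = counts[, "body"],
             nDownstream = counts[, "downstream_flank"],
             regionsHit = regionsHit,
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of DEGs among DMGs
#'
#' One-sided upper-tail hypergeometric test of the DEG/DMG overlap:
#' drawing `nDeg` genes from a universe of `nUniverse` containing `nDmg`
#' DMGs, `p = P(X >= nOverlap)`. Also reports the overlap percentage
#' `100 * nOverlap / nDeg` rounded to one decimal.
#'
#' @param nUniverse Number of genes in the universe (all annotated genes).
#' @param nDmg Number of DMGs in the universe.
#' @param nDeg Number of DEGs.
#' @param nOverlap Number of genes both DEG and DMG.
#' @return A list with `pValue`, `overlapPct`, `expectedOverlap` and the
#'   input counts.
#' @examples
#' degDmgEnrichment(10, 5, 4, 4)$pValue  # 5 / choose(10, 4)
#' @export
degDmgEnrichment <- function(nUniverse, nDmg, nDeg, nOverlap) {
  if (nOverlap > min(nDmg, nDeg) || max(nDmg, nDeg) > nUniverse ||
      min(nUniverse, nDmg, nDeg, nOverlap) < 0)
    stop("inconsistent counts: need nOverlap <= min(nDmg, nDeg) <= nUniverse")
  if (nDeg == 0) stop("nDeg must be positive")
  p <- stats::phyper(nOverlap - 1, nDmg, nUniverse - nDmg, nDeg,
                     lower.tail = FALSE)
  list(pValue = p,
       overlapPct = roundHalfUp(100 * nOverlap / nDeg, 1),
       expectedOverlap = nDeg * nDmg / nUniverse,
       nUniverse = nUniverse, nDmg = nDmg, nDeg = nDeg, nOverlap = nOverlap)
}

#' Percentage of DEGs shared between two comparisons
#'
#' `100 * nShared / nTotal`, rounded half-up to two decimals, as such
#' fractions are conventionally printed.
#'
#' @param nShared Number of shared DEGs.
#' @param nTotal Total DEGs in the comparison of interest.
#' @return A percentage.
#' @examples
#' sharedDegFraction(1181, 1828)  # 64.61
#' @export
sharedDegFraction <- function(nShared, nTotal) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nShared < 0 || nShared > nTotal)
    stop("need 0 <= nShared <= nTotal")
  roundHalfUp(100 * nShared / nTotal, 2)
}

#' Per-gene promoter/body DMR report for candidate genes
#'
#' Browsable summary for a list of candidate genes: for each requested
#' gene, the number of DMRs per context and region (promoter flank, body,
#' downstream flank), the mean delta of those DMRs and the majority
#' direction. Genes without any DMR get a single zero row; unknown ids
#' are collected in `attr(result, "missing")` with a message rather than
#' failing.
#'
#' @param geneIds Character vector of gene ids to report.
#' @param genes `GRanges` of gene models with `id`.
#' @param dmrs A [DmrSet][fruitMethyl-classes].
#' @param flank Flank width (bp).
#' @return A data.frame with columns `gene_id`, `context`, `region`,
#'   `nDmrs`, `meanDelta`, `direction`.
#' @export
promoterDmrReport <- function(geneIds, genes, dmrs, flank = 2000) {
  ids <- S4Vectors::mcols(genes)$id
  missing <- setdiff(geneIds, ids)
  if (length(missing) > 0)
    message("unknown gene id(s) skipped: ", paste(missing, collapse = ", "))
  geneIds <- intersect(geneIds, ids)
  empty <- data.frame(gene_id = character(), context = character(),
                      region = character(), nDmrs = integer(),
                      meanDelta = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (length(geneIds) == 0)
    return(structure(empty, missing = missing))
  sub <- genes[match(geneIds, ids)]
  regions <- geneRegions(sub, flank)
  rows <- list()
  hits <- if (length(dmrs) > 0 && length(regions) > 0) {
    GenomicRanges::findOverlaps(regions, dmrs, ignore.strand = TRUE)
  } else S4Vectors::Hits()
  for (i in seq_along(geneIds)) {
    sel <- S4Vectors::mcols(regions)$geneIdx[S4Vectors::queryHits(hits)] == i
    if (!any(sel)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = geneIds[i], context = NA_character_, region = NA_character_,
        nDmrs = 0L, meanDelta = NA_real_, direction = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    rg <- S4Vectors::mcols(regions)$region[S4Vectors::queryHits(hits)][sel]
    di <- S4Vectors::subjectHits(hits)[sel]
    cx <- context(dmrs)[di]
    dl <- S4Vectors::mcols(dmrs)$delta[di]
    dr <- as.character(S4Vectors::mcols(dmrs)$direction)[di]
    for (key in unique(paste(cx, rg))) {
      k <- paste(cx, rg) == key
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = geneIds[i], context = cx[k][1], region = rg[k][1],
        nDmrs = sum(k), meanDelta = mean(dl[k]),
        direction = names(sort(table(dr[k]), decreasing = TRUE))[1],
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), missing = missing)
}
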