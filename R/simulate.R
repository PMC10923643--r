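#' Specify a synthetic bisulfite experiment
#'
#' Builds the parameter object for the synthetic-data generator. The
#' defaults emulate the study conditions the analysis is designed for:
#' three fruit developmental stages (young YF, expanding EF, mature MF)
#' with genome-wide weighted CHH methylation 0.066 / 0.153 / 0.145 and
#' gradually declining CG and CHG levels, ~40x read coverage, ~1%
#' bisulfite non-conversion, and an unmethylated spike-in control sequence
#' carried in the same FASTA under the reserved name `lambda_control`.
#'
#' `contextLevelMeans` is the target *observed* genome-wide weighted level
#' per stage and context (the quantity a methylome report prints); the
#' generator back-solves the latent per-site methylation mean so that
#' emitted counts, which include non-conversion, average to it. Per-site
#' levels are drawn from a Beta distribution with that mean and
#' concentration `betaConcentration`, reproducing the overdispersion of
#' real methylomes with two parameters.
#'
#' A fraction `diffWindowFraction` of the fixed `windowSize`-bp windows is
#' selected once per context and receives `diffEffect` additively in every
#' stage after the first, so the two later-versus-first comparisons share
#' one differential plan (the behaviour real shared-DMR analyses show).
#'
#' @param genomeLength Total bp across chromosomes (control excluded).
#' @param nChromosomes Number of chromosomes.
#' @param gcFraction GC content of the simulated reference.
#' @param nGenes,nTes Number of gene / transposon annotations.
#' @param geneLengthRange,teLengthRange Feature length ranges (bp).
#' @param stageNames Ordered developmental stage labels.
#' @param contextLevelMeans Matrix (stages x CG/CHG/CHH) of target observed
#'   weighted levels.
#' @param diffWindowFraction Fraction of windows per context given a true
#'   shift in the later stages.
#' @param diffEffect Named per-context additive level shift of a true
#'   differential window.
#' @param windowSize Window size (bp) used for shift placement.
#' @param betaConcentration Beta concentration of per-site levels.
#' @param coverageMean Mean per-cytosine read coverage (Poisson, floor 1).
#' @param nonConversionRate Bisulfite non-conversion error rate.
#' @param controlLength Length of the unmethylated spike-in sequence.
#' @param couplingProb Probability that a true DMG receives a true
#'   expression shift.
#' @param backgroundDegRate Probability that a non-DMG gene receives a true
#'   expression shift (expression changes unrelated to methylation).
#' @param effectLfc,effectAdjP log2 fold change magnitude and adjusted p
#'   assigned to truly shifted genes.
#' @param nullLfcSd Standard deviation of null log2 fold changes.
#' @param seed Integer seed; identical spec + seed reproduces every output.
#' @return A [SimulationSpec][fruitMethyl-classes].
#' @examples
#' simulationSpec(genomeLength = 50000, nGenes = 10, nTes = 5)
#' @export
simulationSpec <- function(genomeLength = 300000,
                           nChromosomes = 2L,
                           gcFraction = 0.36,
                           nGenes = 80L,
                           nTes = 40L,
                           geneLengthRange = c(800, 2000),
                           teLengthRange = c(200, 1000),
                           stageNames = c("YF", "EF", "MF"),
                           contextLevelMeans = NULL,
                           diffWindowFraction = 0.10,
                           diffEffect = c(CG = -0.45, CHG = -0.25, CHH = 0.15),
                           windowSize = 200L,
                           betaConcentration = 20,
                           coverageMean = 40,
                           nonConversionRate = 0.01,
                           controlLength = 20000,
                           couplingProb = 0.9,
                           backgroundDegRate = 0.05,
                           effectLfc = 4,
                           effectAdjP = 1e-6,
                           nullLfcSd = 1,
                           seed = 1L) {
  if (is.null(contextLevelMeans)) {
    contextLevelMeans <- defaultLevelMeans(stageNames)
  }
  new("SimulationSpec",
      genomeLength = genomeLength, nChromosomes = as.integer(nChromosomes),
      gcFraction = gcFraction, nGenes = as.integer(nGenes),
      nTes = as.integer(nTes), geneLengthRange = geneLengthRange,
      teLengthRange = teLengthRange, stageNames = stageNames,
      contextLevelMeans = contextLevelMeans,
      diffWindowFraction = diffWindowFraction, diffEffect = diffEffect,
      windowSize = as.integer(windowSize),
      betaConcentration = betaConcentration, coverageMean = coverageMean,
      nonConversionRate = nonConversionRate, controlLength = controlLength,
      couplingProb = couplingProb, backgroundDegRate = backgroundDegRate,
      effectLfc = effectLfc, effectAdjP = effectAdjP, nullLfcSd = nullLfcSd,
      seed = as.integer(seed))
}

## Stage-wise observed level targets. CHH values are the study's printed
## genome-wide levels; CG/CHG follow the reported gradual decline at
## magnitudes typical of citrus methylomes.
defaultLevelMeans <- function(stageNames) {
  base <- matrix(
    c(0.65, 0.60, 0.58,
      0.45, 0.40, 0.38,
      0.066, 0.153, 0.145),
    ncol = 3, dimnames = list(c("YF", "EF", "MF"), NULL))
  colnames(base) <- METH_CONTEXTS
  if (identical(stageNames, c("YF", "EF", "MF"))) return(base)
  ## other stage vectors: interpolate the three-stage trajectory
  k <- length(stageNames)
  idx <- if (k == 1) 1 else seq(1, 3, length.out = k)
  out <- apply(base, 2, function(col) stats::approx(1:3, col, xout = idx)$y)
  out <- matrix(out, nrow = k, dimnames = list(stageNames, METH_CONTEXTS))
  out
}

#' Generate a synthetic reference genome with annotations
#'
#' Draws i.i.d. bases at the requested GC content for each chromosome plus
#' one fully unmethylated spike-in control sequence named
#' `lambda_control`, then places non-overlapping stranded gene models
#' (genes are packed into equal slots per chromosome and positioned
#' uniformly within their slot) and uniformly placed transposon intervals,
#' which may overlap genes as they do in real genomes.
#'
#' @param spec A [simulationSpec()].
#' @return A list with `genome` ([Biostrings::DNAStringSet] including the
#'   control), `genes` and `tes` (`GRanges` with `id`, `featureClass`),
#'   and `seqlengths` (named, control excluded).
#' @examples
#' sim <- generateGenome(simulationSpec(genomeLength = 40000, nGenes = 8,
#'                                      nTes = 4, controlLength = 5000))
#' sim$genes
#' @export
generateGenome <- function(spec) {
  validObject(spec)
  withSeed(substreamSeed(spec@seed, 0L), {
    chromLens <- rep(floor(spec@genomeLength / spec@nChromosomes),
                     spec@nChromosomes)
    chromLens[1] <- chromLens[1] + spec@genomeLength -
      sum(chromLens)
    names(chromLens) <- paste0("chr", seq_len(spec@nChromosomes))
    gc <- spec@gcFraction
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(chromLens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    ## spike-in control at lambda-like 50% GC
    ctrl <- paste(sample(c("A", "C", "G", "T"), spec@controlLength,
                         replace = TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(c(seqs, stats::setNames(ctrl, CONTROL_CHROM)))

    genes <- placeGenes(spec, chromLens)
    tes <- placeTes(spec, chromLens)
    list(genome = genome, genes = genes, tes = tes, seqlengths = chromLens)
  })
}

placeGenes <- function(spec, chromLens) {
  if (spec@nGenes == 0) {
    return(GenomicRanges::GRanges(seqlengths = chromLens,
                                  id = character(), featureClass = character()))
  }
  ## allocate genes to chromosomes proportional to length
  alloc <- floor(spec@nGenes * chromLens / sum(chromLens))
  while (sum(alloc) < spec@nGenes) {
    i <- which.max(chromLens / (alloc + 1))
    alloc[i] <- alloc[i] + 1
  }
  minLen <- min(spec@geneLengthRange)
  maxLen <- max(spec@geneLengthRange)
  parts <- lapply(seq_along(chromLens), function(i) {
    k <- alloc[i]
    if (k == 0) return(NULL)
    slot <- floor(chromLens[i] / k)
    if (slot < minLen + 2) {
      stop("cannot pack ", k, " genes of >= ", minLen, " bp into ",
           chromLens[i], " bp of ", names(chromLens)[i],
           ": increase genomeLength or reduce nGenes")
    }
    lens <- round(stats::runif(k, minLen, min(maxLen, slot - 2)))
    starts <- (seq_len(k) - 1) * slot +
      floor(stats::runif(k, 1, pmax(2, slot - lens)))
    data.frame(chrom = names(chromLens)[i], start = starts,
               end = starts + lens - 1,
               strand = sample(c("+", "-"), k, replace = TRUE))
  })
  df <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand, seqlengths = chromLens)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = sprintf("gene_%04d", seq_along(gr)), featureClass = "gene")
  gr
}

placeTes <- function(spec, chromLens) {
  if (spec@nTes == 0) {
    return(GenomicRanges::GRanges(seqlengths = chromLens,
                                  id = character(), featureClass = character()))
  }
  chrom <- sample(names(chromLens), spec@nTes, replace = TRUE,
                  prob = chromLens / sum(chromLens))
  lens <- round(stats::runif(spec@nTes, min(spec@teLengthRange),
                             max(spec@teLengthRange)))
  lens <- pmin(lens, chromLens[chrom] - 1)
  starts <- floor(stats::runif(spec@nTes, 1, chromLens[chrom] - lens + 1))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, starts + lens - 1),
                               strand = "+", seqlengths = chromLens)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = sprintf("te_%04d", seq_along(gr)), featureClass = "TE")
  gr
}

#' Simulate per-stage bisulfite count tables with ground truth
#'
#' For every cytosine of the genome (and the spike-in control) and every
#' stage, draws a true per-site methylation level around the stage and
#' context mean, coverage `~ max(1, Poisson(coverageMean))`, and a
#' methylated count `~ Binomial(coverage, level + (1 - level) * r)` where
#' `r` is the non-conversion rate. Control cytosines have true level 0, so
#' their pooled methylated fraction estimates `r`. Windows selected by the
#' differential plan receive the per-context shift in every stage after
#' the first; the returned ground truth lists those windows and the genes
#' whose +/- `flank` neighbourhood contains one.
#'
#' @param spec A [simulationSpec()].
#' @param sim Output of [generateGenome()] (or a compatible list with
#'   `genome` and `genes`).
#' @param flank Flank (bp) used to derive true DMG ids from true windows.
#' @return A list with `stages` (named list of [CytosineReport], one per
#'   stage), `truth` (a [GroundTruth][fruitMethyl-classes]) and
#'   `contexts` (the cytosine skeleton, for reuse).
#' @export
simulateMethylomes <- function(spec, sim, flank = 2000) {
  validObject(spec)
  ctx <- extractContexts(sim$genome)
  isControl <- as.character(GenomicRanges::seqnames(ctx)) == CONTROL_CHROM
  chromLens <- sim$seqlengths %||%
    stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  chromLens <- chromLens[names(chromLens) != CONTROL_CHROM]

  withSeed(substreamSeed(spec@seed, 1L), {
    truthWin <- sampleDiffWindows(spec, chromLens)
    inDiff <- rep(FALSE, length(ctx))
    dir <- trueShiftAssignment(ctx, truthWin, spec@windowSize)
    inDiff <- dir != 0

    r <- spec@nonConversionRate
    kappa <- spec@betaConcentration
    ctxChar <- context(ctx)
    stages <- vector("list", length(spec@stageNames))
    names(stages) <- spec@stageNames
    for (j in seq_along(spec@stageNames)) {
      mObs <- spec@contextLevelMeans[spec@stageNames[j], ctxChar]
      if (j > 1) {
        eff <- spec@diffEffect[ctxChar]
        mObs <- ifelse(inDiff, clamp(mObs + eff, 0.001, 0.999), mObs)
      }
      mLatent <- clamp((mObs - r) / (1 - r), 1e-6, 1 - 1e-6)
      t <- stats::rbeta(length(ctx), mLatent * kappa, (1 - mLatent) * kappa)
      t[isControl] <- 0
      n <- pmax(1L, stats::rpois(length(ctx), spec@coverageMean))
      cc <- stats::rbinom(length(ctx), n, t + (1 - t) * r)
      rep_ <- ctx
      S4Vectors::mcols(rep_)$cCount <- cc
      S4Vectors::mcols(rep_)$totalCount <- n
      stages[[j]] <- new("CytosineReport", rep_)
    }

    dmgIds <- character()
    if (length(sim$genes) > 0 && length(truthWin) > 0) {
      ext <- GenomicRanges::trim(suppressWarnings(
        GenomicRanges::resize(sim$genes, BiocGenerics::width(sim$genes) + 2 * flank,
                              fix = "center")))
      hit <- GenomicRanges::countOverlaps(ext, truthWin, ignore.strand = TRUE) > 0
      dmgIds <- S4Vectors::mcols(sim$genes)$id[hit]
    }
    truth <- new("GroundTruth", trueDiffWindows = truthWin,
                 trueDmgIds = dmgIds, trueDegIds = character())
    list(stages = stages, truth = truth, contexts = ctx)
  })
}

## Pick diffWindowFraction of tiled windows per context, once, shared by
## all later stages.
sampleDiffWindows <- function(spec, chromLens) {
  tiles <- tileWindows(chromLens, spec@windowSize)
  out <- GenomicRanges::GRanges(seqlengths = chromLens)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(context = character(),
                                                direction = character())
  if (spec@diffWindowFraction <= 0 || length(tiles) == 0) return(out)
  parts <- lapply(METH_CONTEXTS, function(cx) {
    k <- floor(spec@diffWindowFraction * length(tiles))
    if (k == 0) return(NULL)
    sel <- BiocGenerics::sort(tiles[sample(length(tiles), k)])
    S4Vectors::mcols(sel) <- S4Vectors::DataFrame(
      context = cx,
      direction = if (spec@diffEffect[[cx]] >= 0) "hyper" else "hypo")
    sel
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0) return(out)
  do.call(c, parts)
}

## +1/-1/0 per cytosine: membership of its (chrom, window, context) in the
## true differential plan.
trueShiftAssignment <- function(ctx, truthWin, windowSize) {
  out <- integer(length(ctx))
  if (length(truthWin) == 0 || length(ctx) == 0) return(out)
  key <- paste(as.character(GenomicRanges::seqnames(ctx)),
               (BiocGenerics::start(ctx) - 1L) %/% windowSize,
               context(ctx))
  tkey <- paste(as.character(GenomicRanges::seqnames(truthWin)),
                (BiocGenerics::start(truthWin) - 1L) %/% windowSize,
                S4Vectors::mcols(truthWin)$context)
  tdir <- ifelse(S4Vectors::mcols(truthWin)$direction == "hyper", 1L, -1L)
  m <- match(key, tkey)
  out[!is.na(m)] <- tdir[m[!is.na(m)]]
  out
}

#' Simulate per-gene expression statistics coupled to the methylation truth
#'
#' Emits one differential-expression statistics table (gene id, log2 fold
#' change, adjusted p) per later-stage-versus-first comparison. True DMGs
#' receive a large effect (`|log2FC| = effectLfc`, `adj_p = effectAdjP`)
#' with probability `couplingProb`; a fraction `backgroundDegRate` of the
#' remaining genes receives the same effect independently of methylation;
#' all other genes draw null statistics (`log2FC ~ N(0, nullLfcSd)`,
#' `adj_p ~ U(0,1)`). The shifted gene set is shared across comparisons
#' and recorded as `trueDegIds`.
#'
#' @param spec A [simulationSpec()].
#' @param genes `GRanges` of gene models with `id`.
#' @param truth [GroundTruth][fruitMethyl-classes] from
#'   [simulateMethylomes()].
#' @return A list with `stats` (named list of data.frames, one per
#'   comparison such as `EF-YF`) and `truth` (updated with `trueDegIds`).
#' @export
simulateExpression <- function(spec, genes, truth) {
  ids <- S4Vectors::mcols(genes)$id
  comparisons <- if (length(spec@stageNames) > 1) {
    paste0(spec@stageNames[-1], "-", spec@stageNames[1])
  } else character()
  withSeed(substreamSeed(spec@seed, 2L), {
    isDmg <- ids %in% trueDmgIds(truth)
    shifted <- logical(length(ids))
    shifted[isDmg] <- stats::runif(sum(isDmg)) < spec@couplingProb
    shifted[!isDmg] <- stats::runif(sum(!isDmg)) < spec@backgroundDegRate
    stats <- lapply(comparisons, function(cmp) {
      lfc <- stats::rnorm(length(ids), 0, spec@nullLfcSd)
      adj <- stats::runif(length(ids))
      sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
      lfc[shifted] <- sgn[shifted] *
        (spec@effectLfc + abs(stats::rnorm(sum(shifted), 0, 0.25)))
      adj[shifted] <- spec@effectAdjP
      data.frame(gene_id = ids, log2_fc = lfc, adj_p = adj,
                 stringsAsFactors = FALSE)
    })
    names(stats) <- comparisons
    truth@trueDegIds <- ids[shifted]
    list(stats = stats, truth = truth)
  })
}

#' Write a full simulation to disk
#'
#' Writes the reference FASTA (control included), gene GFF3, TE BED,
#' per-stage methratio-style TSVs, per-comparison expression TSVs, and a
#' ground-truth TSV of true differential windows. With a fixed spec and
#' seed the byte content is reproducible.
#'
#' @param spec A [simulationSpec()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly; the
#'   full simulation objects as attribute `"objects"`.
#' @export
#' @importFrom rtracklayer export
#' @importFrom Biostrings writeXStringSet
writeSimulation <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generateGenome(spec)
  meth <- simulateMethylomes(spec, sim)
  expr <- simulateExpression(spec, sim$genes, meth$truth)

  files <- c(genome = file.path(outdir, "genome.fa"),
             genes = file.path(outdir, "genes.gff3"),
             tes = file.path(outdir, "tes.bed"),
             truth = file.path(outdir, "truth_windows.tsv"))
  Biostrings::writeXStringSet(sim$genome, files["genome"])
  exportGenesGff3(sim$genes, files["genes"])
  rtracklayer::export(sim$tes, files["tes"], format = "bed")
  tw <- trueDiffWindows(expr$truth)
  data.table::fwrite(data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(tw)),
    start = BiocGenerics::start(tw), end = BiocGenerics::end(tw),
    context = S4Vectors::mcols(tw)$context,
    direction = S4Vectors::mcols(tw)$direction), files["truth"], sep = "\t")
  for (s in names(meth$stages)) {
    f <- file.path(outdir, paste0("methylome_", s, ".tsv"))
    writeMethylome(meth$stages[[s]], f)
    files[paste0("methylome_", s)] <- f
  }
  for (cmp in names(expr$stats)) {
    f <- file.path(outdir, paste0("expression_", cmp, ".tsv"))
    data.table::fwrite(expr$stats[[cmp]], f, sep = "\t")
    files[paste0("expression_", cmp)] <- f
  }
  structure(invisible(files),
            objects = list(sim = sim, stages = meth$stages,
                           truth = expr$truth, expression = expr$stats))
}

## rtracklayer's GFF3 export needs type/ID columns; keep it in one place.
exportGenesGff3 <- function(genes, path) {
  if (length(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  g <- genes
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    source = "fruitMethyl", type = "gene",
    ID = S4Vectors::mcols(genes)$id, Name = S4Vectors::mcols(genes)$id)
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}
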