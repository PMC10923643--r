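#' Default pipeline configuration
#'
#' A plain, fully YAML-serializable list describing one end-to-end run:
#' the simulation spec, DMR parameters, flank sizes, alphas and the seed.
#' [readPipelineConfig()] / [writePipelineConfig()] round-trip it through
#' a YAML file losslessly.
#'
#' @param seed Top-level seed; every stage draws from a substream of it.
#' @param ... Overrides for any [simulationSpec()] argument.
#' @return A named list.
#' @export
defaultPipelineConfig <- function(seed = 1L, ...) {
  spec <- simulationSpec(seed = seed, ...)
  list(
    seed = as.integer(seed),
    spec = specToList(spec),
    dmr = list(windowSize = 200L,
               deltaThresholds = list(CG = 0.4, CHG = 0.2, CHH = 0.1),
               pAlpha = 0.05, qAlpha = 0.05,
               minCoverage = 10, minSites = 3),
    flank = 2000,
    mcAlpha = 0.05,
    degLfcThreshold = 2,
    degAlpha = 0.05,
    densityPermutations = 200L
  )
}

specToList <- function(spec) {
  clm <- spec@contextLevelMeans
  list(
    genomeLength = spec@genomeLength, nChromosomes = spec@nChromosomes,
    gcFraction = spec@gcFraction, nGenes = spec@nGenes, nTes = spec@nTes,
    geneLengthRange = spec@geneLengthRange,
    teLengthRange = spec@teLengthRange,
    stageNames = spec@stageNames,
    contextLevelMeans = stats::setNames(
      lapply(seq_len(nrow(clm)), function(i) as.list(clm[i, ])),
      rownames(clm)),
    diffWindowFraction = spec@diffWindowFraction,
    diffEffect = as.list(spec@diffEffect),
    windowSize = spec@windowSize,
    betaConcentration = spec@betaConcentration,
    coverageMean = spec@coverageMean,
    nonConversionRate = spec@nonConversionRate,
    controlLength = spec@controlLength,
    couplingProb = spec@couplingProb,
    backgroundDegRate = spec@backgroundDegRate,
    effectLfc = spec@effectLfc, effectAdjP = spec@effectAdjP,
    nullLfcSd = spec@nullLfcSd, seed = spec@seed
  )
}

specFromList <- function(lst) {
  clm <- do.call(rbind, lapply(lst$contextLevelMeans, function(r)
    unlist(r)[METH_CONTEXTS]))
  rownames(clm) <- names(lst$contextLevelMeans)
  simulationSpec(
    genomeLength = lst$genomeLength, nChromosomes = lst$nChromosomes,
    gcFraction = lst$gcFraction, nGenes = lst$nGenes, nTes = lst$nTes,
    geneLengthRange = unlist(lst$geneLengthRange),
    teLengthRange = unlist(lst$teLengthRange),
    stageNames = unlist(lst$stageNames),
    contextLevelMeans = clm,
    diffWindowFraction = lst$diffWindowFraction,
    diffEffect = unlist(lst$diffEffect)[METH_CONTEXTS],
    windowSize = lst$windowSize,
    betaConcentration = lst$betaConcentration,
    coverageMean = lst$coverageMean,
    nonConversionRate = lst$nonConversionRate,
    controlLength = lst$controlLength,
    couplingProb = lst$couplingProb,
    backgroundDegRate = lst$backgroundDegRate,
    effectLfc = lst$effectLfc, effectAdjP = lst$effectAdjP,
    nullLfcSd = lst$nullLfcSd, seed = lst$seed
  )
}

#' @rdname defaultPipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname defaultPipelineConfig
#' @param config A pipeline configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

dmrParamsFromConfig <- function(cfg) {
  dmrParams(windowSize = cfg$dmr$windowSize,
            deltaThresholds = unlist(cfg$dmr$deltaThresholds)[METH_CONTEXTS],
            pAlpha = cfg$dmr$pAlpha, qAlpha = cfg$dmr$qAlpha,
            minCoverage = cfg$dmr$minCoverage, minSites = cfg$dmr$minSites)
}

#' Run the full demonstration pipeline on simulated data
#'
#' Simulates a bisulfite experiment, then runs the whole analysis:
#' conversion-rate estimation from the spike-in, per-stage per-context
#' weighted levels and methylcytosine proportions, DMR calling for every
#' later-stage-versus-first comparison, shared-DMR concordance, genome DMR
#' coverage, gene and TE metagene profiles, CHH-hyper DMR density around
#' genes versus random placements, DEG classification, DMG annotation and
#' DEG-DMG hypergeometric enrichment, and a ground-truth scorecard
#' (per-context recall and false-discovery proportion of the first
#' comparison's DMR calls, and shared-DMR direction concordance). All
#' tables are written under `outdir` together with `report.json`; rerunning
#' with the same config is byte-reproducible.
#'
#' @param config A configuration list from [defaultPipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outdir Output directory.
#' @return The report, invisibly (also written as `report.json`).
#' @export
runDemo <- function(config = defaultPipelineConfig(), outdir = tempfile("demo")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  spec <- specFromList(config$spec)
  params <- dmrParamsFromConfig(config)
  flank <- config$flank

  files <- stage("simulate", writeSimulation(spec, file.path(outdir, "sim")))
  obj <- attr(files, "objects")
  sim <- obj$sim; stages <- obj$stages; truth <- obj$truth
  exprStats <- obj$expression
  stageNames <- spec@stageNames

  report <- list(parameters = config)

  report$conversion <- stage("conversion", {
    lapply(stages, function(s) conversionRate(estimateConversion(s)))
  })

  report$levels <- stage("levels", {
    genomeOnly <- lapply(stages, function(s)
      s[as.character(GenomicRanges::seqnames(s)) != CONTROL_CHROM])
    out <- lapply(genomeOnly, function(s) {
      vapply(METH_CONTEXTS, function(cx) weightedLevel(s, context = cx),
             numeric(1))
    })
    df <- do.call(rbind, lapply(names(out), function(nm)
      data.frame(stage = nm, t(out[[nm]]))))
    data.table::fwrite(df, file.path(outdir, "levels.tsv"), sep = "\t")
    out
  })

  report$mcProportions <- stage("callmc", {
    lapply(stageNames, function(nm) {
      conv <- estimateConversion(stages[[nm]])
      calls <- suppressMessages(callMethylcytosines(
        stages[[nm]][as.character(GenomicRanges::seqnames(stages[[nm]])) !=
                       CONTROL_CHROM],
        conv, alpha = config$mcAlpha))
      vapply(METH_CONTEXTS, function(cx) mcProportion(calls, cx), numeric(1))
    }) |> stats::setNames(stageNames)
  })

  comparisons <- paste0(stageNames[-1], "-", stageNames[1])
  dmrSets <- stage("dmr", {
    out <- list()
    for (j in seq_along(comparisons)) {
      wins <- binWindows(stages[[1]], stages[[j + 1]], params,
                         seqlengths = sim$seqlengths)
      dmrs <- callDmrs(wins, params)
      writeDmrBed(dmrs, file.path(outdir, paste0("dmrs_", comparisons[j], ".bed")))
      out[[comparisons[j]]] <- dmrs
    }
    out
  })
  report$dmrCounts <- lapply(dmrSets, function(d) {
    vapply(METH_CONTEXTS, function(cx) sum(context(d) == cx), numeric(1))
  })

  if (length(dmrSets) >= 2) {
    report$sharedDmrs <- stage("shared", {
      df <- sharedDmrs(dmrSets[[1]], dmrSets[[2]])
      data.table::fwrite(df, file.path(outdir, "shared_dmrs.tsv"), sep = "\t")
      df
    })
  }
  report$genomeDmrCoverage <- lapply(dmrSets, genomeDmrCoverage,
                                     seqlengths = sim$seqlengths)

  report$metaprofiles <- stage("metaplot", {
    out <- list()
    for (cx in METH_CONTEXTS) {
      for (what in c("genes", "tes")) {
        feats <- sim[[what]]
        if (length(feats) == 0) next
        prof <- computeMetaprofile(feats, stages[[length(stageNames)]], cx,
                                   flank = flank)
        key <- paste0(what, "_", cx)
        data.table::fwrite(as.data.frame(prof),
                           file.path(outdir, paste0("metaprofile_", key, ".tsv")),
                           sep = "\t")
        out[[key]] <- binLevels(prof)
      }
    }
    out
  })

  report$dmrDensity <- stage("dmrdensity", {
    chh <- dmrSets[[1]]
    chh <- chh[context(chh) == "CHH" &
                 as.character(S4Vectors::mcols(chh)$direction) == "hyper"]
    if (length(sim$genes) == 0) return(NULL)
    dd <- dmrDensityVsRandom(chh, sim$genes, sim$seqlengths, flank = flank,
                             nPermutations = config$densityPermutations,
                             seed = substreamSeed(config$seed, 5L))
    data.table::fwrite(dd@bins, file.path(outdir, "dmr_density.tsv"),
                       sep = "\t")
    list(observedTotal = dd@observedTotal,
         backgroundMean = mean(dd@backgroundTotals),
         empiricalP = empiricalP(dd))
  })

  report$association <- stage("associate", {
    out <- list()
    degSets <- list()
    for (cmp in comparisons) {
      degs <- classifyDegs(exprStats[[cmp]],
                           lfcThreshold = config$degLfcThreshold,
                           alpha = config$degAlpha)
      degSets[[cmp]] <- degs$gene_id[degs$direction != "ns"]
      chh <- dmrSets[[cmp]][context(dmrSets[[cmp]]) == "CHH"]
      dmg <- annotateDmgs(sim$genes, chh, flank = flank)
      data.table::fwrite(dmg, file.path(outdir, paste0("dmgs_", cmp, ".tsv")),
                         sep = "\t")
      nU <- length(sim$genes); nDmg <- sum(dmg$isDmg)
      nDeg <- length(degSets[[cmp]])
      nOv <- sum(degSets[[cmp]] %in% dmg$gene_id[dmg$isDmg])
      out[[cmp]] <- if (nDeg > 0 && nDmg > 0) {
        degDmgEnrichment(nU, nDmg, nDeg, nOv)
      } else list(pValue = NA_real_, overlapPct = NA_real_, nDeg = nDeg,
                  nDmg = nDmg, nOverlap = nOv, nUniverse = nU)
    }
    if (length(degSets) >= 2) {
      shared <- length(intersect(degSets[[1]], degSets[[2]]))
      out$sharedDegPct <- lapply(seq_along(degSets), function(i) {
        if (length(degSets[[i]]) == 0) return(NA_real_)
        sharedDegFraction(shared, length(degSets[[i]]))
      }) |> stats::setNames(names(degSets))
    }
    out
  })

  report$scorecard <- stage("scorecard", {
    sc <- dmrScorecard(dmrSets[[1]], truth)
    if (length(dmrSets) >= 2 && !is.null(report$sharedDmrs)) {
      sc$sharedDirectionConcordance <- stats::weighted.mean(
        report$sharedDmrs$concordance, report$sharedDmrs$nShared, na.rm = TRUE)
    }
    sc
  })

  json <- file.path(outdir, "report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}

#' Score DMR calls against simulation ground truth
#'
#' Per context: recall (fraction of true differential windows recovered as
#' coordinate-identical DMR calls) and false-discovery proportion
#' (fraction of called DMRs that are not true windows).
#'
#' @param dmrs A [DmrSet][fruitMethyl-classes].
#' @param truth A [GroundTruth][fruitMethyl-classes].
#' @return A list with per-context `recall` and `fdp`.
#' @export
dmrScorecard <- function(dmrs, truth) {
  tw <- trueDiffWindows(truth)
  key <- function(gr, cx) paste(as.character(GenomicRanges::seqnames(gr)),
                                (BiocGenerics::start(gr) - 1L), cx)
  out <- list(recall = list(), fdp = list())
  for (cx in METH_CONTEXTS) {
    tk <- key(tw[S4Vectors::mcols(tw)$context == cx], cx)
    dk <- key(dmrs[context(dmrs) == cx], cx)
    out$recall[[cx]] <- if (length(tk) > 0) mean(tk %in% dk) else NA_real_
    out$fdp[[cx]] <- if (length(dk) > 0) mean(!(dk %in% tk)) else NA_real_
  }
  out
}
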