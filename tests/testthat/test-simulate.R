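test_that("generated genomes match the requested GC and carry the control", {
  spec <- simulationSpec(genomeLength = 2e5, nChromosomes = 2L,
                         gcFraction = 0.5, nGenes = 20L, nTes = 10L,
                         controlLength = 5000, seed = 1L)
  sim <- generateGenome(spec)
  expect_setequal(names(sim$genome), c("chr1", "chr2", "lambda_control"))
  main <- sim$genome[names(sim$genome) != "lambda_control"]
  gc <- sum(Biostrings::letterFrequency(main, "GC")) / sum(Biostrings::width(main))
  expect_lt(abs(gc - 0.5), 0.02)
  expect_equal(sum(sim$seqlengths), 2e5)
  ## genes are non-overlapping and inside the genome
  ov <- GenomicRanges::findOverlaps(sim$genes, drop.self = TRUE,
                                    ignore.strand = TRUE)
  expect_length(ov, 0)
  expect_true(all(BiocGenerics::end(sim$genes) <=
                    sim$seqlengths[as.character(GenomicRanges::seqnames(sim$genes))]))
})

test_that("zero genes yield a valid empty annotation and infeasible packing errors", {
  spec0 <- simulationSpec(genomeLength = 5e4, nChromosomes = 1L, nGenes = 0L,
                          nTes = 0L, controlLength = 2000, seed = 2L)
  sim0 <- generateGenome(spec0)
  expect_length(sim0$genes, 0)
  gff <- withr::local_tempfile(fileext = ".gff3")
  fruitMethyl:::exportGenesGff3(sim0$genes, gff)
  lines <- readLines(gff)
  expect_true(startsWith(lines[1], "##gff-version"))
  expect_length(grep("\tgene\t", lines), 0)

  ## spec validity refuses genomes below the minimum gene footprint
  expect_error(simulationSpec(genomeLength = 3e4, nChromosomes = 1L,
                              nGenes = 50L, controlLength = 1000),
               "minimum gene footprint")
  ## a genome that passes the footprint bound can still fail slot packing
  expect_error(
    generateGenome(simulationSpec(genomeLength = 29660, nChromosomes = 1L,
                                  nGenes = 37L, controlLength = 1000)),
    "cannot pack")
})

test_that("simulation output is seed-deterministic, byte for byte", {
  spec <- simulationSpec(genomeLength = 3e4, nChromosomes = 1L, nGenes = 6L,
                         nTes = 3L, controlLength = 3000, seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- writeSimulation(spec, d1)
  f2 <- writeSimulation(spec, d2)
  h1 <- unname(tools::md5sum(sort(unname(f1))))
  h2 <- unname(tools::md5sum(sort(unname(f2))))
  expect_equal(h1, h2)

  spec2 <- simulationSpec(genomeLength = 3e4, nChromosomes = 1L, nGenes = 6L,
                          nTes = 3L, controlLength = 3000, seed = 10L)
  d3 <- withr::local_tempdir()
  f3 <- writeSimulation(spec2, d3)
  expect_false(identical(unname(tools::md5sum(unname(f3["genome"]))),
                         unname(tools::md5sum(unname(f1["genome"])))))
})

test_that("emitted counts are sound and the spike-in calibrates non-conversion", {
  spec <- recoverySpec(seed = 5L, genomeLength = 6e4)
  sim <- generateGenome(spec)
  meth <- simulateMethylomes(spec, sim)
  for (s in meth$stages) {
    expect_true(all(cCount(s) >= 0))
    expect_true(all(cCount(s) <= totalCount(s)))
    expect_true(all(totalCount(s) >= 1))
  }
  ## pooled control fraction ~ non-conversion rate within 3 binomial SE
  ctrl <- meth$stages[[1]][as.character(
    GenomicRanges::seqnames(meth$stages[[1]])) == "lambda_control"]
  nReads <- sum(totalCount(ctrl))
  frac <- sum(cCount(ctrl)) / nReads
  se <- sqrt(0.01 * 0.99 / nReads)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("degenerate generator settings produce the expected extremes", {
  ## zero non-conversion and true level ~0 -> all counts 0 on the control
  spec <- simulationSpec(genomeLength = 2000, nChromosomes = 1L, nGenes = 0L,
                         nTes = 0L, controlLength = 20000,
                         stageNames = "S1",
                         contextLevelMeans = matrix(
                           0, 1, 3, dimnames = list("S1", c("CG", "CHG", "CHH"))),
                         diffWindowFraction = 0,
                         nonConversionRate = 0, seed = 3L)
  meth <- simulateMethylomes(spec, generateGenome(spec))
  ctrl <- meth$stages[[1]][as.character(
    GenomicRanges::seqnames(meth$stages[[1]])) == "lambda_control"]
  expect_true(all(cCount(ctrl) == 0))

  ## no differential fraction -> empty ground truth
  spec0 <- nullSpec(seed = 4L, genomeLength = 3e4)
  meth0 <- simulateMethylomes(spec0, generateGenome(spec0))
  expect_length(trueDiffWindows(meth0$truth), 0)
})

test_that("true differential windows lie inside the genome and drive DMG ids", {
  spec <- recoverySpec(seed = 6L, genomeLength = 6e4)
  sim <- generateGenome(spec)
  meth <- simulateMethylomes(spec, sim)
  tw <- trueDiffWindows(meth$truth)
  expect_gt(length(tw), 0)
  expect_true(all(as.character(GenomicRanges::seqnames(tw)) %in%
                    names(sim$seqlengths)))
  expect_true(all(BiocGenerics::end(tw) <=
                    sim$seqlengths[as.character(GenomicRanges::seqnames(tw))]))
  ## every true DMG's +/-2kb neighbourhood really intersects a true window
  ids <- S4Vectors::mcols(sim$genes)$id
  ext <- suppressWarnings(GenomicRanges::resize(
    sim$genes, BiocGenerics::width(sim$genes) + 4000, fix = "center"))
  hit <- GenomicRanges::countOverlaps(ext, tw, ignore.strand = TRUE) > 0
  expect_setequal(trueDmgIds(meth$truth), ids[hit])
})

test_that("expression coupling follows the configured probabilities", {
  spec <- recoverySpec(seed = 7L, genomeLength = 6e4)
  spec@couplingProb <- 1
  spec@backgroundDegRate <- 0
  sim <- generateGenome(spec)
  meth <- simulateMethylomes(spec, sim)
  ex <- simulateExpression(spec, sim$genes, meth$truth)
  degs <- classifyDegs(ex$stats[[1]])
  called <- degs$gene_id[degs$direction != "ns"]
  ## with coupling 1 every true DMG is a DEG under the thresholds
  expect_true(all(trueDmgIds(meth$truth) %in% called))
  expect_setequal(trueDegIds(ex$truth), trueDmgIds(meth$truth))

  ## with coupling 0 and no background shifts, the truth set is empty
  spec@couplingProb <- 0
  ex0 <- simulateExpression(spec, sim$genes, meth$truth)
  expect_length(trueDegIds(ex0$truth), 0)
})
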