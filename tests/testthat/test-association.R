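test_that("DEG classification applies strict thresholds to supplied statistics", {
  df <- data.frame(gene_id = paste0("g", 1:5),
                   log2_fc = c(3, 2.0, -4, -2.5, 0.1),
                   adj_p = c(0.001, 0.001, 0.2, 0.01, 0.001))
  out <- classifyDegs(df)
  expect_equal(as.character(out$direction),
               c("up", "ns", "ns", "down", "ns"))
  ## boundary adj_p exactly 0.05 is ns
  b <- classifyDegs(data.frame(gene_id = "g", log2_fc = 5, adj_p = 0.05))
  expect_equal(as.character(b$direction), "ns")

  expect_error(classifyDegs(df[c(1, 1), ]), "duplicate")
  expect_error(classifyDegs(data.frame(gene_id = "g", log2_fc = Inf,
                                       adj_p = 0.1)), "finite")
  expect_error(classifyDegs(data.frame(gene_id = "g", log2_fc = 0,
                                       adj_p = 1.2)), "\\[0,1\\]")
})

mkGenes <- function(starts, ends, strands, chromLen = 20000) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                               strand = strands,
                               seqlengths = c(chr1 = chromLen))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = paste0("g", seq_along(gr)), featureClass = "gene")
  gr
}

mkDmrs <- function(starts, ends, context = "CHH", direction = "hyper") {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = rep_len(context, length(gr)),
    delta = ifelse(rep_len(direction, length(gr)) == "hyper", 0.25, -0.25),
    pValue = 1e-5, qValue = 1e-4,
    direction = rep_len(direction, length(gr)))
  new("DmrSet", gr)
}

test_that("DMG annotation is strand-aware over promoter, body and downstream", {
  ## plus-strand gene [5001, 8000]: promoter flank is [3001, 5000]
  genes <- mkGenes(5001, 8000, "+")
  dmg <- annotateDmgs(genes, mkDmrs(3501, 3700))
  expect_true(dmg$isDmg)
  expect_equal(dmg$regionsHit, "promoter_flank")
  ## a DMR far upstream of the flank does not count
  expect_false(annotateDmgs(genes, mkDmrs(501, 700))$isDmg)
  ## minus-strand gene: 5' flank is downstream in genome coordinates
  minus <- mkGenes(5001, 8000, "-")
  dmgM <- annotateDmgs(minus, mkDmrs(8101, 8300))
  expect_true(dmgM$isDmg)
  expect_equal(dmgM$regionsHit, "promoter_flank")
  ## body hit
  expect_equal(annotateDmgs(genes, mkDmrs(6001, 6200))$regionsHit, "body")

  ## one DMR spanning promoter and body counts once but hits both regions
  span <- annotateDmgs(genes, mkDmrs(4901, 5100))
  expect_equal(span$nDmrs, 1)
  expect_equal(span$regionsHit, "promoter_flank,body")
})

test_that("DMG status is invariant under a constant coordinate shift", {
  set.seed(14)
  starts <- sort(sample(3000:15000, 6)) ; ends <- starts + 1000
  genes <- mkGenes(starts, ends, sample(c("+", "-"), 6, TRUE),
                   chromLen = 40000)
  dmrs <- mkDmrs(seq(2000, 17000, by = 3100), seq(2000, 17000, by = 3100) + 199)
  base <- annotateDmgs(genes, dmrs)
  shift <- 5000
  genes2 <- GenomicRanges::shift(genes, shift)
  movedGr <- GenomicRanges::shift(GenomicRanges::granges(dmrs), shift)
  S4Vectors::mcols(movedGr) <- S4Vectors::mcols(dmrs)
  dmrs2 <- new("DmrSet", movedGr)
  moved <- annotateDmgs(genes2, dmrs2)
  expect_equal(base$isDmg, moved$isDmg)
  expect_equal(base$regionsHit, moved$regionsHit)
})

test_that("hypergeometric enrichment matches enumeration and reports overlap", {
  res <- degDmgEnrichment(10, 5, 4, 4)
  expect_equal(res$pValue, 5 / choose(10, 4), tolerance = 1e-12)
  ## overlap 0 has the whole upper tail: p = 1
  expect_equal(degDmgEnrichment(10, 5, 4, 0)$pValue, 1)
  ## published overlap percentage arithmetic
  expect_equal(degDmgEnrichment(20000, 15000, 5799, 4955)$overlapPct, 85.4)
  expect_error(degDmgEnrichment(10, 5, 4, 5), "inconsistent")
})

test_that("shared-DEG percentages round half-up to two decimals", {
  expect_equal(sharedDegFraction(1181, 1828), 64.61)
  expect_equal(sharedDegFraction(2750, 3971), 69.25)
  expect_equal(sharedDegFraction(0, 10), 0)
  expect_equal(sharedDegFraction(1, 3), 33.33)
  expect_equal(sharedDegFraction(1, 16), 6.25)
  expect_error(sharedDegFraction(1, 0), "positive")
  expect_error(sharedDegFraction(5, 4), "nShared")
})

test_that("enrichment p agrees with a permutation oracle on a small universe", {
  nU <- 60; nDmg <- 20; nDeg <- 15; nOv <- 7
  p <- degDmgEnrichment(nU, nDmg, nDeg, nOv)$pValue
  set.seed(99)
  nPerm <- 20000
  dmgSet <- seq_len(nDmg)
  hits <- vapply(seq_len(nPerm), function(i) {
    sum(sample.int(nU, nDeg) <= nDmg)
  }, numeric(1))
  pPerm <- mean(hits >= nOv)
  se <- sqrt(pPerm * (1 - pPerm) / nPerm)
  expect_lt(abs(p - pPerm), 3 * se)
})

test_that("enrichment p-values are calibrated when DEGs are decoupled from DMGs", {
  ## DEG draws independent of DMG membership: P(p <= t) must not exceed t
  ## beyond Monte-Carlo error (hypergeometric p is discrete, conservative)
  nU <- 100; nDmg <- 35; nDeg <- 12
  nSeeds <- 200
  set.seed(123)
  ps <- vapply(seq_len(nSeeds), function(i) {
    deg <- sample.int(nU, nDeg)
    degDmgEnrichment(nU, nDmg, nDeg, sum(deg <= nDmg))$pValue
  }, numeric(1))
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    mcse <- sqrt(t * (1 - t) / nSeeds)
    expect_lte(mean(ps <= t), t + 3 * mcse)
  }
})

test_that("candidate-gene promoter reports summarize DMRs per context and region", {
  genes <- mkGenes(c(5001, 12001), c(8000, 14000), c("+", "+"))
  dmrs <- mkDmrs(c(3501, 4001, 6001), c(3700, 4200, 6200))
  rep <- promoterDmrReport(c("g1", "g2"), genes, dmrs)
  g1prom <- rep[rep$gene_id == "g1" & rep$region == "promoter_flank", ]
  expect_equal(g1prom$nDmrs, 2)
  expect_equal(g1prom$direction, "hyper")
  expect_equal(g1prom$context, "CHH")
  ## gene with no DMRs gets a single zero row
  g2 <- rep[rep$gene_id == "g2", ]
  expect_equal(g2$nDmrs, 0)
  ## unknown ids are reported, not fatal; empty request -> empty table
  expect_message(r2 <- promoterDmrReport(c("g1", "nope"), genes, dmrs),
                 "nope")
  expect_equal(attr(r2, "missing"), "nope")
  expect_equal(nrow(promoterDmrReport(character(), genes, dmrs)), 0)
})
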