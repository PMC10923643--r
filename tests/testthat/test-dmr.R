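test_that("chromosomes tile into non-overlapping windows with a truncated tail", {
  tiles <- fruitMethyl:::tileWindows(c(chr1 = 450), 200L)
  expect_equal(BiocGenerics::start(tiles), c(1L, 201L, 401L))
  expect_equal(BiocGenerics::end(tiles), c(200L, 400L, 450L))
})

test_that("window binning pools counts per context and flags testability", {
  a <- CytosineReport(rep("chr1", 3), c(50, 120, 260), "+",
                      c("CHH", "CHH", "CG"), c(2, 0, 5), c(10, 0, 10),
                      seqlengths = c(chr1 = 450))
  b <- CytosineReport(rep("chr1", 3), c(50, 120, 260), "+",
                      c("CHH", "CHH", "CG"), c(8, 1, 0), c(10, 4, 10),
                      seqlengths = c(chr1 = 450))
  w <- binWindows(a, b, dmrParams(minCoverage = 10, minSites = 1))
  mc <- S4Vectors::mcols(w)
  chh1 <- which(mc$context == "CHH" & BiocGenerics::start(w) == 1)
  expect_equal(mc$cA[chh1], 2); expect_equal(mc$nA[chh1], 10)
  expect_equal(mc$cB[chh1], 9); expect_equal(mc$nB[chh1], 14)
  expect_equal(mc$levelA[chh1], 0.2)
  expect_equal(mc$levelB[chh1], 9 / 14)
  ## CG window has only 10 reads per sample: testable at the floor
  cg <- which(mc$context == "CG")
  expect_true(mc$testable[cg])
  ## zero reads in one sample -> untestable
  b0 <- CytosineReport("chr1", 50, "+", "CHH", 0, 0,
                       seqlengths = c(chr1 = 450))
  w0 <- binWindows(a, b0, dmrParams(minCoverage = 1, minSites = 1))
  expect_false(any(S4Vectors::mcols(w0)$testable[
    S4Vectors::mcols(w0)$context == "CHH"]))

  ## mismatched chromosome sets are refused with the difference named
  c2 <- CytosineReport("chr2", 5, "+", "CHH", 1, 5)
  expect_error(binWindows(a, c2, dmrParams()), "chr2")
})

test_that("windowed Fisher test reproduces enumeration on canonical tables", {
  expect_equal(fisherWindowTest(10, 10, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisherWindowTest(3, 10, 3, 10), 1)    # identical counts
  expect_equal(fisherWindowTest(0, 10, 0, 10), 1)    # degenerate margin
  expect_true(is.na(fisherWindowTest(0, 0, 1, 10)))

  ## enumeration oracle across all tables with margins <= 8
  for (nA in 1:8) for (nB in 1:8) {
    cA <- 0:nA
    for (cB in 0:nB) {
      p <- fisherWindowTest(cA, rep(nA, nA + 1), rep(cB, nA + 1),
                            rep(nB, nA + 1))
      oracle <- vapply(cA, fisherOracle, numeric(1), nA = nA, cB = cB, nB = nB)
      expect_equal(p, oracle, tolerance = 1e-10)
    }
  }
})

test_that("windowed Fisher test agrees with stats::fisher.test", {
  set.seed(33)
  for (i in 1:50) {
    nA <- sample(1:300, 1); nB <- sample(1:300, 1)
    cA <- rbinom(1, nA, runif(1)); cB <- rbinom(1, nB, runif(1))
    ours <- fisherWindowTest(cA, nA, cB, nB)
    ref <- stats::fisher.test(matrix(c(cA, nA - cA, cB, nB - cB), 2,
                                     byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("BH step-up and the delta thresholds gate DMR calls", {
  ## q-values follow the standard step-up: p (0.01..0.04, m=4) -> all 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  ## a CHH window with huge significance but delta below 0.1 is not a DMR
  mkRep <- function(cc, nn) {
    CytosineReport(rep("chr1", 5), seq(10, 90, 20), "+", "CHH", cc, nn,
                   seqlengths = c(chr1 = 200))
  }
  a <- mkRep(rep(0, 5), rep(2000, 5))
  b <- mkRep(rep(180, 5), rep(2000, 5))  # delta 0.09
  d <- callDmrs(binWindows(a, b, dmrParams()), dmrParams())
  expect_length(d, 0)
  tested <- S4Vectors::metadata(d)$tested
  expect_lt(S4Vectors::mcols(tested)$pValue, 1e-9)

  ## raising the difference past the threshold calls it, direction hyper
  b2 <- mkRep(rep(400, 5), rep(2000, 5))  # delta 0.2
  d2 <- callDmrs(binWindows(a, b2, dmrParams()), dmrParams())
  expect_length(d2, 1)
  expect_equal(as.character(S4Vectors::mcols(d2)$direction), "hyper")
})

test_that("DMR calling is antisymmetric under sample swap", {
  spec <- recoverySpec(seed = 12L, genomeLength = 5e4)
  sim <- generateGenome(spec)
  meth <- simulateMethylomes(spec, sim)
  p <- dmrParams()
  fwd <- callDmrs(binWindows(meth$stages[[1]], meth$stages[[2]], p,
                             seqlengths = sim$seqlengths), p)
  rev <- callDmrs(binWindows(meth$stages[[2]], meth$stages[[1]], p,
                             seqlengths = sim$seqlengths), p)
  key <- function(d) paste(GenomicRanges::seqnames(d), BiocGenerics::start(d),
                           context(d))
  expect_setequal(key(fwd), key(rev))
  m <- match(key(fwd), key(rev))
  expect_equal(S4Vectors::mcols(fwd)$delta,
               -S4Vectors::mcols(rev)$delta[m])
  expect_true(all(S4Vectors::mcols(fwd)$direction !=
                    S4Vectors::mcols(rev)$direction[m]))
  expect_equal(S4Vectors::mcols(fwd)$pValue,
               S4Vectors::mcols(rev)$pValue[m], tolerance = 1e-12)
})

test_that("shared-DMR reports count identity-matched windows and concordance", {
  mk <- function(starts, contexts, directions) {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(starts, starts + 199))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      context = contexts,
      delta = ifelse(directions == "hyper", 0.3, -0.3),
      pValue = 1e-4, qValue = 1e-3, direction = directions)
    new("DmrSet", gr)
  }
  d1 <- mk(c(1, 201, 401), c("CHH", "CHH", "CG"), c("hyper", "hyper", "hypo"))
  d2 <- mk(c(1, 201, 601), c("CHH", "CHH", "CHH"), c("hyper", "hypo", "hyper"))
  rep <- sharedDmrs(d1, d2)
  chh <- rep[rep$context == "CHH", ]
  expect_equal(chh$nShared, 2)
  expect_equal(chh$concordance, 0.5)
  expect_equal(rep[rep$context == "CG", "nShared"], 0)
  expect_true(is.na(rep[rep$context == "CG", "concordance"]))

  ## identical sets are fully concordant; disjoint sets share nothing
  same <- sharedDmrs(d1, d1)
  expect_equal(same$concordance[same$context == "CHH"], 1.0)
  expect_equal(sum(sharedDmrs(mk(1, "CHH", "hyper"),
                              mk(801, "CHH", "hyper"))$nShared), 0)
})

test_that("genome DMR coverage is the union fraction of window bases", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(200, 400)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = c("CHH", "CHH"), delta = 0.2, pValue = 1e-4, qValue = 1e-3,
    direction = "hyper")
  d <- new("DmrSet", gr)
  cov <- genomeDmrCoverage(d, c(chr1 = 1000))
  expect_equal(unname(cov["CHH"]), 0.4)
  expect_equal(unname(cov["CG"]), 0)
  expect_equal(unname(cov["all"]), 0.4)
  expect_equal(unname(genomeDmrCoverage(d[0], c(chr1 = 1000))["all"]), 0)
})
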