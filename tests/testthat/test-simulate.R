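test_that("simulated label counts and bounds follow the SimulationSpec", {
  spec <- simulationSpec(c(chrA = 300000L, chrB = 200000L),
                         nBackground = 2000L, nSignal = 500L,
                         regionCount = 4L, regionWidth = 1500L, seed = 2L)
  sim <- simulateFragments(spec)
  expect_equal(sum(sim$fragments$label == "background"), 2000L)
  expect_equal(sum(sim$fragments$label == "signal"), 500L)
  expect_true(all(start(sim$fragments) >= 1L))
  sl <- GenomeInfoDb::seqlengths(sim$fragments)
  expect_true(all(end(sim$fragments) <=
                  sl[as.character(seqnames(sim$fragments))]))
  expect_length(sim$truth, 4L)
  expect_true(IRanges::isDisjoint(sim$truth))
})

test_that("fragment lengths respect the truncation bounds", {
  spec <- simulationSpec(c(chrS = 500000L), nBackground = 3000L,
                         nSignal = 0L, fragMean = 200, fragSd = 80,
                         fragMin = 50L, fragMax = 500L, seed = 14L)
  sim <- simulateFragments(spec)
  w <- width(sim$fragments)
  expect_true(all(w >= 50L & w <= 500L))
  expect_equal(mean(w), 200, tolerance = 0.1)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- simulationSpec(c(chrS = 100000L), nBackground = 500L,
                         nSignal = 100L, regionCount = 2L,
                         regionWidth = 1000L, seed = 77L)
  s1 <- simulateFragments(spec)
  s2 <- simulateFragments(spec)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$truth, s2$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(simulateFragments(spec)); b <- runif(1)
  expect_identical(a, b)
})

test_that("zero-signal and signal-only extremes behave as constructed", {
  bgOnly <- simulateFragments(simulationSpec(c(chrS = 100000L),
    nBackground = 1000L, nSignal = 0L, seed = 5L))
  expect_equal(unique(bgOnly$fragments$label), "background")
  expect_length(bgOnly$truth, 0L)

  sigOnly <- simulateFragments(simulationSpec(c(chrS = 100000L),
    nBackground = 0L, nSignal = 300L,
    regions = GRanges("chrS", IRanges(50001, 51000)), seed = 5L))
  expect_equal(unique(sigOnly$fragments$label), "signal")
  expect_true(all(countOverlaps(sigOnly$fragments, sigOnly$truth) > 0L))
})

test_that("planted regions are enriched by roughly the configured fold", {
  # 20000 bg over 1 Mb vs 2000 signal in 10 kb: expected fold = 10x
  sim <- simulateFragments(simulationSpec(c(chrS = 1e6L),
    nBackground = 20000L, nSignal = 2000L, regionCount = 5L,
    regionWidth = 2000L, seed = 8L))
  trk <- fragmentPileup(sim$fragments, c(chrS = 1e6L))
  idx <- buildCoverageIndex(trk, c(chrS = 1e6L))
  inside <- mean(intervalMean(idx, sim$truth))
  outMask <- GenomicRanges::setdiff(GRanges("chrS", IRanges(1, 1e6),
                                            seqlengths = c(chrS = 1e6L)),
                                    sim$truth + 1000L)
  outside <- sum(intervalMean(idx, outMask) * width(outMask)) /
    sum(width(outMask))
  fold <- (inside - outside) / outside
  expect_equal(fold, 10, tolerance = 0.25)
})

test_that("a region narrower than the minimum fragment length is rejected", {
  spec <- simulationSpec(c(chrS = 10000L), nBackground = 0L, nSignal = 10L,
                         regions = GRanges("chrS", IRanges(100, 120)),
                         seed = 1L)
  expect_error(simulateFragments(spec), "narrower")
})

test_that("written simulations round-trip through the BED reader", {
  sim <- simulateFragments(simulationSpec(c(chrS = 50000L),
    nBackground = 40L, nSignal = 10L, regionCount = 1L,
    regionWidth = 2000L, seed = 33L))
  outdir <- withr::local_tempdir()
  writeSimulation(sim, outdir)
  expect_equal(length(readLines(file.path(outdir, "reads.bed"))), 50L)
  back <- readAlignments(file.path(outdir, "reads.bed"), format = "bed")
  expect_equal(start(back), start(sim$fragments))
  expect_equal(end(back), end(sim$fragments))
  expect_equal(as.character(seqnames(back)),
               as.character(seqnames(sim$fragments)))
  expect_equal(back$source_id, sim$fragments$source_id)
  labels <- read.table(file.path(outdir, "labels.tsv"), header = TRUE,
                       sep = "\t")
  expect_equal(labels$label, sim$fragments$label)
})
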