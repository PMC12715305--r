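test_that("Poisson upper tails match closed forms", {
  expect_equal(poissonTail(0, 5), 1)
  expect_equal(poissonTail(1, 1), 1 - exp(-1))
  expect_equal(poissonTail(3, 1), 1 - 2.5 * exp(-1))
  expect_error(poissonTail(1, 0), "positive")
  expect_error(poissonTail(-1, 1), "non-negative")
})

test_that("window eligibility follows the exact Poisson tail", {
  sl <- c(chrS = 2000000L)
  set.seed(31)
  # homogeneous fragments: counts per window are ~Poisson(lambda_w)
  n <- 10000L
  frags <- GRanges("chrS", IRanges(sample.int(1999800L, n, replace = TRUE),
                                   width = 100L))
  w <- 200L
  p0 <- 0.2
  win <- scoreWindows(frags, sl, windowSize = w, p0 = p0)
  lambdaW <- n / 2e6 * w
  # oracle: the smallest eligible count from CDF enumeration
  kmin <- min(which(ppois(0:100 - 1, lambdaW, lower.tail = FALSE) < p0)) - 1L
  expect_true(all(win$count >= kmin))
  # eligible fraction of all windows ~ P(X >= kmin)
  expFrac <- ppois(kmin - 1, lambdaW, lower.tail = FALSE)
  expect_equal(length(win) / (2e6 / w), expFrac, tolerance = 0.15)
  expect_true(all(win$score > 0))
})

test_that("fragments are assigned to the window holding their midpoint", {
  sl <- c(chrS = 1000L)
  # midpoint of [1,399] is 200 -> window 1; of [199,601] is 400 -> window 2
  frags <- GRanges("chrS", IRanges(c(1, 199), c(399, 601)))
  win <- scoreWindows(frags, sl, windowSize = 200L, p0 = 0.999)
  expect_equal(start(win), c(1L, 201L))
  expect_equal(win$count, c(1L, 1L))
})

test_that("a window holding everything on an empty chromosome dominates", {
  sl <- c(chrS = 100000L)
  frags <- rep(GRanges("chrS", IRanges(501, 600)), 50L)
  win <- scoreWindows(frags, sl, windowSize = 200L, p0 = 0.2)
  expect_length(win, 1L)
  expect_equal(start(win), 401L)
  expect_gt(win$score, 50)
})

test_that("gap merging matches a brute-force oracle", {
  sl <- c(chrS = 100000L)
  mk <- function(starts) {
    g <- GRanges("chrS", IRanges(starts, width = 200L), seqlengths = sl)
    g$count <- rep(2L, length(g))
    g$score <- rep(1.5, length(g))
    sort(g)
  }
  # adjacent windows merge; an 800 bp gap with g = 600 does not
  one <- mergeIslands(mk(c(1, 201)), gapSize = 600L)
  expect_length(one, 1L)
  expect_equal(c(start(one), end(one)), c(1L, 400L))
  two <- mergeIslands(mk(c(1, 1001)), gapSize = 600L)
  expect_length(two, 2L)

  set.seed(17)
  for (rep in 1:5) {
    starts <- sort(sample(seq(1L, 90000L, by = 200L), 60L))
    win <- mk(starts)
    got <- mergeIslands(win, gapSize = 600L)
    want <- naiveMerge(start(win), end(win), 600L)
    expect_equal(start(got), want$start)
    expect_equal(end(got), want$end)
    # additivity: island score/count are sums over members
    expect_equal(sum(got$score), sum(win$score))
    expect_equal(sum(got$total_count), sum(win$count))
    # separation: consecutive gaps exceed g
    if (length(got) > 1L)
      expect_true(all(start(got)[-1] - end(got)[-length(got)] - 1L > 600L))
  }
})

test_that("peak calling recovers planted regions and only them", {
  sim <- simulateFragments(simulationSpec(c(chrS = 2e6L),
    nBackground = 20000L, nSignal = 2000L, regionCount = 5L,
    regionWidth = 2000L, seed = 6L))
  res <- classifyReads(sim$fragments, chromSizes = c(chrS = 2e6L),
    config = enrichmentConfig(nPseudo = 1000L, fdr = 0.2, seed = 6L))
  peaks <- callPeaks(res$pass, c(chrS = 2e6L),
                     backgroundCount = length(sim$fragments))
  expect_true(all(countOverlaps(sim$truth, peaks) >= 1L))
  expect_true(all(countOverlaps(peaks, sim$truth) >= 1L))
})

test_that("exact duplication of every fragment leaves peak locations unchanged", {
  sim <- simulateFragments(simulationSpec(c(chrS = 1e6L),
    nBackground = 0L, nSignal = 3000L, regionCount = 4L,
    regionWidth = 2000L, seed = 27L))
  frags <- sim$fragments
  pk1 <- callPeaks(frags, c(chrS = 1e6L))
  pk2 <- callPeaks(rep(frags, 2L), c(chrS = 1e6L))
  expect_identical(granges(pk1), granges(pk2))
  expect_equal(pk2$total_count, 2L * pk1$total_count)
})

test_that("no fragments give no windows and no peaks, with a warning", {
  expect_warning(w <- scoreWindows(GRanges(), c(chrS = 1000L)), "no fragments")
  expect_length(w, 0L)
  pk <- suppressWarnings(callPeaks(GRanges(), c(chrS = 1000L)))
  expect_length(pk, 0L)
})

test_that("a homogeneous background yields essentially no islands", {
  set.seed(55)
  n <- 50000L
  frags <- GRanges("chrS", IRanges(sample.int(4999500L, n, replace = TRUE),
                                   width = 200L))
  pk <- callPeaks(frags, c(chrS = 5e6L))
  expect_lte(length(pk), 1L)
})
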