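smallNull <- function(stats) {
  new("NullDistribution", chrom = "chrS",
      lengthRange = c(100L, 100L), sampledLength = 100L,
      stats = sort(stats), nPseudo = length(stats))
}

test_that("empirical p-values use the add-one estimator with ties to the null", {
  nd <- smallNull(c(0, 1, 2, 3))
  expect_equal(empiricalPvalue(nd, 2), 0.6)        # (1 + 2)/5
  expect_equal(empiricalPvalue(nd, 10), 1 / 5)     # above all nulls
  expect_equal(empiricalPvalue(nd, 0), 1)          # at or below all nulls
  # vectorised, against a direct-count oracle
  set.seed(2)
  stats <- round(runif(200, 0, 5), 2)
  nd <- smallNull(stats)
  obs <- round(runif(50, -1, 6), 2)
  want <- vapply(obs, function(o) (1 + sum(stats >= o)) / 201, numeric(1))
  expect_equal(empiricalPvalue(nd, obs), want)
})

test_that("p-values never fall below the add-one floor", {
  nd <- smallNull(runif(500))
  p <- empiricalPvalue(nd, c(-1, 0, 0.5, 2, 1e6))
  expect_true(all(p >= 1 / 501))
  expect_true(all(p <= 1))
})

test_that("BH adjustment matches the textbook step-up", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.5, 7)), rep(0.5, 7))
  set.seed(8)
  p <- runif(300)^2
  expect_equal(bhAdjust(p), naiveBH(p))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("null sampling reproduces degenerate tracks exactly", {
  sl <- c(chrS = 500L)
  zero <- buildCoverageIndex(trackFromVector(rep(0, 500)), sl)
  nd <- sampleNull(zero, "chrS", 50L, 100L)
  expect_true(all(nullStats(nd) == 0))
  const <- buildCoverageIndex(trackFromVector(rep(3, 500)), sl)
  nd <- sampleNull(const, "chrS", 50L, 100L)
  expect_true(all(nullStats(nd) == 3))  # translation invariance
})

test_that("sampled null converges to the exact enumeration on a tiny chromosome", {
  seqlen <- 50L
  len <- 10L
  v <- c(rep(0, 20), rep(4, 10), rep(1, 20))
  idx <- buildCoverageIndex(trackFromVector(v), c(chrS = seqlen))
  # oracle: every possible placement
  exact <- vapply(seq_len(seqlen - len + 1L),
                  function(s) mean(v[s:(s + len - 1L)]), numeric(1))
  set.seed(123)
  nd <- sampleNull(idx, "chrS", len, 20000L)
  expect_equal(mean(nullStats(nd)), mean(exact), tolerance = 0.02)
  for (q in c(0.25, 0.5, 0.75))
    expect_equal(unname(quantile(nullStats(nd), q)),
                 unname(quantile(exact, q)), tolerance = 0.15)
})

test_that("pseudo-reads honour the exclusion set or fail loudly", {
  sl <- c(chrS = 1000L)
  idx <- buildCoverageIndex(trackFromVector(rep(1, 1000)), sl)
  excl <- GRanges("chrS", IRanges(1, 600))
  set.seed(4)
  nd <- sampleNull(idx, "chrS", 50L, 200L, exclusion = excl)
  expect_equal(nPseudo(nd), 200L)
  full <- GRanges("chrS", IRanges(1, 1000))
  expect_error(
    sampleNull(idx, "chrS", 50L, 10L, exclusion = full, maxRetries = 5L),
    "exclusion")
  expect_error(sampleNull(idx, "chrS", 2000L, 10L), "exceeds")
})

test_that("classification is deterministic and partitions the input", {
  sim <- simulateFragments(simulationSpec(c(chrS = 300000L),
    nBackground = 3000L, nSignal = 300L, regionCount = 3L,
    regionWidth = 2000L, seed = 21L))
  cfg <- enrichmentConfig(nPseudo = 500L, fdr = 0.2, seed = 9L)
  r1 <- classifyReads(sim$fragments, chromSizes = c(chrS = 300000L),
                      config = cfg)
  r2 <- classifyReads(sim$fragments, chromSizes = c(chrS = 300000L),
                      config = cfg)
  expect_identical(r1$verdicts$passed, r2$verdicts$passed)
  expect_identical(r1$verdicts$pvalue, r2$verdicts$pvalue)
  expect_equal(length(r1$pass) + length(r1$fail), length(sim$fragments))
  expect_length(intersect(r1$pass$source_id, r1$fail$source_id), 0L)
  # identical coordinates => identical verdicts
  same <- rep(granges(sim$fragments[1]), 5)
  idx <- buildCoverageIndex(fragmentPileup(sim$fragments,
                                           c(chrS = 300000L)),
                            c(chrS = 300000L))
  rs <- classifyReads(same, index = idx, config = cfg)
  expect_equal(length(unique(rs$verdicts$pvalue)), 1L)
})

test_that("the pass set shrinks monotonically with the FDR level", {
  sim <- simulateFragments(simulationSpec(c(chrS = 300000L),
    nBackground = 3000L, nSignal = 300L, regionCount = 3L,
    regionWidth = 2000L, seed = 22L))
  strict <- classifyReads(sim$fragments, chromSizes = c(chrS = 300000L),
    config = enrichmentConfig(nPseudo = 500L, fdr = 0.1, seed = 9L))
  loose <- classifyReads(sim$fragments, chromSizes = c(chrS = 300000L),
    config = enrichmentConfig(nPseudo = 500L, fdr = 0.2, seed = 9L))
  expect_true(all(strict$verdicts$passed <= loose$verdicts$passed))
})

test_that("planted signal fragments are recovered at high sensitivity", {
  sim <- simulateFragments(simulationSpec(c(chrS = 1e6L),
    nBackground = 10000L, nSignal = 1000L, regionCount = 5L,
    regionWidth = 2000L, seed = 13L))
  res <- classifyReads(sim$fragments, chromSizes = c(chrS = 1e6L),
    config = enrichmentConfig(nPseudo = 1000L, fdr = 0.2, seed = 13L))
  sig <- sim$fragments$label == "signal"
  expect_gt(sum(res$verdicts$passed[sig]) / sum(sig), 0.9)
  # pass reads concentrate inside planted regions
  inRegion <- countOverlaps(res$pass, sim$truth) > 0
  expect_gt(mean(inRegion), 0.8)
})

test_that("degenerate inputs are handled per contract", {
  empty <- GRanges()
  r <- classifyReads(empty, chromSizes = c(chrS = 1000L),
                     config = enrichmentConfig(nPseudo = 10L))
  expect_length(r$pass, 0L)
  expect_length(r$fail, 0L)
  long <- GRanges("chrS", IRanges(1, 5000L))
  expect_error(
    classifyReads(long, chromSizes = c(chrS = 1000L),
                  config = enrichmentConfig(nPseudo = 10L)),
    "longer")
})
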