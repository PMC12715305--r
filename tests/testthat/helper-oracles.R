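suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# Per-base coverage by a naive counter: the brute-force pile-up oracle.
basewisePileup <- function(fragments, seqlen, chrom = "chrS") {
  v <- numeric(seqlen)
  fr <- fragments[as.character(seqnames(fragments)) == chrom]
  for (i in seq_along(fr)) {
    s <- max(1L, start(fr)[i])
    e <- min(seqlen, end(fr)[i])
    if (s <= e) v[s:e] <- v[s:e] + 1
  }
  v
}

bruteMean <- function(v, s, e) mean(v[s:e])
bruteMax <- function(v, s, e) max(v[s:e])

# O(n^2) island merge oracle: grow each island by repeatedly absorbing any
# window within gap g of its current span.
naiveMerge <- function(starts, ends, g) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] &&
          (starts[j] - ends[i] - 1L) <= g && (starts[i] - ends[j] - 1L) <= g) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(grp), function(k) {
    data.frame(start = min(starts[grp == k]), end = max(ends[grp == k]))
  }))
  out[order(out$start), , drop = FALSE]
}

# Textbook BH step-up, written independently of stats::p.adjust.
naiveBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# All-pairs interval overlap width (0 if disjoint), 1-based closed coords.
pairOverlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# All-pairs oracle: for each interval in a, does any interval in b overlap
# it by >= minov bp? Dense |a| x |b| computation, no interval trees.
allPairsHit <- function(a, b, minov = 1L) {
  if (length(b) == 0L) return(rep(FALSE, length(a)))
  ov <- outer(seq_along(a), seq_along(b), function(i, j)
    pmin(end(a)[i], end(b)[j]) - pmax(start(a)[i], start(b)[j]) + 1L)
  apply(ov >= minov, 1L, any)
}

# Random non-overlapping sorted intervals on [1, seqlen].
randomDisjointIntervals <- function(n, seqlen, maxWidth = 50L) {
  gapBudget <- seqlen - n * maxWidth
  stopifnot(gapBudget > n)
  starts <- sort(sample.int(gapBudget, n)) + cumsum(rep(maxWidth, n)) - maxWidth
  widths <- sample.int(maxWidth, n, replace = TRUE)
  GRanges("chrS", IRanges(starts + 1L, width = widths))
}

# A small track as an RleList from a per-base vector.
trackFromVector <- function(v, chrom = "chrS") {
  rl <- IRanges::RleList(S4Vectors::Rle(v))
  names(rl) <- chrom
  rl
}

# Write a tiny SAM file and convert to BAM (coordinates 1-based).
# `reads` is a data.frame with qname, flag, pos, cigar, rnext, pnext, tlen.
makeBam <- function(reads, seqlen = 10000L, chrom = "chr1") {
  sam <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, seqlen))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    mapped <- !bitwAnd(r$flag, 4L)
    lines <- c(lines, paste(
      r$qname, r$flag,
      if (mapped) chrom else "*",
      if (mapped) r$pos else 0L,
      if (mapped) r$mapq else 0L,
      if (mapped) r$cigar else "*",
      r$rnext, r$pnext, r$tlen,
      "*", "*", sep = "\t"))
  }
  writeLines(lines, sam)
  bam <- tempfile()
  Rsamtools::asBam(sam, bam, overwrite = TRUE, indexDestination = FALSE)
}

samRead <- function(qname, flag, pos, cigar = "100M", mapq = 30L,
                    rnext = "*", pnext = 0L, tlen = 0L) {
  data.frame(qname = qname, flag = flag, pos = pos, cigar = cigar,
             mapq = mapq, rnext = rnext, pnext = pnext, tlen = tlen)
}

# The standard calibration simulation shared by the heavier tests.
standardSim <- function(seed) {
  simulateFragments(simulationSpec(c(chrS = 1e7L), nBackground = 100000L,
    nSignal = 10000L, regionCount = 25L, regionWidth = 2000L, seed = seed))
}
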