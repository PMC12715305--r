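#' Upper-tail Poisson probability P(X >= k)
#'
#' The background-model primitive of the island caller, computed stably via
#' the survival function (`ppois(k - 1, lambda, lower.tail = FALSE)`).
#'
#' @param k non-negative integer count(s).
#' @param lambda positive Poisson rate(s).
#' @return P(X >= k) for X ~ Poisson(lambda).
#' @examples
#' poissonTail(0, 5)        # 1
#' poissonTail(1, 1)        # 1 - exp(-1)
#' @export
poissonTail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(k < 0)) stop("k must be non-negative")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Score fixed-width windows against a Poisson background
#'
#' Chromosomes are tiled with non-overlapping windows of `windowSize` bp
#' (the terminal window may be truncated). Each fragment is assigned to the
#' window containing its midpoint. Under a uniform background the per-window
#' count is Poisson with rate `lambda_w = backgroundCount / effectiveLength *
#' windowSize`; a window is eligible iff `P(X >= count) < p0`, and eligible
#' windows are scored `-ln P(X >= count)`. Ineligible windows are dropped.
#'
#' `backgroundCount` is the size of the sequencing library the fragments
#' came from. When calling peaks on a de-noised subset (the pass reads),
#' supply the original library size: enrichment is a claim relative to the
#' experiment's depth, and rating the subset against its own thinned density
#' would reward the thinning itself, flooding the caller with small noise
#' clusters. For a raw library the default (the number of input fragments)
#' is the right rate.
#'
#' @param fragments a `GRanges` (typically the pass set).
#' @param chromSizes chromosome lengths (named vector, `Seqinfo` or
#'   `GRanges` with seqlengths).
#' @param windowSize window width in bp (default 200).
#' @param p0 window eligibility threshold on the Poisson tail (default 0.2).
#' @param effectiveLength effective genome length for the background rate;
#'   defaults to the sum of chromosome lengths.
#' @param backgroundCount library size behind the background rate; defaults
#'   to `length(fragments)`.
#' @return a `GRanges` of eligible windows with metadata columns `count`
#'   and `score`, sorted by coordinate. Empty (with a warning) when there
#'   are no fragments.
#' @export
scoreWindows <- function(fragments, chromSizes, windowSize = 200L,
                         p0 = 0.2, effectiveLength = NULL,
                         backgroundCount = NULL) {
  sl <- asSeqlengths(chromSizes)
  windowSize <- as.integer(windowSize)
  stopifnot(windowSize >= 1L, p0 > 0, p0 <= 1)
  if (is.null(effectiveLength)) effectiveLength <- sum(as.numeric(sl))
  empty <- GRanges(seqlengths = sl)
  mcols(empty) <- DataFrame(count = integer(0), score = numeric(0))
  if (length(fragments) == 0L) {
    warning("no fragments to score")
    return(empty)
  }
  chr <- as.character(seqnames(fragments))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown))
    stop("fragment chromosome(s) absent from chrom sizes: ",
         paste(unknown, collapse = ", "))
  if (is.null(backgroundCount)) backgroundCount <- length(fragments)
  if (backgroundCount < length(fragments))
    stop("backgroundCount cannot be smaller than the fragment count")
  lambdaW <- backgroundCount / effectiveLength * windowSize
  mid <- (start(fragments) + end(fragments)) %/% 2L
  winIdx <- (mid - 1L) %/% windowSize  # 0-based window number
  pieces <- lapply(names(sl), function(c1) {
    i <- chr == c1
    if (!any(i)) return(empty)
    counts <- table(winIdx[i])
    wi <- as.integer(names(counts))
    cnt <- as.integer(counts)
    ws <- wi * windowSize + 1L
    we <- pmin(ws + windowSize - 1L, sl[[c1]])
    # floor at the smallest normal double: tails underflow to 0 for very
    # large counts, and downstream needs finite scores and p > 0
    pt <- pmax(poissonTail(cnt, lambdaW), .Machine$double.xmin)
    keep <- pt < p0
    g <- GRanges(c1, IRanges(ws[keep], we[keep]), seqlengths = sl)
    mcols(g) <- DataFrame(count = cnt[keep], score = -log(pt[keep]))
    g
  })
  ans <- do.call(c, pieces)
  sort(ans, ignore.strand = TRUE)
}

#' Merge eligible windows into islands
#'
#' Consecutive eligible windows on a chromosome separated by a gap of at
#' most `gapSize` bp are merged into one island spanning first start to
#' last end. Island score and count are the sums over member windows.
#'
#' @param windows eligible windows from [scoreWindows()], sorted by
#'   coordinate.
#' @param gapSize maximum gap in bp allowed inside an island (default 600).
#' @return a `GRanges` of islands with metadata columns `total_count` and
#'   `score`; islands are disjoint and consecutive islands on a chromosome
#'   are separated by gaps greater than `gapSize`.
#' @export
mergeIslands <- function(windows, gapSize = 600L) {
  gapSize <- as.integer(gapSize)
  if (length(windows) == 0L) {
    ans <- granges(windows)
    mcols(ans) <- DataFrame(total_count = integer(0), score = numeric(0))
    return(ans)
  }
  if (is.unsorted(order(match(as.character(seqnames(windows)),
                              seqlevels(windows)), start(windows))))
    stop("windows must be sorted by coordinate")
  islands <- reduce(granges(windows), min.gapwidth = gapSize + 1L,
                    ignore.strand = TRUE)
  hit <- findOverlaps(windows, islands, ignore.strand = TRUE)
  stopifnot(length(hit) == length(windows))
  total <- tapply(windows$count[S4Vectors::queryHits(hit)],
                  S4Vectors::subjectHits(hit), sum)
  scr <- tapply(windows$score[S4Vectors::queryHits(hit)],
                S4Vectors::subjectHits(hit), sum)
  ord <- as.integer(names(total))
  mcols(islands) <- DataFrame(total_count = integer(length(islands)),
                              score = numeric(length(islands)))
  islands$total_count[ord] <- as.integer(total)
  islands$score[ord] <- as.numeric(scr)
  islands
}

#' Call peaks on a fragment set with a SICER-style island algorithm
#'
#' Runs [scoreWindows()] then [mergeIslands()], assigns each island a
#' Poisson tail p-value on its total count with the background rate scaled
#' to the island length, adjusts with Benjamini-Hochberg, and keeps islands
#' with q <= `islandFdr`.
#'
#' The BH adjustment uses the number of windows in the effective genome as
#' the number of tests, not the number of candidate islands: candidates are
#' the extreme tail of one Poisson test per window, so adjusting only
#' within candidates would condition on significance already achieved and
#' understate the multiplicity. Ineligible windows count as tests with
#' larger p-values, which is exactly what `p.adjust(p, n = nWindows)`
#' assumes.
#'
#' Defaults (`windowSize` 200 bp, `gapSize` 600 bp, `p0` 0.2, `islandFdr`
#' 0.01) are the canonical settings for this family of callers. As in
#' [scoreWindows()], pass the parent library size as `backgroundCount`
#' when `fragments` is a de-noised subset.
#'
#' @inheritParams scoreWindows
#' @param gapSize maximum within-island gap in bp.
#' @param islandFdr FDR level for island significance.
#' @return a sorted `GRanges` of peaks with metadata columns `name`,
#'   `total_count`, `score`, `pvalue`, `qvalue`.
#' @examples
#' sim <- simulateFragments(simulationSpec(c(chrS = 200000L),
#'   nBackground = 200L, nSignal = 300L, regionCount = 2L,
#'   regionWidth = 2000L, seed = 4L))
#' sig <- sim$fragments[sim$fragments$label == "signal"]
#' callPeaks(sig, c(chrS = 200000L))
#' @export
callPeaks <- function(fragments, chromSizes, windowSize = 200L,
                      gapSize = 600L, p0 = 0.2, islandFdr = 0.01,
                      effectiveLength = NULL, backgroundCount = NULL) {
  sl <- asSeqlengths(chromSizes)
  if (is.null(effectiveLength)) effectiveLength <- sum(as.numeric(sl))
  if (is.null(backgroundCount)) backgroundCount <- length(fragments)
  win <- suppressWarnings(
    scoreWindows(fragments, sl, windowSize = windowSize, p0 = p0,
                 effectiveLength = effectiveLength,
                 backgroundCount = backgroundCount))
  islands <- mergeIslands(win, gapSize = gapSize)
  if (length(islands) == 0L) {
    mcols(islands) <- DataFrame(name = character(0),
      total_count = integer(0), score = numeric(0),
      pvalue = numeric(0), qvalue = numeric(0))
    return(islands)
  }
  lambdaBp <- backgroundCount / effectiveLength
  islands$pvalue <- pmax(poissonTail(islands$total_count,
                                     lambdaBp * width(islands)),
                         .Machine$double.xmin)
  nWindows <- ceiling(effectiveLength / windowSize)
  islands$qvalue <- p.adjust(islands$pvalue, method = "BH",
                             n = max(nWindows, length(islands)))
  islands <- islands[islands$qvalue <= islandFdr]
  islands <- sort(islands, ignore.strand = TRUE)
  if (length(islands))
    islands$name <- paste0("island_", seq_along(islands))
  else islands$name <- character(0)
  islands[, c("name", "total_count", "score", "pvalue", "qvalue")]
}

#' Write an island summary table
#'
#' TSV with 0-based half-open coordinates, counts, scores and island-level
#' p/q-values.
#'
#' @param islands a `GRanges` from [callPeaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeIslandsTsv <- function(islands, path) {
  df <- data.frame(chrom = as.character(seqnames(islands)),
                   start = start(islands) - 1L, end = end(islands),
                   name = islands$name, total_count = islands$total_count,
                   score = islands$score, pvalue = islands$pvalue,
                   qvalue = islands$qvalue)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
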