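.checkPeakSet <- function(x, what) {
  if (length(x) == 0L) return(invisible(x))
  if (!isDisjoint(x))
    stop(what, " contains overlapping intervals")
  ord <- order(match(as.character(seqnames(x)), seqlevels(x)), start(x))
  if (is.unsorted(ord))
    stop(what, " is not sorted by (chromosome, start)")
  invisible(x)
}

#' Two-sided peak-set overlap summary
#'
#' Counts, from each side, how many peaks overlap (by >= 1 bp) at least one
#' peak of the other set. The common count is reported from both sides
#' because many-to-one overlaps make it asymmetric.
#'
#' @param a,b `GRanges` peak sets, each internally disjoint and sorted.
#' @return a list with `n_a_only`, `n_common_a`, `n_b_only`, `n_common_b`;
#'   `n_a_only + n_common_a == length(a)` and symmetrically for `b`.
#' @export
overlapPeaks <- function(a, b) {
  .checkPeakSet(a, "peak set A")
  .checkPeakSet(b, "peak set B")
  commonA <- sum(countOverlaps(a, b, ignore.strand = TRUE) > 0L)
  commonB <- sum(countOverlaps(b, a, ignore.strand = TRUE) > 0L)
  list(n_a_only = length(a) - commonA, n_common_a = commonA,
       n_b_only = length(b) - commonB, n_common_b = commonB)
}

#' Per-peak maximum coverage intensity
#'
#' @param peaks a `GRanges` of peaks, within chromosome bounds.
#' @param index a [CoverageIndex-class] over the track of interest (the
#'   original or the pass pile-up).
#' @return numeric vector of per-peak maxima.
#' @export
peakMaxIntensity <- function(peaks, index) {
  intervalMax(index, peaks)
}

#' Precision and recall of called peaks against truth regions
#'
#' Precision is the fraction of called peaks overlapping a truth region by
#' at least `minOverlap` bp; recall is the fraction of truth regions so
#' overlapped by at least one called peak. With no called peaks precision
#' is NaN (0/0); with no truth regions recall is NaN.
#'
#' @param called,truth `GRanges` sets, each internally disjoint.
#' @param minOverlap minimum overlap in bp (>= 1).
#' @return a list with numeric elements `precision` and `recall`.
#' @export
precisionRecall <- function(called, truth, minOverlap = 1L) {
  if (minOverlap < 1L) stop("minOverlap must be >= 1")
  if (length(called) && !isDisjoint(called))
    stop("called peaks overlap each other")
  if (length(truth) && !isDisjoint(truth))
    stop("truth regions overlap each other")
  precision <- mean(countOverlaps(called, truth, minoverlap = minOverlap,
                                  ignore.strand = TRUE) > 0L)
  recall <- mean(countOverlaps(truth, called, minoverlap = minOverlap,
                               ignore.strand = TRUE) > 0L)
  list(precision = precision, recall = recall)
}
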