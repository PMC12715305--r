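#' Pile up fragments into a base-resolution coverage track
#'
#' The value at base b is the number of fragments whose span covers b
#' (whole-fragment occupancy, not 5' end counts). Fragments extending past a
#' chromosome end are clipped to the chromosome, so coverage mass equals the
#' sum of clipped fragment lengths exactly (conservation).
#'
#' @param fragments a `GRanges` of fragments.
#' @param chromSizes named vector of chromosome lengths, a `Seqinfo`, or a
#'   `GRanges` carrying seqlengths.
#' @return an `RleList` with one full-length run-length vector per
#'   chromosome in `chromSizes`.
#' @examples
#' frags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 6), c(10, 15)))
#' fragmentPileup(frags, c(chr1 = 20L))
#' @export
fragmentPileup <- function(fragments, chromSizes) {
  sl <- asSeqlengths(chromSizes)
  chr <- as.character(seqnames(fragments))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown))
    stop("fragment(s) on chromosome(s) absent from chrom sizes: ",
         paste(unknown, collapse = ", "))
  gr <- granges(fragments)
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  suppressWarnings(seqlengths(gr) <- sl)
  gr <- trim(gr)
  coverage(gr)
}

#' Total coverage mass of a track
#'
#' @param track an `RleList`.
#' @return sum over all chromosomes of value x run length.
#' @export
trackMass <- function(track) {
  sum(vapply(track, function(r)
    sum(as.numeric(S4Vectors::runValue(r)) *
        as.numeric(S4Vectors::runLength(r))), numeric(1)))
}

#' Pointwise difference of two coverage tracks
#'
#' Used to materialise the noise track: fail pile-up = all-reads pile-up
#' minus pass pile-up. Requires `b <= a` at every base.
#'
#' @param a,b `RleList` tracks over the same chromosomes and lengths.
#' @return the `RleList` `a - b`.
#' @export
subtractTracks <- function(a, b) {
  if (!identical(names(a), names(b)) ||
      !identical(S4Vectors::elementNROWS(a), S4Vectors::elementNROWS(b)))
    stop("tracks must cover the same chromosomes and lengths")
  for (chr in names(a)) {
    if (any(b[[chr]] > a[[chr]]))
      stop("subtrahend exceeds track on chromosome ", chr)
  }
  a - b
}
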