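#' @importFrom rtracklayer import export
#' @importFrom Rsamtools ScanBamParam scanBamFlag countBam testPairedEndBam
#'   BamFile
#' @importFrom GenomicAlignments readGAlignments readGAlignmentPairs
#' @importFrom S4Vectors metadata metadata<-
NULL

#' Read a two-column chrom.sizes table
#'
#' @param path path to a `name TAB length` file.
#' @return a named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names in ", path)
  if (any(tab$length <= 0L)) stop("non-positive chromosome length in ", path)
  stats::setNames(tab$length, tab$chrom)
}

#' Read aligned fragments from BAM or BED
#'
#' Normalises both formats to a `GRanges` of sequenced fragments: one range
#' per single-end read, or one range spanning min(mate starts) to
#' max(mate ends) per properly paired mate pair. Unmapped, secondary,
#' supplementary and below-`minMapq` BAM records are skipped; discordant
#' pairs (not flagged proper, or mates on different chromosomes) are skipped.
#' Skip counts are retained in `metadata(result)$records`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bam"` or `"bed"`.
#' @param pairing `"auto"` (BAM flags decide), `"single"` or `"paired"`.
#'   BED input carries no mate information, so `pairing = "paired"` on BED
#'   is an error.
#' @param minMapq minimum mapping quality for BAM records (default 0).
#' @param extend optionally extend single-end reads to this many bp from
#'   their 5' end (strand-aware); `NA` (default) leaves spans untouched.
#' @param dedup drop exact-coordinate duplicate fragments.
#' @return a `GRanges` with metadata columns `source_id` and `origin`
#'   (`"single-end"` or `"paired-end-merged"`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tr1\t0\t+", bed)
#' readAlignments(bed)
#' @export
readAlignments <- function(path, format = c("auto", "bam", "bed"),
                           pairing = c("auto", "single", "paired"),
                           minMapq = 0L, extend = NA, dedup = FALSE) {
  format <- match.arg(format)
  pairing <- match.arg(pairing)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam"
              else if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else stop("cannot infer format from extension: ", path)
  }
  gr <- if (format == "bam") {
    .readBamFragments(path, pairing, minMapq)
  } else {
    .readBedFragments(path, pairing)
  }
  if (!is.na(extend) && length(gr)) {
    single <- gr$origin == "single-end"
    if (any(single))
      gr[single] <- GenomicRanges::resize(gr[single], as.integer(extend),
                                          fix = "start")
  }
  if (isTRUE(dedup) && length(gr)) {
    dup <- duplicated(granges(gr))
    metadata(gr)$records$duplicates_removed <- sum(dup)
    gr <- gr[!dup]
  }
  gr
}

.readBedFragments <- function(path, pairing) {
  if (pairing == "paired")
    stop("BED records carry no mate information; cannot merge pairs")
  gr <- import(path, format = "BED")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name)
         else if (length(gr)) paste0("rec_", seq_along(gr))
         else character(0)
  mcols(gr) <- DataFrame(source_id = ids,
                         origin = rep("single-end", length(gr)))
  metadata(gr)$records <- list(total = length(gr), yielded = length(gr),
                               skipped = 0L)
  gr
}

.readBamFragments <- function(path, pairing, minMapq) {
  bf <- BamFile(path)
  if (pairing == "auto") {
    pairing <- if (suppressMessages(testPairedEndBam(bf))) "paired"
               else "single"
  }
  total <- countBam(bf)$records
  baseFlag <- scanBamFlag(isUnmappedQuery = FALSE,
                          isSecondaryAlignment = FALSE,
                          isSupplementaryAlignment = FALSE)
  if (pairing == "single") {
    param <- ScanBamParam(flag = baseFlag, mapqFilter = minMapq,
                          what = "qname")
    ga <- readGAlignments(bf, param = param)
    gr <- granges(ga)
    mcols(gr) <- DataFrame(source_id = mcols(ga)$qname,
                           origin = rep("single-end", length(gr)))
    used <- length(gr)
  } else {
    if (!suppressMessages(testPairedEndBam(bf)))
      stop("paired mode requested but ", path, " has no paired records")
    flag <- scanBamFlag(isUnmappedQuery = FALSE,
                        isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE,
                        isProperPair = TRUE)
    param <- ScanBamParam(flag = flag, mapqFilter = minMapq)
    gp <- readGAlignmentPairs(bf, param = param, use.names = TRUE)
    gr <- granges(gp, on.discordant.seqnames = "drop")
    mcols(gr) <- DataFrame(source_id = names(gr),
                           origin = rep("paired-end-merged", length(gr)))
    names(gr) <- NULL
    used <- 2L * length(gr)
  }
  metadata(gr)$records <- list(total = total, yielded = length(gr),
                               skipped = total - used)
  gr
}

#' Read and write bedGraph coverage tracks
#'
#' Tracks are `RleList` objects (one run-length vector per chromosome, full
#' chromosome length). On write, zero-coverage runs are omitted and adjacent
#' equal-valued runs are merged, so write-then-read reproduces the track
#' exactly and read-then-write is identity up to run merging. Positions
#' absent from the file read back as coverage 0.
#'
#' @param path bedGraph file (`chrom start end value`, 0-based half-open).
#' @param chromSizes named vector of chromosome lengths, a `Seqinfo`, or a
#'   `GRanges` with seqlengths.
#' @return `readBedGraph`: an `RleList`; `writeBedGraph`: `path`, invisibly.
#' @examples
#' trk <- IRanges::RleList(chr1 = S4Vectors::Rle(c(0, 2, 0), c(5, 10, 5)))
#' f <- tempfile(fileext = ".bedGraph")
#' writeBedGraph(trk, f)
#' identical(readBedGraph(f, c(chr1 = 20L)), IRanges::RleList(
#'   chr1 = S4Vectors::Rle(as.numeric(c(0, 2, 0)), c(5, 10, 5))))
#' @export
readBedGraph <- function(path, chromSizes) {
  sl <- asSeqlengths(chromSizes)
  gr <- import(path, format = "bedGraph")
  if (length(gr)) {
    if (any(start(gr) < 1L))
      stop("negative coordinates in bedGraph: ", path)
    if (!isDisjoint(gr))
      stop("overlapping intervals within a chromosome in bedGraph: ", path)
    chr <- as.character(seqnames(gr))
    if (!all(chr %in% names(sl)))
      stop("bedGraph chromosome(s) absent from chrom sizes: ",
           paste(unique(setdiff(chr, names(sl))), collapse = ", "))
    if (any(end(gr) > sl[chr]))
      stop("bedGraph interval(s) beyond chromosome end in ", path)
  }
  seqlevels(gr) <- names(sl)
  seqlengths(gr) <- sl
  coverage(gr, weight = if (length(gr)) gr$score else 1)
}

#' @rdname readBedGraph
#' @param track an `RleList` coverage track.
#' @export
writeBedGraph <- function(track, path) {
  gr <- .trackToRuns(track)
  gr <- gr[score(gr) != 0]
  export(gr, path, format = "bedGraph")
  invisible(path)
}

# RleList -> GRanges of runs (score column), chromosomes in track order
.trackToRuns <- function(track) {
  stopifnot(is(track, "RleList"))
  pieces <- lapply(names(track), function(chr) {
    r <- track[[chr]]
    rl <- S4Vectors::runLength(r)
    if (length(rl) == 0L) return(GRanges())
    ends <- cumsum(as.numeric(rl))
    GRanges(chr, IRanges(start = c(1, ends[-length(ends)] + 1), end = ends),
            score = as.numeric(S4Vectors::runValue(r)))
  })
  ans <- do.call(c, pieces)
  seqlevels(ans) <- names(track)
  ans
}

#' Write fragments or peaks as BED
#'
#' `writeFragmentsBed` emits 6-column BED (name = `source_id`, score = 0);
#' `writePeaksBed` emits 5-column BED (name = island id, score = island
#' score), sorted by (chromosome, start).
#'
#' @param fragments a `GRanges` of fragments (with optional `source_id`).
#' @param islands a `GRanges` of called islands (with optional `score`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFragmentsBed <- function(fragments, path) {
  gr <- granges(fragments)
  gr$name <- if (!is.null(fragments$source_id)) fragments$source_id
             else if (length(gr)) paste0("frag_", seq_along(gr))
             else character(0)
  gr$score <- rep(0L, length(gr))
  export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeFragmentsBed
#' @export
writePeaksBed <- function(islands, path) {
  ord <- order(match(as.character(seqnames(islands)), seqlevels(islands)),
               start(islands))
  gr <- islands[ord]
  sc <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  nm <- if (!is.null(gr$name)) gr$name
        else if (length(gr)) paste0("island_", seq_along(gr))
        else character(0)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = sc)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
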