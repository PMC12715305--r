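#' @importFrom jsonlite write_json read_json
#' @importFrom tools md5sum
NULL

.openLog <- function(outDir, name = "run.log") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  file(file.path(outDir, name), open = "wt")
}

#' Run the full de-noising stage
#'
#' Reads aligned fragments, piles them up, builds the prefix-sum index,
#' classifies every fragment against its empirical null, and writes the
#' standard output layout into `outDir`: `pass.bed`, `fail.bed`,
#' `pass.bedGraph`, `fail.bedGraph`, `verdicts.tsv`, `run.json` (all
#' parameters, seed, input checksum, pass/fail counts and pass percentage)
#' and `run.log`. Reruns with the same inputs and seed are byte-identical.
#'
#' @param input BAM or BED file of aligned reads.
#' @param chromSizes path to a chrom.sizes file, or a named vector of
#'   chromosome lengths.
#' @param outDir output directory (created; all outputs land here).
#' @param format,pairing,minMapq,extend,dedup passed to [readAlignments()].
#' @param nPseudo,fdr,lengthBinWidth,seed,selfSubtract passed to
#'   [enrichmentConfig()].
#' @param exclusion optional BED file (or `GRanges`) of regions pseudo-reads
#'   must avoid.
#' @param callPeaks also run the island caller on the pass set and write
#'   `peaks.bed` / `islands.tsv`.
#' @param windowSize,gapSize,p0,islandFdr island-caller parameters (used
#'   when `callPeaks = TRUE`).
#' @return invisibly, a list with the classification result, the tracks and
#'   the run summary.
#' @export
runDenoise <- function(input, chromSizes, outDir,
                       format = "auto", pairing = "auto", minMapq = 0L,
                       extend = NA, dedup = FALSE,
                       nPseudo = 5000L, fdr = 0.2, lengthBinWidth = 50L,
                       seed = 1L, selfSubtract = TRUE, exclusion = NULL,
                       callPeaks = FALSE, windowSize = 200L, gapSize = 600L,
                       p0 = 0.2, islandFdr = 0.01) {
  log <- .openLog(outDir)
  on.exit(close(log))
  sl <- if (is.character(chromSizes)) readChromSizes(chromSizes)
        else asSeqlengths(chromSizes)
  excl <- if (is.null(exclusion)) GRanges()
          else if (is.character(exclusion)) import(exclusion, format = "BED")
          else exclusion
  logLine(log, "stage=read input=", input)
  frags <- readAlignments(input, format = format, pairing = pairing,
                          minMapq = minMapq, extend = extend, dedup = dedup)
  logLine(log, "stage=read fragments=", length(frags))
  logLine(log, "stage=pileup")
  track <- fragmentPileup(frags, sl)
  index <- buildCoverageIndex(track, sl)
  logLine(log, "stage=classify nPseudo=", nPseudo, " fdr=", fdr,
          " seed=", seed)
  cfg <- enrichmentConfig(nPseudo = nPseudo, fdr = fdr,
                          lengthBinWidth = lengthBinWidth, seed = seed,
                          exclusion = excl, selfSubtract = selfSubtract)
  res <- classifyReads(frags, index = index, config = cfg)
  passTrack <- fragmentPileup(res$pass, sl)
  failTrack <- subtractTracks(track, passTrack)

  writeFragmentsBed(res$pass, file.path(outDir, "pass.bed"))
  writeFragmentsBed(res$fail, file.path(outDir, "fail.bed"))
  writeBedGraph(passTrack, file.path(outDir, "pass.bedGraph"))
  writeBedGraph(failTrack, file.path(outDir, "fail.bedGraph"))
  writeVerdicts(res$verdicts, file.path(outDir, "verdicts.tsv"))

  nPass <- length(res$pass)
  passPct <- if (length(frags)) 100 * nPass / length(frags) else 0
  summary <- list(
    input = input,
    input_md5 = unname(md5sum(input)),
    parameters = list(format = format, pairing = pairing,
      min_mapq = minMapq, extend = extend, dedup = dedup,
      n_pseudo = nPseudo, fdr = fdr, length_bin_width = lengthBinWidth,
      seed = seed, self_subtract = selfSubtract),
    n_fragments = length(frags),
    n_pass = nPass,
    n_fail = length(res$fail),
    pass_percent = passPct)
  logLine(log, sprintf("stage=classify pass=%d fail=%d pass_percent=%.2f",
                       nPass, length(res$fail), passPct))
  peaks <- NULL
  if (isTRUE(callPeaks)) {
    logLine(log, "stage=peaks w=", windowSize, " g=", gapSize)
    peaks <- chromsieve::callPeaks(res$pass, sl, windowSize = windowSize,
      gapSize = gapSize, p0 = p0, islandFdr = islandFdr,
      backgroundCount = length(frags))
    writePeaksBed(peaks, file.path(outDir, "peaks.bed"))
    writeIslandsTsv(peaks, file.path(outDir, "islands.tsv"))
    summary$n_peaks <- length(peaks)
    logLine(log, "stage=peaks n=", length(peaks))
  }
  write_json(summary, file.path(outDir, "run.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(list(result = res, track = track, passTrack = passTrack,
                 failTrack = failTrack, peaks = peaks, summary = summary))
}

#' Run the island peak caller as a stage
#'
#' @param input a pass-reads BED file, a `GRanges`, or a [runDenoise()]
#'   output directory (its `pass.bed` is used, and the original library
#'   size is recovered from `run.json` for the background rate).
#' @param chromSizes chrom.sizes path or named vector.
#' @param outDir output directory for `peaks.bed` and `islands.tsv`.
#' @param windowSize,gapSize,p0,islandFdr island-caller parameters.
#' @param backgroundCount parent library size for the background rate; see
#'   [callPeaks()]. Defaults to the fragment count (or to `n_fragments`
#'   from `run.json` when `input` is a denoise output directory).
#' @return invisibly, the peaks `GRanges`.
#' @export
runPeaks <- function(input, chromSizes, outDir, windowSize = 200L,
                     gapSize = 600L, p0 = 0.2, islandFdr = 0.01,
                     backgroundCount = NULL) {
  log <- .openLog(outDir, "peaks.log")
  on.exit(close(log))
  sl <- if (is.character(chromSizes)) readChromSizes(chromSizes)
        else asSeqlengths(chromSizes)
  frags <- if (is(input, "GRanges")) input
           else if (dir.exists(input)) {
             runJson <- file.path(input, "run.json")
             if (is.null(backgroundCount) && file.exists(runJson))
               backgroundCount <- read_json(runJson)$n_fragments
             readAlignments(file.path(input, "pass.bed"), format = "bed")
           } else readAlignments(input, format = "bed")
  logLine(log, "stage=peaks fragments=", length(frags))
  if (length(frags) == 0L)
    logLine(log, "stage=peaks warning=no-pass-fragments")
  peaks <- callPeaks(frags, sl, windowSize = windowSize, gapSize = gapSize,
                     p0 = p0, islandFdr = islandFdr,
                     backgroundCount = backgroundCount)
  writePeaksBed(peaks, file.path(outDir, "peaks.bed"))
  writeIslandsTsv(peaks, file.path(outDir, "islands.tsv"))
  logLine(log, "stage=peaks islands=", length(peaks))
  invisible(peaks)
}

#' Run the synthetic-data generator as a stage
#'
#' @param outDir output directory for `reads.bed`, `truth.bed`,
#'   `labels.tsv` and `chrom.sizes`.
#' @param ... passed to [simulationSpec()].
#' @return invisibly, the [simulateFragments()] result.
#' @export
runSimulate <- function(outDir, ...) {
  spec <- simulationSpec(...)
  sim <- simulateFragments(spec)
  writeSimulation(sim, outDir)
  write.table(data.frame(names(spec@seqlengths), unname(spec@seqlengths)),
              file.path(outDir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(sim)
}

#' Evaluate called peaks against another peak set and/or truth
#'
#' Writes a JSON report with the two-sided overlap summary and, when truth
#' regions are given, precision and recall at `minOverlap` bp.
#'
#' @param called peaks BED path or `GRanges`.
#' @param other optional second peak set (BED path or `GRanges`) for the
#'   overlap summary.
#' @param truth optional truth regions (BED path or `GRanges`).
#' @param outDir output directory for `evaluation.json`.
#' @param minOverlap minimum overlap in bp for precision/recall.
#' @return invisibly, the report list.
#' @export
runEvaluate <- function(called, other = NULL, truth = NULL, outDir,
                        minOverlap = 1L) {
  asGr <- function(x) {
    if (is(x, "GRanges")) granges(x) else granges(import(x, format = "BED"))
  }
  calledGr <- sort(asGr(called), ignore.strand = TRUE)
  report <- list(n_called = length(calledGr))
  if (!is.null(other)) {
    otherGr <- sort(asGr(other), ignore.strand = TRUE)
    report$overlap <- overlapPeaks(calledGr, otherGr)
  }
  if (!is.null(truth)) {
    truthGr <- sort(asGr(truth), ignore.strand = TRUE)
    pr <- precisionRecall(calledGr, truthGr, minOverlap = minOverlap)
    report$precision <- pr$precision
    report$recall <- pr$recall
    report$min_overlap_bp <- minOverlap
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write_json(report, file.path(outDir, "evaluation.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
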