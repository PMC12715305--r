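# Truncated-normal lengths by inverse-CDF sampling; rounding is clamped
# back into [lo, hi] so the bounds are hard.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep.int(as.integer(round(mean)), n))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(as.integer(round(qnorm(u, mean, sd))), as.integer(lo)),
       as.integer(hi))
}

# Place `count` disjoint regions of `width` bp with pairwise gaps >= minGap,
# by rejection sampling across the genome (chromosomes weighted by length).
.placeRegions <- function(seqlengths, count, width, minGap) {
  sl <- seqlengths
  ok <- sl >= width
  if (!any(ok)) stop("no chromosome can hold a region of width ", width)
  sl <- sl[ok]
  placed <- GRanges(seqlengths = seqlengths)
  guard <- 0L
  while (length(placed) < count) {
    guard <- guard + 1L
    if (guard > 10000L * count)
      stop("could not place ", count, " disjoint regions; genome too small")
    chr <- sample(names(sl), 1L, prob = as.numeric(sl))
    s <- sample.int(sl[[chr]] - width + 1L, 1L)
    cand <- GRanges(chr, IRanges(s, width = width), seqlengths = seqlengths)
    pad <- suppressWarnings(trim(GRanges(chr,
      IRanges(max(1L, s - minGap), s + width - 1L + minGap),
      seqlengths = seqlengths)))
    if (length(placed) == 0L || !any(countOverlaps(pad, placed)))
      placed <- c(placed, cand)
  }
  sort(placed, ignore.strand = TRUE)
}

#' Generate a labelled synthetic fragment set
#'
#' Produces `nBackground` fragments with start positions uniform over the
#' genome plus `nSignal` fragments with start positions uniform within the
#' planted regions, all with truncated-normal lengths, clipped to
#' chromosome ends. Every fragment carries its truth label. Generation is
#' fully reproducible from `spec@seed`.
#'
#' @param spec a [SimulationSpec-class].
#' @return a list with `fragments` (a `GRanges` with metadata columns
#'   `source_id` and `label` in \{`"background"`, `"signal"`\}) and `truth`
#'   (the planted regions as a `GRanges`).
#' @examples
#' sim <- simulateFragments(simulationSpec(c(chrS = 100000L),
#'   nBackground = 500L, nSignal = 100L, regionCount = 2L,
#'   regionWidth = 1000L, seed = 11L))
#' table(sim$fragments$label)
#' @export
simulateFragments <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  sl <- spec@seqlengths
  withSeed(spec@seed, {
    truth <- if (length(spec@regions)) {
      g <- spec@regions
      seqlevels(g) <- union(seqlevels(g), names(sl))
      suppressWarnings(seqlengths(g) <- sl)
      sort(granges(g), ignore.strand = TRUE)
    } else if (spec@nSignal > 0L) {
      .placeRegions(sl, spec@regionCount, spec@regionWidth, spec@regionMinGap)
    } else {
      GRanges(seqlengths = sl)
    }
    if (spec@nSignal > 0L && any(width(truth) < spec@fragMin))
      stop("planted region(s) narrower than the minimum fragment length")

    nb <- spec@nBackground
    ns <- spec@nSignal
    lens <- .rtruncnorm(nb + ns, spec@fragMean, spec@fragSd,
                        spec@fragMin, spec@fragMax)
    frags <- GRanges()
    if (nb > 0L) {
      chr <- sample(names(sl), nb, replace = TRUE, prob = as.numeric(sl))
      nStarts <- pmax(sl[chr] - lens[seq_len(nb)] + 1L, 1L)
      s <- floor(runif(nb, 1, nStarts + 1))
      bg <- GRanges(chr, IRanges(s, width = lens[seq_len(nb)]))
      mcols(bg) <- DataFrame(source_id = paste0("bg_", seq_len(nb)),
                             label = rep("background", nb))
      frags <- c(frags, bg)
    }
    if (ns > 0L) {
      ri <- sample(seq_along(truth), ns, replace = TRUE,
                   prob = as.numeric(width(truth)))
      s <- start(truth)[ri] +
        floor(runif(ns, 0, width(truth)[ri]))
      sg <- GRanges(as.character(seqnames(truth))[ri],
                    IRanges(s, width = lens[nb + seq_len(ns)]))
      mcols(sg) <- DataFrame(source_id = paste0("sig_", seq_len(ns)),
                             label = rep("signal", ns))
      frags <- c(frags, sg)
    }
    seqlevels(frags) <- names(sl)
    suppressWarnings(seqlengths(frags) <- sl)
    frags <- trim(frags)
    list(fragments = frags, truth = truth)
  })
}

#' Write a simulation to disk
#'
#' Emits `reads.bed` (6-column BED of fragments), `truth.bed` (planted
#' regions) and `labels.tsv` (`source_id TAB label`) into `outdir`.
#'
#' @param sim a [simulateFragments()] result.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeFragmentsBed(sim$fragments, file.path(outdir, "reads.bed"))
  export(granges(sim$truth), file.path(outdir, "truth.bed"), format = "BED")
  write.table(data.frame(source_id = sim$fragments$source_id,
                         label = sim$fragments$label),
              file.path(outdir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(outdir)
}
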