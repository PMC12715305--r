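#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges coverage findOverlaps countOverlaps
#'   reduce trim
#' @importFrom BiocGenerics sort order
#' @importFrom IRanges IRanges Views viewMeans viewMaxs
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#'   seqlevels<- Seqinfo seqinfo
#' @importFrom stats p.adjust ppois qnorm pnorm runif median
#' @importFrom utils write.table read.table
NULL

#' CoverageIndex: exact O(1) interval queries over a coverage track
#'
#' A per-chromosome prefix-sum structure over the run-length encoded coverage.
#' For each chromosome it stores the 1-based start position of every run, the
#' run values, and the cumulative coverage mass up to the start of each run.
#' Interval sums (hence means) are answered exactly with two binary searches;
#' interval maxima scan the runs overlapping the query.
#'
#' Raw pile-ups are integer-valued, and the cumulative sums are kept as
#' doubles, which represent integers exactly up to 2^53 -- far beyond any
#' genome-scale coverage mass -- so integer-track means are exact rationals.
#'
#' @slot runStarts named list; per chromosome, 1-based start of each run
#'   (first element is always 1).
#' @slot runValues named list; per chromosome, coverage value of each run.
#' @slot cumMass named list; per chromosome, coverage mass strictly before
#'   each run start (first element is always 0).
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#'
#' @seealso [buildCoverageIndex()], [intervalMean()], [intervalMax()]
#' @export
setClass("CoverageIndex",
  representation(
    runStarts = "list",
    runValues = "list",
    cumMass = "list",
    seqlengths = "integer"
  )
)

setValidity("CoverageIndex", function(object) {
  nm <- names(object@seqlengths)
  if (is.null(nm) || anyDuplicated(nm))
    return("seqlengths must be uniquely named")
  if (!identical(names(object@runStarts), nm) ||
      !identical(names(object@runValues), nm) ||
      !identical(names(object@cumMass), nm))
    return("runStarts/runValues/cumMass must be named like seqlengths")
  for (chr in nm) {
    s <- object@runStarts[[chr]]
    cm <- object@cumMass[[chr]]
    if (length(s) == 0L || s[1L] != 1 || cm[1L] != 0)
      return(sprintf("chromosome %s: first run must start at 1 with mass 0", chr))
    if (is.unsorted(s, strictly = TRUE))
      return(sprintf("chromosome %s: run starts must be strictly increasing", chr))
    if (is.unsorted(cm))
      return(sprintf("chromosome %s: cumulative mass must be non-decreasing", chr))
    if (any(object@runValues[[chr]] < 0))
      return(sprintf("chromosome %s: negative coverage", chr))
  }
  TRUE
})

#' @describeIn CoverageIndex-class compact display
#' @param object a `CoverageIndex`
#' @export
setMethod("show", "CoverageIndex", function(object) {
  cat("CoverageIndex over", length(object@seqlengths), "chromosome(s)\n")
  cat("  total length:", sum(as.numeric(object@seqlengths)), "bp\n")
  cat("  total mass:  ", sum(vapply(names(object@seqlengths), function(chr)
    .indexPrefixSum(object, chr, object@seqlengths[[chr]]), numeric(1))), "\n")
})

#' NullDistribution: the empirical null for one (chromosome, length-bin)
#'
#' Holds the sorted interval-mean coverage values observed at `nPseudo`
#' pseudo-read placements -- intervals of a fixed length dropped uniformly at
#' random on one chromosome. Fragments falling in the same chromosome and
#' fragment-length bin share one such null.
#'
#' @slot chrom chromosome the pseudo-reads were placed on.
#' @slot lengthRange integer(2); the fragment-length bin (bp, inclusive)
#'   this null serves.
#' @slot sampledLength integer(1); the pseudo-read length actually placed
#'   (the bin's median fragment length).
#' @slot stats sorted non-negative numeric vector of length `nPseudo`.
#' @slot nPseudo number of pseudo-reads.
#'
#' @seealso [sampleNull()], [empiricalPvalue()]
#' @export
setClass("NullDistribution",
  representation(
    chrom = "character",
    lengthRange = "integer",
    sampledLength = "integer",
    stats = "numeric",
    nPseudo = "integer"
  )
)

setValidity("NullDistribution", function(object) {
  if (length(object@chrom) != 1L) return("chrom must be a single name")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1L] > object@lengthRange[2L])
    return("lengthRange must be (lower, upper) with lower <= upper")
  if (object@nPseudo < 1L) return("nPseudo must be >= 1")
  if (length(object@stats) != object@nPseudo)
    return("stats must hold exactly nPseudo values")
  if (is.unsorted(object@stats)) return("stats must be sorted ascending")
  if (any(object@stats < 0)) return("stats must be non-negative")
  TRUE
})

#' @describeIn NullDistribution-class compact display
#' @param object a `NullDistribution`
#' @export
setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %s, lengths [%d,%d] bp (sampled at %d), n=%d\n",
    object@chrom, object@lengthRange[1L], object@lengthRange[2L],
    object@sampledLength, object@nPseudo))
  cat(sprintf("  mean stat %.4g, range [%.4g, %.4g]\n",
    mean(object@stats), object@stats[1L], object@stats[object@nPseudo]))
})

#' @rdname NullDistribution-class
#' @param x a `NullDistribution`
#' @export
nullStats <- function(x) {
  stopifnot(is(x, "NullDistribution"))
  x@stats
}

#' @rdname NullDistribution-class
#' @export
nPseudo <- function(x) {
  stopifnot(is(x, "NullDistribution"))
  x@nPseudo
}

#' EnrichmentConfig: parameters of the read-level enrichment test
#'
#' @slot nPseudo pseudo-reads per null distribution (default 5000).
#' @slot fdr nominal false discovery rate for the pass/fail split
#'   (default 0.2).
#' @slot lengthBinWidth width of the fragment-length bins sharing one null
#'   (bp, default 50).
#' @slot seed integer seed; per-(chromosome, bin) substreams are derived
#'   from it so results do not depend on iteration order.
#' @slot exclusion `GRanges` of regions pseudo-reads must avoid (e.g.
#'   assembly gaps or a blacklist); empty by default.
#' @slot selfSubtract if TRUE (the default), subtract 1 -- the fragment's
#'   own contribution to the pile-up -- from each observed mean before
#'   testing, so the observed statistic is on the same footing as the
#'   pseudo-read null (pseudo-reads add no read of their own). Without it
#'   every fragment sits one coverage unit above its null and the empirical
#'   FDR is not controlled.
#' @slot maxRetries rejection-sampling retries per pseudo-read when an
#'   exclusion set is given.
#'
#' @seealso [enrichmentConfig()], [classifyReads()]
#' @export
setClass("EnrichmentConfig",
  representation(
    nPseudo = "integer",
    fdr = "numeric",
    lengthBinWidth = "integer",
    seed = "integer",
    exclusion = "GRanges",
    selfSubtract = "logical",
    maxRetries = "integer"
  )
)

setValidity("EnrichmentConfig", function(object) {
  if (object@nPseudo < 1L) return("nPseudo must be >= 1")
  if (object@fdr <= 0 || object@fdr >= 1) return("fdr must be in (0,1)")
  if (object@lengthBinWidth < 1L) return("lengthBinWidth must be >= 1")
  if (object@maxRetries < 1L) return("maxRetries must be >= 1")
  TRUE
})

#' Construct an EnrichmentConfig
#'
#' Defaults follow the recommended operating point: a nominal FDR of 0.2 with
#' 5000 pseudo-reads per null. A stringent analysis typically uses
#' `fdr = 0.1` with the same number of pseudo-reads.
#'
#' @param nPseudo pseudo-reads per null distribution.
#' @param fdr nominal FDR in (0,1).
#' @param lengthBinWidth fragment-length bin width in bp.
#' @param seed integer seed for pseudo-read placement.
#' @param exclusion optional `GRanges` pseudo-reads must avoid.
#' @param selfSubtract subtract the fragment's own coverage contribution
#'   from its observed mean (default TRUE; see
#'   [EnrichmentConfig-class]).
#' @param maxRetries rejection-sampling cap per pseudo-read.
#' @return an [EnrichmentConfig-class] object.
#' @examples
#' enrichmentConfig(seed = 7)
#' @export
enrichmentConfig <- function(nPseudo = 5000L, fdr = 0.2, lengthBinWidth = 50L,
                             seed = 1L, exclusion = GRanges(),
                             selfSubtract = TRUE, maxRetries = 1000L) {
  new("EnrichmentConfig",
    nPseudo = as.integer(nPseudo), fdr = as.numeric(fdr),
    lengthBinWidth = as.integer(lengthBinWidth), seed = as.integer(seed),
    exclusion = exclusion, selfSubtract = isTRUE(selfSubtract),
    maxRetries = as.integer(maxRetries))
}

#' @describeIn EnrichmentConfig-class compact display
#' @param object an `EnrichmentConfig`
#' @export
setMethod("show", "EnrichmentConfig", function(object) {
  cat(sprintf(paste0(
    "EnrichmentConfig: nPseudo=%d, fdr=%.3g, lengthBinWidth=%d bp, seed=%d\n",
    "  selfSubtract=%s, exclusion: %d region(s)\n"),
    object@nPseudo, object@fdr, object@lengthBinWidth, object@seed,
    object@selfSubtract, length(object@exclusion)))
})

#' SimulationSpec: a labelled synthetic fragment set
#'
#' Describes a mixture of uniformly placed background fragments and signal
#' fragments concentrated in planted enriched regions, with truncated-normal
#' fragment lengths, on one or more artificial chromosomes. Used to exercise
#' and calibrate the enrichment test and peak caller against known truth.
#'
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#' @slot nBackground number of background fragments (starts uniform over the
#'   genome, chromosomes weighted by length).
#' @slot nSignal number of signal fragments (starts uniform within the
#'   planted regions, regions weighted by width).
#' @slot regions planted enriched regions (`GRanges`); empty means auto-place
#'   `regionCount` disjoint regions of `regionWidth` bp.
#' @slot regionCount,regionWidth auto-placement parameters.
#' @slot regionMinGap minimum gap between auto-placed regions (bp).
#' @slot fragMean,fragSd,fragMin,fragMax truncated-normal fragment-length
#'   parameters (bp).
#' @slot seed integer seed; generation is fully reproducible.
#'
#' @seealso [simulationSpec()], [simulateFragments()]
#' @export
setClass("SimulationSpec",
  representation(
    seqlengths = "integer",
    nBackground = "integer",
    nSignal = "integer",
    regions = "GRanges",
    regionCount = "integer",
    regionWidth = "integer",
    regionMinGap = "integer",
    fragMean = "numeric",
    fragSd = "numeric",
    fragMin = "integer",
    fragMax = "integer",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  if (length(object@seqlengths) == 0L || any(object@seqlengths <= 0L))
    return("seqlengths must be positive")
  if (is.null(names(object@seqlengths)) || anyDuplicated(names(object@seqlengths)))
    return("seqlengths must have unique names")
  if (object@nBackground < 0L || object@nSignal < 0L)
    return("fragment counts must be non-negative")
  if (!(object@fragMin <= object@fragMean && object@fragMean <= object@fragMax))
    return("fragment lengths require min <= mean <= max")
  if (object@fragMin < 1L) return("fragMin must be >= 1")
  if (length(object@regions) > 0L) {
    if (!isDisjoint(object@regions))
      return("planted regions must be pairwise disjoint")
    sl <- object@seqlengths
    chr <- as.character(seqnames(object@regions))
    if (!all(chr %in% names(sl)))
      return("planted regions on unknown chromosomes")
    if (any(start(object@regions) < 1L) ||
        any(end(object@regions) > sl[chr]))
      return("planted regions outside chromosome bounds")
  } else if (object@nSignal > 0L &&
             (object@regionCount < 1L || object@regionWidth < object@fragMin)) {
    return("auto-placement needs regionCount >= 1 and regionWidth >= fragMin")
  }
  TRUE
})

#' @describeIn SimulationSpec-class compact display
#' @param object a `SimulationSpec`
#' @export
setMethod("show", "SimulationSpec", function(object) {
  nr <- if (length(object@regions)) length(object@regions) else object@regionCount
  cat(sprintf(paste0(
    "SimulationSpec: %d chromosome(s), %s bp total\n",
    "  %d background + %d signal fragments, %d planted region(s)\n",
    "  fragment lengths ~ truncN(mean=%g, sd=%g, [%d,%d]); seed=%d\n"),
    length(object@seqlengths), format(sum(as.numeric(object@seqlengths)),
      big.mark = ","),
    object@nBackground, object@nSignal, nr,
    object@fragMean, object@fragSd, object@fragMin, object@fragMax,
    object@seed))
})

#' Construct a SimulationSpec
#'
#' The default fragment-length model (mean 200 bp, sd 30, truncated to
#' 50-500 bp) matches typical ChIP-seq / CUT&RUN fragmentation.
#'
#' @param seqlengths named vector of chromosome lengths in bp.
#' @param nBackground,nSignal background / signal fragment counts.
#' @param regions optional `GRanges` of planted regions; if empty,
#'   `regionCount` disjoint regions of `regionWidth` bp are auto-placed at
#'   least `regionMinGap` bp apart.
#' @param regionCount,regionWidth,regionMinGap auto-placement parameters.
#' @param fragMean,fragSd,fragMin,fragMax truncated-normal length parameters.
#' @param seed integer seed.
#' @return a [SimulationSpec-class] object.
#' @examples
#' simulationSpec(c(chrS = 1e6L), nBackground = 1000L, nSignal = 100L,
#'                regionCount = 5L, regionWidth = 2000L, seed = 1L)
#' @export
simulationSpec <- function(seqlengths, nBackground, nSignal,
                           regions = GRanges(), regionCount = 25L,
                           regionWidth = 2000L, regionMinGap = 5000L,
                           fragMean = 200, fragSd = 30,
                           fragMin = 50L, fragMax = 500L, seed = 1L) {
  sl <- seqlengths
  storage.mode(sl) <- "integer"
  new("SimulationSpec",
    seqlengths = sl, nBackground = as.integer(nBackground),
    nSignal = as.integer(nSignal), regions = regions,
    regionCount = as.integer(regionCount),
    regionWidth = as.integer(regionWidth),
    regionMinGap = as.integer(regionMinGap),
    fragMean = as.numeric(fragMean), fragSd = as.numeric(fragSd),
    fragMin = as.integer(fragMin), fragMax = as.integer(fragMax),
    seed = as.integer(seed))
}
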