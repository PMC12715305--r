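#' @importFrom BiocGenerics start end width strand strand<- score score<-
#' @importFrom IRanges isDisjoint
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit substream seed from (seed, chromosome, bin index), so
# per-group null sampling is independent of group iteration order.
substreamSeed <- function(seed, chrom, bin) {
  m <- 2147483629  # prime < 2^31
  h <- 0
  for (code in utf8ToInt(chrom)) h <- (h * 131 + code) %% m
  as.integer((h + 1000003 * (bin %% 10000) + (seed %% m) * 7919) %% m)
}

# named integer seqlengths from a GRanges / Seqinfo / named vector
asSeqlengths <- function(x) {
  sl <- if (is(x, "GRanges")) seqlengths(x)
        else if (is(x, "Seqinfo")) seqlengths(x)
        else x
  if (is.null(names(sl)) || anyNA(sl))
    stop("chromosome lengths must be a complete named vector")
  storage.mode(sl) <- "integer"
  sl
}

logLine <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
  invisible(msg)
}
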