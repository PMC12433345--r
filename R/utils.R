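#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats cor p.adjust phyper pt rbinom rlnorm rnbinom rnorm runif
#'   sd t.test
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Region data.frames use 0-based half-open coordinates throughout; IRanges
# is 1-based closed, so conversion happens only at this boundary.
gr_from_regions <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

gr_from_points <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

region_midpoint <- function(df) (df$start + df$end) %/% 2L

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_sample_sheet <- function(samples) {
  need <- c("sample_id", "tissue", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicated sample_id in sample sheet")
  samples
}
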