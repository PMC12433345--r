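#' Extend peaks to fixed-width summit windows
#'
#' Each peak is replaced by the interval `[summit - flank, summit + flank + 1)`
#' clipped to the chromosome, i.e. the summit plus `flank` bp on either
#' side (151 bp at the default flank of 75). Peaks without a called summit
#' (`summit_offset = -1`) use the interval midpoint.
#'
#' @param peaks Data.frame from [read_narrowpeak()].
#' @param flank Bases added on each side of the summit.
#' @param chrom_lens Named integer vector of chromosome lengths.
#' @return Data.frame with `chrom`, `start`, `end`, `summit`, `sample_id`.
#' @export
extend_to_fixed_width <- function(peaks, flank = 75L, chrom_lens) {
  if (flank < 0L) stopf("flank must be >= 0")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      sample_id = character(), stringsAsFactors = FALSE))
  miss <- setdiff(unique(peaks$chrom), names(chrom_lens))
  if (length(miss)) stopf("unknown chromosome %s", miss[1L])
  len <- unname(chrom_lens[peaks$chrom])
  off <- ifelse(peaks$summit_offset < 0L,
                (peaks$end - peaks$start) %/% 2L, peaks$summit_offset)
  summit <- peaks$start + off
  if (any(summit < 0L | summit >= len))
    stopf("summit at %d outside chromosome %s of length %d",
          summit[summit < 0L | summit >= len][1L],
          peaks$chrom[summit < 0L | summit >= len][1L],
          len[summit < 0L | summit >= len][1L])
  data.frame(
    chrom = peaks$chrom,
    start = pmax(summit - flank, 0L),
    end = pmin(summit + flank + 1L, len),
    summit = summit,
    sample_id = peaks$sample_id,
    stringsAsFactors = FALSE
  )
}

#' Build consensus regions from per-sample peak sets
#'
#' Summit-extended fixed-width windows from all samples are clustered by
#' single-linkage overlap (at least 1 bp). Every cluster supported by at
#' least `min_overlap` distinct samples yields one consensus region
#' centred at the median member summit (ties resolved to the lower
#' coordinate), re-extended by `flank` on each side and clipped to the
#' chromosome. Regions are sorted by position and assigned identifiers
#' `peak_000001, ...` in sorted order.
#'
#' @param peaksets Named list of per-sample peak data.frames (names are
#'   used as `sample_id` when the column is absent or NA).
#' @param flank Bases added on each side of a summit.
#' @param min_overlap Minimum number of distinct supporting samples.
#' @param chrom_lens Named integer vector of chromosome lengths.
#' @return Data.frame with `region_id`, `chrom`, `start`, `end`,
#'   `consensus_summit`, `n_support`.
#' @export
build_consensus <- function(peaksets, flank = 75L, min_overlap = 2L,
                            chrom_lens) {
  if (length(peaksets) < min_overlap)
    stopf("need at least min_overlap = %d peak sets, got %d",
          min_overlap, length(peaksets))
  nm <- names(peaksets) %||% as.character(seq_along(peaksets))
  ext <- do.call(rbind, lapply(seq_along(peaksets), function(i) {
    p <- peaksets[[i]]
    if (nrow(p) > 0L && (is.null(p$sample_id) || anyNA(p$sample_id)))
      p$sample_id <- nm[i]
    extend_to_fixed_width(p, flank = flank, chrom_lens = chrom_lens)
  }))
  if (nrow(ext) == 0L)
    return(empty_consensus())
  gr <- gr_from_regions(ext)
  # min.gapwidth = 0: merge only on true overlap, never bookended windows
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, clusters)
  cl <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  n_support <- vapply(split(ext$sample_id, cl),
                      function(s) length(unique(s)), integer(1))
  med_summit <- vapply(split(ext$summit, cl), function(s) {
    s <- sort(s)
    s[ceiling(length(s) / 2)]
  }, integer(1))
  chrom <- vapply(split(ext$chrom, cl), `[`, character(1), 1L)
  keep <- n_support >= min_overlap
  if (!any(keep)) return(empty_consensus())
  chrom <- chrom[keep]
  summit <- med_summit[keep]
  len <- unname(chrom_lens[chrom])
  out <- data.frame(
    chrom = chrom,
    start = pmax(summit - flank, 0L),
    end = pmin(summit + flank + 1L, len),
    consensus_summit = summit,
    n_support = n_support[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("peak_%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_consensus <- function() {
  data.frame(region_id = character(), chrom = character(),
             start = integer(), end = integer(),
             consensus_summit = integer(), n_support = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a region-by-sample count matrix
#'
#' @param counts Integer matrix, regions x samples.
#' @param regions Consensus region data.frame ([build_consensus()]).
#' @param samples Sample sheet data.frame (`sample_id`, `tissue`,
#'   `replicate`).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, regions, samples) {
  samples <- check_sample_sheet(samples)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(regions) || ncol(counts) != nrow(samples))
    stopf("counts must be %d regions x %d samples",
          nrow(regions), nrow(samples))
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (anyDuplicated(regions$region_id)) stopf("duplicated region_id")
  dimnames(counts) <- list(regions$region_id, samples$sample_id)
  structure(list(counts = counts, regions = regions, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d regions x %d samples (%d tissues)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$tissue))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Count fragments in consensus regions
#'
#' A fragment is assigned to the single region containing its midpoint
#' (`floor((start + end) / 2)`), so the counts partition fragments:
#' a fragment contributes to at most one region.
#'
#' @param fragments Named list (by `sample_id`) of BED3-style data.frames
#'   with `chrom`, `start`, `end`.
#' @param regions Consensus regions (non-overlapping).
#' @param samples Sample sheet; its `sample_id` order defines columns.
#' @return A [count_matrix()].
#' @export
count_fragments <- function(fragments, regions, samples) {
  samples <- check_sample_sheet(samples)
  miss <- setdiff(samples$sample_id, names(fragments))
  if (length(miss)) stopf("no fragments supplied for sample %s", miss[1L])
  rgr <- gr_from_regions(regions)
  counts <- vapply(samples$sample_id, function(sid) {
    fr <- fragments[[sid]]
    if (nrow(fr) == 0L) return(integer(nrow(regions)))
    if (any(fr$end <= fr$start))
      stopf("sample %s: fragment with end <= start", sid)
    mid <- (fr$start + fr$end) %/% 2L
    hit <- GenomicRanges::findOverlaps(gr_from_points(fr$chrom, mid), rgr)
    tabulate(S4Vectors::subjectHits(hit), nbins = nrow(regions))
  }, integer(nrow(regions)))
  count_matrix(counts, regions, samples)
}

#' Apply consensus inclusion filters
#'
#' A region is kept iff (a) in at least one tissue, at least
#' `ceiling(min_group_fraction * n_replicates)` of that tissue's samples
#' have a count of at least `min_count`, and (b) its total count over all
#' samples is at least `min_total`. Defaults follow the standard
#' consensus-filter settings: minimum read count 10, representation in
#' 75% of samples of some group, and a 100-read total threshold.
#'
#' @param cm A [count_matrix()].
#' @param min_count Per-sample count for a sample to "represent" a region.
#' @param min_group_fraction Required fraction of a tissue's replicates.
#' @param min_total Minimum total count across all samples.
#' @return A filtered [count_matrix()] (row order preserved).
#' @export
filter_regions <- function(cm, min_count = 10, min_group_fraction = 0.75,
                           min_total = 100) {
  if (min_group_fraction <= 0 || min_group_fraction > 1)
    stopf("min_group_fraction must be in (0, 1]")
  tiss <- cm$samples$tissue
  rep_ok <- rep(FALSE, nrow(cm$counts))
  for (t in unique(tiss)) {
    cols <- which(tiss == t)
    need <- ceiling(min_group_fraction * length(cols))
    rep_ok <- rep_ok |
      rowSums(cm$counts[, cols, drop = FALSE] >= min_count) >= need
  }
  keep <- rep_ok & rowSums(cm$counts) >= min_total
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$regions[keep, , drop = FALSE], cm$samples)
}

#' Reads-per-million normalization
#'
#' Scales each sample so its in-matrix total is one million: the library
#' size is the number of reads assigned to consensus regions, making the
#' normalization self-contained.
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix of RPM values with the same dimnames.
#' @export
rpm_normalize <- function(cm) {
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    stopf("sample %s has zero total count",
          colnames(cm$counts)[totals == 0][1L])
  sweep(cm$counts, 2L, totals, "/") * 1e6
}
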