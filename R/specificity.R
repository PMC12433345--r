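#' Per-tissue mean accessibility profiles
#'
#' Averages RPM over each tissue's replicates, giving the per-region,
#' per-tissue accessibility `Ei` that the specificity index is built on.
#'
#' @param rpm RPM matrix (regions x samples) from [rpm_normalize()].
#' @param samples Sample sheet; every column of `rpm` must appear.
#' @param tissue_order Optional tissue ordering for the output columns
#'   (also the tie-break order in [classify_specificity()]).
#' @return Numeric matrix regions x tissues of mean RPM.
#' @export
tissue_profile <- function(rpm, samples, tissue_order = NULL) {
  samples <- check_sample_sheet(samples)
  miss <- setdiff(colnames(rpm), samples$sample_id)
  if (length(miss)) stopf("sample %s has no tissue label", miss[1L])
  tiss <- samples$tissue[match(colnames(rpm), samples$sample_id)]
  tissue_order <- tissue_order %||% unique(samples$tissue)
  bad <- setdiff(unique(tiss), tissue_order)
  if (length(bad)) stopf("unknown tissue label %s", bad[1L])
  E <- vapply(tissue_order, function(t) {
    cols <- which(tiss == t)
    if (length(cols) == 0L) stopf("tissue %s has no samples", t)
    rowMeans(rpm[, cols, drop = FALSE])
  }, numeric(nrow(rpm)))
  if (nrow(rpm) == 1L) E <- matrix(E, nrow = 1L,
                                   dimnames = list(rownames(rpm), tissue_order))
  E
}

#' Relative accessibility
#'
#' `Ri = Ei / sum(E)`: the share of a region's accessibility falling in
#' tissue i. Rows (or a vector) summing to zero are returned as all-zero
#' and are treated as unclassifiable downstream.
#'
#' @param E Non-negative vector or matrix of per-tissue accessibilities.
#' @return Object of the same shape with rows summing to 1 (or 0).
#' @export
relative_accessibility <- function(E) {
  if (any(E < 0)) stopf("Ei must be >= 0")
  if (is.matrix(E)) {
    tot <- rowSums(E)
    R <- E / ifelse(tot == 0, 1, tot)
    R[tot == 0, ] <- 0
    R
  } else {
    tot <- sum(E)
    if (tot == 0) rep(0, length(E)) else E / tot
  }
}

#' Shannon entropy of a relative-accessibility profile
#'
#' `H = -sum(Ri * log2(Ri))` with the convention `0 * log2(0) = 0`.
#' H ranges from 0 (all accessibility in one tissue) to `log2(N)`
#' (uniform across N tissues). All-zero profiles are unclassifiable and
#' return `NA`.
#'
#' @param R Vector or matrix of relative accessibilities; nonzero rows
#'   must sum to 1 within 1e-6.
#' @return Entropy in bits (scalar, or per-row vector for a matrix).
#' @export
shannon_entropy <- function(R) {
  if (any(R < 0)) stopf("Ri must be >= 0")
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  tot <- rowSums(R)
  live <- tot > 0
  if (any(abs(tot[live] - 1) > 1e-6))
    stopf("Ri must sum to 1 (deviation %.3g)", max(abs(tot[live] - 1)))
  P <- R
  P[P == 0] <- 1  # 0 * log2(0) := 0
  H <- -rowSums(R * log2(P)) + 0  # + 0 normalizes IEEE negative zero
  H[!live] <- NA_real_
  unname(H)
}

#' Classify tissue-specific regions
#'
#' A region is labeled with its argmax-Ri tissue iff its entropy is
#' strictly below `h_max` and its maximal relative accessibility is at
#' least `r_min`; otherwise the label is `NA`. Argmax ties resolve to the
#' earlier column of `E` (the configured tissue order). Classification
#' depends only on Ri, so it is invariant to uniform rescaling of E.
#'
#' @param E Matrix regions x tissues of mean RPM ([tissue_profile()]).
#' @param h_max Entropy threshold in bits (strict `<`).
#' @param r_min Minimum maximal relative accessibility (inclusive `>=`).
#' @return Data.frame with `region_id`, the `E_*` and `R_*` columns,
#'   `H`, and `label` (`NA` = not tissue-specific; all-zero regions get
#'   `H = NA` and are flagged `unclassifiable`).
#' @export
classify_specificity <- function(E, h_max = 2.0, r_min = 0.33) {
  if (!is.matrix(E) || is.null(colnames(E)))
    stopf("E must be a matrix with tissue column names")
  R <- relative_accessibility(E)
  H <- shannon_entropy(R)
  rmax <- apply(R, 1L, max)
  imax <- max.col(R, ties.method = "first")
  label <- ifelse(!is.na(H) & H < h_max & rmax >= r_min,
                  colnames(E)[imax], NA_character_)
  out <- data.frame(
    region_id = rownames(E) %||% sprintf("region_%d", seq_len(nrow(E))),
    stringsAsFactors = FALSE
  )
  Edf <- as.data.frame(E)
  names(Edf) <- paste0("E_", colnames(E))
  Rdf <- as.data.frame(R)
  names(Rdf) <- paste0("R_", colnames(E))
  out <- cbind(out, Edf, Rdf)
  out$H <- H
  out$label <- label
  out$unclassifiable <- is.na(H)
  rownames(out) <- NULL
  out
}

#' Fraction of reads in peaks
#'
#' @param fragment_totals Named per-sample total fragment counts.
#' @param in_region_totals Named per-sample counts of fragments assigned
#'   to consensus regions (e.g. `colSums` of a [count_matrix()]).
#' @return Named numeric vector of FRiP scores in `[0, 1]`.
#' @export
qc_frip <- function(fragment_totals, in_region_totals) {
  if (any(fragment_totals <= 0)) stopf("fragment totals must be > 0")
  in_region_totals <- in_region_totals[names(fragment_totals)]
  if (any(in_region_totals > fragment_totals))
    stopf("in-region total exceeds fragment total for sample %s",
          names(fragment_totals)[in_region_totals > fragment_totals][1L])
  in_region_totals / fragment_totals
}

#' Percentage of regions whose summit lies in a TSS window
#'
#' A region counts when its summit falls within `[tss + window[1],
#' tss + window[2]]` in the transcript's reading direction (the window is
#' mirrored on the minus strand). The default window of -1000..+100 bp is
#' the standard promoter-proximal TSS window for this QC metric.
#'
#' @param regions Consensus regions (uses `consensus_summit`, falling
#'   back to the interval midpoint).
#' @param transcripts A `transcript_models` object or its `transcripts`
#'   data.frame.
#' @param window Length-2 integer vector, strand-oriented offsets
#'   relative to the TSS (inclusive).
#' @return Percentage in `[0, 100]`.
#' @export
tss_peak_fraction <- function(regions, transcripts,
                              window = c(-1000L, 100L)) {
  if (nrow(regions) == 0L) stopf("empty region set")
  tx <- if (inherits(transcripts, "transcript_models"))
    transcripts$transcripts else transcripts
  summit <- regions$consensus_summit %||% region_midpoint(regions)
  if (nrow(tx) == 0L) return(0)
  lo <- ifelse(tx$strand == "-", tx$tss - window[2L], tx$tss + window[1L])
  hi <- ifelse(tx$strand == "-", tx$tss - window[1L], tx$tss + window[2L])
  win <- GenomicRanges::GRanges(tx$chrom,
                                IRanges::IRanges(lo + 1L, hi + 1L))
  pts <- gr_from_points(regions$chrom, summit)
  100 * mean(suppressWarnings(IRanges::overlapsAny(pts, win)))
}

#' Pearson correlation between samples on log RPM
#'
#' @param rpm RPM matrix (regions x samples).
#' @param pseudo Pseudo-count added before `log10` (zeros are common in
#'   sparse regions).
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal; zero-variance samples give `NA` off-diagonals.
#' @export
sample_correlation <- function(rpm, pseudo = 1.0) {
  if (ncol(rpm) < 2L) stopf("need at least 2 samples")
  C <- suppressWarnings(cor(log10(rpm + pseudo)))
  diag(C) <- 1
  C
}

#' Genomic context of consensus regions
#'
#' Assigns each region's midpoint one of `promoter`, `exon`, `intron`,
#' `other`, in that precedence order across all overlapping transcripts.
#' The promoter is the `promoter_up` bp upstream of (and including) the
#' TSS, strand-oriented; intron means inside a transcript span but not in
#' an exon.
#'
#' @param regions Consensus regions.
#' @param transcripts A `transcript_models` object.
#' @param promoter_up Promoter extent upstream of the TSS, in bp.
#' @return Character vector of context labels, one per region.
#' @export
genomic_context <- function(regions, transcripts, promoter_up = 3000L) {
  tx <- transcripts$transcripts
  ex <- transcripts$exons
  mid <- region_midpoint(regions)
  pts <- gr_from_points(regions$chrom, mid)
  lab <- rep("other", nrow(regions))
  if (nrow(tx) > 0L) {
    span <- gr_from_regions(tx)
    lab[suppressWarnings(IRanges::overlapsAny(pts, span))] <- "intron"
  }
  if (nrow(ex) > 0L)
    lab[suppressWarnings(
      IRanges::overlapsAny(pts, gr_from_regions(ex)))] <- "exon"
  if (nrow(tx) > 0L) {
    lo <- ifelse(tx$strand == "-", tx$tss, tx$tss - promoter_up)
    hi <- ifelse(tx$strand == "-", tx$tss + promoter_up, tx$tss)
    prom <- GenomicRanges::GRanges(tx$chrom,
                                   IRanges::IRanges(lo + 1L, hi + 1L))
    lab[suppressWarnings(IRanges::overlapsAny(pts, prom))] <- "promoter"
  }
  lab
}

#' Fragment-length histogram
#'
#' @param fragments BED3-style data.frame, or a named list of them
#'   (pooled).
#' @return Data.frame with `length` (bp) and `count`.
#' @export
fragment_length_hist <- function(fragments) {
  if (is.data.frame(fragments)) fragments <- list(fragments)
  w <- unlist(lapply(fragments, function(f) f$end - f$start),
              use.names = FALSE)
  tb <- table(w)
  data.frame(length = as.integer(names(tb)), count = as.integer(tb))
}

#' Assemble a QC report
#'
#' Bundles the per-sample FRiP scores, the TSS-proximal peak percentage,
#' the pairwise sample correlation on log10 RPM, a pooled fragment-length
#' histogram, and a TSS enrichment fold (fragment-midpoint density within
#' 500 bp of a TSS relative to the genome-wide density).
#'
#' @param cm A filtered [count_matrix()].
#' @param rpm Its RPM matrix.
#' @param fragments Named list of per-sample fragment data.frames, or
#'   `NULL` to skip fragment-based metrics.
#' @param fragment_totals Named per-sample total fragment counts (defaults
#'   to the sizes of `fragments`).
#' @param transcripts A `transcript_models` object.
#' @param chrom_lens Named chromosome lengths (for the density baseline).
#' @return A list of class `qc_report`.
#' @export
qc_report <- function(cm, rpm, fragments = NULL, fragment_totals = NULL,
                      transcripts, chrom_lens) {
  if (is.null(fragment_totals) && !is.null(fragments))
    fragment_totals <- vapply(fragments, nrow, integer(1))
  frip <- if (!is.null(fragment_totals))
    qc_frip(fragment_totals, colSums(cm$counts)) else NULL
  tssf <- tss_peak_fraction(cm$regions, transcripts)
  sc <- sample_correlation(rpm)
  flh <- if (!is.null(fragments)) fragment_length_hist(fragments) else NULL
  tsse <- if (!is.null(fragments))
    tss_enrichment(fragments, transcripts, chrom_lens) else NULL
  structure(list(frip = frip, tss_peak_fraction = tssf,
                 sample_correlation = sc,
                 fragment_length_histogram = flh,
                 tss_enrichment = tsse),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  if (!is.null(x$frip))
    cat(sprintf("  FRiP: mean %.3f (range %.3f-%.3f)\n",
                mean(x$frip), min(x$frip), max(x$frip)))
  cat(sprintf("  %% TSS peaks: %.2f\n", x$tss_peak_fraction))
  if (!is.null(x$tss_enrichment))
    cat(sprintf("  TSS enrichment fold: %.2f\n", x$tss_enrichment))
  invisible(x)
}

tss_enrichment <- function(fragments, transcripts, chrom_lens,
                           half_window = 500L) {
  tx <- transcripts$transcripts
  if (nrow(tx) == 0L) return(NA_real_)
  win <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(pmax(tx$tss - half_window, 0L) + 1L,
                     tx$tss + half_window + 1L)
  ))
  win_bp <- sum(BiocGenerics::width(win))
  tot_bp <- sum(as.numeric(chrom_lens))
  n_in <- 0; n_all <- 0
  for (fr in fragments) {
    mid <- (fr$start + fr$end) %/% 2L
    n_in <- n_in + sum(IRanges::overlapsAny(
      gr_from_points(fr$chrom, mid), win))
    n_all <- n_all + nrow(fr)
  }
  (n_in / win_bp) / (n_all / tot_bp)
}
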