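#' Pair consensus regions with promoter-proximal transcripts
#'
#' A (region, transcript) pair is emitted when the region midpoint lies
#' within `window` bp of the transcript's TSS on either side (inclusive,
#' strand-agnostic: the +/- window is symmetric). One region may pair
#' with many transcripts and vice versa.
#'
#' @param regions Consensus regions.
#' @param transcripts A `transcript_models` object or its `transcripts`
#'   data.frame.
#' @param window Half-width of the promoter window in bp.
#' @return Data.frame `region_id`, `transcript_id`, `gene_id`, `tss`,
#'   `distance` (midpoint minus TSS, signed).
#' @export
map_promoter_pairs <- function(regions, transcripts, window = 3000L) {
  tx <- if (inherits(transcripts, "transcript_models"))
    transcripts$transcripts else transcripts
  if (nrow(regions) == 0L || nrow(tx) == 0L)
    return(data.frame(region_id = character(), transcript_id = character(),
                      gene_id = character(), tss = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  mid <- region_midpoint(regions)
  pts <- gr_from_points(regions$chrom, mid)
  win <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$tss - window + 1L, tx$tss + window + 1L)
  )
  hit <- suppressWarnings(GenomicRanges::findOverlaps(pts, win))
  q <- S4Vectors::queryHits(hit)
  s <- S4Vectors::subjectHits(hit)
  data.frame(
    region_id = regions$region_id[q],
    transcript_id = tx$transcript_id[s],
    gene_id = tx$gene_id[s],
    tss = tx$tss[s],
    distance = mid[q] - tx$tss[s],
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation with a two-sided t test
#'
#' `p` comes from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t
#' distribution with `n - 2` degrees of freedom; perfect correlations
#' (`r = +/-1`) report `p = 0`. Zero variance in either vector makes the
#' correlation undefined and both values are returned as `NA`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3L) stopf("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("x and y must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Per-tissue cis correlation of promoter accessibility and expression
#'
#' For every promoter (region, transcript) pair and every tissue,
#' correlates the region's RPM with the gene's expression across that
#' tissue's replicates. Sample pairing is by shared `sample_id` between
#' the two matrices. A Benjamini-Hochberg adjusted p-value within each
#' tissue is emitted alongside the raw one.
#'
#' @param rpm RPM matrix (regions x samples).
#' @param expr Expression matrix (genes x samples; same sample IDs).
#' @param pairs Output of [map_promoter_pairs()].
#' @param samples Sample sheet.
#' @return Data.frame of `CisPair` records: `gene_id`, `transcript_id`,
#'   `region_id`, `tissue`, `r`, `p`, `p_adj`, `n`.
#' @export
cis_correlate <- function(rpm, expr, pairs, samples) {
  samples <- check_sample_sheet(samples)
  shared <- intersect(colnames(rpm), colnames(expr))
  shared <- intersect(shared, samples$sample_id)
  if (length(shared) == 0L) stopf("no shared samples between rpm and expr")
  pairs <- pairs[pairs$region_id %in% rownames(rpm) &
                   pairs$gene_id %in% rownames(expr), , drop = FALSE]
  tiss <- samples$tissue[match(shared, samples$sample_id)]
  out <- list()
  for (t in unique(tiss)) {
    cols <- shared[tiss == t]
    if (length(cols) < 3L) next
    X <- rpm[pairs$region_id, cols, drop = FALSE]
    Y <- expr[pairs$gene_id, cols, drop = FALSE]
    n <- length(cols)
    sx <- apply(X, 1L, sd)
    sy <- apply(Y, 1L, sd)
    zx <- (X - rowMeans(X))
    zy <- (Y - rowMeans(Y))
    r <- rowSums(zx * zy) / ((n - 1) * sx * sy)
    r[sx == 0 | sy == 0] <- NA_real_
    r <- pmin(pmax(r, -1), 1)
    p <- ifelse(abs(r) >= 1, 0,
                2 * pt(-abs(r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))),
                       df = n - 2))
    out[[t]] <- data.frame(
      gene_id = pairs$gene_id, transcript_id = pairs$transcript_id,
      region_id = pairs$region_id, tissue = t, r = unname(r),
      p = unname(p), p_adj = p.adjust(unname(p), method = "BH"),
      n = n, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Best positive cis pair per gene and tissue
#'
#' Keeps pairs with `r > 0` and `p < alpha`, then retains for every
#' (gene, tissue) the pair with the highest correlation coefficient.
#' Also tabulates per-tissue gene counts and all tissue-set intersection
#' counts (UpSet data) over genes.
#'
#' @param cis Data.frame from [cis_correlate()].
#' @param alpha Raw p-value threshold.
#' @return List with `pairs` (one row per gene x tissue), `per_tissue`
#'   (gene counts), and `intersections` (all non-empty tissue subsets).
#' @export
best_positive_cis <- function(cis, alpha = 0.05) {
  keep <- !is.na(cis$r) & cis$r > 0 & !is.na(cis$p) & cis$p < alpha
  q <- cis[keep, , drop = FALSE]
  tissues <- unique(cis$tissue)
  if (nrow(q) == 0L) {
    return(list(pairs = q,
                per_tissue = data.frame(tissue = tissues, n_genes = 0L,
                                        stringsAsFactors = FALSE),
                intersections = data.frame(tissues = character(),
                                           degree = integer(),
                                           count = integer(),
                                           stringsAsFactors = FALSE)))
  }
  q <- q[order(q$gene_id, q$tissue, -q$r), , drop = FALSE]
  best <- q[!duplicated(q[, c("gene_id", "tissue")]), , drop = FALSE]
  rownames(best) <- NULL
  per_tissue <- data.frame(
    tissue = tissues,
    n_genes = vapply(tissues, function(t)
      sum(best$tissue == t), integer(1)),
    stringsAsFactors = FALSE
  )
  pattern <- vapply(split(best$tissue, best$gene_id), function(ts)
    paste(tissues[tissues %in% ts], collapse = "&"), character(1))
  subsets <- unlist(lapply(seq_along(tissues), function(k)
    utils::combn(tissues, k, paste, collapse = "&")))
  inter <- data.frame(
    tissues = subsets,
    degree = lengths(strsplit(subsets, "&", fixed = TRUE)),
    count = vapply(subsets, function(s)
      sum(pattern == s), integer(1)),
    stringsAsFactors = FALSE
  )
  list(pairs = best, per_tissue = per_tissue, intersections = inter)
}

#' Expression support for tissue-unique motifs
#'
#' For every motif unique to a tissue, checks whether its transcription
#' factor is expressed there (mean expression at least `expr_min`) and
#' whether that expression is tissue-specific: the motif's tissue must
#' have the maximal mean and a one-sided Welch two-sample test against
#' every other tissue must reject at `alpha`.
#'
#' @param unique_sets Named list (tissue -> motif names), e.g.
#'   `unique_motifs(...)$unique`.
#' @param expr Expression matrix (genes x samples).
#' @param samples Sample sheet.
#' @param tf_map Data.frame mapping motifs to genes, columns `motif`
#'   (or `tf_name`) and `gene_id`; TFs without a mapping fall back to a
#'   case-insensitive match of the TF name against `rownames(expr)`.
#' @param expr_min Expression floor for "expressed".
#' @param alpha Per-comparison significance level of the Welch tests.
#' @return List with `records` (data.frame `motif`, `tf_gene`, `tissue`,
#'   `expressed`, `tissue_specific_expression`, `mean_<tissue>` columns)
#'   and `skipped` (unmappable TF names).
#' @export
tf_support <- function(unique_sets, expr, samples, tf_map = NULL,
                       expr_min = 1.0, alpha = 0.05) {
  samples <- check_sample_sheet(samples)
  tiss <- samples$tissue[match(colnames(expr), samples$sample_id)]
  tissues <- unique(samples$tissue)
  map_gene <- function(motif) {
    if (!is.null(tf_map)) {
      key <- tf_map$motif %||% tf_map$tf_name
      i <- match(motif, key)
      if (!is.na(i)) return(tf_map$gene_id[i])
    }
    tf <- sub("[(/].*$", "", motif)
    i <- match(toupper(tf), toupper(rownames(expr)))
    if (!is.na(i)) rownames(expr)[i] else NA_character_
  }
  rows <- list()
  skipped <- character()
  for (t in names(unique_sets)) {
    for (m in unique_sets[[t]]) {
      g <- map_gene(m)
      if (is.na(g) || !(g %in% rownames(expr))) {
        skipped <- c(skipped, m)
        next
      }
      vals <- split(expr[g, ], tiss)
      means <- vapply(vals, mean, numeric(1))[tissues]
      expressed <- means[[t]] >= expr_min
      specific <- FALSE
      if (expressed && means[[t]] == max(means)) {
        pv <- vapply(setdiff(tissues, t), function(o) {
          if (sd(vals[[t]]) == 0 && sd(vals[[o]]) == 0)
            return(if (mean(vals[[t]]) > mean(vals[[o]])) 0 else 1)
          t.test(vals[[t]], vals[[o]], alternative = "greater")$p.value
        }, numeric(1))
        specific <- all(pv < alpha)
      }
      rec <- data.frame(motif = m, tf_gene = g, tissue = t,
                        expressed = expressed,
                        tissue_specific_expression = specific,
                        stringsAsFactors = FALSE)
      for (tt in tissues) rec[[paste0("mean_", tt)]] <- means[[tt]]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(), tf_gene = character(),
               tissue = character(), expressed = logical(),
               tissue_specific_expression = logical(),
               stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records, skipped = unique(skipped))
}
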