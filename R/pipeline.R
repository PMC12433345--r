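#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its standard
#' default: summit flank 75 bp, support from at least 2 peak sets,
#' minimum read count 10 with 75% group representation and a 100-read
#' total, entropy below 2 bits with relative accessibility at least
#' 0.33, motif significance at p < 0.001 with a 2:1 GC-matched
#' background, promoter window of +/-3 kb, cis significance at p < 0.05,
#' and the -1000..+100 bp TSS QC window.
#'
#' @param seed Seed driving background sampling (and simulation when the
#'   pipeline generates its own inputs).
#' @param flank,min_overlap,min_count,group_frac,min_total Consensus
#'   construction and filter settings.
#' @param h_max,r_min Specificity classification thresholds.
#' @param motif_alpha,bg_ratio,gc_bin Motif enrichment settings.
#' @param cis_alpha,promoter_window Integration settings.
#' @param tss_window TSS QC window (strand-oriented offsets).
#' @param expr_min,tf_alpha TF expression-support settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 7L, flank = 75L, min_overlap = 2L,
                            min_count = 10, group_frac = 0.75,
                            min_total = 100, h_max = 2.0, r_min = 0.33,
                            motif_alpha = 0.001, bg_ratio = 2,
                            gc_bin = 0.05, cis_alpha = 0.05,
                            promoter_window = 3000L,
                            tss_window = c(-1000L, 100L),
                            expr_min = 1.0, tf_alpha = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_comments <- function(cfg) {
  vapply(names(cfg), function(k)
    sprintf("%s=%s", k, paste(cfg[[k]], collapse = ",")), character(1))
}

write_tsv_audit <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the full analysis
#'
#' Executes consensus construction, specificity classification, motif
#' enrichment and accessibility-expression integration on a bundle of
#' inputs (a simulated [simulate_bundle()] or a directory loaded with
#' [load_bundle_dir()]), optionally writing all result tables plus a run
#' manifest to `out_dir`. Stage progress and timing go to `stderr`.
#'
#' @param bundle Input bundle: needs `peaks`, `samples`, `chrom_lens`;
#'   `fragments` (or simulated counts), `genome`, `models`, `motifs`,
#'   `expr`, `tf_gene_map` enable the later stages.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param config A [pipeline_config()].
#' @param fragments Optional named list of per-sample fragment
#'   data.frames overriding `bundle$fragments`.
#' @return A list of class `pipeline_result` with the per-stage outputs
#'   and the manifest.
#' @export
run_pipeline <- function(bundle, out_dir = NULL,
                         config = pipeline_config(), fragments = NULL) {
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] starting (seed %d)", name, config$seed))
    out <- tryCatch(force(expr), error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  samples <- check_sample_sheet(bundle$samples)
  tissues <- unique(samples$tissue)

  cons <- stage("consensus", {
    regions <- build_consensus(bundle$peaks, flank = config$flank,
                               min_overlap = config$min_overlap,
                               chrom_lens = bundle$chrom_lens)
    fr <- fragments %||% bundle$fragments
    if (is.null(fr) && inherits(bundle, "atac_bundle"))
      fr <- simulate_fragments(bundle)
    if (is.null(fr))
      stopf("no fragments available; supply fragments= or a counts matrix")
    cm <- count_fragments(fr, regions, samples)
    cmf <- filter_regions(cm, min_count = config$min_count,
                          min_group_fraction = config$group_frac,
                          min_total = config$min_total)
    list(raw = cm, filtered = cmf, rpm = rpm_normalize(cmf),
         fragment_totals = vapply(fr, nrow, integer(1)))
  })

  spec <- stage("specificity", {
    E <- tissue_profile(cons$rpm, samples, tissue_order = tissues)
    cls <- classify_specificity(E, h_max = config$h_max,
                                r_min = config$r_min)
    qc <- if (!is.null(bundle$models))
      qc_report(cons$filtered, cons$rpm,
                fragment_totals = cons$fragment_totals,
                transcripts = bundle$models,
                chrom_lens = bundle$chrom_lens)
    list(classified = cls, qc = qc)
  })

  mot <- NULL
  if (!is.null(bundle$genome) && !is.null(bundle$motifs)) {
    mot <- stage("motifs", {
      recs <- list()
      for (i in seq_along(tissues)) {
        t <- tissues[i]
        ids <- spec$classified$region_id[!is.na(spec$classified$label) &
                                           spec$classified$label == t]
        tr <- cons$filtered$regions[
          cons$filtered$regions$region_id %in% ids, , drop = FALSE]
        if (nrow(tr) == 0L) next
        bg <- sample_background(bundle$genome, tr, ratio = config$bg_ratio,
                                gc_bin = config$gc_bin,
                                seed = config$seed + 7000L + i)
        recs[[t]] <- enrich_tissue(region_seqs(bundle$genome, tr),
                                   region_seqs(bundle$genome, bg),
                                   bundle$motifs,
                                   alpha = config$motif_alpha, tissue = t)
      }
      pmat <- enrichment_matrix(recs)
      um <- unique_motifs(pmat, alpha = config$motif_alpha)
      cv <- suppressWarnings(rank_by_cv(-log10(pmat)))
      list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
           pmat = pmat, unique = um, cv = cv)
    })
  }

  integ <- NULL
  if (!is.null(bundle$expr) && !is.null(bundle$models)) {
    integ <- stage("integration", {
      pairs <- map_promoter_pairs(cons$filtered$regions, bundle$models,
                                  window = config$promoter_window)
      cis <- cis_correlate(cons$rpm, bundle$expr, pairs, samples)
      best <- best_positive_cis(cis, alpha = config$cis_alpha)
      tf <- if (!is.null(mot))
        tf_support(mot$unique$unique, bundle$expr, samples,
                   tf_map = bundle$tf_gene_map,
                   expr_min = config$expr_min, alpha = config$tf_alpha)
      list(pairs = pairs, cis = cis, best = best, tf = tf)
    })
  }

  manifest <- list(
    package = "entropeaks",
    version = as.character(utils::packageVersion("entropeaks")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = unclass(config),
    stages = list(
      consensus = list(n_regions_raw = nrow(cons$raw$counts),
                       n_regions_filtered = nrow(cons$filtered$counts)),
      specificity = list(
        n_specific = sum(!is.na(spec$classified$label)),
        per_tissue = as.list(table(spec$classified$label))),
      motifs = if (!is.null(mot)) list(
        n_significant = mot$unique$n_significant,
        n_unique = sum(lengths(mot$unique$unique))),
      integration = if (!is.null(integ)) list(
        n_pairs_tested = nrow(integ$cis),
        n_cis = nrow(integ$best$pairs))
    ),
    elapsed_s = round(proc.time()[["elapsed"]] - t_all, 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cmt <- config_comments(config)
    fp <- function(x) file.path(out_dir, x)
    write_bed(cons$filtered$regions, fp("consensus.bed"))
    write_matrix_tsv(cons$filtered$counts, fp("counts.tsv"),
                     id_col = "region_id", comments = cmt)
    write_matrix_tsv(cons$rpm, fp("rpm.tsv"), id_col = "region_id",
                     comments = cmt)
    write_tsv_audit(spec$classified, fp("specificity.tsv"), cmt)
    if (!is.null(mot)) {
      write_tsv_audit(mot$records, fp("motif_enrichment.tsv"), cmt)
      write_matrix_tsv(mot$pmat, fp("motif_pvalue_matrix.tsv"),
                       id_col = "motif", comments = cmt)
      write_tsv_audit(mot$unique$intersections, fp("motif_upset.tsv"), cmt)
      if (nrow(mot$cv)) write_tsv_audit(mot$cv, fp("motif_cv.tsv"), cmt)
    }
    if (!is.null(integ)) {
      write_tsv_audit(integ$cis, fp("cis_pairs_all.tsv"), cmt)
      write_tsv_audit(integ$best$pairs, fp("cis_pairs_best.tsv"), cmt)
      write_tsv_audit(integ$best$per_tissue, fp("cis_per_tissue.tsv"), cmt)
      write_tsv_audit(integ$best$intersections, fp("cis_upset.tsv"), cmt)
      if (!is.null(integ$tf) && nrow(integ$tf$records))
        write_tsv_audit(integ$tf$records, fp("tf_support.tsv"), cmt)
    }
    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(consensus = cons, specificity = spec, motifs = mot,
                 integration = integ, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n")
  cat(sprintf("  consensus: %d regions (%d before filters)\n",
              m$stages$consensus$n_regions_filtered,
              m$stages$consensus$n_regions_raw))
  cat(sprintf("  tissue-specific regions: %d\n",
              m$stages$specificity$n_specific))
  if (!is.null(m$stages$motifs))
    cat(sprintf("  significant motifs: %d (%d tissue-unique)\n",
                m$stages$motifs$n_significant, m$stages$motifs$n_unique))
  if (!is.null(m$stages$integration))
    cat(sprintf("  cis pairs: %d (of %d tested)\n",
                m$stages$integration$n_cis,
                m$stages$integration$n_pairs_tested))
  invisible(x)
}
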