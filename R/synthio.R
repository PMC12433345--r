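#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the pipeline is built for: six
#' tissues (amygdala, hippocampus, hypothalamus, thalamus, adrenal and
#' pituitary glands) with eight replicates each, negative-binomial peak
#' counts with moderate biological dispersion, a 0.6 expected relative
#' accessibility for planted tissue-specific loci, one planted motif per
#' tissue, and promoter-linked expression at correlation 0.9 for 30% of
#' genes.
#'
#' @param seed Master seed; each generator stage derives its own stream
#'   from it (stage offsets), so stages are independently reproducible.
#' @param tissues Tissue names.
#' @param replicates Replicates per tissue.
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param gc Genome GC fraction.
#' @param n_shared Number of shared (non-specific) accessible loci.
#' @param n_specific Tissue-specific loci per tissue.
#' @param specificity_fraction Expected relative accessibility of a
#'   specific locus in its target tissue (must exceed `1/length(tissues)`).
#' @param nb_mean Expected reads per peak per sample for a shared locus;
#'   per-tissue means scale with the locus's tissue share.
#' @param nb_dispersion Negative-binomial dispersion
#'   (`var = mu + dispersion * mu^2`).
#' @param planted_motif Named character vector, one consensus per tissue.
#' @param motif_plant_rate Fraction of a tissue's specific loci carrying
#'   its motif.
#' @param background_plant_rate Chance a shared locus carries some motif.
#' @param n_genes Number of genes/transcripts.
#' @param rho_pos Planted within-tissue promoter correlation.
#' @param frac_corr_genes Fraction of genes given a planted correlation.
#' @param peak_halfwidth Half-width of emitted narrowPeak intervals.
#' @param fragment_len Fragment length (midpoint at the locus summit).
#' @param min_locus_gap Minimum spacing between locus summits.
#' @param peak_min_count Per-sample count below which no narrowPeak entry
#'   is emitted for a locus.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 7L,
                       tissues = c("Amy", "Hip", "HT", "Tal", "AG", "PG"),
                       replicates = 8L,
                       n_chrom = 2L,
                       chrom_len = 1000000L,
                       gc = 0.42,
                       n_shared = 3000L,
                       n_specific = 100L,
                       specificity_fraction = 0.6,
                       nb_mean = 50,
                       nb_dispersion = 0.2,
                       planted_motif = c(Amy = "TGACTCAGGT",
                                         Hip = "CAGCTGCCAA",
                                         HT = "TAATTACGCT",
                                         Tal = "GGGCGGAAGT",
                                         AG = "GATAAGGATA",
                                         PG = "CACGTGACTT"),
                       motif_plant_rate = 0.8,
                       background_plant_rate = 0.02,
                       n_genes = 500L,
                       rho_pos = 0.9,
                       frac_corr_genes = 0.3,
                       peak_halfwidth = 100L,
                       fragment_len = 150L,
                       min_locus_gap = 300L,
                       peak_min_count = 5L) {
  if (specificity_fraction <= 1 / length(tissues))
    stopf("specificity_fraction must exceed 1/%d", length(tissues))
  if (motif_plant_rate <= 0 || motif_plant_rate > 1)
    stopf("motif_plant_rate must be in (0, 1]")
  if (any(c(replicates, n_chrom, chrom_len, n_shared, n_specific) <= 0))
    stopf("design counts must be positive")
  if (!all(tissues %in% names(planted_motif)))
    stopf("planted_motif must name one consensus per tissue")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> seed %d: %d tissues x %d reps, %d chrom x %s bp,\n",
    "  %d shared + %d x %d specific loci (f = %.2f), NB(mean %.0f, disp %.2f)\n"),
    x$seed, length(x$tissues), x$replicates, x$n_chrom,
    format(x$chrom_len, big.mark = ","), x$n_shared, length(x$tissues),
    x$n_specific, x$specificity_fraction, x$nb_mean, x$nb_dispersion))
  invisible(x)
}

# Per-tissue PWM built from a consensus string: matching base 0.97,
# others 0.01; threshold defaults to 80% of the maximal score.
consensus_pwm <- function(name, consensus, match_prob = 0.97) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  probs <- matrix((1 - match_prob) / 3, nrow = 4L, ncol = length(bases),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <-
    match_prob
  pwm(name = name, probs = probs, consensus = consensus)
}

revcomp_string <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

#' Generate a random genome and transcript annotation
#'
#' Chromosomes are i.i.d. bases at the configured GC fraction; genes are
#' non-overlapping transcripts with random strands and 2-5 exons.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character vector), `chrom_lens`,
#'   and `models` (a `transcript_models` object).
#' @export
simulate_genome <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
           G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
    chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
    genome <- vapply(chroms, function(ch)
      paste(sample(names(p), cfg$chrom_len, replace = TRUE, prob = p),
            collapse = ""), character(1))
    chrom_lens <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms)
    if (cfg$n_genes == 0L)
      return(list(genome = genome, chrom_lens = chrom_lens,
                  models = transcript_models()))
    per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chrom + 1)))
    tx_rows <- list()
    ex_rows <- list()
    gi <- 0L
    for (ci in seq_along(chroms)) {
      n <- per_chrom[ci]
      if (n == 0L) next
      placed <- IRanges::IRanges()
      tries <- 0L
      while (length(placed) < n) {
        tries <- tries + 1L
        if (tries > 200L)
          stopf("could not place %d genes on %s; use longer chromosomes",
                n, chroms[ci])
        k <- n - length(placed)
        len <- sample(800:2500, k, replace = TRUE)
        st <- floor(runif(k, 100, cfg$chrom_len - max(len) - 100))
        cand <- IRanges::IRanges(start = st, width = len)
        ok <- !IRanges::overlapsAny(cand, placed)
        # drop within-batch overlaps, keeping earlier candidates
        hit <- IRanges::findOverlaps(cand, cand)
        dup <- unique(S4Vectors::queryHits(hit)[
          S4Vectors::queryHits(hit) > S4Vectors::subjectHits(hit)])
        ok[dup] <- FALSE
        placed <- c(placed, cand[ok])
      }
      placed <- placed[order(BiocGenerics::start(placed))]
      for (j in seq_along(placed)) {
        gi <- gi + 1L
        s0 <- BiocGenerics::start(placed)[j]  # already 0-based by construction
        e0 <- s0 + BiocGenerics::width(placed)[j]
        strand <- sample(c("+", "-"), 1L)
        k_ex <- sample(2:5, 1L)
        bp <- sort(sample((s0 + 1L):(e0 - 1L), 2L * (k_ex - 1L)))
        ex_start <- c(s0, bp[seq(2L, length(bp), by = 2L)])
        ex_end <- c(bp[seq(1L, length(bp), by = 2L)], e0)
        biotype <- sample(c("protein_coding", "lncRNA", "other"), 1L,
                          prob = c(0.70, 0.25, 0.05))
        tx_rows[[gi]] <- data.frame(
          transcript_id = sprintf("T%04d", gi),
          gene_id = sprintf("G%04d", gi),
          chrom = chroms[ci], strand = strand, start = s0, end = e0,
          tss = if (strand == "-") e0 - 1L else s0,
          biotype = biotype, stringsAsFactors = FALSE
        )
        ex_rows[[gi]] <- data.frame(
          transcript_id = sprintf("T%04d", gi), chrom = chroms[ci],
          start = ex_start, end = ex_end, stringsAsFactors = FALSE
        )
      }
    }
    list(genome = genome, chrom_lens = chrom_lens,
         models = transcript_models(do.call(rbind, tx_rows),
                                    do.call(rbind, ex_rows)))
  })
}

# Place locus summits: ~30% of shared loci inside promoter windows (to
# exercise the accessibility-expression integration), the rest on a
# jittered grid that guarantees the minimum summit spacing.
simulate_loci <- function(cfg, models, chrom_lens) {
  with_seed(cfg$seed + 202L, {
    tissues <- cfg$tissues
    n_loci <- cfg$n_shared + length(tissues) * cfg$n_specific
    tx <- models$transcripts
    n_prom <- if (nrow(tx) > 0L) round(0.3 * cfg$n_shared) else 0L
    prom <- data.frame(chrom = character(), summit = integer(),
                       stringsAsFactors = FALSE)
    if (n_prom > 0L) {
      acc_ch <- character(0)
      acc_pos <- integer(0)
      tries <- 0L
      while (length(acc_pos) < n_prom) {
        tries <- tries + 1L
        if (tries > 50L * n_prom)
          stopf("could not place promoter loci; use longer chromosomes")
        i <- sample.int(nrow(tx), 1L)
        pos <- tx$tss[i] + sample(-2500:2500, 1L)
        ch <- tx$chrom[i]
        if (pos < 200L || pos > chrom_lens[ch] - 200L) next
        same <- acc_pos[acc_ch == ch]
        if (length(same) && min(abs(same - pos)) < cfg$min_locus_gap) next
        acc_ch <- c(acc_ch, ch)
        acc_pos <- c(acc_pos, pos)
      }
      prom <- data.frame(chrom = acc_ch, summit = acc_pos,
                         stringsAsFactors = FALSE)
    }
    n_grid <- n_loci - n_prom
    usable <- sum(chrom_lens - 1000)
    # grid step: keep summit spacing >= min_locus_gap (after +/-50 jitter)
    # while leaving slack for candidates lost near promoter-placed summits
    step <- max(cfg$min_locus_gap + 100L,
                floor(usable / (n_grid + 2.5 * n_prom + 100)))
    if (floor(usable / step) < n_grid)
      stopf("cannot fit %d loci at %d bp spacing; use longer chromosomes",
            n_loci, cfg$min_locus_gap)
    cand <- do.call(rbind, lapply(names(chrom_lens), function(ch) {
      centers <- seq(500L, chrom_lens[ch] - 500L, by = step)
      data.frame(chrom = ch,
                 summit = as.integer(centers + sample(-50:50,
                                                      length(centers),
                                                      replace = TRUE)),
                 stringsAsFactors = FALSE)
    }))
    # drop grid candidates too close to a promoter-placed summit
    if (nrow(prom) > 0L) {
      pgr <- gr_from_points(prom$chrom, prom$summit)
      pgr <- GenomicRanges::resize(pgr, width = 2L * cfg$min_locus_gap,
                                   fix = "center")
      cand <- cand[!IRanges::overlapsAny(
        gr_from_points(cand$chrom, cand$summit), pgr), , drop = FALSE]
    }
    if (nrow(cand) < n_grid)
      stopf("only %d candidate positions for %d loci; use longer chromosomes",
            nrow(cand), n_grid)
    grid <- cand[sample.int(nrow(cand), n_grid), , drop = FALSE]
    prom$forced_shared <- rep(TRUE, nrow(prom))
    grid$forced_shared <- rep(FALSE, nrow(grid))
    loci <- rbind(prom, grid)
    types <- c(rep("shared", cfg$n_shared - n_prom),
               rep(tissues, each = cfg$n_specific))
    free <- which(!loci$forced_shared)
    loci$type <- "shared"
    loci$type[free] <- sample(types)
    loci <- loci[order(loci$chrom, loci$summit), , drop = FALSE]
    loci$locus_id <- sprintf("locus_%05d", seq_len(nrow(loci)))
    loci$start <- loci$summit - cfg$peak_halfwidth
    loci$end <- loci$summit + cfg$peak_halfwidth
    rownames(loci) <- NULL
    loci[, c("locus_id", "chrom", "start", "end", "summit", "type")]
  })
}

# Negative-binomial counts: per-sample mean = nb_mean * N * tissue share,
# where shares are uniform for shared loci and f / (1-f)/(N-1) for
# specific loci; var = mu + dispersion * mu^2.
simulate_counts <- function(cfg, loci, samples) {
  with_seed(cfg$seed + 303L, {
    tissues <- cfg$tissues
    N <- length(tissues)
    share <- matrix(1 / N, nrow = nrow(loci), ncol = N,
                    dimnames = list(loci$locus_id, tissues))
    for (t in tissues) {
      rows <- loci$type == t
      share[rows, ] <- (1 - cfg$specificity_fraction) / (N - 1)
      share[rows, t] <- cfg$specificity_fraction
    }
    mu <- cfg$nb_mean * N * share[, samples$tissue, drop = FALSE]
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
      nrow = nrow(loci),
      dimnames = list(loci$locus_id, samples$sample_id)
    )
    counts
  })
}

peaks_from_counts <- function(cfg, loci, counts, samples) {
  out <- lapply(samples$sample_id, function(sid) {
    keep <- counts[, sid] >= cfg$peak_min_count
    n <- sum(keep)
    cnt <- counts[keep, sid]
    data.frame(
      chrom = loci$chrom[keep], start = loci$start[keep],
      end = loci$end[keep],
      name = paste0(loci$locus_id[keep], "_", sid),
      score = pmin(as.numeric(cnt), 1000), strand = ".",
      signal = cnt / 10, pvalue_nlog10 = cnt / 5,
      qvalue_nlog10 = cnt / 10,
      summit_offset = cfg$peak_halfwidth,
      sample_id = sid, stringsAsFactors = FALSE
    )
  })
  names(out) <- samples$sample_id
  out
}

#' Per-sample fragment intervals for a simulated bundle
#'
#' Emits one fixed-length fragment per counted read, with its midpoint at
#' the locus summit.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @return Named list of BED3-style data.frames.
#' @export
simulate_fragments <- function(bundle) {
  cfg <- bundle$config
  half <- cfg$fragment_len %/% 2L
  loci <- bundle$truth_regions
  out <- lapply(colnames(bundle$counts), function(sid) {
    cnt <- bundle$counts[, sid]
    idx <- rep.int(seq_along(cnt), cnt)
    data.frame(chrom = loci$chrom[idx],
               start = loci$summit[idx] - half,
               end = loci$summit[idx] - half + cfg$fragment_len,
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(bundle$counts)
  out
}

# Write each tissue's motif into motif_plant_rate of its specific loci
# (random strand, random offset within +/-40 bp of the summit, so planted
# instances stay inside the 151-bp consensus window); shared loci carry a
# random motif at background_plant_rate.
plant_motifs <- function(cfg, genome, loci) {
  with_seed(cfg$seed + 404L, {
    planted <- rep(NA_character_, nrow(loci))
    ins_ch <- character(0); ins_pos <- integer(0); ins_seq <- character(0)
    for (t in cfg$tissues) {
      cons <- cfg$planted_motif[[t]]
      L <- nchar(cons)
      rows <- which(loci$type == t)
      # deterministic planted count: exactly plant_rate of the loci
      hit <- rows[sample.int(length(rows),
                             round(cfg$motif_plant_rate * length(rows)))]
      if (length(hit) == 0L) next
      off <- sample(-40:40, length(hit), replace = TRUE)
      rc <- runif(length(hit)) < 0.5
      seqs <- ifelse(rc, revcomp_string(cons), cons)
      pos <- loci$summit[hit] + off - L %/% 2L
      if (any(L > loci$end[hit] - loci$start[hit]))
        stopf("motif %s longer than its target region", t)
      ins_ch <- c(ins_ch, loci$chrom[hit])
      ins_pos <- c(ins_pos, pos)
      ins_seq <- c(ins_seq, seqs)
      planted[hit] <- t
    }
    sh <- which(loci$type == "shared")
    bg_hit <- sh[runif(length(sh)) < cfg$background_plant_rate]
    if (length(bg_hit) > 0L) {
      bt <- sample(cfg$tissues, length(bg_hit), replace = TRUE)
      cons <- cfg$planted_motif[bt]
      rc <- runif(length(bg_hit)) < 0.5
      seqs <- ifelse(rc, vapply(cons, revcomp_string, character(1)), cons)
      ins_ch <- c(ins_ch, loci$chrom[bg_hit])
      ins_pos <- c(ins_pos, loci$summit[bg_hit] +
                     sample(-40:40, length(bg_hit), replace = TRUE) -
                     nchar(cons) %/% 2L)
      ins_seq <- c(ins_seq, unname(seqs))
      planted[bg_hit] <- bt
    }
    for (ch in unique(ins_ch)) {
      s <- genome[[ch]]
      idx <- which(ins_ch == ch)
      for (i in idx)
        substr(s, ins_pos[i] + 1L, ins_pos[i] + nchar(ins_seq[i])) <-
          ins_seq[i]
      genome[[ch]] <- s
    }
    loci$planted_motif <- planted
    list(genome = genome, loci = loci)
  })
}

# Expression: selected genes with a promoter-proximal locus track that
# locus's RPM within each tissue at correlation rho_pos; other genes are
# independent noise; one designated TF gene per tissue is strongly
# over-expressed there so the motif expression-support filter has signal.
simulate_expression <- function(cfg, loci, counts, models, samples) {
  with_seed(cfg$seed + 505L, {
    tx <- models$transcripts
    n_genes <- nrow(tx)
    rpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
    genes <- tx$gene_id
    expr <- matrix(0, nrow = n_genes, ncol = nrow(samples),
                   dimnames = list(genes, samples$sample_id))
    mu_g <- rlnorm(n_genes, meanlog = 3, sdlog = 1)
    sig_g <- 0.25 * mu_g
    for (i in seq_len(n_genes))
      expr[i, ] <- pmax(mu_g[i] + sig_g[i] * rnorm(nrow(samples)), 0)
    # candidate (gene, locus) promoter links
    pts <- gr_from_points(loci$chrom, loci$summit)
    win <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$tss - 3000L + 1L, tx$tss + 3000L + 1L))
    hit <- GenomicRanges::findOverlaps(pts, win)
    cand <- data.frame(locus = S4Vectors::queryHits(hit),
                       gene = S4Vectors::subjectHits(hit))
    cand <- cand[order(cand$gene,
                       abs(loci$summit[cand$locus] - tx$tss[cand$gene])), ]
    cand <- cand[!duplicated(cand$gene), , drop = FALSE]  # nearest locus
    n_corr <- round(cfg$frac_corr_genes * n_genes)
    if (nrow(cand) < n_corr) {
      message(sprintf(
        "only %d genes have a promoter-proximal locus; planting %d correlations",
        nrow(cand), nrow(cand)))
      n_corr <- nrow(cand)
    }
    pick <- cand[sample.int(nrow(cand), n_corr), , drop = FALSE]
    rho <- cfg$rho_pos
    for (j in seq_len(nrow(pick))) {
      g <- pick$gene[j]
      l <- pick$locus[j]
      y <- numeric(nrow(samples))
      for (t in cfg$tissues) {
        cols <- which(samples$tissue == t)
        x <- rpm[l, cols]
        zx <- if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
        y[cols] <- rho * zx + sqrt(max(0, 1 - rho^2)) * rnorm(length(cols))
      }
      expr[g, ] <- pmax(mu_g[g] + sig_g[g] * y, 0)
    }
    # TF genes: one per tissue, excluded from the correlated set
    tf_pool <- setdiff(seq_len(n_genes), pick$gene)
    tf_idx <- sample(tf_pool, length(cfg$tissues))
    names(tf_idx) <- cfg$tissues
    for (t in cfg$tissues) {
      g <- tf_idx[[t]]
      on_cols <- which(samples$tissue == t)
      off_cols <- which(samples$tissue != t)
      expr[g, on_cols] <- pmax(50 * (1 + 0.1 * rnorm(length(on_cols))), 0)
      expr[g, off_cols] <- pmax(1 + 0.3 * rnorm(length(off_cols)), 0)
    }
    truth_genes <- data.frame(
      gene_id = genes,
      rho = ifelse(seq_len(n_genes) %in% pick$gene, rho, 0),
      linked_locus = NA_character_,
      tf_tissue = NA_character_, stringsAsFactors = FALSE
    )
    truth_genes$linked_locus[pick$gene] <- loci$locus_id[pick$locus]
    truth_genes$tf_tissue[tf_idx] <- cfg$tissues
    tf_gene_map <- data.frame(
      motif = paste0("TF_", cfg$tissues),
      tf_name = paste0("TF_", cfg$tissues),
      gene_id = genes[tf_idx], stringsAsFactors = FALSE
    )
    list(expr = expr, truth_genes = truth_genes, tf_gene_map = tf_gene_map)
  })
}

#' Generate the full synthetic bundle
#'
#' Runs all generator stages (genome and annotation, locus placement,
#' motif planting, counts, expression) and returns every pipeline input
#' plus the ground truth, in memory. All stages are deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `atac_bundle`: `config`, `genome` (with planted
#'   motifs), `chrom_lens`, `models`, `samples`, `truth_regions` (loci
#'   with `type` and `planted_motif`), `counts` (truth loci x samples),
#'   `peaks` (per-sample narrowPeak data.frames), `expr`, `truth_genes`,
#'   `tf_gene_map`, `motifs` (the planted [pwm()] library).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  gen <- simulate_genome(cfg)
  loci <- simulate_loci(cfg, gen$models, gen$chrom_lens)
  pl <- plant_motifs(cfg, gen$genome, loci)
  samples <- data.frame(
    sample_id = paste0(rep(cfg$tissues, each = cfg$replicates), "_r",
                       rep(seq_len(cfg$replicates), length(cfg$tissues))),
    tissue = rep(cfg$tissues, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), length(cfg$tissues)),
    stringsAsFactors = FALSE
  )
  counts <- simulate_counts(cfg, pl$loci, samples)
  peaks <- peaks_from_counts(cfg, pl$loci, counts, samples)
  ex <- simulate_expression(cfg, pl$loci, counts, gen$models, samples)
  motifs <- lapply(cfg$tissues, function(t)
    consensus_pwm(paste0("TF_", t), cfg$planted_motif[[t]]))
  names(motifs) <- paste0("TF_", cfg$tissues)
  structure(
    list(config = cfg, genome = pl$genome, chrom_lens = gen$chrom_lens,
         models = gen$models, samples = samples, truth_regions = pl$loci,
         counts = counts, peaks = peaks, expr = ex$expr,
         truth_genes = ex$truth_genes, tf_gene_map = ex$tf_gene_map,
         motifs = motifs),
    class = "atac_bundle"
  )
}

#' @export
print.atac_bundle <- function(x, ...) {
  cat(sprintf(
    "<atac_bundle> %d loci x %d samples, %d genes, %d planted motifs\n",
    nrow(x$truth_regions), ncol(x$counts), nrow(x$expr), length(x$motifs)))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits every external-format pipeline input: `genome.fa`, `anno.gtf`,
#' `samples.tsv`, one `<sample>.narrowPeak` and `<sample>.fragments.bed`
#' per sample, `expr.tsv`, `counts.tsv`, `truth_regions.tsv`,
#' `truth_genes.tsv`, `tf_gene_map.tsv` and `planted.motifs`.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param dir Output directory (created if missing).
#' @param fragments Write per-sample fragment BEDs (the bulkiest files).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, fragments = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(bundle$genome, fp("genome.fa"))
  write_gtf(bundle$models, fp("anno.gtf"))
  write.table(bundle$samples, fp("samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(bundle$counts, fp("counts.tsv"), id_col = "locus_id")
  write_matrix_tsv(bundle$expr, fp("expr.tsv"), id_col = "gene_id")
  write.table(bundle$truth_regions, fp("truth_regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth_genes, fp("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$tf_gene_map, fp("tf_gene_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_homer_motifs(bundle$motifs, fp("planted.motifs"))
  for (sid in bundle$samples$sample_id)
    write_narrowpeak(bundle$peaks[[sid]], fp(paste0(sid, ".narrowPeak")))
  if (fragments) {
    frags <- simulate_fragments(bundle)
    for (sid in names(frags))
      data.table::fwrite(frags[[sid]], fp(paste0(sid, ".fragments.bed")),
                         sep = "\t", col.names = FALSE)
  }
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @param fragments Also load per-sample fragment BEDs.
#' @return A list shaped like [simulate_bundle()] output (without
#'   `config`), plus `fragments` when requested.
#' @export
load_bundle_dir <- function(dir, fragments = TRUE) {
  fp <- function(x) file.path(dir, x)
  samples <- read_sample_sheet(fp("samples.tsv"))
  genome <- read_fasta(fp("genome.fa"))
  models <- read_gtf(fp("anno.gtf"))
  peaks <- lapply(samples$sample_id, function(sid)
    read_narrowpeak(fp(paste0(sid, ".narrowPeak")), sample_id = sid))
  names(peaks) <- samples$sample_id
  out <- list(
    genome = genome, chrom_lens = nchar(genome), models = models,
    samples = samples, peaks = peaks,
    expr = if (file.exists(fp("expr.tsv"))) read_matrix_tsv(fp("expr.tsv")),
    motifs = if (file.exists(fp("planted.motifs")))
      read_homer_motifs(fp("planted.motifs")),
    tf_gene_map = if (file.exists(fp("tf_gene_map.tsv")))
      read.delim(fp("tf_gene_map.tsv"), stringsAsFactors = FALSE)
  )
  if (fragments) {
    out$fragments <- lapply(samples$sample_id, function(sid)
      read_bed(fp(paste0(sid, ".fragments.bed"))))
    names(out$fragments) <- samples$sample_id
  }
  out
}
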