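# Base encoding used by the scanner: A=1 C=2 G=3 T=4, anything else 5 (N).
encode_seq <- function(seq) {
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

#' Log-odds score matrix for a PWM
#'
#' `score[b, j] = log2(probs[b, j] / background[b])`, with probabilities
#' floored at 1e-3 before the ratio so zero-probability bases stay finite.
#' A fifth row handles ambiguous (N) bases, which contribute a flat
#' -10 bits at any position.
#'
#' @param pwm A [pwm()] object.
#' @param background Named base frequencies (A, C, G, T), all > 0,
#'   summing to 1.
#' @return 5 x L numeric matrix (rows A, C, G, T, N) of scores in bits.
#' @export
log_odds_matrix <- function(pwm,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  background <- background[c("A", "C", "G", "T")]
  if (anyNA(background) || any(background <= 0))
    stopf("background frequencies must be > 0 for A, C, G, T")
  if (abs(sum(background) - 1) > 1e-6)
    stopf("background frequencies must sum to 1")
  lom <- log2(pmax(pwm$probs, 1e-3) / background)
  rbind(lom, N = rep(-10, ncol(lom)))
}

# Scores of all length-L windows of an encoded sequence against a 5 x L
# log-odds matrix; returns numeric(0) when the sequence is shorter than L.
window_scores <- function(code, lom) {
  L <- ncol(lom)
  n <- length(code)
  if (n < L) return(numeric(0))
  m <- n - L + 1L
  S <- numeric(m)
  for (j in seq_len(L)) S <- S + lom[, j][code[j:(j + m - 1L)]]
  unname(S)
}

revcomp_code <- function(code) c(4L, 3L, 2L, 1L, 5L)[rev(code)]

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands (the reverse strand is the
#' reverse complement scored with the same matrix) and reports windows
#' whose total log-odds score reaches the motif's threshold. Positions
#' are 0-based, forward-strand leftmost. Sequences shorter than the motif
#' yield an empty hit list.
#'
#' @param seq A DNA string over `A, C, G, T, N`.
#' @param pwm A [pwm()] object.
#' @param background Base frequencies passed to [log_odds_matrix()].
#' @return Data.frame with `position`, `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm,
                     background = c(A = 0.25, C = 0.25,
                                    G = 0.25, T = 0.25)) {
  lom <- log_odds_matrix(pwm, background)
  code <- encode_seq(seq)
  L <- ncol(lom)
  n <- length(code)
  fwd <- window_scores(code, lom)
  rev_ <- window_scores(revcomp_code(code), lom)
  thr <- pwm$log_odds_threshold
  hf <- which(fwd >= thr)
  hr <- which(rev_ >= thr)
  out <- data.frame(
    position = c(hf - 1L, n - (hr - 1L) - L),
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = c(fwd[hf], rev_[hr]),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

# TRUE per sequence iff the motif hits at least once on either strand.
motif_indicator <- function(seqs, pwm, background) {
  lom <- log_odds_matrix(pwm, background)
  thr <- pwm$log_odds_threshold
  vapply(seqs, function(s) {
    code <- encode_seq(s)
    any(window_scores(code, lom) >= thr) ||
      any(window_scores(revcomp_code(code), lom) >= thr)
  }, logical(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    code <- encode_seq(s)
    mean(code == 2L | code == 3L)
  }, numeric(1), USE.NAMES = FALSE)
}

base_frequencies <- function(seqs) {
  code <- unlist(lapply(seqs, encode_seq), use.names = FALSE)
  n <- tabulate(code, nbins = 4L)
  if (sum(n) == 0L) return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  p <- n / sum(n)
  p <- pmax(p, 1e-4)
  p <- p / sum(p)
  names(p) <- c("A", "C", "G", "T")
  p
}

#' Sample GC-matched background windows
#'
#' Draws `ratio` background windows per target from the genome, matching
#' the target windows' length distribution exactly and their GC
#' distribution per `gc_bin`-wide bin (quotas by largest-remainder
#' rounding). Background windows overlap neither the excluded regions
#' (the targets, by default) nor each other. Sampling is deterministic
#' given `seed`. Bins that cannot be filled after `max_rounds` batches of
#' oversampling are topped up from the nearest filled bin, with a
#' warning.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param targets Target regions (`chrom`, `start`, `end`).
#' @param ratio Background windows per target window.
#' @param gc_bin GC bin width.
#' @param exclude Regions background windows must not overlap.
#' @param seed Integer seed for reproducible draws.
#' @param max_rounds Oversampling rounds before nearest-bin fallback.
#' @return Data.frame with `chrom`, `start`, `end`, `gc`.
#' @export
sample_background <- function(genome, targets, ratio = 2, gc_bin = 0.05,
                              exclude = targets, seed = 1L,
                              max_rounds = 1000L) {
  if (nrow(targets) == 0L) stopf("no target regions")
  tseq <- region_seqs(genome, targets)
  tgc <- gc_fraction(tseq)
  bin_of <- function(gc) pmin(floor(gc / gc_bin), floor(1 / gc_bin) - 1)
  tbin <- bin_of(tgc)
  n_total <- round(ratio * nrow(targets))
  # largest-remainder apportionment of n_total over the target bins
  tab <- table(tbin)
  raw <- n_total * as.numeric(tab) / nrow(targets)
  quota <- floor(raw)
  rem <- n_total - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  names(quota) <- names(tab)
  lens <- targets$end - targets$start
  chrom_lens <- nchar(genome)
  with_seed(seed, {
    taken <- gr_from_regions(exclude)
    got <- vector("list", 0L)
    need <- quota
    rounds <- 0L
    while (sum(need) > 0L && rounds < max_rounds) {
      rounds <- rounds + 1L
      nb <- max(4L * sum(need), 64L)
      w <- lens[sample.int(length(lens), nb, replace = TRUE)]
      ch <- sample(names(genome), nb, replace = TRUE,
                   prob = chrom_lens / sum(chrom_lens))
      maxs <- chrom_lens[ch] - w
      ok <- maxs >= 0
      st <- floor(runif(nb, 0, maxs + 1))
      cand <- data.frame(chrom = ch, start = as.integer(st),
                         end = as.integer(st + w),
                         stringsAsFactors = FALSE)[ok, , drop = FALSE]
      if (nrow(cand) == 0L) next
      cgr <- gr_from_regions(cand)
      free <- !IRanges::overlapsAny(cgr, taken)
      # also reject overlaps within the batch itself
      self_hit <- GenomicRanges::findOverlaps(cgr, cgr)
      dup <- unique(S4Vectors::queryHits(self_hit)[
        S4Vectors::queryHits(self_hit) > S4Vectors::subjectHits(self_hit)])
      free[dup] <- FALSE
      cand <- cand[free, , drop = FALSE]
      if (nrow(cand) == 0L) next
      cand$gc <- gc_fraction(region_seqs(genome, cand))
      cbin <- as.character(bin_of(cand$gc))
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        b <- cbin[i]
        if (!is.na(need[b]) && need[b] > 0L) {
          keep[i] <- TRUE
          need[b] <- need[b] - 1L
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > 0L) {
        got[[length(got) + 1L]] <- cand
        taken <- c(taken, gr_from_regions(cand))
      }
    }
    out <- if (length(got)) do.call(rbind, got) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 gc = numeric(), stringsAsFactors = FALSE)
    if (sum(need) > 0L) {
      warnf("could not fill %d background windows in their GC bin; using nearest bins",
            sum(need))
      # relax: accept any non-overlapping window, nearest unmet bin first
      while (sum(need) > 0L) {
        w <- lens[sample.int(length(lens), 1L)]
        ch <- sample(names(genome), 1L, prob = chrom_lens / sum(chrom_lens))
        if (chrom_lens[ch] < w) next
        st <- floor(runif(1L, 0, chrom_lens[ch] - w + 1))
        cand <- data.frame(chrom = ch, start = as.integer(st),
                           end = as.integer(st + w),
                           stringsAsFactors = FALSE)
        if (IRanges::overlapsAny(gr_from_regions(cand), taken)) next
        cand$gc <- gc_fraction(region_seqs(genome, cand))
        b <- names(need)[need > 0L]
        nearest <- b[which.min(abs(as.numeric(b) - bin_of(cand$gc)))]
        need[nearest] <- need[nearest] - 1L
        out <- rbind(out, cand)
        taken <- c(taken, gr_from_regions(cand))
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` items without replacement from a
#' population of `M` items of which `K` are successes. Computed via the
#' numerically stable distribution-function implementation in
#' `stats::phyper`.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param M Population size.
#' @return Tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, M) {
  if (any(c(k, K, n, M) < 0) || K > M || n > M || k > min(K, n))
    stopf("inconsistent hypergeometric counts (k=%s K=%s n=%s M=%s)",
          k, K, n, M)
  min(1, phyper(k - 1, K, M - K, n, lower.tail = FALSE))
}

#' Known-motif enrichment in one tissue's target set
#'
#' For every motif, counts the target and background sequences containing
#' at least one hit (overlapping hits and both strands count once), and
#' tests over-representation with the upper-tail hypergeometric
#' probability: population = targets plus backgrounds, successes =
#' motif-containing sequences, draws = the target set. Fold enrichment is
#' `(k_t/n_t) / (k_b/n_b)`; an infinite fold (no background hits) is
#' reported as the capped sentinel 1e6.
#'
#' @param target_seqs Character vector of target sequences.
#' @param background_seqs Character vector of background sequences.
#' @param motifs List of [pwm()] objects.
#' @param alpha Significance threshold on the raw p-value.
#' @param background_freq Base frequencies for log-odds scoring; default
#'   is the composition of the background sequences.
#' @param tissue Optional tissue name recorded in the output.
#' @return Data.frame with one row per motif: `motif`, `tissue`,
#'   `n_target`, `k_target`, `n_background`, `k_background`, `p`, `fold`,
#'   `significant`.
#' @export
enrich_tissue <- function(target_seqs, background_seqs, motifs,
                          alpha = 0.001, background_freq = NULL,
                          tissue = NA_character_) {
  if (length(target_seqs) == 0L || length(background_seqs) == 0L)
    stopf("target and background sets must be non-empty")
  bg <- background_freq %||% base_frequencies(background_seqs)
  n_t <- length(target_seqs)
  n_b <- length(background_seqs)
  rows <- lapply(motifs, function(p) {
    k_t <- sum(motif_indicator(target_seqs, p, bg))
    k_b <- sum(motif_indicator(background_seqs, p, bg))
    pv <- hypergeom_tail(k_t, k_t + k_b, n_t, n_t + n_b)
    fold <- if (k_b == 0) {
      if (k_t == 0) 0 else 1e6
    } else (k_t / n_t) / (k_b / n_b)
    data.frame(motif = p$name, tissue = tissue, n_target = n_t,
               k_target = k_t, n_background = n_b, k_background = k_b,
               p = pv, fold = fold, significant = pv < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif x tissue p-value matrix
#'
#' @param records Named list of per-tissue [enrich_tissue()] results, or
#'   a single data.frame with a `tissue` column.
#' @return Numeric matrix of p-values, motifs as rows, tissues as
#'   columns.
#' @export
enrichment_matrix <- function(records) {
  if (is.data.frame(records))
    records <- split(records, records$tissue)[unique(records$tissue)]
  motifs <- unique(unlist(lapply(records, `[[`, "motif")))
  m <- matrix(NA_real_, nrow = length(motifs), ncol = length(records),
              dimnames = list(motifs, names(records)))
  for (t in names(records)) {
    r <- records[[t]]
    m[r$motif, t] <- r$p
  }
  m
}

#' Uniquely-significant motifs and intersection counts
#'
#' A motif is unique to a tissue when it is significant (`p < alpha`) in
#' exactly that tissue. Also tabulates all `2^N - 1` non-empty tissue-set
#' intersection counts (UpSet data): each significant motif contributes
#' to exactly the set it is significant in.
#'
#' @param pmat Motif x tissue p-value matrix ([enrichment_matrix()]).
#' @param alpha Significance threshold.
#' @return List with `unique` (named list of motif names per tissue),
#'   `n_significant` (motifs significant in at least one tissue), and
#'   `intersections` (data.frame `tissues`, `degree`, `count` over all
#'   non-empty subsets).
#' @export
unique_motifs <- function(pmat, alpha = 0.001) {
  sig <- !is.na(pmat) & pmat < alpha
  tissues <- colnames(pmat)
  pattern <- apply(sig, 1L, function(r) paste(tissues[r], collapse = "&"))
  uniq <- lapply(tissues, function(t)
    rownames(pmat)[rowSums(sig) == 1L & sig[, t]])
  names(uniq) <- tissues
  subsets <- unlist(lapply(seq_along(tissues), function(k)
    utils::combn(tissues, k, paste, collapse = "&")))
  counts <- vapply(subsets, function(s) sum(pattern == s), integer(1))
  list(
    unique = uniq,
    n_significant = sum(rowSums(sig) >= 1L),
    intersections = data.frame(
      tissues = subsets,
      degree = lengths(strsplit(subsets, "&", fixed = TRUE)),
      count = as.integer(counts), stringsAsFactors = FALSE
    )
  )
}

#' Rank motifs by coefficient of variation of enrichment
#'
#' Operates on a motif x tissue matrix of enrichment scores
#' (`-log10(p)`). Motifs with mean score above `mean_min` are ranked by
#' CV (= sd / mean) in decreasing order and the top `top_k` returned.
#'
#' @param score_mat Matrix of `-log10(p)` enrichment scores.
#' @param mean_min Minimum mean score (strict `>`).
#' @param top_k Number of motifs to return.
#' @return Data.frame `motif`, `mean`, `cv`, ordered by decreasing CV.
#' @export
rank_by_cv <- function(score_mat, mean_min = 20, top_k = 50) {
  mu <- rowMeans(score_mat, na.rm = TRUE)
  keep <- which(mu > mean_min)
  if (length(keep) == 0L) {
    warnf("no motifs with mean enrichment > %g", mean_min)
    return(data.frame(motif = character(), mean = numeric(),
                      cv = numeric(), stringsAsFactors = FALSE))
  }
  cv <- apply(score_mat[keep, , drop = FALSE], 1L, sd, na.rm = TRUE) /
    mu[keep]
  ord <- order(cv, decreasing = TRUE)
  if (length(ord) < top_k)
    warnf("only %d motifs pass the mean filter (requested %d)",
          length(ord), top_k)
  sel <- head(ord, top_k)
  data.frame(motif = rownames(score_mat)[keep][sel],
             mean = unname(mu[keep][sel]), cv = unname(cv[sel]),
             stringsAsFactors = FALSE)
}
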