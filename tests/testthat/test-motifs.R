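# Non-palindromic 4-mer favouring TGAC; threshold 4 bits admits only the
# exact match under a uniform background (one mismatch scores < 2 bits).
tgac_pwm <- function(threshold = 4) {
  probs <- matrix(0.01, nrow = 4L, ncol = 4L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[cbind(c(4L, 3L, 1L, 2L), 1:4)] <- 0.97
  pwm("TGAC_test", probs, log_odds_threshold = threshold)
}

test_that("log-odds scores are log2 ratios with a probability floor", {
  p <- pwm("half", matrix(rep(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3), 4),
                          nrow = 4L), log_odds_threshold = 1)
  lom <- log_odds_matrix(p)
  expect_equal(unname(lom["A", 1]), 1)  # log2(0.5 / 0.25)
  flat <- pwm("flat", matrix(0.25, 4, 4), log_odds_threshold = 1)
  expect_equal(unname(log_odds_matrix(flat)[1:4, ]),
               matrix(0, 4, 4))
  zerop <- pwm("zero", matrix(c(0.999, 0.001, 0, 0,
                                0.25, 0.25, 0.25, 0.25,
                                0.25, 0.25, 0.25, 0.25,
                                0.25, 0.25, 0.25, 0.25), nrow = 4),
               log_odds_threshold = 1)
  lom0 <- log_odds_matrix(zerop)
  expect_equal(unname(lom0["C", 1]), log2(0.001 / 0.25))  # floored at 1e-3
  expect_equal(unname(lom0["G", 1]), log2(0.001 / 0.25))  # true zero also floored
  expect_equal(unname(lom0["N", 1]), -10)
  expect_error(log_odds_matrix(p, c(A = 0.5, C = 0.5, G = 0, T = 0)),
               "> 0")
})

test_that("scanning finds exact-match windows on both strands", {
  p <- tgac_pwm()
  fwd <- scan_pwm("GGTGACGG", p)
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$position, 2L)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$score, 4 * log2(0.97 / 0.25))
  # reverse complement of the same sequence: one minus-strand hit at the
  # forward-leftmost position of the embedded GTCA
  rev_ <- scan_pwm("CCGTCACC", p)
  expect_equal(nrow(rev_), 1L)
  expect_equal(rev_$position, 2L)
  expect_equal(rev_$strand, "-")
  expect_equal(nrow(scan_pwm("GGGGGGGG", p)), 0L)
  expect_equal(nrow(scan_pwm("TGA", p)), 0L)  # shorter than the motif
  # N bases never contribute positive score
  expect_equal(nrow(scan_pwm("NNTNACNN", p)), 0L)
})

test_that("scanner agrees with the naive per-window oracle", {
  set.seed(21)
  p <- tgac_pwm(threshold = 2)  # permissive: plenty of near-hits
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (i in 1:100) {
    s <- random_dna(sample(10:60, 1), gc = runif(1, 0.3, 0.7))
    if (runif(1) < 0.3)  # sprinkle ambiguous bases
      substr(s, 2, 3) <- "NN"
    got <- scan_pwm(s, p, background = bg)
    want <- naive_scan(s, p, background = bg)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("hypergeometric tail matches exact enumeration", {
  expect_equal(hypergeom_tail(5, 6, 10, 20), 13013 / 184756,
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 6, 10, 20), 1.0)
  expect_equal(hypergeom_tail(4, 4, 4, 4), 1.0)  # forced degenerate draw
  for (M in c(5L, 12L, 25L)) {
    for (K in 0:M) {
      for (n in 0:M) {
        for (k in max(0, n - (M - K)):min(K, n)) {
          expect_equal(hypergeom_tail(k, K, n, M), hyper_exact(k, K, n, M),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeom_tail(5, 2, 10, 20), "inconsistent")
})

test_that("no-enrichment configurations are never significant", {
  # k_t * n_b = k_b * n_t: equal hit rates give p >= 0.5
  for (cfg in list(c(5, 10, 10, 20), c(2, 10, 4, 20), c(0, 10, 0, 30))) {
    p <- hypergeom_tail(cfg[1], cfg[1] + cfg[3], cfg[2], cfg[2] + cfg[4])
    expect_gte(p, 0.5)
  }
})

test_that("planted motifs enrich in targets but not in matched sets", {
  set.seed(31)
  # 8-mer: long enough that chance hits in a 60-mer are rare
  probs <- matrix(0.01, nrow = 4L, ncol = 8L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[cbind(match(strsplit("TGACCGTT", "")[[1]],
                    c("A", "C", "G", "T")), 1:8)] <- 0.97
  p <- pwm("planted8", probs, log_odds_threshold = 10)
  plant <- function(s, motif = "TGACCGTT") {
    pos <- sample(nchar(s) - nchar(motif), 1)
    substr(s, pos, pos + nchar(motif) - 1L) <- motif
    s
  }
  targets <- replicate(200, random_dna(60))
  targets[1:160] <- vapply(targets[1:160], plant, character(1))
  bg <- replicate(400, random_dna(60))
  bg[1:20] <- vapply(bg[1:20], plant, character(1))
  rec <- enrich_tissue(targets, bg, list(p), tissue = "AG")
  expect_true(rec$significant)
  expect_lt(rec$p, 1e-10)
  expect_gt(rec$fold, 5)
  # identical target and background sets: fold 1, not significant
  same <- enrich_tissue(targets, targets, list(p))
  expect_equal(same$fold, 1)
  expect_false(same$significant)
  expect_gte(same$p, 0.5)
  # a motif absent everywhere: k = 0, p = 1
  none <- enrich_tissue(replicate(50, random_dna(20, gc = 0)),
                        replicate(50, random_dna(20, gc = 0)),
                        list(tgac_pwm()))
  expect_equal(none$k_target, 0L)
  expect_equal(none$p, 1.0)
})

test_that("background windows are GC-matched, non-overlapping, reproducible", {
  set.seed(41)
  genome <- c(chr1 = random_dna(60000, gc = 0.42),
              chr2 = random_dna(60000, gc = 0.42))
  targets <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 5L),
    start = rep(seq(1000L, 41000L, by = 10000L), 2L),
    stringsAsFactors = FALSE
  )
  targets$end <- targets$start + 151L
  bg <- sample_background(genome, targets, ratio = 2, seed = 99)
  expect_equal(nrow(bg), 20L)
  expect_equal(unique(bg$end - bg$start), 151L)
  tg <- GenomicRanges::GRanges(targets$chrom,
                               IRanges::IRanges(targets$start + 1L,
                                                targets$end))
  bgr <- GenomicRanges::GRanges(bg$chrom,
                                IRanges::IRanges(bg$start + 1L, bg$end))
  expect_false(any(IRanges::overlapsAny(bgr, tg)))
  expect_equal(sum(IRanges::overlapsAny(bgr, bgr)), 20L)  # only self-hits
  # GC histogram matches the target histogram within one window per bin
  tgc <- table(floor(20 * (sapply(strsplit(region_seqs(genome, targets),
                                           ""), function(x)
    mean(x %in% c("G", "C")))))) * 2
  bgc <- table(floor(20 * bg$gc))
  for (b in names(tgc))
    expect_lte(abs(tgc[[b]] - ifelse(b %in% names(bgc), bgc[[b]], 0L)), 1L)
  # determinism
  bg2 <- sample_background(genome, targets, ratio = 2, seed = 99)
  expect_identical(bg, bg2)
  expect_false(identical(
    bg, sample_background(genome, targets, ratio = 2, seed = 100)))
})

test_that("unique motifs and intersection counts partition significance", {
  pmat <- rbind(
    m_ag = c(1e-5, 1, 1, 1, 1, 1),
    m_agpg = c(1e-5, 1, 1, 1, 1, 1e-4),
    m_none = rep(0.5, 6),
    m_all = rep(1e-9, 6)
  )
  colnames(pmat) <- c("AG", "Amy", "Hip", "HT", "Tal", "PG")
  um <- unique_motifs(pmat, alpha = 0.001)
  expect_equal(um$unique$AG, "m_ag")
  expect_equal(um$n_significant, 3L)
  inter <- um$intersections
  expect_equal(nrow(inter), 2^6 - 1)
  expect_equal(inter$count[inter$tissues == "AG"], 1L)
  expect_equal(inter$count[inter$tissues == "AG&PG"], 1L)
  expect_equal(inter$count[inter$tissues == paste(colnames(pmat),
                                                  collapse = "&")], 1L)
  expect_equal(sum(inter$count), 3L)
})

test_that("CV ranking filters on mean enrichment and orders by dispersion", {
  scores <- rbind(
    flat = rep(60, 6),                  # CV 0
    onetissue = c(360, 0, 0, 0, 0, 0),  # mean 60, max CV
    twotissue = c(180, 180, 0, 0, 0, 0),
    weak = rep(10, 6)                   # mean 10: excluded
  )
  colnames(scores) <- paste0("t", 1:6)
  expect_warning(rk <- rank_by_cv(scores, mean_min = 20, top_k = 50),
                 "only 3")
  expect_equal(rk$motif, c("onetissue", "twotissue", "flat"))
  expect_equal(rk$cv[3], 0)
  expect_false("weak" %in% rk$motif)
})
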