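six <- c("Amy", "Hip", "HT", "Tal", "AG", "PG")

samples6 <- function(reps = 2L) {
  data.frame(sample_id = paste0(rep(six, each = reps), "_r",
                                rep(seq_len(reps), 6L)),
             tissue = rep(six, each = reps),
             replicate = rep(seq_len(reps), 6L), stringsAsFactors = FALSE)
}

test_that("tissue profiles average RPM over replicates", {
  s <- samples6(2L)
  rpm <- matrix(0, nrow = 2L, ncol = 12L,
                dimnames = list(c("r1", "r2"), s$sample_id))
  rpm["r1", ] <- rep(c(100, 300), 6L)
  rpm["r2", ] <- seq_len(12L)
  E <- tissue_profile(rpm, s)
  expect_equal(unname(E["r1", ]), rep(200, 6L))
  # permuting replicate columns changes nothing
  E2 <- tissue_profile(rpm[, sample(ncol(rpm))], s)
  expect_equal(E2, E[rownames(E2), colnames(E2)])
  # single replicate per tissue: profile equals that sample
  s1 <- samples6(1L)
  rpm1 <- matrix(seq_len(6L), nrow = 1L,
                 dimnames = list("r1", s1$sample_id))
  expect_equal(unname(tissue_profile(rpm1, s1)[1, ]), as.numeric(1:6))
  colnames(rpm)[1] <- "mystery"
  expect_error(tissue_profile(rpm, s), "no tissue label")
})

test_that("relative accessibility normalizes to shares", {
  expect_equal(relative_accessibility(c(10, 0, 0, 0, 0, 0)),
               c(1, 0, 0, 0, 0, 0))
  expect_equal(relative_accessibility(rep(7, 6)), rep(1 / 6, 6))
  expect_equal(relative_accessibility(c(6, 2, 2, 0, 0, 0)),
               c(0.6, 0.2, 0.2, 0, 0, 0))
  expect_equal(relative_accessibility(rep(0, 6)), rep(0, 6))
  expect_error(relative_accessibility(c(-1, 2)), ">= 0")
})

test_that("entropy matches brute force on random simplex vectors", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 6, 6)), log2(6))
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0, 0, 0)), 1.0)
  set.seed(5)
  for (i in 1:1000) {
    r <- rexp(6)
    r <- r / sum(r)
    brute <- 0
    for (x in r) if (x > 0) brute <- brute - x * log2(x)
    expect_equal(shannon_entropy(r), brute, tolerance = 1e-12)
    expect_true(shannon_entropy(r) >= 0 && shannon_entropy(r) <= log2(6))
  }
  expect_true(is.na(shannon_entropy(rep(0, 6))))
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("classification applies strict entropy and inclusive Ri bounds", {
  E <- rbind(
    onehot = c(10, 0, 0, 0, 0, 0),
    uniform = rep(5, 6),
    # dyadic profile with H exactly 2 bits and max Ri 0.5
    boundary = c(0.5, 0.125, 0.125, 0.125, 0.125, 0) * 8,
    zero = rep(0, 6)
  )
  colnames(E) <- six
  cls <- classify_specificity(E)
  expect_equal(cls$label[1], "Amy")
  expect_true(is.na(cls$label[2]))
  expect_equal(cls$H[3], 2.0)
  expect_true(is.na(cls$label[3]))  # strict H < 2
  expect_true(cls$unclassifiable[4])
  # r_min is inclusive: max Ri exactly 0.33 passes when H < 2
  E2 <- matrix(c(0.33, 0.33, 0.14, 0.10, 0.10, 0), nrow = 1L,
               dimnames = list("tie", six))
  cls2 <- classify_specificity(E2, h_max = 3)
  expect_equal(cls2$label, "Amy")  # argmax tie resolves to tissue order
  # classification depends only on Ri: uniform rescaling changes nothing
  cls10 <- classify_specificity(E * 10)
  expect_equal(cls10$label, cls$label)
  expect_equal(cls10$H, cls$H)
})

test_that("labels always point at the argmax tissue", {
  cls <- small_result()$specificity$classified
  lab <- cls$label[!is.na(cls$label)]
  R <- as.matrix(cls[!is.na(cls$label), paste0("R_", six)])
  expect_true(all(lab == six[max.col(R, ties.method = "first")]))
  expect_true(all(abs(rowSums(R) - 1) < 1e-9))
})

test_that("FRiP is the in-region read share", {
  tot <- c(s1 = 100, s2 = 40, s3 = 10)
  inr <- c(s1 = 35, s2 = 0, s3 = 10)
  expect_equal(unname(qc_frip(tot, inr)), c(0.35, 0, 1))
  expect_error(qc_frip(c(s1 = 10), c(s1 = 11)), "exceeds")
})

test_that("TSS-window percentage respects strand and boundaries", {
  tx <- data.frame(
    transcript_id = c("t+", "t-"), gene_id = c("g1", "g2"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(5000L, 20000L), end = c(8000L, 26000L),
    tss = c(5000L, 25999L), biotype = "protein_coding",
    stringsAsFactors = FALSE
  )
  reg <- function(summit)
    data.frame(region_id = "r", chrom = "chr1", start = summit - 75L,
               end = summit + 76L, consensus_summit = summit,
               stringsAsFactors = FALSE)
  frac <- function(summit) tss_peak_fraction(reg(summit), tx)
  expect_equal(frac(5000L), 100)     # exactly at the + TSS
  expect_equal(frac(5100L), 100)     # +100 inclusive
  expect_equal(frac(5101L), 0)       # one bp past the window
  expect_equal(frac(4000L), 100)     # -1000 inclusive
  expect_equal(frac(3999L), 0)
  # minus strand: window mirrors to [tss - 100, tss + 1000]
  expect_equal(frac(25999L + 1000L), 100)
  expect_equal(frac(25999L + 1001L), 0)
  expect_equal(frac(25999L - 100L), 100)
  expect_equal(frac(25999L - 101L), 0)
  expect_equal(tss_peak_fraction(reg(5000L), transcript_models()), 0)
  expect_error(tss_peak_fraction(reg(5000L)[0, ], tx), "empty")
})

test_that("sample correlation is scale-free and symmetric", {
  set.seed(8)
  counts <- matrix(rnbinom(3000, mu = 50, size = 5), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  counts[, 2] <- counts[, 1]          # duplicate sample
  cm_like <- sweep(counts, 2, colSums(counts), "/") * 1e6
  C <- sample_correlation(cm_like)
  expect_equal(C["a", "b"], 1)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 3))
  # doubling a sample's depth leaves its RPM profile identical
  c2 <- counts
  c2[, 3] <- 2L * counts[, 1]
  r2 <- sweep(c2, 2, colSums(c2), "/") * 1e6
  expect_equal(sample_correlation(r2)["a", "c"], 1)
  # independent samples decorrelate at large region counts
  big <- matrix(rnbinom(20000, mu = 50, size = 5), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  rb <- sweep(big, 2, colSums(big), "/") * 1e6
  expect_lt(abs(sample_correlation(rb)["x", "y"]), 0.05)
})

test_that("genomic context follows promoter > exon > intron precedence", {
  tx <- data.frame(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
    start = 10000L, end = 16000L, tss = 10000L,
    biotype = "protein_coding", stringsAsFactors = FALSE
  )
  ex <- data.frame(transcript_id = "t1", chrom = "chr1",
                   start = c(10000L, 14000L), end = c(11000L, 16000L),
                   stringsAsFactors = FALSE)
  tm <- transcript_models(tx, ex)
  reg <- function(mid, chrom = "chr1")
    data.frame(region_id = "r", chrom = chrom, start = mid - 75L,
               end = mid + 76L, stringsAsFactors = FALSE)
  expect_equal(genomic_context(reg(9500L), tm), "promoter")   # 500 bp up
  expect_equal(genomic_context(reg(14500L), tm), "exon")      # exon 2
  expect_equal(genomic_context(reg(12000L), tm), "intron")
  expect_equal(genomic_context(reg(50000L), tm), "other")
  # promoter wins over exon where the windows coincide
  expect_equal(genomic_context(reg(10000L), tm), "promoter")
  # gene-free chromosome
  expect_equal(genomic_context(reg(9500L, "chr9"), tm), "other")
})
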