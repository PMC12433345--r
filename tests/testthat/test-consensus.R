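chrlen <- c(chr1 = 100000L)

peak_row <- function(start, end, summit, chrom = "chr1", sid = "a") {
  data.frame(chrom = chrom, start = start, end = end, name = "p",
             score = 1, strand = ".", signal = 1, pvalue_nlog10 = 1,
             qvalue_nlog10 = 1, summit_offset = summit, sample_id = sid,
             stringsAsFactors = FALSE)
}

test_that("summit windows are fixed-width and clipped at boundaries", {
  ext <- extend_to_fixed_width(peak_row(900L, 1100L, 100L), 75L, chrlen)
  expect_equal(c(ext$start, ext$end), c(925L, 1076L))
  expect_equal(ext$end - ext$start, 151L)

  ext0 <- extend_to_fixed_width(peak_row(900L, 1100L, 100L), 0L, chrlen)
  expect_equal(c(ext0$start, ext0$end), c(1000L, 1001L))

  clip <- extend_to_fixed_width(peak_row(0L, 80L, 40L), 75L, chrlen)
  expect_equal(c(clip$start, clip$end), c(0L, 116L))

  # peaks without a called summit fall back to the interval midpoint
  mid <- extend_to_fixed_width(peak_row(900L, 1100L, -1L), 75L, chrlen)
  expect_equal(mid$summit, 1000L)

  expect_error(
    extend_to_fixed_width(peak_row(99990L, 100200L, 100L), 75L,
                          c(chr1 = 100000L)),
    "outside chromosome")
})

test_that("consensus requires support from min_overlap distinct samples", {
  a <- peak_row(900L, 1100L, 100L, sid = "a")
  b <- peak_row(900L, 1100L, 100L, sid = "b")
  one <- build_consensus(list(a = a, b = b), 75L, 2L, chrlen)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(925L, 1076L))
  expect_equal(one$n_support, 2L)
  expect_equal(one$region_id, "peak_000001")

  none <- build_consensus(list(a = a, b = peak_row(5000L, 5200L, 100L,
                                                   sid = "b")),
                          75L, 2L, chrlen)
  expect_equal(none$n_support, c(1L, 1L)[0])  # both singletons dropped
  expect_equal(nrow(none), 0L)
})

test_that("chained overlaps merge and centre on the median summit", {
  sets <- list(a = peak_row(900L, 1100L, 100L, sid = "a"),   # summit 1000
               b = peak_row(950L, 1150L, 100L, sid = "b"),   # summit 1050
               c = peak_row(1000L, 1200L, 100L, sid = "c"))  # summit 1100
  out <- build_consensus(sets, 75L, 2L, chrlen)
  expect_equal(nrow(out), 1L)
  expect_equal(out$consensus_summit, 1050L)
  expect_equal(c(out$start, out$end), c(975L, 1126L))
  # even member count resolves the median tie to the lower summit
  out2 <- build_consensus(sets[1:2], 75L, 2L, chrlen)
  expect_equal(out2$consensus_summit, 1000L)
})

test_that("consensus is invariant to sample order and matches the
           brute-force overlap closure", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    summits <- sample(500:6000, n)
    sid <- sample(letters[1:5], n, replace = TRUE)
    peaks <- do.call(rbind, lapply(seq_len(n), function(i)
      peak_row(summits[i] - 100L, summits[i] + 100L, 100L, sid = sid[i])))
    sets <- split(peaks, peaks$sample_id)
    fwd <- build_consensus(sets, 75L, 2L, chrlen)
    rev_ <- build_consensus(rev(sets), 75L, 2L, chrlen)
    expect_equal(fwd, rev_)
    # oracle: all-pairs single-linkage closure over the summit windows
    cl <- brute_clusters(summits - 75L, summits + 76L)
    keep <- vapply(split(sid, cl), function(s)
      length(unique(s)) >= 2L, logical(1))
    expect_equal(nrow(fwd), sum(keep))
    med <- vapply(split(summits, cl), function(s) {
      s <- sort(s)
      s[ceiling(length(s) / 2)]
    }, integer(1))
    expect_setequal(fwd$consensus_summit, med[keep])
  }
})

test_that("fragments are counted by midpoint containment, at most once", {
  regions <- data.frame(region_id = "peak_000001", chrom = "chr1",
                        start = 925L, end = 1076L,
                        consensus_summit = 1000L, n_support = 2L,
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = "s1", tissue = "Amy", replicate = 1L,
                        stringsAsFactors = FALSE)
  frags <- list(s1 = data.frame(chrom = "chr1",
                                start = c(950L, 0L, 990L, 990L),
                                end = c(1050L, 100L, 1010L, 1010L)))
  cm <- count_fragments(frags, regions, samples)
  expect_equal(unname(cm$counts[1, 1]), 3L)  # midpoint 50 falls outside

  # boundary: midpoint exactly at end is outside the half-open region
  edge <- list(s1 = data.frame(chrom = "chr1", start = 1066L, end = 1086L))
  expect_equal(unname(count_fragments(edge, regions, samples)$counts[1, 1]),
               0L)
  bad <- list(s1 = data.frame(chrom = "chr1", start = 10L, end = 10L))
  expect_error(count_fragments(bad, regions, samples), "end <= start")
})

test_that("inclusion filters implement representation and total-count rules", {
  # 2 tissues x 4 replicates; ceil(0.75 * 4) = 3 samples must reach 10
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    tissue = rep(c("AG", "PG"), each = 4L), replicate = rep(1:4, 2L),
    stringsAsFactors = FALSE
  )
  counts <- rbind(
    r1 = c(12, 12, 12, 0, 0, 0, 0, 100),   # AG 3/4 >= 10, total 136: kept
    r2 = c(30, 30, 0, 0, 30, 30, 0, 0),    # best tissue 2/4: dropped (a)
    r3 = c(12, 12, 12, 12, 0, 0, 0, 0),    # total 48 < 100: dropped (b)
    r4 = c(25, 25, 25, 24, 0, 0, 0, 0),    # 4/4 and total 99: dropped (b)
    r5 = c(25, 25, 25, 25, 0, 0, 0, 0),    # total exactly 100: kept
    r6 = c(9, 9, 9, 9, 9, 9, 9, 37)        # nobody reaches 10: dropped (a)
  )
  regions <- data.frame(region_id = rownames(counts), chrom = "chr1",
                        start = seq(0L, by = 1000L, length.out = 6L),
                        end = seq(151L, by = 1000L, length.out = 6L),
                        consensus_summit = seq(75L, by = 1000L,
                                               length.out = 6L),
                        n_support = 2L, stringsAsFactors = FALSE)
  cm <- count_matrix(counts, regions, samples)
  kept <- filter_regions(cm)
  expect_equal(kept$regions$region_id, c("r1", "r5"))
  expect_error(filter_regions(cm, min_group_fraction = 1.5),
               "min_group_fraction")
})

test_that("filters are monotone: raising thresholds never adds regions", {
  b <- small_bundle()
  regions <- data.frame(region_id = b$truth_regions$locus_id,
                        chrom = b$truth_regions$chrom,
                        start = b$truth_regions$summit - 75L,
                        end = b$truth_regions$summit + 76L,
                        consensus_summit = b$truth_regions$summit,
                        n_support = 2L, stringsAsFactors = FALSE)
  cm <- count_matrix(b$counts, regions, b$samples)
  base <- filter_regions(cm, min_total = 100)$regions$region_id
  for (mt in c(200, 400, 800)) {
    ids <- filter_regions(cm, min_total = mt)$regions$region_id
    expect_true(all(ids %in% base))
    base <- ids
  }
})

test_that("RPM columns sum to one million and are depth-invariant", {
  samples <- data.frame(sample_id = c("s1", "s2"), tissue = "Amy",
                        replicate = 1:2, stringsAsFactors = FALSE)
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(0L, 1000L), end = c(151L, 1151L),
                        consensus_summit = c(75L, 1075L), n_support = 2L,
                        stringsAsFactors = FALSE)
  cm <- count_matrix(cbind(c(1, 3), c(2, 6)), regions, samples)
  rpm <- rpm_normalize(cm)
  expect_equal(unname(rpm[, 1]), c(250000, 750000))
  # doubling depth leaves RPM unchanged
  expect_equal(unname(rpm[, 2]), unname(rpm[, 1]))
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6), tolerance = 1e-6)

  cm0 <- count_matrix(cbind(c(1, 3), c(0, 0)), regions, samples)
  expect_error(rpm_normalize(cm0), "s2")
})
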