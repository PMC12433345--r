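# Independent oracles used by the tests; deliberately written as direct,
# naive implementations that share no code with the package internals.

# Exact upper-tail hypergeometric probability by combinatorial enumeration.
hyper_exact <- function(k, K, n, M) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n - (M - K))]
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

# Naive per-window PWM scorer: explicit loops, probabilities floored at
# 1e-3, N contributes -10 bits, both strands, forward-leftmost positions.
naive_scan <- function(seq, pwm, background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  bases <- c("A", "C", "G", "T")
  L <- pwm$length
  score_at <- function(chars, start) {
    s <- 0
    for (j in seq_len(L)) {
      b <- chars[start + j - 1L]
      s <- s + if (b %in% bases)
        log2(max(pwm$probs[b, j], 1e-3) / background[[b]]) else -10
    }
    s
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  hits <- list()
  if (n >= L) {
    rc <- rev(unname(comp[chars]))
    for (i in seq_len(n - L + 1L)) {
      s <- score_at(chars, i)
      if (s >= pwm$log_odds_threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          position = i - 1L, strand = "+", score = s)
      s <- score_at(rc, i)
      if (s >= pwm$log_odds_threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          position = n - (i - 1L) - L, strand = "-", score = s)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Brute-force single-linkage overlap closure: repeatedly merge any two
# clusters containing a pair of overlapping intervals.
brute_clusters <- function(start, end) {
  n <- length(start)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && start[i] < end[j] && start[j] < end[i]) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
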