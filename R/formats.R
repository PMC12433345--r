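#' Read a MACS2 narrowPeak file
#'
#' Parses the BED6+4 narrowPeak dialect. Coordinates are kept 0-based
#' half-open as in the file; column 10 (the summit offset from `start`)
#' is stored as `summit_offset`, with `-1` meaning "no summit called".
#' Structural problems are rejected with the offending line number rather
#' than silently repaired.
#'
#' @param path Path to a narrowPeak file.
#' @param sample_id Optional sample identifier attached to every record.
#' @return A data.frame with one row per peak: `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `signal`, `pvalue_nlog10`, `qvalue_nlog10`,
#'   `summit_offset`, `sample_id`.
#' @export
read_narrowpeak <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_peaks(sample_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L))
    stopf("%s line %d: expected 10 tab-separated columns, found %d",
          path, which(nf != 10L)[1L], nf[nf != 10L][1L])
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  summit <- suppressWarnings(as.integer(m[, 10L]))
  bad <- which(is.na(start) | is.na(end) | is.na(summit))
  if (length(bad))
    stopf("%s line %d: non-integer coordinate field", path, bad[1L])
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stopf("%s line %d: requires 0 <= start < end", path, bad[1L])
  bad <- which(summit != -1L & (summit < 0L | summit >= end - start))
  if (length(bad))
    stopf("%s line %d: summit offset %d outside peak of width %d",
          path, bad[1L], summit[bad[1L]], (end - start)[bad[1L]])
  data.frame(
    chrom = m[, 1L], start = start, end = end, name = m[, 4L],
    score = as.numeric(m[, 5L]), strand = m[, 6L],
    signal = as.numeric(m[, 7L]), pvalue_nlog10 = as.numeric(m[, 8L]),
    qvalue_nlog10 = as.numeric(m[, 9L]), summit_offset = summit,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}

empty_peaks <- function(sample_id = NA_character_) {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    signal = numeric(), pvalue_nlog10 = numeric(),
    qvalue_nlog10 = numeric(), summit_offset = integer(),
    sample_id = character(), stringsAsFactors = FALSE
  )[, , drop = FALSE]
}

#' Write peaks or regions to narrowPeak
#'
#' @param peaks A data.frame shaped like [read_narrowpeak()] output.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score,
    peaks$strand, peaks$signal, peaks$pvalue_nlog10, peaks$qvalue_nlog10,
    peaks$summit_offset
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Imports `transcript` and `exon` features (Ensembl dialect) via
#' rtracklayer and converts the 1-based closed GTF coordinates to the
#' package-wide 0-based half-open convention. The transcription start site
#' is the first transcribed base: `start` on the plus strand, `end - 1`
#' on the minus strand (0-based). Biotypes other than `protein_coding`
#' and `lncRNA` are mapped to `"other"`.
#'
#' @param path Path to a GTF file.
#' @return An object of class `transcript_models`: a list with data.frames
#'   `transcripts` (`transcript_id`, `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `biotype`) and `exons` (`transcript_id`, `chrom`,
#'   `start`, `end`).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("transcript", "exon")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(transcript_models())
  if (is.null(md$transcript_id) || anyNA(md$transcript_id))
    stopf("%s: feature without a transcript_id attribute", path)
  is_tx <- md$type == "transcript"
  biotype <- if ("transcript_biotype" %in% names(md)) {
    as.character(md$transcript_biotype)
  } else rep(NA_character_, length(gr))
  biotype[!(biotype %in% c("protein_coding", "lncRNA"))] <- "other"
  strand <- as.character(BiocGenerics::strand(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  tx <- data.frame(
    transcript_id = as.character(md$transcript_id[is_tx]),
    gene_id = as.character(md$gene_id[is_tx] %||% md$transcript_id[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
    strand = strand[is_tx],
    start = start0[is_tx], end = end0[is_tx],
    tss = ifelse(strand[is_tx] == "-", end0[is_tx] - 1L, start0[is_tx]),
    biotype = biotype[is_tx], stringsAsFactors = FALSE
  )
  ex <- data.frame(
    transcript_id = as.character(md$transcript_id[!is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr))[!is_tx],
    start = start0[!is_tx], end = end0[!is_tx],
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  ov <- unlist(tapply(seq_len(nrow(ex)), ex$transcript_id, function(i) {
    if (length(i) < 2L) return(FALSE)
    any(ex$start[i][-1L] < ex$end[i][-length(i)])
  }))
  if (any(ov))
    stopf("%s: overlapping exons in transcript %s", path, names(ov)[ov][1L])
  transcript_models(tx, ex)
}

transcript_models <- function(transcripts = NULL, exons = NULL) {
  if (is.null(transcripts))
    transcripts <- data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), start = integer(),
      end = integer(), tss = integer(), biotype = character(),
      stringsAsFactors = FALSE
    )
  if (is.null(exons))
    exons <- data.frame(
      transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), stringsAsFactors = FALSE
    )
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts, %d exons\n",
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Write transcript models to GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates are
#' emitted as 1-based closed GTF `transcript` and `exon` features.
#'
#' @param models A `transcript_models` object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  ex <- models$exons
  attr_tx <- sprintf(
    'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    tx$gene_id, tx$transcript_id, tx$biotype
  )
  gmap <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
  smap <- tx$strand[match(ex$transcript_id, tx$transcript_id)]
  attr_ex <- sprintf('gene_id "%s"; transcript_id "%s";',
                     gmap, ex$transcript_id)
  lines <- c(
    sprintf("%s\tentropeaks\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, tx$start + 1L, tx$end, tx$strand, attr_tx),
    sprintf("%s\tentropeaks\texon\t%d\t%d\t.\t%s\t.\t%s",
            ex$chrom, ex$start + 1L, ex$end, smap, attr_ex)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased on read; masking of ambiguous bases is handled
#' at motif-scoring time, not here. Header names are truncated at the
#' first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stopf("%s: duplicate sequence name %s",
                               path, nm[duplicated(nm)][1L])
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract region sequences from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param regions Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Character vector of sequences, named by `region_id` if present.
#' @export
region_seqs <- function(genome, regions) {
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss)) stopf("chromosome %s absent from genome", miss[1L])
  out <- substr(genome[regions$chrom], regions$start + 1L, regions$end)
  names(out) <- regions$region_id %||% NULL
  out
}

#' Write regions as BED
#'
#' Emits BED3, or BED4 when a `region_id` (or `name`) column is present.
#'
#' @param regions Data.frame with `chrom`, `start`, `end` and optionally
#'   `region_id`/`name`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  df <- regions[, c("chrom", "start", "end")]
  nm <- regions$region_id %||% regions$name
  if (!is.null(nm)) df$name <- nm
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' @param path Path to a BED file.
#' @return Data.frame with `chrom`, `start`, `end` and `name` when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- tryCatch(
    as.data.frame(data.table::fread(path, header = FALSE, sep = "\t")),
    error = function(e) stopf("%s: %s", path, conditionMessage(e))
  )
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  if (ncol(df) < 3L) stopf("%s: fewer than 3 BED columns", path)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]), stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stopf("%s line %d: non-integer coordinate",
          path, which(is.na(as.integer(df[[2L]])) | is.na(as.integer(df[[3L]])))[1L])
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  out
}

#' Read a labeled numeric matrix from TSV
#'
#' Expects a header row (sample/column labels), a first column of row
#' identifiers, and tab separation. Lines starting with `#` are skipped,
#' so matrices written with parameter-audit comments round-trip.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("%s: expected an ID column plus data columns", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("%s: duplicate row label %s", path, ids[duplicated(ids)][1L])
  if (anyDuplicated(names(df)[-1L]))
    stopf("%s: duplicate column label", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a labeled numeric matrix to TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the identifier column.
#' @param comments Optional character vector written as leading `#` lines.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", comments = character()) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("matrix must carry row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Construct a position probability matrix object
#'
#' @param name Motif name (e.g. the HOMER `name` field).
#' @param probs 4 x L matrix of base probabilities, rows in A,C,G,T order;
#'   each column must sum to 1 within 1e-6.
#' @param log_odds_threshold Minimum window log-odds score (bits) for a
#'   hit; when `NA` it defaults to 80% of the motif's maximal attainable
#'   score against a uniform background.
#' @param consensus Optional consensus string; derived from `probs` when
#'   missing.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, log_odds_threshold = NA_real_,
                consensus = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stopf("pwm probs must have 4 rows (A,C,G,T)")
  if (ncol(probs) < 4L) stopf("pwm must have length >= 4")
  if (any(probs < 0)) stopf("pwm probabilities must be >= 0")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-6)) stopf("pwm columns must sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  if (is.null(consensus))
    consensus <- paste(rownames(probs)[apply(probs, 2L, which.max)],
                       collapse = "")
  if (is.na(log_odds_threshold))
    log_odds_threshold <- 0.8 * sum(log2(pmax(apply(probs, 2L, max), 1e-3) / 0.25))
  structure(
    list(name = name, tf_name = sub("[(/].*$", "", name),
         consensus = consensus, length = ncol(probs), probs = probs,
         log_odds_threshold = log_odds_threshold),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d, threshold %.2f bits\n",
              x$name, x$consensus, x$length, x$log_odds_threshold))
  invisible(x)
}

#' Read a HOMER-format known-motif library
#'
#' Each record is a `>` header (consensus, name, log-odds threshold,
#' tab-separated) followed by one row of four base probabilities per
#' position. Rows off unity by at most 1e-3 are renormalized; larger
#' deviations are parse errors.
#'
#' @param path Path to a `.motif` / `.motifs` file.
#' @return List of [pwm()] objects.
#' @export
read_homer_motifs <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stopf("%s line %d: expected '>' header", path, lineno[1L])
  rec <- cumsum(hdr)
  out <- vector("list", max(rec))
  for (i in seq_len(max(rec))) {
    idx <- which(rec == i)
    h <- strsplit(sub("^>", "", lines[idx[1L]]), "\t", fixed = TRUE)[[1L]]
    if (length(h) < 3L)
      stopf("%s line %d: header needs consensus, name and threshold fields",
            path, lineno[idx[1L]])
    body <- idx[-1L]
    if (length(body) < 4L)
      stopf("%s line %d: motif %s shorter than 4 positions",
            path, lineno[idx[1L]], h[2L])
    probs <- matrix(NA_real_, nrow = 4L, ncol = length(body))
    for (j in seq_along(body)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[body[j]]),
                                                "[ \t]+")[[1L]]))
      if (length(v) < 4L || anyNA(v))
        stopf("%s line %d: expected 4 numeric probabilities",
              path, lineno[body[j]])
      v <- v[1:4]
      if (abs(sum(v) - 1) > 1e-3)
        stopf("%s line %d: probabilities sum to %.4f, not 1",
              path, lineno[body[j]], sum(v))
      probs[, j] <- v / sum(v)
    }
    out[[i]] <- pwm(name = h[2L], probs = probs,
                    log_odds_threshold = as.numeric(h[3L]),
                    consensus = h[1L])
  }
  out
}

#' Write motifs in HOMER format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @export
write_homer_motifs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s\t%s\t%.6g", p$consensus, p$name,
                       p$log_odds_threshold), con)
    writeLines(apply(p$probs, 2L, function(col)
      paste(sprintf("%.3f", col), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `tissue`, `replicate`.
#' @return Data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  check_sample_sheet(df)
}
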