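# FASTQ input and read-level summary statistics (the inputs of the RAW
# flag rules).

#' Adapter sequences screened by the adapter-content statistic
#'
#' The universal adapter prefix used by common library preparations; reads
#' containing it (read-through into the adapter) are counted per position.
#' @export
QC_ADAPTERS <- c(illumina_universal = "AGATCGGAAGAG")

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (plain or gzip) with Phred+33 qualities.
#' Malformed records -- a line count that is not a multiple of four, missing
#' `@`/`+` markers, or a quality string whose length differs from the
#' sequence -- raise a parse error naming the record index. An empty file
#' yields zero records without error.
#'
#' @param path FASTQ file path.
#' @param max_reads maximum number of records to read (default unlimited).
#' @return a `qc_fastq_reads` list with character vectors `id`, `sequence`
#'   and `quality` (raw Phred+33 strings).
#' @export
read_fastq <- function(path, max_reads = Inf) {
  if (!file.exists(path)) stop_ngsqc("FASTQ file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  n_lines <- if (is.finite(max_reads)) 4L * as.integer(max_reads) else -1L
  lines <- readLines(con, n = n_lines)
  if (length(lines) %% 4L != 0L)
    stop_ngsqc("malformed FASTQ: line count not a multiple of 4 ",
               "(truncated record ", length(lines) %/% 4L + 1L, ")")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(structure(list(id = character(), sequence = character(),
                          quality = character()),
                     class = "qc_fastq_reads"))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop_ngsqc("malformed FASTQ: record ", bad[1L], " does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop_ngsqc("malformed FASTQ: record ", bad[1L], " lacks the '+' separator")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop_ngsqc("malformed FASTQ: record ", bad[1L],
               " quality length differs from sequence length")
  structure(list(id = sub("^@", "", hdr), sequence = seqs, quality = qual),
            class = "qc_fastq_reads")
}

#' @export
print.qc_fastq_reads <- function(x, ...) {
  cat("FASTQ reads:", length(x$sequence), "records\n")
  invisible(x)
}

# Decode Phred+33 quality strings into an n x Lmax integer matrix (NA pad).
quality_matrix <- function(quality) {
  qs <- lapply(quality, function(s) utf8ToInt(s) - 33L)
  L <- max(lengths(qs))
  m <- matrix(NA_integer_, nrow = length(qs), ncol = L)
  for (i in seq_along(qs)) {
    v <- qs[[i]]
    if (length(v)) m[i, seq_along(v)] <- v
  }
  m
}

base_matrix <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)
  L <- max(lengths(ch))
  m <- matrix(NA_character_, nrow = length(ch), ncol = L)
  for (i in seq_along(ch)) {
    v <- ch[[i]]
    if (length(v)) m[i, seq_along(v)] <- v
  }
  m
}

# Extract the tile field from Illumina-style read ids
# (instrument:run:flowcell:lane:tile:x:y); NA when the id has no tile token.
parse_tiles <- function(ids) {
  coord <- vapply(strsplit(ids, " ", fixed = TRUE), `[[`, "", 1L)
  parts <- strsplit(coord, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= 7L && grepl("^[0-9]+$", p[[5L]])) p[[5L]] else NA_character_
  }, "")
}

#' Summarise a batch of reads
#'
#' Computes the read-level summary statistics from which the eleven RAW
#' report flags are derived: per-position quality quartiles, the per-read
#' mean-quality histogram, per-position base content, the per-read GC
#' histogram, per-position N fraction, the read-length histogram, sequence
#' duplication (estimated from the first `dup_track_limit` distinct
#' sequences truncated to `dup_truncate` bp, the reference tool's
#' procedure), overrepresented sequences, cumulative adapter content per
#' position, per-tile quality deviations (absent when read ids carry no
#' tile field), and positionally biased k-mer enrichment.
#'
#' @param reads a `qc_fastq_reads` object from [read_fastq()].
#' @param adapters named character vector of adapter sequences to screen.
#' @param dup_track_limit number of distinct sequences tracked for the
#'   duplication estimate.
#' @param dup_truncate truncation length (bp) applied before duplicate
#'   counting.
#' @param kmer_k k-mer length for the positional-bias statistic.
#' @param kmer_sample_reads number of reads (file order) scanned for k-mers.
#' @return a `qc_read_stats` list; see the field docs in the source.
#' @export
summarize_reads <- function(reads, adapters = QC_ADAPTERS,
                            dup_track_limit = 100000L, dup_truncate = 50L,
                            kmer_k = 7L, kmer_sample_reads = 2000L) {
  if (!inherits(reads, "qc_fastq_reads"))
    stop_ngsqc("reads must come from read_fastq()")
  n <- length(reads$sequence)
  if (n == 0L) stop_ngsqc("empty input: no reads to summarise")

  Q <- quality_matrix(reads$quality)
  B <- base_matrix(reads$sequence)
  L <- ncol(Q)

  qq <- apply(Q, 2L, stats::quantile,
              probs = c(.1, .25, .5, .75, .9), na.rm = TRUE)
  per_position_quality <- data.frame(
    position = seq_len(L),
    mean = colMeans(Q, na.rm = TRUE),
    p10 = qq[1L, ], p25 = qq[2L, ], median = qq[3L, ],
    p75 = qq[4L, ], p90 = qq[5L, ])

  mean_q <- floor(rowMeans(Q, na.rm = TRUE))
  per_read_mean_quality <- table(factor(mean_q, levels = 0:60))

  counts_of <- function(base) colSums(B == base, na.rm = TRUE)
  nb <- colSums(!is.na(B))
  per_position_base_content <- rbind(
    A = counts_of("A") / nb, C = counts_of("C") / nb,
    G = counts_of("G") / nb, T = counts_of("T") / nb)

  lens <- nchar(reads$sequence)
  gc <- round(100 * (counts_per_read(B, c("G", "C")) / pmax(lens, 1L)))
  gc_histogram <- table(factor(gc, levels = 0:100))

  per_position_n_fraction <- counts_of("N") / nb
  length_histogram <- table(lens)

  trunc <- substr(reads$sequence, 1L, dup_truncate)
  first_idx <- !duplicated(trunc)
  tracked <- trunc[first_idx]
  if (length(tracked) > dup_track_limit)
    tracked <- tracked[seq_len(dup_track_limit)]
  occ <- table(trunc[trunc %in% tracked])
  lvl <- pmin(as.integer(occ), 10L)
  duplication_histogram <- table(factor(lvl, levels = 1:10))
  names(duplication_histogram)[10L] <- "10+"
  pct_non_unique <- 100 * sum(occ[occ > 1L]) / sum(occ)

  frac <- as.numeric(occ) / n
  keep <- frac > 0.001
  overrepresented <- data.frame(
    sequence = names(occ)[keep], count = as.integer(occ)[keep],
    fraction = frac[keep], stringsAsFactors = FALSE)
  overrepresented <- overrepresented[order(-overrepresented$fraction), ,
                                     drop = FALSE]

  adapter_content <- adapter_cumulative(reads$sequence, adapters, L)

  tiles <- parse_tiles(reads$id)
  per_tile_quality <- NULL
  if (!anyNA(tiles) && length(unique(tiles)) > 1L) {
    col_mean <- colMeans(Q, na.rm = TRUE)
    tile_means <- rowsum(ifelse(is.na(Q), 0, Q), tiles) /
      rowsum((!is.na(Q)) * 1, tiles)
    per_tile_quality <- sweep(tile_means, 2L, col_mean)
  }

  kmer_stats <- kmer_bias(reads$sequence, k = kmer_k,
                          sample_reads = kmer_sample_reads)

  structure(list(
    n_reads = n, max_length = L,
    per_position_quality = per_position_quality,
    per_read_mean_quality = per_read_mean_quality,
    per_position_base_content = per_position_base_content,
    gc_histogram = gc_histogram,
    per_position_n_fraction = per_position_n_fraction,
    length_histogram = length_histogram,
    duplication_histogram = duplication_histogram,
    pct_non_unique = pct_non_unique,
    overrepresented = overrepresented,
    adapter_content = adapter_content,
    per_tile_quality = per_tile_quality,
    kmer_stats = kmer_stats), class = "qc_read_stats")
}

counts_per_read <- function(B, bases) {
  rowSums(matrix(B %in% bases, nrow = nrow(B)), na.rm = TRUE)
}

# Cumulative fraction of reads in which any adapter starts at or before each
# position.
adapter_cumulative <- function(sequence, adapters, L) {
  n <- length(sequence)
  starts <- rep(NA_integer_, n)
  for (ad in adapters) {
    m <- regexpr(ad, sequence, fixed = TRUE)
    hit <- m > 0L
    starts[hit] <- pmin(starts[hit], m[hit], na.rm = TRUE)
  }
  tab <- tabulate(starts[!is.na(starts)], nbins = L)
  cumsum(tab) / n
}

# Positional k-mer bias: for k-mers frequent enough to test, a binomial
# upper-tail test of the most loaded position bin against uniform occupancy,
# Bonferroni-adjusted over bins and tested k-mers.
kmer_bias <- function(sequence, k = 7L, sample_reads = 2000L,
                      min_count = 20L, n_bins = 10L) {
  sequence <- sequence[seq_len(min(length(sequence), sample_reads))]
  lens <- nchar(sequence)
  sequence <- sequence[lens >= k]
  if (!length(sequence))
    return(data.frame(kmer = character(), count = integer(),
                      max_bin = integer(), p_adj = numeric()))
  L <- max(nchar(sequence))
  n_bins <- min(n_bins, max(1L, L - k + 1L))
  bin_of <- function(pos) pmin(n_bins, 1L + ((pos - 1L) * n_bins) %/%
                                 max(1L, (L - k + 1L)))
  kmers <- character(0); bins <- integer(0)
  for (i in seq_along(sequence)) {
    s <- sequence[[i]]
    np <- nchar(s) - k + 1L
    pos <- seq_len(np)
    kmers <- c(kmers, substring(s, pos, pos + k - 1L))
    bins <- c(bins, bin_of(pos))
  }
  keep <- !grepl("N", kmers, fixed = TRUE)
  kmers <- kmers[keep]; bins <- bins[keep]
  tot <- table(kmers)
  tested <- names(tot)[tot >= min_count]
  if (!length(tested) || n_bins < 2L)
    return(data.frame(kmer = character(), count = integer(),
                      max_bin = integer(), p_adj = numeric()))
  sel <- kmers %in% tested
  grp <- split(bins[sel], kmers[sel])
  res <- lapply(names(grp), function(km) {
    cnt <- tabulate(grp[[km]], nbins = n_bins)
    mx <- which.max(cnt)
    p <- stats::pbinom(cnt[mx] - 1L, sum(cnt), 1 / n_bins,
                       lower.tail = FALSE)
    data.frame(kmer = km, count = sum(cnt), max_bin = mx,
               p_adj = min(1, p * n_bins * length(tested)))
  })
  out <- do.call(rbind, res)
  out[order(out$p_adj), , drop = FALSE]
}
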