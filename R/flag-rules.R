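# The eleven warn/fail rules applied to read-level summary statistics.
# Thresholds are the documented defaults of the reference read-level QC
# tool, frozen here so flags are comparable across runs:
#
#   per-base quality   : warn any lower quartile < 10 or median < 25;
#                        fail any lower quartile < 5 or median < 20
#   per-tile quality   : warn any tile >= 2 Phred below the column mean;
#                        fail >= 5 below; Pass when ids carry no tile field
#   per-seq quality    : warn modal mean quality < 27; fail < 20
#   per-base content   : warn any |A-T| or |G-C| > 10 points; fail > 20
#   per-seq GC content : warn summed deviation from a fitted normal > 15%
#                        of reads; fail > 30%
#   per-base N content : warn any position > 5% N; fail > 20%
#   length distribution: warn if read lengths differ; fail if any length 0
#   duplication        : warn non-unique reads > 20%; fail > 50%
#   overrepresented    : warn any sequence > 0.1% of reads; fail > 1%
#   adapter content    : warn cumulative adapter >= 5% at any position;
#                        fail >= 10% (inclusive at the limit)
#   k-mer content      : warn positional binomial p < 0.01; fail < 1e-5
#                        (Bonferroni-adjusted)

flag_of <- function(fail, warn) {
  if (fail) "Fail" else if (warn) "Warning" else "Pass"
}

#' Apply the eleven report-flag rules
#'
#' Converts read-level summary statistics into the RAW feature set of
#' eleven Pass/Warning/Fail flags, using the frozen default thresholds
#' documented in the package (see source header). Deterministic: identical
#' statistics always yield identical flags. Modules whose inputs are absent
#' (e.g. no tile information in the read ids) return Pass.
#'
#' @param stats a `qc_read_stats` object from [summarize_reads()].
#' @return a `qc_raw_features` object.
#' @export
apply_flag_rules <- function(stats) {
  if (!inherits(stats, "qc_read_stats"))
    stop_ngsqc("stats must come from summarize_reads()")
  pp <- stats$per_position_quality
  f_quality <- flag_of(any(pp$p25 < 5) || any(pp$median < 20),
                       any(pp$p25 < 10) || any(pp$median < 25))

  f_tile <- "Pass"
  if (!is.null(stats$per_tile_quality)) {
    deficit <- -min(stats$per_tile_quality, na.rm = TRUE)
    f_tile <- flag_of(deficit >= 5, deficit >= 2)
  }

  h <- stats$per_read_mean_quality
  modal_q <- as.integer(names(h)[which.max(h)])
  f_perseq <- flag_of(modal_q < 20, modal_q < 27)

  bc <- stats$per_position_base_content * 100
  diffs <- pmax(abs(bc["A", ] - bc["T", ]), abs(bc["G", ] - bc["C", ]))
  f_content <- flag_of(any(diffs > 20, na.rm = TRUE),
                       any(diffs > 10, na.rm = TRUE))

  f_gc <- gc_flag(stats$gc_histogram, stats$n_reads)

  nf <- stats$per_position_n_fraction * 100
  f_n <- flag_of(any(nf > 20, na.rm = TRUE), any(nf > 5, na.rm = TRUE))

  lh <- stats$length_histogram
  lens <- as.integer(names(lh))
  f_len <- flag_of(any(lens == 0L), length(lh) > 1L)

  f_dup <- flag_of(stats$pct_non_unique > 50, stats$pct_non_unique > 20)

  ov <- stats$overrepresented
  max_frac <- if (nrow(ov)) max(ov$fraction) else 0
  f_over <- flag_of(max_frac > 0.01, max_frac > 0.001)

  max_ad <- if (length(stats$adapter_content))
    100 * max(stats$adapter_content) else 0
  f_adapter <- flag_of(max_ad >= 10, max_ad >= 5)

  ks <- stats$kmer_stats
  min_p <- if (nrow(ks)) min(ks$p_adj) else 1
  f_kmer <- flag_of(min_p < 1e-5, min_p < 0.01)

  new_raw_features(c(f_quality, f_tile, f_perseq, f_content, f_gc, f_n,
                     f_len, f_dup, f_over, f_adapter, f_kmer))
}

# Summed absolute deviation of the observed per-read GC histogram from a
# normal distribution fitted to the observed mean and sd, as a percentage
# of reads (factor 2 so that identical distributions give 0 and disjoint
# ones give 100).
gc_flag <- function(gc_histogram, n_reads) {
  obs <- as.numeric(gc_histogram)
  x <- as.numeric(names(gc_histogram))
  mu <- sum(x * obs) / n_reads
  sdev <- sqrt(sum((x - mu)^2 * obs) / n_reads)
  if (sdev < 1e-9) return("Pass")
  theo <- stats::dnorm(x, mu, sdev)
  theo <- theo / sum(theo) * n_reads
  dev_pct <- 100 * sum(abs(obs - theo)) / (2 * n_reads)
  flag_of(dev_pct > 30, dev_pct > 15)
}

#' Compute RAW features straight from a FASTQ file
#'
#' Convenience wrapper: [read_fastq()] then [summarize_reads()] then
#' [apply_flag_rules()].
#'
#' @param path FASTQ file (plain or gzip, Phred+33).
#' @param max_reads cap on the number of reads summarised.
#' @param ... passed to [summarize_reads()].
#' @return a `qc_raw_features` object.
#' @export
raw_features <- function(path, max_reads = Inf, ...) {
  apply_flag_rules(summarize_reads(read_fastq(path, max_reads), ...))
}
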