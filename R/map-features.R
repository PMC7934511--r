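# MAP feature set: mapping-rate percentages, either parsed from an aligner
# summary log or recomputed from alignment records. Four features for
# single-end data (unmapped / uniquely mapped / multi-mapped / overall
# rate) and eight for paired-end (concordant 0/1/multi, discordant unique,
# residual mates 0/1/multi, overall rate) -- exactly the category lines of
# the standard short-read aligner's summary output, with the log's own
# denominators.

MAP_SINGLE_FIELDS <- c("pct_unmapped", "pct_uniquely_mapped",
                       "pct_multi_mapped", "overall_rate")
MAP_PAIRED_FIELDS <- c("pct_concordant_zero", "pct_concordant_unique",
                       "pct_concordant_multi", "pct_discordant_unique",
                       "pct_mate_unmapped", "pct_mate_unique",
                       "pct_mate_multi", "overall_rate")

new_map_features <- function(layout, values) {
  fields <- if (layout == "single") MAP_SINGLE_FIELDS else MAP_PAIRED_FIELDS
  stopifnot(identical(names(values), fields))
  if (any(values < -1e-9 | values > 100 + 1e-9))
    stop_ngsqc("mapping percentages must lie in [0, 100]")
  structure(list(layout = layout, values = values),
            class = "qc_map_features")
}

#' @export
print.qc_map_features <- function(x, ...) {
  cat("MAP feature set (", x$layout, "-end):\n", sep = "")
  for (nm in names(x$values))
    cat(sprintf("  %-22s %6.2f\n", nm, x$values[[nm]]))
  invisible(x)
}

log_pct <- function(line) {
  m <- regmatches(line, regexec("\\(([0-9.]+)%\\)", line))[[1L]]
  if (length(m) == 2L) as.numeric(m[[2L]]) else NA_real_
}

log_count <- function(line) {
  m <- regmatches(line, regexec("^\\s*([0-9]+) ", line))[[1L]]
  if (length(m) == 2L) as.numeric(m[[2L]]) else NA_real_
}

grab <- function(lines, pattern) {
  hit <- grep(pattern, lines)
  if (!length(hit)) return(NA_integer_)
  hit[[1L]]
}

pct_or_recompute <- function(line, denom) {
  p <- log_pct(line)
  if (!is.na(p)) return(p)
  cnt <- log_count(line)
  if (is.na(cnt) || is.na(denom) || denom == 0)
    stop_ngsqc("alignment log line carries neither percentage nor ",
               "usable count: ", trimws(line))
  100 * cnt / denom
}

#' Parse an aligner summary log
#'
#' Parses the standard short-read aligner's alignment-summary text (the
#' count lines with parenthesized percentages plus the "overall alignment
#' rate" line) into a MAP feature set. The layout is auto-detected from the
#' presence of "aligned concordantly" lines. Percentages are taken from the
#' log when printed and recomputed from counts otherwise.
#'
#' @param x path to a log file, or a character vector of its lines.
#' @return a `qc_map_features` object.
#' @export
parse_alignment_log <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  i_overall <- grab(lines, "overall alignment rate")
  if (is.na(i_overall))
    stop_ngsqc("alignment log lacks the 'overall alignment rate' line")
  overall <- as.numeric(sub("%.*$", "", trimws(lines[[i_overall]])))
  paired <- any(grepl("aligned concordantly", lines))

  i_tot <- grab(lines, "reads; of these")
  total <- if (!is.na(i_tot)) log_count(lines[[i_tot]]) else NA_real_

  if (!paired) {
    i0 <- grab(lines, "aligned 0 times$")
    i1 <- grab(lines, "aligned exactly 1 time")
    im <- grab(lines, "aligned >1 times")
    if (anyNA(c(i0, i1, im)))
      stop_ngsqc("alignment log lacks single-end category lines")
    cnts <- vapply(lines[c(i0, i1, im)], log_count, 0)
    if (!anyNA(cnts) && !is.na(total) && sum(cnts) > total + 0.5)
      stop_ngsqc("alignment log counts inconsistent: categories exceed total")
    v <- c(pct_or_recompute(lines[[i0]], total),
           pct_or_recompute(lines[[i1]], total),
           pct_or_recompute(lines[[im]], total),
           overall)
    names(v) <- MAP_SINGLE_FIELDS
    return(new_map_features("single", v))
  }

  ic0 <- grab(lines, "aligned concordantly 0 times")
  ic1 <- grab(lines, "aligned concordantly exactly 1 time")
  icm <- grab(lines, "aligned concordantly >1 times")
  if (anyNA(c(ic0, ic1, icm)))
    stop_ngsqc("alignment log lacks paired-end concordant lines")
  conc0_pairs <- log_count(lines[[ic0]])
  cnts <- vapply(lines[c(ic0, ic1, icm)], log_count, 0)
  if (!anyNA(cnts) && !is.na(total) && sum(cnts) > total + 0.5)
    stop_ngsqc("alignment log counts inconsistent: categories exceed total")

  id <- grab(lines, "aligned discordantly 1 time")
  disc <- if (is.na(id)) 0 else pct_or_recompute(lines[[id]], conc0_pairs)

  i_mates <- grab(lines, "mates make up the pairs")
  m0 <- mu <- mm <- 0
  if (!is.na(i_mates)) {
    tail_lines <- lines[seq(i_mates + 1L, length(lines))]
    mate_total <- log_count(lines[[i_mates]])
    j0 <- grab(tail_lines, "aligned 0 times$")
    j1 <- grab(tail_lines, "aligned exactly 1 time")
    jm <- grab(tail_lines, "aligned >1 times")
    if (!is.na(j0)) m0 <- pct_or_recompute(tail_lines[[j0]], mate_total)
    if (!is.na(j1)) mu <- pct_or_recompute(tail_lines[[j1]], mate_total)
    if (!is.na(jm)) mm <- pct_or_recompute(tail_lines[[jm]], mate_total)
  }
  v <- c(pct_or_recompute(lines[[ic0]], total),
         pct_or_recompute(lines[[ic1]], total),
         pct_or_recompute(lines[[icm]], total),
         disc, m0, mu, mm, overall)
  names(v) <- MAP_PAIRED_FIELDS
  new_map_features("paired", v)
}

#' Render a MAP feature set as an aligner-style summary log
#'
#' Inverse of [parse_alignment_log()] up to the stated total: percentages
#' are printed with two decimals and counts are reconstructed from
#' `n_reads`, so a set whose percentages carry at most two decimals
#' round-trips exactly.
#'
#' @param map a `qc_map_features` object.
#' @param n_reads total reads (single-end) or pairs (paired-end) to print.
#' @return character vector of log lines.
#' @export
format_alignment_log <- function(map, n_reads = 10000L) {
  stopifnot(inherits(map, "qc_map_features"))
  v <- map$values
  cnt <- function(p, denom) round(p / 100 * denom)
  if (map$layout == "single") {
    lines <- c(
      sprintf("%d reads; of these:", n_reads),
      sprintf("  %d (100.00%%) were unpaired; of these:", n_reads),
      sprintf("    %d (%.2f%%) aligned 0 times",
              cnt(v[["pct_unmapped"]], n_reads), v[["pct_unmapped"]]),
      sprintf("    %d (%.2f%%) aligned exactly 1 time",
              cnt(v[["pct_uniquely_mapped"]], n_reads),
              v[["pct_uniquely_mapped"]]),
      sprintf("    %d (%.2f%%) aligned >1 times",
              cnt(v[["pct_multi_mapped"]], n_reads),
              v[["pct_multi_mapped"]]),
      sprintf("%.2f%% overall alignment rate", v[["overall_rate"]]))
    return(lines)
  }
  conc0 <- cnt(v[["pct_concordant_zero"]], n_reads)
  disc1 <- cnt(v[["pct_discordant_unique"]], conc0)
  leftover <- conc0 - disc1
  mates <- 2L * leftover
  c(sprintf("%d reads; of these:", n_reads),
    sprintf("  %d (100.00%%) were paired; of these:", n_reads),
    sprintf("    %d (%.2f%%) aligned concordantly 0 times",
            conc0, v[["pct_concordant_zero"]]),
    sprintf("    %d (%.2f%%) aligned concordantly exactly 1 time",
            cnt(v[["pct_concordant_unique"]], n_reads),
            v[["pct_concordant_unique"]]),
    sprintf("    %d (%.2f%%) aligned concordantly >1 times",
            cnt(v[["pct_concordant_multi"]], n_reads),
            v[["pct_concordant_multi"]]),
    "    ----",
    sprintf("    %d pairs aligned concordantly 0 times; of these:", conc0),
    sprintf("      %d (%.2f%%) aligned discordantly 1 time",
            disc1, v[["pct_discordant_unique"]]),
    "    ----",
    sprintf("    %d pairs aligned 0 times concordantly or discordantly; of these:",
            leftover),
    sprintf("      %d mates make up the pairs; of these:", mates),
    sprintf("        %d (%.2f%%) aligned 0 times",
            cnt(v[["pct_mate_unmapped"]], mates), v[["pct_mate_unmapped"]]),
    sprintf("        %d (%.2f%%) aligned exactly 1 time",
            cnt(v[["pct_mate_unique"]], mates), v[["pct_mate_unique"]]),
    sprintf("        %d (%.2f%%) aligned >1 times",
            cnt(v[["pct_mate_multi"]], mates), v[["pct_mate_multi"]]),
    sprintf("%.2f%% overall alignment rate", v[["overall_rate"]]))
}

#' Recompute MAP features from alignment records
#'
#' Computes the same field semantics as [parse_alignment_log()] directly
#' from SAM/BAM records, over primary records only. A read counts as
#' multi-mapped when its `NH` tag exceeds 1 or when secondary alignments
#' share its name. Paired-end pairs are classified as concordant
#' (proper-pair flag; unique when both mates have `NH` 1), discordant
#' (both mates mapped without the proper-pair flag), or residual, whose
#' mates are counted individually -- mirroring the aligner's categories
#' and denominators.
#'
#' @param x path to a SAM (or BAM, when Rsamtools is installed) file, or a
#'   data frame of records as returned by the internal SAM reader.
#' @param layout `"single"` or `"paired"`; auto-detected from the paired
#'   flag when omitted.
#' @return a `qc_map_features` object.
#' @export
compute_map_stats <- function(x, layout = NULL) {
  rec <- as_sam_records(x)
  rec <- rec[bitwAnd(rec$flag, 0x100) == 0L &
               bitwAnd(rec$flag, 0x800) == 0L, , drop = FALSE]
  if (!nrow(rec)) stop_ngsqc("alignment stream has zero primary records")
  paired_flag <- bitwAnd(rec$flag, 0x1) > 0L
  if (is.null(layout)) layout <- if (any(paired_flag)) "paired" else "single"
  layout <- match.arg(layout, c("single", "paired"))

  unmapped <- bitwAnd(rec$flag, 0x4) > 0L
  multi <- !unmapped & !is.na(rec$nh) & rec$nh > 1L
  sec_names <- attr(rec, "secondary_qnames")
  if (!is.null(sec_names))
    multi <- multi | (!unmapped & rec$qname %in% sec_names)
  unique_m <- !unmapped & !multi

  if (layout == "single") {
    n <- nrow(rec)
    v <- 100 * c(sum(unmapped), sum(unique_m), sum(multi)) / n
    v <- c(v, 100 - v[[1L]])
    names(v) <- MAP_SINGLE_FIELDS
    return(new_map_features("single", v))
  }

  cls <- ifelse(unmapped, "u", ifelse(multi, "m", "q"))
  split_idx <- split(seq_len(nrow(rec)), rec$qname)
  n_pairs <- length(split_idx)
  conc0 <- conc1 <- concm <- disc1 <- 0L
  mate_u <- mate_1 <- mate_m <- 0L
  leftover_pairs <- 0L
  for (idx in split_idx) {
    proper <- any(bitwAnd(rec$flag[idx], 0x2) > 0L)
    mapped <- !unmapped[idx]
    if (proper && all(mapped)) {
      if (all(cls[idx] == "q")) conc1 <- conc1 + 1L else concm <- concm + 1L
    } else {
      conc0 <- conc0 + 1L
      if (length(idx) == 2L && all(mapped) && all(cls[idx] == "q")) {
        disc1 <- disc1 + 1L
      } else {
        leftover_pairs <- leftover_pairs + 1L
        mate_u <- mate_u + sum(cls[idx] == "u")
        mate_1 <- mate_1 + sum(cls[idx] == "q")
        mate_m <- mate_m + sum(cls[idx] == "m")
      }
    }
  }
  mates <- mate_u + mate_1 + mate_m
  total_mates <- nrow(rec)
  overall <- 100 * sum(!unmapped) / total_mates
  v <- c(100 * conc0 / n_pairs, 100 * conc1 / n_pairs, 100 * concm / n_pairs,
         if (conc0 > 0L) 100 * disc1 / conc0 else 0,
         if (mates > 0L) 100 * c(mate_u, mate_1, mate_m) / mates else c(0, 0, 0),
         overall)
  names(v) <- MAP_PAIRED_FIELDS
  new_map_features("paired", v)
}

# Light SAM reader: primary fields plus the NH tag; secondary-alignment
# names kept as an attribute for multi-mapping detection.
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), nh = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 11L)
  if (length(short))
    stop_ngsqc("malformed SAM record at line ", short[1L])
  f <- function(i) vapply(parts, `[[`, "", i)
  nh <- vapply(parts, function(p) {
    tag <- grep("^NH:i:", p[-seq_len(11L)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[[1L]])) else NA_integer_
  }, 1L)
  rec <- data.frame(qname = f(1L), flag = as.integer(f(2L)), rname = f(3L),
                    pos = as.integer(f(4L)), cigar = f(6L), nh = nh,
                    stringsAsFactors = FALSE)
  sec <- rec$qname[bitwAnd(rec$flag, 0x100) > 0L]
  attr(rec, "secondary_qnames") <- unique(sec)
  rec
}

read_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop_ngsqc("reading BAM requires the Rsamtools package; ",
               "provide a SAM file instead")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NH")
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  nh <- b$tag$NH %||% rep(NA_integer_, length(b$flag))
  rec <- data.frame(qname = b$qname, flag = b$flag,
                    rname = as.character(b$rname),
                    pos = ifelse(is.na(b$pos), 0L, b$pos),
                    cigar = ifelse(is.na(b$cigar), "*", b$cigar),
                    nh = nh, stringsAsFactors = FALSE)
  sec <- rec$qname[bitwAnd(rec$flag, 0x100) > 0L]
  attr(rec, "secondary_qnames") <- unique(sec)
  rec
}

as_sam_records <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!is.character(x) || length(x) != 1L || !file.exists(x))
    stop_ngsqc("expected a SAM/BAM path or a record data frame")
  if (grepl("\\.bam$", x, ignore.case = TRUE)) read_bam(x) else read_sam(x)
}
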