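# LOC and TSS feature sets: read anchors sampled from mapped alignments,
# fractions over the nine region categories, and binned read density in
# the +/- 5 kb window around transcription start sites.

#' TSS bin labels
#'
#' The ten 1 kb bins tiling TSS +/- 5 kb, named by their central offset;
#' `TSS-4500` covers offsets [-5000, -4000) relative to the TSS, oriented
#' by transcription direction (negative = upstream).
#' @export
TSS_BIN_NAMES <- paste0("TSS", c(sprintf("-%d", seq(4500, 500, by = -1000)),
                                 sprintf("+%d", seq(500, 4500, by = 1000))))

#' Sample read anchors from mapped alignments
#'
#' Draws a uniform random sample of up to `n` mapped primary records and
#' reduces each to a single anchor position: the midpoint of the aligned
#' interval (default) or its 5' end. For proper pairs, the pair counts
#' once and the fragment interval spanned by both mates is anchored.
#' Identical input and seed give identical output.
#'
#' @param x SAM/BAM path or record data frame ([compute_map_stats()] input).
#' @param n sample size cap (default one million reads).
#' @param seed integer seed for the sampling.
#' @param anchor `"midpoint"` or `"five_prime"`.
#' @return data frame `chrom`, `pos`, `strand` of class `qc_anchors`.
#' @export
sample_alignments <- function(x, n = 1e6, seed = 1L,
                              anchor = c("midpoint", "five_prime")) {
  anchor <- match.arg(anchor)
  stopifnot(n >= 1)
  rec <- as_sam_records(x)
  rec <- rec[bitwAnd(rec$flag, 0x100) == 0L &
               bitwAnd(rec$flag, 0x800) == 0L &
               bitwAnd(rec$flag, 0x4) == 0L, , drop = FALSE]
  if (!nrow(rec)) stop_ngsqc("zero mapped reads to sample from")

  proper <- bitwAnd(rec$flag, 0x1) > 0L & bitwAnd(rec$flag, 0x2) > 0L
  width <- cigar_ref_width(rec$cigar)
  start <- rec$pos
  end <- rec$pos + width - 1L
  strand <- ifelse(bitwAnd(rec$flag, 0x10) > 0L, "-", "+")

  if (any(proper)) {
    # one fragment per proper pair: join mate intervals by name
    pp <- rec[proper, , drop = FALSE]
    ps <- start[proper]; pe <- end[proper]
    frag_start <- tapply(ps, pp$qname, min)
    frag_end <- tapply(pe, pp$qname, max)
    first_mate <- !duplicated(pp$qname)
    frag <- data.frame(
      chrom = pp$rname[first_mate],
      start = as.integer(frag_start[pp$qname[first_mate]]),
      end = as.integer(frag_end[pp$qname[first_mate]]),
      strand = strand[proper][first_mate], stringsAsFactors = FALSE)
    rest <- data.frame(chrom = rec$rname[!proper], start = start[!proper],
                       end = end[!proper], strand = strand[!proper],
                       stringsAsFactors = FALSE)
    iv <- rbind(frag, rest)
  } else {
    iv <- data.frame(chrom = rec$rname, start = start, end = end,
                     strand = strand, stringsAsFactors = FALSE)
  }

  if (nrow(iv) > n) {
    keep <- with_seed(seed, sort(sample.int(nrow(iv), n)))
    iv <- iv[keep, , drop = FALSE]
  }
  pos <- if (anchor == "midpoint") {
    (iv$start + iv$end) %/% 2L
  } else {
    ifelse(iv$strand == "-", iv$end, iv$start)
  }
  structure(data.frame(chrom = iv$chrom, pos = pos, strand = iv$strand,
                       stringsAsFactors = FALSE),
            class = c("qc_anchors", "data.frame"))
}

# Reference-consuming CIGAR width (M, D, N, =, X); "*" counts as width 1.
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(1L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    w <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    max(w, 1L)
  }, 1L, USE.NAMES = FALSE)
}

#' LOC features: read fractions over the nine region categories
#'
#' Assigns every anchor to its region category and returns the fraction of
#' anchors per category. The distal-intergenic catch-all guarantees the
#' nine fractions sum to exactly 1.
#'
#' @param anchors a `qc_anchors` data frame from [sample_alignments()].
#' @param index a `qc_region_index`.
#' @return named numeric vector of 9 fractions, class `qc_loc_features`.
#' @export
loc_features <- function(anchors, index) {
  if (!nrow(anchors)) stop_ngsqc("empty anchors")
  cats <- suppressWarnings(category_of(index, anchors$chrom, anchors$pos))
  out <- as.numeric(table(cats)) / nrow(anchors)
  names(out) <- REGION_CATEGORIES
  structure(out, class = "qc_loc_features")
}

#' TSS features: binned read density around transcription start sites
#'
#' For every (anchor, TSS) pair whose transcription-oriented offset lies in
#' [-5000, 5000), increments the covering 1 kb bin; an anchor near several
#' TSSs contributes once per TSS. All ten bins are divided by the total
#' number of sampled anchors, making the profile comparable across files
#' regardless of how many reads were available.
#'
#' @param anchors a `qc_anchors` data frame.
#' @param tss a TSS table from [tss_list()].
#' @param halfwidth window half-width in bp (default 5000).
#' @param bins number of bins (default 10).
#' @return named numeric vector (`TSS-4500` ... `TSS+4500`), class
#'   `qc_tss_features`.
#' @export
tss_features <- function(anchors, tss, halfwidth = 5000, bins = 10L) {
  if (!nrow(anchors)) stop_ngsqc("empty anchors")
  if (!nrow(tss)) stop_ngsqc("empty TSS list")
  binw <- 2 * halfwidth / bins
  plus <- tss$strand != "-"
  win_start <- ifelse(plus, tss$tss - halfwidth, tss$tss - halfwidth + 1)
  win_end <- ifelse(plus, tss$tss + halfwidth - 1, tss$tss + halfwidth)
  win <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(pmax(1, win_start), win_end))
  q <- GenomicRanges::GRanges(anchors$chrom,
                              IRanges::IRanges(anchors$pos, width = 1L))
  GenomeInfoDb::seqlevels(q) <- union(GenomeInfoDb::seqlevels(q),
                                      GenomeInfoDb::seqlevels(win))
  GenomeInfoDb::seqlevels(win) <- GenomeInfoDb::seqlevels(q)
  hits <- GenomicRanges::findOverlaps(q, win, ignore.strand = TRUE)
  counts <- numeric(bins)
  if (length(hits)) {
    a <- S4Vectors::queryHits(hits); t <- S4Vectors::subjectHits(hits)
    off <- ifelse(plus[t], anchors$pos[a] - tss$tss[t],
                  tss$tss[t] - anchors$pos[a])
    in_win <- off >= -halfwidth & off < halfwidth
    b <- floor((off[in_win] + halfwidth) / binw) + 1L
    counts <- tabulate(b, nbins = bins)
  }
  out <- counts / nrow(anchors)
  names(out) <- if (bins == 10L && halfwidth == 5000) TSS_BIN_NAMES else
    paste0("TSS_bin", seq_len(bins))
  structure(out, class = "qc_tss_features")
}
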