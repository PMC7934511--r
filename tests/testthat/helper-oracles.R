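# Independent oracles, deliberately brute-force.

# Pairwise-concordance auROC: count over all (positive, negative) pairs,
# half credit for ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Brute-force region categorization: scan every gene's intervals and take
# the highest-priority category.
oracle_category <- function(model, chrom, pos, promoter_halfwidth = 3000,
                            downstream_length = 3000) {
  hits <- character(0)
  g <- model$genes
  if (nrow(g)) {
    for (i in seq_len(nrow(g))) {
      if (g$chrom[i] != chrom) next
      if (pos >= g$tss[i] - promoter_halfwidth &&
          pos <= g$tss[i] + promoter_halfwidth)
        hits <- c(hits, "promoter")
      if (g$strand[i] == "+") {
        if (pos > g$end[i] && pos <= g$end[i] + downstream_length)
          hits <- c(hits, "downstream")
      } else {
        if (pos < g$start[i] && pos >= g$start[i] - downstream_length)
          hits <- c(hits, "downstream")
      }
    }
  }
  in_gr <- function(gr, p, ch) {
    if (!length(gr)) return(logical(0))
    as.character(GenomicRanges::seqnames(gr)) == ch &
      GenomicRanges::start(gr) <= p & GenomicRanges::end(gr) >= p
  }
  if (any(in_gr(model$utr5, pos, chrom))) hits <- c(hits, "5UTR")
  if (any(in_gr(model$utr3, pos, chrom))) hits <- c(hits, "3UTR")
  ex_hit <- in_gr(model$exons, pos, chrom)
  if (any(ex_hit & model$exons$rank == 1L)) hits <- c(hits, "first exon")
  if (any(ex_hit & model$exons$rank > 1L)) hits <- c(hits, "other exon")
  in_hit <- in_gr(model$introns, pos, chrom)
  if (any(in_hit & model$introns$rank == 1L)) hits <- c(hits, "first intron")
  if (any(in_hit & model$introns$rank > 1L)) hits <- c(hits, "other intron")
  priority <- c("promoter", "5UTR", "3UTR", "first exon", "other exon",
                "first intron", "other intron", "downstream")
  for (p in priority) if (p %in% hits) return(p)
  "distal intergenic"
}

# Brute-force Dunn index over all point pairs.
oracle_dunn <- function(points, groups) {
  points <- as.matrix(points)
  n <- nrow(points)
  min_inter <- Inf; max_intra <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt(sum((points[i, ] - points[j, ])^2))
    if (groups[i] == groups[j]) max_intra <- max(max_intra, d)
    else min_inter <- min(min_inter, d)
  }
  if (max_intra == 0) return(if (min_inter > 0) Inf else 0)
  min_inter / max_intra
}

# Brute-force confusion-matrix precision/recall/F1 at one threshold.
oracle_prf <- function(p, y, t) {
  called <- p >= t
  tp <- sum(called & y == 1); fp <- sum(called & y == 0)
  fn <- sum(!called & y == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- tp / sum(y == 1)
  f1 <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec)
  else NA_real_
  c(precision = prec, recall = rec, f1 = f1)
}
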