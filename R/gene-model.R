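# Gene models from GTF. One representative transcript per gene (the
# longest) defines the exon/intron/UTR structure; "first exon/intron" is
# first in transcription order (strand-aware); the TSS is the 5' end of
# the gene span. All coordinates are 1-based inclusive (the GTF and
# GRanges convention).

#' The nine genomic region categories
#'
#' Fixed display order of the read-localization categories.
#' @export
REGION_CATEGORIES <- c("promoter", "5UTR", "first exon", "other exon",
                       "first intron", "other intron", "3UTR",
                       "downstream", "distal intergenic")

# Assignment priority: a position inside several region types receives the
# highest-priority one. UTRs outrank exon categories.
REGION_PRIORITY <- c("promoter", "5UTR", "3UTR", "first exon", "other exon",
                     "first intron", "other intron", "downstream")

#' Parse gene models from a GTF file
#'
#' Reads gene/transcript/exon (and optionally five_prime_utr /
#' three_prime_utr) features from a GTF annotation. For each gene the
#' longest transcript is taken as representative; its exons are ranked in
#' transcription order, introns are the exact gaps between consecutive
#' exons, and the TSS is the 5' end of the gene span (the highest
#' coordinate for minus-strand genes).
#'
#' @param path GTF file (1-based inclusive coordinates).
#' @return a `qc_gene_model` list with a `genes` data frame (gene_id,
#'   chrom, strand, start, end, tss) and `GRanges` components `exons`,
#'   `introns`, `utr5`, `utr3` carrying `gene_id` (and exon/intron `rank`
#'   in transcription order).
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop_ngsqc("GTF file not found: ", path)
  content <- readLines(path)
  content <- content[nzchar(content) & !startsWith(content, "#")]
  if (!length(content)) return(empty_gene_model())
  raw <- utils::read.delim(text = content, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c(V4 = "numeric", V5 = "numeric"))
  if (nrow(raw) && any(raw$V5 < raw$V4))
    stop_ngsqc("GTF parse error: feature end < start at line ",
               which(raw$V5 < raw$V4)[1L])
  gr <- rtracklayer::import(path, format = "gtf")
  if (!length(gr)) return(empty_gene_model())

  type <- as.character(gr$type)
  gid <- gr$gene_id
  tid <- if ("transcript_id" %in% names(S4Vectors::mcols(gr)))
    gr$transcript_id else rep(NA_character_, length(gr))

  tx <- gr[type == "transcript"]
  exons <- gr[type == "exon"]
  if (length(exons)) {
    orphan <- !(exons$transcript_id %in% tx$transcript_id)
    if (any(orphan))
      stop_ngsqc("exon without parent transcript: ",
                 exons$transcript_id[orphan][1L])
  }

  genes <- gr[type == "gene"]
  gene_ids <- unique(if (length(genes)) genes$gene_id else tx$gene_id)

  rep_tx <- vapply(gene_ids, function(g) {
    cand <- tx[tx$gene_id == g]
    if (!length(cand))
      stop_ngsqc("gene without transcript: ", g)
    cand$transcript_id[[which.max(GenomicRanges::width(cand))]]
  }, "")

  keep_ex <- exons[exons$transcript_id %in% rep_tx]
  ex_list <- S4Vectors::split(keep_ex, keep_ex$gene_id)

  gene_rows <- lapply(gene_ids, function(g) {
    if (length(genes) && g %in% genes$gene_id) {
      grow <- genes[genes$gene_id == g][1L]
    } else {
      grow <- range(tx[tx$gene_id == g])[1L]
    }
    st <- as.character(GenomicRanges::strand(grow))
    if (st == "*") st <- "+"
    s <- GenomicRanges::start(grow); e <- GenomicRanges::end(grow)
    data.frame(gene_id = g,
               chrom = as.character(GenomicRanges::seqnames(grow)),
               strand = st, start = s, end = e,
               tss = if (st == "+") s else e,
               stringsAsFactors = FALSE)
  })
  genes_df <- do.call(rbind, gene_rows)

  ex_out <- GenomicRanges::GRanges(); in_out <- GenomicRanges::GRanges()
  for (g in gene_ids) {
    ex <- ex_list[[g]]
    if (is.null(ex) || !length(ex)) next
    st <- genes_df$strand[genes_df$gene_id == g]
    o <- order(GenomicRanges::start(ex),
               decreasing = identical(st, "-"))
    ex <- ex[o]
    ex$rank <- seq_along(ex)
    ex$gene_id <- g
    S4Vectors::mcols(ex) <- S4Vectors::mcols(ex)[c("gene_id", "rank")]
    ex_out <- suppressWarnings(c(ex_out, ex))
    if (length(ex) > 1L) {
      sorted <- ex[order(GenomicRanges::start(ex))]
      istart <- GenomicRanges::end(sorted)[-length(sorted)] + 1L
      iend <- GenomicRanges::start(sorted)[-1L] - 1L
      ok <- iend >= istart
      if (any(ok)) {
        intr <- GenomicRanges::GRanges(
          seqnames = as.character(GenomicRanges::seqnames(ex))[1L],
          ranges = IRanges::IRanges(istart[ok], iend[ok]),
          strand = st)
        o2 <- order(GenomicRanges::start(intr),
                    decreasing = identical(st, "-"))
        intr <- intr[o2]
        intr$gene_id <- g
        intr$rank <- seq_along(intr)
        in_out <- suppressWarnings(c(in_out, intr))
      }
    }
  }

  utr_of <- function(what) {
    u <- gr[type %in% what]
    u <- u[u$transcript_id %in% rep_tx]
    if (length(u)) {
      u$gene_id <- u$gene_id
      S4Vectors::mcols(u) <- S4Vectors::mcols(u)["gene_id"]
    } else {
      S4Vectors::mcols(u) <- NULL
    }
    u
  }
  utr5 <- utr_of(c("five_prime_utr", "5UTR"))
  utr3 <- utr_of(c("three_prime_utr", "3UTR"))

  structure(list(genes = genes_df, exons = ex_out, introns = in_out,
                 utr5 = utr5, utr3 = utr3),
            class = "qc_gene_model")
}

empty_gene_model <- function() {
  structure(list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       strand = character(), start = numeric(),
                       end = numeric(), tss = numeric(),
                       stringsAsFactors = FALSE),
    exons = GenomicRanges::GRanges(), introns = GenomicRanges::GRanges(),
    utr5 = GenomicRanges::GRanges(), utr3 = GenomicRanges::GRanges()),
    class = "qc_gene_model")
}

#' @export
print.qc_gene_model <- function(x, ...) {
  cat("Gene model:", nrow(x$genes), "genes,",
      length(x$exons), "exons (representative transcripts)\n")
  invisible(x)
}

#' List transcription start sites
#'
#' One TSS per gene (the 5' end of the gene span, strand-aware), in
#' deterministic (chromosome, coordinate) order.
#'
#' @param model a `qc_gene_model`.
#' @return data frame with columns `chrom`, `tss`, `strand`, `gene_id`.
#' @export
tss_list <- function(model) {
  stopifnot(inherits(model, "qc_gene_model"))
  g <- model$genes
  out <- data.frame(chrom = g$chrom, tss = g$tss, strand = g$strand,
                    gene_id = g$gene_id, stringsAsFactors = FALSE)
  out[order(out$chrom, out$tss), , drop = FALSE]
}

#' Build the position-to-region-category index
#'
#' Assembles interval structures mapping any genomic position to exactly
#' one of the nine region categories, resolved by the fixed priority
#' promoter > 5'UTR > 3'UTR > first exon > other exon > first intron >
#' other intron > downstream > distal intergenic. The promoter is the TSS
#' +/- `promoter_halfwidth`; downstream is the `downstream_length` window
#' past the gene's 3' end, strand-aware. Positions outside every
#' gene-linked interval are distal intergenic.
#'
#' @param model a `qc_gene_model`.
#' @param promoter_halfwidth promoter half-window in bp (default 3000).
#' @param downstream_length downstream window length in bp (default 3000).
#' @return a `qc_region_index`.
#' @export
build_region_index <- function(model, promoter_halfwidth = 3000,
                               downstream_length = 3000) {
  stopifnot(inherits(model, "qc_gene_model"))
  g <- model$genes
  pieces <- list()
  if (nrow(g)) {
    prom <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(pmax(1, g$tss - promoter_halfwidth),
                                g$tss + promoter_halfwidth))
    prom$category <- "promoter"
    plus <- g$strand == "+"
    dstart <- ifelse(plus, g$end + 1, pmax(1, g$start - downstream_length))
    dend <- ifelse(plus, g$end + downstream_length, g$start - 1)
    okd <- dend >= dstart
    down <- GenomicRanges::GRanges(g$chrom[okd],
                                   IRanges::IRanges(dstart[okd], dend[okd]))
    if (length(down)) down$category <- "downstream"
    pieces <- c(pieces, list(prom, down))
  }
  cat_gr <- function(gr, category) {
    if (is.null(gr) || !length(gr)) return(NULL)
    out <- GenomicRanges::granges(gr)
    out$category <- category
    out
  }
  ex <- model$exons; intr <- model$introns
  pieces <- c(pieces, list(
    cat_gr(model$utr5, "5UTR"),
    cat_gr(model$utr3, "3UTR"),
    cat_gr(if (length(ex)) ex[ex$rank == 1L] else NULL, "first exon"),
    cat_gr(if (length(ex)) ex[ex$rank > 1L] else NULL, "other exon"),
    cat_gr(if (length(intr)) intr[intr$rank == 1L] else NULL, "first intron"),
    cat_gr(if (length(intr)) intr[intr$rank > 1L] else NULL, "other intron")))
  pieces <- Filter(function(p) !is.null(p) && length(p), pieces)
  regions <- if (length(pieces)) {
    r <- suppressWarnings(do.call(c, lapply(pieces, function(p) {
      GenomicRanges::strand(p) <- "*"
      p
    })))
    r$priority <- match(r$category, REGION_PRIORITY)
    r
  } else {
    GenomicRanges::GRanges()
  }
  structure(list(regions = regions,
                 params = list(promoter_halfwidth = promoter_halfwidth,
                               downstream_length = downstream_length),
                 chroms = unique(g$chrom)),
            class = "qc_region_index")
}

#' @export
print.qc_region_index <- function(x, ...) {
  cat("Region index:", length(x$regions), "intervals; promoter +/-",
      x$params$promoter_halfwidth, "bp, downstream",
      x$params$downstream_length, "bp\n")
  invisible(x)
}

#' Resolve positions to region categories
#'
#' Maps each (chromosome, position) to exactly one of the nine region
#' categories via the index's priority scheme. Positions on chromosomes
#' unknown to the index resolve to distal intergenic with a warning.
#'
#' @param index a `qc_region_index`.
#' @param chrom character vector of chromosome names.
#' @param position numeric vector of 1-based positions (recycled against
#'   `chrom`).
#' @return factor with the nine [REGION_CATEGORIES] levels.
#' @export
category_of <- function(index, chrom, position) {
  stopifnot(inherits(index, "qc_region_index"))
  if (any(position < 0)) stop_ngsqc("positions must be non-negative")
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n); position <- rep_len(position, n)
  out <- rep("distal intergenic", n)
  known <- chrom %in% GenomeInfoDb::seqlevels(index$regions) |
    chrom %in% index$chroms
  if (any(!known))
    warning("position(s) on chromosome(s) unknown to the index: ",
            paste(unique(chrom[!known]), collapse = ", "),
            "; resolved as distal intergenic", call. = FALSE)
  idx <- which(known & position >= 1)
  if (length(idx) && length(index$regions)) {
    q <- GenomicRanges::GRanges(chrom[idx],
                                IRanges::IRanges(position[idx], width = 1L))
    hits <- GenomicRanges::findOverlaps(q, index$regions,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      pr <- index$regions$priority[S4Vectors::subjectHits(hits)]
      first_of <- split(seq_along(qh), qh)
      sel <- vapply(names(first_of), function(k) {
        ids <- first_of[[k]]
        ids[[which.min(pr[ids])]]
      }, 1L)
      out[idx[as.integer(names(first_of))]] <-
        index$regions$category[S4Vectors::subjectHits(hits)[sel]]
    }
  }
  factor(out, levels = REGION_CATEGORIES)
}
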