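# GTF parsing, gene models and the region-category index.

simple_gtf <- function(strand = "+") {
  at <- 'gene_id "g1"; transcript_id "g1.t1";'
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    sprintf('chr1\ttest\tgene\t101\t400\t.\t%s\t.\tgene_id "g1";', strand),
    sprintf("chr1\ttest\ttranscript\t101\t400\t.\t%s\t.\t%s", strand, at),
    sprintf("chr1\ttest\texon\t101\t200\t.\t%s\t.\t%s", strand, at),
    sprintf("chr1\ttest\texon\t301\t400\t.\t%s\t.\t%s", strand, at)), p)
  p
}

test_that("gene structure follows transcription order", {
  m <- parse_gtf(simple_gtf("+"))
  expect_equal(m$genes$tss, 101)
  intr <- m$introns
  expect_equal(GenomicRanges::start(intr), 201)
  expect_equal(GenomicRanges::end(intr), 300)
  expect_equal(intr$rank, 1L)
  first_ex <- m$exons[m$exons$rank == 1L]
  expect_equal(GenomicRanges::start(first_ex), 101)

  mm <- parse_gtf(simple_gtf("-"))
  expect_equal(mm$genes$tss, 400)
  first_ex_m <- mm$exons[mm$exons$rank == 1L]
  expect_equal(GenomicRanges::start(first_ex_m), 301)
  expect_equal(GenomicRanges::end(first_ex_m), 400)
})

test_that("invalid GTF coordinates and orphans are rejected", {
  p <- tempfile(fileext = ".gtf")
  writeLines(
    'chr1\ttest\tgene\t400\t101\t.\t+\t.\tgene_id "g1";', p)
  expect_error(parse_gtf(p), "end < start")

  writeLines(c(
    'chr1\ttest\tgene\t101\t400\t.\t+\t.\tgene_id "g1";',
    'chr1\ttest\ttranscript\t101\t400\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "ghost";'),
    p)
  expect_error(parse_gtf(p), "without parent transcript")
})

test_that("region priorities resolve as documented", {
  m <- parse_gtf(write_two_gene_gtf())
  idx <- build_region_index(m)
  # inside the promoter window
  expect_equal(as.character(category_of(idx, "chrT", 10001 - 1000)),
               "promoter")
  # first-exon position that also sits in a promoter window stays promoter
  expect_equal(as.character(category_of(idx, "chrT", 10500)), "promoter")
  # interior first-exon position beyond the promoter and the 5'UTR
  expect_equal(as.character(category_of(idx, "chrT", 11900)), "promoter")
  idx_narrow <- build_region_index(m, promoter_halfwidth = 500)
  expect_equal(as.character(category_of(idx_narrow, "chrT", 11900)),
               "first exon")
  # far from every gene
  expect_equal(as.character(category_of(idx, "chrT", 40000)),
               "distal intergenic")
  # downstream of the plus-strand gene (past its 3' end)
  expect_equal(as.character(category_of(idx_narrow, "chrT", 21000)),
               "downstream")
})

test_that("lookups match the brute-force interval scan", {
  g <- make_genome(seed = 31, n_chromosomes = 2, chrom_length = 1.5e5,
                   n_genes = 8)
  m <- parse_gtf(g$gtf)
  idx <- build_region_index(m)
  set.seed(32)
  chrom <- sample(g$chroms, 500, replace = TRUE)
  pos <- sample.int(g$chrom_length, 500, replace = TRUE)
  got <- as.character(category_of(idx, chrom, pos))
  want <- mapply(function(ch, p) oracle_category(m, ch, p), chrom, pos)
  expect_identical(got, unname(want))
})

test_that("every position resolves to exactly one category", {
  m <- parse_gtf(write_two_gene_gtf())
  idx <- build_region_index(m)
  pos <- seq(1, 80000, by = 97)
  cats <- category_of(idx, "chrT", pos)
  expect_false(anyNA(cats))
  expect_length(cats, length(pos))
  expect_true(all(as.character(cats) %in% REGION_CATEGORIES))
})

test_that("mirrored layouts preserve promoter and downstream classes", {
  L <- 100000
  m <- parse_gtf(simple_gtf("+"))
  idx <- build_region_index(m, promoter_halfwidth = 50,
                            downstream_length = 100)
  # mirror: gene span [101,400] + strand maps to [L-400+1, L-100] - strand
  mirror_gtf <- tempfile(fileext = ".gtf")
  at <- 'gene_id "g1"; transcript_id "g1.t1";'
  writeLines(c(
    sprintf('chr1\ttest\tgene\t%d\t%d\t.\t-\t.\tgene_id "g1";',
            L - 400 + 1, L - 101 + 1),
    sprintf("chr1\ttest\ttranscript\t%d\t%d\t.\t-\t.\t%s",
            L - 400 + 1, L - 101 + 1, at),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t-\t.\t%s",
            L - 200 + 1, L - 101 + 1, at),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t-\t.\t%s",
            L - 400 + 1, L - 301 + 1, at)), mirror_gtf)
  m2 <- parse_gtf(mirror_gtf)
  idx2 <- build_region_index(m2, promoter_halfwidth = 50,
                             downstream_length = 100)
  for (p in c(101, 90, 250, 350, 420, 480, 600)) {
    expect_identical(as.character(category_of(idx, "chr1", p)),
                     as.character(category_of(idx2, "chr1", L - p + 1)),
                     label = paste("mirrored position", p))
  }
})

test_that("tss_list is complete, ordered and strand-aware", {
  g <- make_genome(seed = 33, n_genes = 3, chrom_length = 1e5,
                   n_chromosomes = 1)
  m <- parse_gtf(g$gtf)
  tl <- tss_list(m)
  expect_equal(nrow(tl), 3L)
  expect_true(!is.unsorted(tl$tss))
  minus <- m$genes[m$genes$strand == "-", ]
  if (nrow(minus))
    expect_true(all(tl$tss[match(minus$gene_id, tl$gene_id)] == minus$end))

  empty <- parse_gtf({p <- tempfile(); writeLines(character(0), p); p})
  expect_equal(nrow(tss_list(empty)), 0L)
  idx <- build_region_index(empty)
  expect_equal(as.character(suppressWarnings(
    category_of(idx, "chrX", 5000))), "distal intergenic")
})

test_that("bad queries are handled", {
  m <- parse_gtf(write_two_gene_gtf())
  idx <- build_region_index(m)
  expect_error(category_of(idx, "chrT", -5), "non-negative")
  expect_warning(res <- category_of(idx, "chrUnknown", 100), "unknown")
  expect_equal(as.character(res), "distal intergenic")
})
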