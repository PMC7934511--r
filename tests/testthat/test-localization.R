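# Read-anchor sampling and the LOC / TSS feature sets.

make_anchors <- function(chrom, pos) {
  structure(data.frame(chrom = chrom, pos = pos,
                       strand = rep("+", length(pos)),
                       stringsAsFactors = FALSE),
            class = c("qc_anchors", "data.frame"))
}

test_that("sampling keeps everything when fewer reads than requested", {
  g <- make_genome(seed = 40, n_genes = 2, chrom_length = 1e5)
  aln <- simulate_alignments(g, mapping_profile(unique = 1, multi = 0,
                                                unmapped = 0),
                             n_reads = 500, seed = 41)
  a <- sample_alignments(aln$sam, n = 1e6, seed = 1)
  expect_equal(nrow(a), 500L)

  a1 <- sample_alignments(aln$sam, n = 100, seed = 7)
  a2 <- sample_alignments(aln$sam, n = 100, seed = 7)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 100L)

  unmapped_only <- sam_records(rep(4L, 3))
  expect_error(sample_alignments(unmapped_only, seed = 1),
               "zero mapped")
})

test_that("subsampling is position-unbiased", {
  # uniform positions; the retained subsample should still look uniform
  rec <- sam_records(rep(0L, 10000), pos = seq_len(10000))
  a <- sample_alignments(rec, n = 100, seed = 43)
  ks <- suppressWarnings(stats::ks.test(a$pos, "punif", 1, 10000))
  expect_gt(ks$p.value, 0.01)
})

test_that("LOC fractions match direct categorization and sum to one", {
  m <- parse_gtf(write_two_gene_gtf())
  idx <- build_region_index(m, promoter_halfwidth = 500)
  # anchors placed in gA's first exon, beyond promoter and 5'UTR
  a <- make_anchors("chrT", rep(11500, 20))
  lf <- loc_features(a, idx)
  expect_equal(unname(lf[["first exon"]]), 1)
  expect_equal(sum(lf), 1)

  # anchors on a gene-free chromosome: all distal intergenic
  empty <- parse_gtf({p <- tempfile(); writeLines(character(0), p); p})
  lf2 <- loc_features(make_anchors("chrZ", c(100, 5000, 99999)),
                      build_region_index(empty))
  expect_equal(unname(lf2[["distal intergenic"]]), 1)

  # random anchors: fractions equal brute-force per-anchor counts
  g <- make_genome(seed = 44, n_genes = 6, chrom_length = 1.5e5)
  mg <- parse_gtf(g$gtf)
  idxg <- build_region_index(mg)
  set.seed(45)
  a3 <- make_anchors(sample(g$chroms, 300, replace = TRUE),
                     sample.int(g$chrom_length, 300))
  lf3 <- loc_features(a3, idxg)
  want <- table(factor(mapply(function(ch, p) oracle_category(mg, ch, p),
                              a3$chrom, a3$pos),
                       levels = REGION_CATEGORIES)) / nrow(a3)
  expect_equal(unname(as.numeric(lf3)), unname(as.numeric(want)))
  expect_equal(sum(lf3), 1)
})

test_that("TSS bins follow the offset and strand conventions", {
  tss <- data.frame(chrom = "chrT", tss = 50000, strand = "+",
                    gene_id = "g1", stringsAsFactors = FALSE)
  # single anchor at offset -4200: bin TSS-4500 gets 1/total
  a <- make_anchors("chrT", 50000 - 4200)
  tf <- tss_features(a, tss)
  expect_equal(unname(tf[["TSS-4500"]]), 1)
  expect_equal(sum(tf), 1)

  # offset +5 relative to a minus-strand TSS lands in TSS+500
  tss_m <- transform(tss, strand = "-")
  a2 <- make_anchors("chrT", 50000 - 5)
  tf2 <- tss_features(a2, tss_m)
  expect_equal(unname(tf2[["TSS+500"]]), 1)

  # an anchor 20 kb away contributes to no bin
  tf3 <- tss_features(make_anchors("chrT", 70000), tss)
  expect_equal(sum(tf3), 0)

  # window boundaries: -5000 is inside the first bin, +5000 outside
  expect_equal(unname(tss_features(make_anchors("chrT", 45000),
                                   tss)[["TSS-4500"]]), 1)
  expect_equal(sum(tss_features(make_anchors("chrT", 55000), tss)), 0)
  expect_equal(unname(tss_features(make_anchors("chrT", 54999),
                                   tss)[["TSS+4500"]]), 1)
})

test_that("TSS profiles are order- and naming-invariant, seeds reproduce", {
  g <- make_genome(seed = 46, n_genes = 5, chrom_length = 1.5e5)
  m <- parse_gtf(g$gtf)
  tl <- tss_list(m)
  aln <- simulate_alignments(g, mapping_profile(
    unique = 1, multi = 0, unmapped = 0,
    placement = c(exonic = 0.5, promoter = 0.5, uniform = 0)),
    n_reads = 2000, seed = 47)
  a <- sample_alignments(aln$sam, n = 1500, seed = 48)
  tf <- tss_features(a, tl)

  perm <- a[sample.int(nrow(a)), , drop = FALSE]
  class(perm) <- class(a)
  expect_equal(tss_features(perm, tl), tf)

  renamed <- a
  renamed$chrom <- sub("^chr", "CHROM", renamed$chrom)
  tl2 <- tl
  tl2$chrom <- sub("^chr", "CHROM", tl2$chrom)
  expect_equal(unname(unclass(tss_features(renamed, tl2))),
               unname(unclass(tf)))

  a_again <- sample_alignments(aln$sam, n = 1500, seed = 48)
  expect_identical(tss_features(a_again, tl), tf)
  idx <- build_region_index(m)
  expect_identical(loc_features(a_again, idx), loc_features(a, idx))

  # anchors far from genes: TSS bins empty, LOC collapses to distal
  far <- make_anchors("chr2", seq(120000, 149000, by = 1000))
  gtf_one <- write_two_gene_gtf()
  m1 <- parse_gtf(gtf_one)
  expect_equal(sum(suppressWarnings(tss_features(far, tss_list(m1)))), 0)
  lf <- suppressWarnings(loc_features(far, build_region_index(m1)))
  expect_equal(unname(lf[["distal intergenic"]]), 1)
})

test_that("empty inputs error", {
  m <- parse_gtf(write_two_gene_gtf())
  idx <- build_region_index(m)
  empty <- make_anchors(character(0), numeric(0))
  expect_error(loc_features(empty, idx), "empty")
  expect_error(tss_features(empty, tss_list(m)), "empty")
  a <- make_anchors("chrT", 100)
  expect_error(tss_features(a, tss_list(parse_gtf({
    p <- tempfile(); writeLines(character(0), p); p}))), "empty TSS")
})
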