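# Shared fixtures, built in code at test time.

# Write a FASTQ file from explicit records.
write_fastq_records <- function(seqs, quals = NULL, ids = NULL,
                                path = tempfile(fileext = ".fastq")) {
  n <- length(seqs)
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(L)
      paste(rep("I", L), collapse = ""), "")
  if (is.null(ids)) ids <- paste0("read_", seq_len(n))
  out <- character(4L * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", ids)
  out[seq(2, by = 4, length.out = n)] <- seqs
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- quals
  writeLines(out, path)
  path
}

# Random read sequences under a local seed.
random_seqs <- function(n, len = 50L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

quality_string <- function(q, len) {
  paste(rep(intToUtf8(q + 33L), len), collapse = "")
}

# A tiny hand-written two-gene GTF (one gene per strand).
write_two_gene_gtf <- function(path = tempfile(fileext = ".gtf")) {
  at <- function(g) sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
  lines <- c(
    sprintf('chrT\ttest\tgene\t10001\t20000\t.\t+\t.\tgene_id "gA";'),
    sprintf("chrT\ttest\ttranscript\t10001\t20000\t.\t+\t.\t%s", at("gA")),
    sprintf("chrT\ttest\texon\t10001\t12000\t.\t+\t.\t%s", at("gA")),
    sprintf("chrT\ttest\texon\t15001\t20000\t.\t+\t.\t%s", at("gA")),
    sprintf("chrT\ttest\tfive_prime_utr\t10001\t10100\t.\t+\t.\t%s", at("gA")),
    sprintf("chrT\ttest\tthree_prime_utr\t19901\t20000\t.\t+\t.\t%s", at("gA")),
    sprintf('chrT\ttest\tgene\t60001\t66000\t.\t-\t.\tgene_id "gB";'),
    sprintf("chrT\ttest\ttranscript\t60001\t66000\t.\t-\t.\t%s", at("gB")),
    sprintf("chrT\ttest\texon\t60001\t61000\t.\t-\t.\t%s", at("gB")),
    sprintf("chrT\ttest\texon\t63001\t66000\t.\t-\t.\t%s", at("gB")))
  writeLines(lines, path)
  path
}

# SAM record data frame in the internal reader's shape.
sam_records <- function(flag, rname = "chr1", pos = 100L, nh = 1L,
                        qname = NULL) {
  n <- length(flag)
  data.frame(qname = qname %||% paste0("r", seq_len(n)),
             flag = as.integer(flag),
             rname = rep_len(rname, n), pos = rep_len(as.integer(pos), n),
             cigar = rep_len("50M", n), nh = rep_len(as.integer(nh), n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
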