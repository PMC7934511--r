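# Seeded synthetic-data generators: small genomes with gene annotation,
# FASTQ files with controllable quality degradation, alignment files with
# controlled mapping-outcome mixtures and placement biases (plus the
# matching aligner-style log), and labeled feature tables with known
# class separation. Every generator is a pure function of its parameters
# and seed.

#' Quality degradation profile
#'
#' Knobs emulating the failure modes behind the RAW report flags. The
#' zero profile produces pristine reads (all eleven flags Pass at
#' realistic read counts).
#'
#' @param base_quality_mean mean Phred base quality at position 1.
#' @param decay per-position linear quality decay (Phred/position).
#' @param adapter_rate fraction of reads carrying the adapter suffix;
#'   contaminated counts are exact (`ceiling(rate * n_reads)`).
#' @param duplication_rate fraction of reads drawn from a small pool of
#'   template sequences.
#' @param gc_bias fraction of reads drawn from a GC-rich composition
#'   (bimodal GC contamination).
#' @param n_rate per-base probability of an N call.
#' @return a `qc_degradation_profile` list.
#' @export
degradation_profile <- function(base_quality_mean = 36, decay = 0,
                                adapter_rate = 0, duplication_rate = 0,
                                gc_bias = 0, n_rate = 0) {
  rates <- c(adapter_rate = adapter_rate,
             duplication_rate = duplication_rate,
             gc_bias = gc_bias, n_rate = n_rate)
  if (any(rates < 0 | rates > 1))
    stop_ngsqc("degradation rates must lie in [0, 1]")
  if (base_quality_mean < 2 || base_quality_mean > 41 || decay < 0)
    stop_ngsqc("invalid quality parameters")
  structure(list(base_quality_mean = base_quality_mean, decay = decay,
                 adapter_rate = adapter_rate,
                 duplication_rate = duplication_rate,
                 gc_bias = gc_bias, n_rate = n_rate),
            class = "qc_degradation_profile")
}

#' Mapping outcome and placement profile
#'
#' @param unique,multi,unmapped mapping-outcome fractions (sum to 1).
#' @param placement weights over `c(exonic, promoter, uniform)` genomic
#'   placement for mapped reads (sum to 1).
#' @return a `qc_mapping_profile` list.
#' @export
mapping_profile <- function(unique = 0.8, multi = 0.1, unmapped = 0.1,
                            placement = c(exonic = 0, promoter = 0,
                                          uniform = 1)) {
  if (abs(unique + multi + unmapped - 1) > 1e-9)
    stop_ngsqc("mapping fractions must sum to 1")
  placement <- placement[c("exonic", "promoter", "uniform")]
  if (anyNA(placement) || abs(sum(placement) - 1) > 1e-9)
    stop_ngsqc("placement weights must be named exonic/promoter/uniform ",
               "and sum to 1")
  structure(list(unique = unique, multi = multi, unmapped = unmapped,
                 placement = placement), class = "qc_mapping_profile")
}

#' Generate a small genome with gene annotation
#'
#' Writes a random genome FASTA and a matching GTF with `n_genes` genes
#' (2-6 exons each, 5'/3' UTRs, both strands, >= 10 kb spacing between
#' genes). Byte-identical output for identical parameters and seed.
#'
#' @param seed integer seed.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total number of genes (0 gives an empty GTF).
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gtf` paths and the `genes` layout table.
#' @export
make_genome <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 2e5,
                        n_genes = 8L, dir = tempfile("genome")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "genes.gtf")
  chroms <- paste0("chr", seq_len(n_chromosomes))
  with_seed(seed, {
    seqs <- vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = ""), "")
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- chroms
    Biostrings::writeXStringSet(set, fasta, width = 80L)

    lines <- character(0)
    genes <- NULL
    if (n_genes > 0L) {
      per_chrom <- table(factor(chroms[1L + (seq_len(n_genes) - 1L) %%
                                         n_chromosomes], levels = chroms))
      gi <- 0L
      rows <- list()
      for (ch in chroms) {
        cursor <- 10000L
        for (k in seq_len(per_chrom[[ch]])) {
          gi <- gi + 1L
          n_ex <- sample(2:6, 1L)
          ex_len <- sample(150:600, n_ex, replace = TRUE)
          in_len <- if (n_ex > 1L) sample(200:1500, n_ex - 1L,
                                          replace = TRUE) else integer(0)
          span <- sum(ex_len) + sum(in_len)
          start <- cursor + sample(0:2000, 1L)
          end <- start + span - 1L
          if (end + 10000L > chrom_length)
            stop_ngsqc("infeasible packing: genes do not fit chromosome ",
                       ch, " with 10 kb spacing")
          strand <- sample(c("+", "-"), 1L)
          ex_start <- integer(n_ex); ex_end <- integer(n_ex)
          p <- start
          for (e in seq_len(n_ex)) {
            ex_start[e] <- p
            ex_end[e] <- p + ex_len[e] - 1L
            p <- ex_end[e] + if (e < n_ex) in_len[e] + 1L else 1L
          }
          gid <- sprintf("gene%03d", gi)
          tid <- paste0(gid, ".t1")
          rows[[gi]] <- data.frame(gene_id = gid, chrom = ch,
                                   strand = strand, start = start,
                                   end = end, stringsAsFactors = FALSE)
          at <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
          gl <- function(type, s, e)
            sprintf("%s\tngsqc\t%s\t%d\t%d\t.\t%s\t.\t%s",
                    ch, type, s, e, strand, at)
          # UTRs occupy the outer ends of the terminal exons in
          # transcription order
          u5_len <- sample(50:150, 1L); u3_len <- sample(50:150, 1L)
          if (strand == "+") {
            utr5 <- c(ex_start[1L], min(ex_end[1L], ex_start[1L] + u5_len))
            utr3 <- c(max(ex_start[n_ex], ex_end[n_ex] - u3_len),
                      ex_end[n_ex])
          } else {
            utr5 <- c(max(ex_start[n_ex], ex_end[n_ex] - u5_len),
                      ex_end[n_ex])
            utr3 <- c(ex_start[1L], min(ex_end[1L], ex_start[1L] + u3_len))
          }
          lines <- c(lines,
                     sprintf("%s\tngsqc\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                             ch, start, end, strand, gid),
                     gl("transcript", start, end),
                     vapply(seq_len(n_ex),
                            function(e) gl("exon", ex_start[e], ex_end[e]),
                            ""),
                     gl("five_prime_utr", utr5[1L], utr5[2L]),
                     gl("three_prime_utr", utr3[1L], utr3[2L]))
          cursor <- end + 10000L
        }
      }
      genes <- do.call(rbind, rows)
    }
    writeLines(lines, gtf)
  })
  list(fasta = fasta, gtf = gtf, genes = genes,
       chrom_length = chrom_length, chroms = chroms)
}

QC_ADAPTER_SEQ <- "AGATCGGAAGAG"

#' Simulate a FASTQ file with controlled degradation
#'
#' Base qualities are drawn per position from a normal around
#' `base_quality_mean - decay * position`, clipped to [2, 40]; adapter
#' contamination replaces the read suffix with a fixed 12-mer in an exact
#' `ceiling(adapter_rate * n_reads)` count of reads; duplicated reads are
#' copies from a small template pool; `gc_bias` reads use a GC-rich base
#' composition; N calls are injected per base at `n_rate`. With the zero
#' profile all eleven RAW flags come out Pass (at realistic read counts);
#' `adapter_rate >= 0.1` drives the adapter flag to Fail and
#' `duplication_rate >= 0.6` the duplication flag.
#'
#' @param profile a `qc_degradation_profile`.
#' @param n_reads number of reads (>= 1).
#' @param read_length read length in bp.
#' @param seed integer seed.
#' @param path output FASTQ path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(profile = degradation_profile(), n_reads = 10000L,
                           read_length = 100L, seed = 1L,
                           path = tempfile(fileext = ".fastq")) {
  if (!inherits(profile, "qc_degradation_profile"))
    stop_ngsqc("profile must come from degradation_profile()")
  stopifnot(n_reads >= 1L, read_length >= 20L)
  with_seed(seed, {
    n <- as.integer(n_reads); L <- as.integer(read_length)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(bases, L, replace = TRUE), collapse = ""), "")

    n_gc <- ceiling(profile$gc_bias * n)
    if (n_gc > 0L) {
      idx <- sample.int(n, n_gc)
      seqs[idx] <- vapply(idx, function(i)
        paste(sample(bases, L, replace = TRUE,
                     prob = c(0.08, 0.42, 0.42, 0.08)), collapse = ""), "")
    }

    n_dup <- ceiling(profile$duplication_rate * n)
    if (n_dup > 0L) {
      pool <- seqs[seq_len(max(1L, min(n %/% 1000L, 20L)))]
      idx <- sample.int(n, n_dup)
      seqs[idx] <- sample(pool, n_dup, replace = TRUE)
    }

    n_ad <- ceiling(profile$adapter_rate * n)
    if (n_ad > 0L) {
      idx <- sample.int(n, n_ad)
      ad_start <- L - nchar(QC_ADAPTER_SEQ) + 1L
      substr(seqs[idx], ad_start, L) <- QC_ADAPTER_SEQ
    }

    if (profile$n_rate > 0) {
      mask <- matrix(stats::runif(n * L) < profile$n_rate, nrow = n)
      for (i in which(rowSums(mask) > 0L)) {
        s <- strsplit(seqs[i], "")[[1L]]
        s[mask[i, ]] <- "N"
        seqs[i] <- paste(s, collapse = "")
      }
    }

    mu <- profile$base_quality_mean - profile$decay * (seq_len(L) - 1L)
    qm <- matrix(stats::rnorm(n * L, mean = rep(mu, each = n), sd = 2),
                 nrow = n)
    qm <- round(qm)
    qm[qm > 40] <- 40
    qm[qm < 2] <- 2
    quals <- apply(qm, 1L, function(q) intToUtf8(q + 33L))

    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    out <- character(4L * n)
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@read_", seq_len(n))
    out[seq(2L, by = 4L, length.out = n)] <- seqs
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- quals
    writeLines(out, con)
  })
  invisible(path)
}

#' Simulate alignments and the matching aligner log
#'
#' Draws mapping outcomes per read (or pair) from the profile's
#' fractions, places mapped reads according to the placement mixture
#' (exonic / promoter / uniform), and writes a SAM file together with an
#' aligner-style summary log computed from the same counts, so
#' [parse_alignment_log()] and [compute_map_stats()] agree on the output.
#'
#' @param genome a [make_genome()] result (or a compatible list with
#'   `chroms`, `chrom_length`, `genes`).
#' @param profile a `qc_mapping_profile`.
#' @param n_reads number of reads (single-end) or pairs (paired-end).
#' @param seed integer seed.
#' @param layout `"single"` or `"paired"`.
#' @param read_length aligned read length in bp.
#' @param promoter_halfwidth promoter placement window half-width.
#' @param dir output directory.
#' @return list with `sam` and `log` paths.
#' @export
simulate_alignments <- function(genome, profile = mapping_profile(),
                                n_reads = 10000L, seed = 1L,
                                layout = c("single", "paired"),
                                read_length = 100L,
                                promoter_halfwidth = 3000L,
                                dir = tempfile("aln")) {
  layout <- match.arg(layout)
  if (!inherits(profile, "qc_mapping_profile"))
    stop_ngsqc("profile must come from mapping_profile()")
  needs_genes <- profile$placement[["exonic"]] > 0 ||
    profile$placement[["promoter"]] > 0
  if (needs_genes && (is.null(genome$genes) || !nrow(genome$genes)))
    stop_ngsqc("profile/genome mismatch: gene-linked placement requested ",
               "but the genome has no genes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, paste0("sample_", layout, ".sam"))
  log <- file.path(dir, paste0("sample_", layout, ".log"))

  counts <- exact_counts(n_reads, c(unique = profile$unique,
                                    multi = profile$multi,
                                    unmapped = profile$unmapped))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chroms,
                      genome$chrom_length))

  with_seed(seed, {
    place <- function(k) {
      if (k == 0L)
        return(data.frame(chrom = character(), pos = integer()))
      kind <- sample(c("exonic", "promoter", "uniform"), k, replace = TRUE,
                     prob = profile$placement)
      chrom <- character(k); pos <- integer(k)
      g <- genome$genes
      for (i in seq_len(k)) {
        if (kind[i] == "uniform" || is.null(g)) {
          chrom[i] <- sample(genome$chroms, 1L)
          pos[i] <- sample.int(genome$chrom_length - read_length, 1L)
        } else {
          row <- g[sample.int(nrow(g), 1L), ]
          chrom[i] <- row$chrom
          if (kind[i] == "promoter") {
            tssp <- if (row$strand == "+") row$start else row$end
            pos[i] <- max(1L, tssp + sample(seq(-promoter_halfwidth,
                                                promoter_halfwidth), 1L))
          } else {
            pos[i] <- sample(seq(row$start, max(row$start, row$end -
                                                  read_length)), 1L)
          }
        }
      }
      data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    }

    if (layout == "single") {
      recs <- character(0)
      pl_u <- place(counts[["unique"]])
      if (counts[["unique"]] > 0L)
        recs <- c(recs, sprintf(
          "uniq_%d\t0\t%s\t%d\t42\t%dM\t*\t0\t0\t*\t*\tNH:i:1",
          seq_len(counts[["unique"]]), pl_u$chrom, pl_u$pos, read_length))
      pl_m <- place(counts[["multi"]])
      if (counts[["multi"]] > 0L) {
        alt <- place(counts[["multi"]])
        recs <- c(recs,
          sprintf("multi_%d\t0\t%s\t%d\t1\t%dM\t*\t0\t0\t*\t*\tNH:i:2",
                  seq_len(counts[["multi"]]), pl_m$chrom, pl_m$pos,
                  read_length),
          sprintf("multi_%d\t256\t%s\t%d\t1\t%dM\t*\t0\t0\t*\t*\tNH:i:2",
                  seq_len(counts[["multi"]]), alt$chrom, alt$pos,
                  read_length))
      }
      if (counts[["unmapped"]] > 0L)
        recs <- c(recs, sprintf(
          "unm_%d\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
          seq_len(counts[["unmapped"]])))
      writeLines(c(header, recs), sam)
      writeLines(single_end_log(n_reads, counts), log)
    } else {
      conc1 <- counts[["unique"]]; concm <- counts[["multi"]]
      conc0 <- counts[["unmapped"]]
      disc1 <- floor(conc0 * 0.25)
      leftover <- conc0 - disc1
      mate_counts <- exact_counts(2L * leftover,
                                  c(unmapped = 0.5, unique = 0.3,
                                    multi = 0.2))
      recs <- character(0)
      pid <- 0L
      emit_pair <- function(qname, flag1, flag2, c1, p1, c2, p2, nh) {
        tagged <- if (is.na(nh)) "" else sprintf("\tNH:i:%d", nh)
        c(sprintf("%s\t%d\t%s\t%d\t42\t%dM\t=\t%d\t0\t*\t*%s",
                  qname, flag1, c1, p1, read_length, p2, tagged),
          sprintf("%s\t%d\t%s\t%d\t42\t%dM\t=\t%d\t0\t*\t*%s",
                  qname, flag2, c2, p2, read_length, p1, tagged))
      }
      if (conc1 > 0L) {
        pl <- place(conc1)
        for (i in seq_len(conc1)) {
          pid <- pid + 1L
          recs <- c(recs, emit_pair(paste0("pair_", pid),
                                    bitwOr(bitwOr(1L, 2L), 64L),
                                    bitwOr(bitwOr(bitwOr(1L, 2L), 128L), 16L),
                                    pl$chrom[i], pl$pos[i], pl$chrom[i],
                                    pl$pos[i] + 150L, 1L))
        }
      }
      if (concm > 0L) {
        pl <- place(concm)
        for (i in seq_len(concm)) {
          pid <- pid + 1L
          recs <- c(recs, emit_pair(paste0("pair_", pid),
                                    bitwOr(bitwOr(1L, 2L), 64L),
                                    bitwOr(bitwOr(bitwOr(1L, 2L), 128L), 16L),
                                    pl$chrom[i], pl$pos[i], pl$chrom[i],
                                    pl$pos[i] + 150L, 2L))
        }
      }
      if (disc1 > 0L) {
        pl <- place(disc1); pl2 <- place(disc1)
        for (i in seq_len(disc1)) {
          pid <- pid + 1L
          recs <- c(recs, c(
            sprintf("pair_%d\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t*\t*\tNH:i:1",
                    pid, bitwOr(1L, 64L), pl$chrom[i], pl$pos[i],
                    read_length),
            sprintf("pair_%d\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t*\t*\tNH:i:1",
                    pid, bitwOr(bitwOr(1L, 128L), 16L), pl2$chrom[i],
                    pl2$pos[i], read_length)))
        }
      }
      if (leftover > 0L) {
        cls <- sample(rep(c("u", "q", "m"),
                          times = mate_counts[c("unmapped", "unique",
                                                "multi")]))
        # a residual pair with two unique mates would be discordant, not
        # residual; demote one mate to unmapped and recount
        for (i in seq_len(leftover)) {
          if (cls[2L * i - 1L] == "q" && cls[2L * i] == "q")
            cls[2L * i] <- "u"
        }
        mate_counts <- c(unmapped = sum(cls == "u"),
                         unique = sum(cls == "q"),
                         multi = sum(cls == "m"))
        for (i in seq_len(leftover)) {
          pid <- pid + 1L
          m1 <- cls[2L * i - 1L]; m2 <- cls[2L * i]
          mk <- function(cl, mate_flag, other_unmapped) {
            base <- bitwOr(1L, mate_flag)
            if (other_unmapped) base <- bitwOr(base, 8L)
            if (cl == "u")
              return(sprintf("pair_%d\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*",
                             pid, bitwOr(base, 4L)))
            pl1 <- place(1L)
            nh <- if (cl == "m") 2L else 1L
            mapq <- if (cl == "m") 1L else 42L
            sprintf("pair_%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                    pid, base, pl1$chrom, pl1$pos, mapq, read_length, nh)
          }
          recs <- c(recs, mk(m1, 64L, m2 == "u"), mk(m2, 128L, m1 == "u"))
        }
      }
      writeLines(c(header, recs), sam)
      writeLines(paired_end_log(n_reads, conc0, conc1, concm, disc1,
                                leftover, mate_counts), log)
    }
  })
  list(sam = sam, log = log)
}

# Deterministic integer counts that honour the fractions and sum to n.
exact_counts <- function(n, fractions) {
  cnt <- floor(fractions * n)
  rem <- n - sum(cnt)
  if (rem > 0L) {
    o <- order(-(fractions * n - cnt))
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(cnt), names(fractions))
}

single_end_log <- function(n, counts) {
  pct <- function(k) 100 * k / n
  c(sprintf("%d reads; of these:", n),
    sprintf("  %d (100.00%%) were unpaired; of these:", n),
    sprintf("    %d (%.2f%%) aligned 0 times", counts[["unmapped"]],
            pct(counts[["unmapped"]])),
    sprintf("    %d (%.2f%%) aligned exactly 1 time", counts[["unique"]],
            pct(counts[["unique"]])),
    sprintf("    %d (%.2f%%) aligned >1 times", counts[["multi"]],
            pct(counts[["multi"]])),
    sprintf("%.2f%% overall alignment rate", 100 - pct(counts[["unmapped"]])))
}

paired_end_log <- function(n, conc0, conc1, concm, disc1, leftover,
                           mate_counts) {
  pct <- function(k, d) if (d > 0) 100 * k / d else 0
  mates <- 2L * leftover
  mapped_mates <- 2L * (conc1 + concm + disc1) + mate_counts[["unique"]] +
    mate_counts[["multi"]]
  c(sprintf("%d reads; of these:", n),
    sprintf("  %d (100.00%%) were paired; of these:", n),
    sprintf("    %d (%.2f%%) aligned concordantly 0 times", conc0,
            pct(conc0, n)),
    sprintf("    %d (%.2f%%) aligned concordantly exactly 1 time", conc1,
            pct(conc1, n)),
    sprintf("    %d (%.2f%%) aligned concordantly >1 times", concm,
            pct(concm, n)),
    "    ----",
    sprintf("    %d pairs aligned concordantly 0 times; of these:", conc0),
    sprintf("      %d (%.2f%%) aligned discordantly 1 time", disc1,
            pct(disc1, conc0)),
    "    ----",
    sprintf("    %d pairs aligned 0 times concordantly or discordantly; of these:",
            leftover),
    sprintf("      %d mates make up the pairs; of these:", mates),
    sprintf("        %d (%.2f%%) aligned 0 times", mate_counts[["unmapped"]],
            pct(mate_counts[["unmapped"]], mates)),
    sprintf("        %d (%.2f%%) aligned exactly 1 time",
            mate_counts[["unique"]], pct(mate_counts[["unique"]], mates)),
    sprintf("        %d (%.2f%%) aligned >1 times", mate_counts[["multi"]],
            pct(mate_counts[["multi"]], mates)),
    sprintf("%.2f%% overall alignment rate", pct(mapped_mates, 2L * n)))
}

#' Simulate a labeled feature table with known class separation
#'
#' Numeric feature blocks are class-conditional Gaussians: informative
#' columns get a standardized mean shift of `effect_size` for the
#' low-quality class (baseline mean 50, sd 10, values clipped at 0 so
#' chi-squared selection applies). Optional flag features are one-hot
#' encoded categorical columns with class-dependent Pass/Warning/Fail
#' probabilities. Labels alternate so that consecutive experiment groups
#' mix both classes. The Bayes-optimal auROC implied by the numeric
#' shift, `pnorm(sqrt(n_informative) * effect_size / sqrt(2))`, is
#' returned alongside.
#'
#' @param n_samples number of samples (balanced classes).
#' @param n_informative number of shifted numeric features.
#' @param n_noise number of unshifted numeric features.
#' @param effect_size standardized mean shift per informative feature.
#' @param n_flag_features number of categorical flag features.
#' @param flag_probs_high,flag_probs_low Pass/Warning/Fail probabilities
#'   per class for the flag features.
#' @param group_size experiment-group size.
#' @param seed integer seed.
#' @return list with `x` (matrix), `y`, `experiment`, `bayes_auroc`.
#' @export
simulate_feature_table <- function(n_samples = 200L, n_informative = 1L,
                                   n_noise = 9L, effect_size = 1,
                                   n_flag_features = 0L,
                                   flag_probs_high = c(0.9, 0.08, 0.02),
                                   flag_probs_low = c(0.5, 0.3, 0.2),
                                   group_size = 4L, seed = 1L) {
  stopifnot(n_samples >= 4L, n_samples %% 2L == 0L, effect_size >= 0)
  n <- as.integer(n_samples)
  y <- rep(c(0, 1), n %/% 2L)
  with_seed(seed, {
    p_num <- n_informative + n_noise
    x <- matrix(stats::rnorm(n * p_num, mean = 50, sd = 10), nrow = n)
    if (n_informative > 0L)
      x[y == 1, seq_len(n_informative)] <-
        x[y == 1, seq_len(n_informative), drop = FALSE] + 10 * effect_size
    x <- pmax(x, 0)
    colnames(x) <- c(if (n_informative > 0L)
      paste0("informative_", seq_len(n_informative)),
      if (n_noise > 0L) paste0("noise_", seq_len(n_noise)))
    if (n_flag_features > 0L) {
      oh <- matrix(0, nrow = n, ncol = 3L * n_flag_features)
      cn <- character(3L * n_flag_features)
      for (j in seq_len(n_flag_features)) {
        pr <- ifelse(y == 1, list(flag_probs_low), list(flag_probs_high))
        lv <- vapply(seq_len(n), function(i)
          sample(QC_FLAG_LEVELS, 1L, prob = pr[[i]]), "")
        for (l in seq_along(QC_FLAG_LEVELS)) {
          oh[, 3L * (j - 1L) + l] <- as.numeric(lv == QC_FLAG_LEVELS[l])
          cn[3L * (j - 1L) + l] <- paste0("flag", j, "_",
                                          QC_FLAG_LEVELS[l])
        }
      }
      colnames(oh) <- cn
      x <- cbind(x, oh)
    }
    rownames(x) <- sprintf("sample_%03d", seq_len(n))
  })
  experiment <- sprintf("exp%03d", 1L + (seq_len(n) - 1L) %/% group_size)
  bayes <- stats::pnorm(sqrt(n_informative) * effect_size / sqrt(2))
  list(x = x, y = y, experiment = experiment,
       bayes_auroc = if (n_informative > 0L) bayes else 0.5)
}
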