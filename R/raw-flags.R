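# RAW feature set: the eleven Pass/Warning/Fail report flags summarising
# read-level statistics of one FASTQ file, plus the summary-file dialect
# used to exchange them.

#' Quality flag levels
#'
#' The three admissible values of a report flag, in increasing severity.
#' @export
QC_FLAG_LEVELS <- c("Pass", "Warning", "Fail")

#' The eleven RAW report modules
#'
#' The fixed, ordered set of report modules whose flags form the RAW feature
#' set: the standard module list of the reference read-level QC tool,
#' excluding its "Basic Statistics" header module. Tool versions differ on
#' whether a k-mer module is reported; this set freezes it in.
#' @export
RAW_MODULES <- c(
  "Per base sequence quality",
  "Per tile sequence quality",
  "Per sequence quality scores",
  "Per base sequence content",
  "Per sequence GC content",
  "Per base N content",
  "Sequence Length Distribution",
  "Sequence Duplication Levels",
  "Overrepresented sequences",
  "Adapter Content",
  "Kmer Content")

quality_flag <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), QC_FLAG_LEVELS)
  if (length(bad))
    stop_ngsqc("invalid quality flag value(s): ", paste(bad, collapse = ", "))
  factor(x, levels = QC_FLAG_LEVELS, ordered = TRUE)
}

new_raw_features <- function(flags) {
  stopifnot(length(flags) == length(RAW_MODULES))
  out <- quality_flag(flags)
  names(out) <- RAW_MODULES
  class(out) <- c("qc_raw_features", class(out))
  out
}

#' @export
print.qc_raw_features <- function(x, ...) {
  cat("RAW feature set (", length(x), " report flags):\n", sep = "")
  for (m in names(x))
    cat(sprintf("  %-30s %s\n", m, as.character(x[[m]])))
  invisible(x)
}

#' Parse a summary file from the reference read-level QC tool
#'
#' Reads the tab-separated summary dialect (`STATUS<TAB>Module name<TAB>file`)
#' written by the standard read-level QC tool and maps the statuses onto the
#' eleven RAW flags. The "Basic Statistics" line is ignored; every one of the
#' eleven modules in [RAW_MODULES] must be present.
#'
#' @param x path to a summary file, or a character vector of its lines.
#' @return a `qc_raw_features` object (named ordered factor of 11 flags).
#' @export
parse_fastqc_summary <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop_ngsqc("malformed summary line(s): ", paste(bad, collapse = ", "))
  status <- vapply(parts, `[[`, "", 1L)
  module <- vapply(parts, `[[`, "", 2L)
  keep <- tolower(module) != "basic statistics"
  status <- status[keep]; module <- module[keep]
  map <- c(PASS = "Pass", WARN = "Warning", FAIL = "Fail")
  unknown <- setdiff(unique(status), names(map))
  if (length(unknown))
    stop_ngsqc("unknown status token(s): ", paste(unknown, collapse = ", "))
  idx <- match(tolower(RAW_MODULES), tolower(module))
  missing <- RAW_MODULES[is.na(idx)]
  if (length(missing))
    stop_ngsqc("summary is missing module(s): ",
               paste(missing, collapse = "; "))
  new_raw_features(map[status[idx]])
}

#' Write RAW flags in the summary-file dialect
#'
#' Inverse of [parse_fastqc_summary()]: `parse_fastqc_summary(
#' write_fastqc_summary(flags, f))` returns flags identical to the input.
#'
#' @param flags a `qc_raw_features` object.
#' @param path output file path.
#' @param filename the filename field written on every line.
#' @return `path`, invisibly.
#' @export
write_fastqc_summary <- function(flags, path, filename = "sample.fastq") {
  stopifnot(inherits(flags, "qc_raw_features"))
  map <- c(Pass = "PASS", Warning = "WARN", Fail = "FAIL")
  lines <- c(paste("PASS", "Basic Statistics", filename, sep = "\t"),
             paste(map[as.character(flags)], RAW_MODULES, filename, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
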