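# Feature-table assembly: one numeric row per sample from the RAW / MAP /
# LOC / TSS feature sets, and alignment of rows into a matrix with a union
# schema across sequencing layouts.

#' Feature-set subsets
#' @export
FEATURE_SUBSETS <- c("RAW", "MAP", "LOC", "TSS", "ALL")

raw_onehot_names <- function() {
  mods <- gsub(" ", "_", RAW_MODULES)
  as.vector(t(outer(mods, QC_FLAG_LEVELS, paste, sep = "_")))
}

#' Assemble one feature row
#'
#' Encodes the available feature sets of one sample into a single named
#' numeric vector with a fixed column order per subset and layout. RAW
#' flags are one-hot encoded (11 modules x 3 levels = 33 columns, each
#' one-hot group summing to 1); MAP contributes its 4 (single-end) or 8
#' (paired-end) percentages plus a binary `MAP_is_paired` layout
#' indicator; LOC and TSS contribute their 9 and 10 numeric values
#' unchanged. Column provenance is carried in the `feature_set` attribute.
#'
#' @param raw a `qc_raw_features` or `NULL`.
#' @param map a `qc_map_features` or `NULL`.
#' @param loc a `qc_loc_features` or `NULL`.
#' @param tss a `qc_tss_features` or `NULL`.
#' @param subset `"ALL"` or any subset of `c("RAW","MAP","LOC","TSS")`;
#'   requesting a set that was not provided is an error.
#' @return named numeric vector with attribute `feature_set`.
#' @export
assemble_features <- function(raw = NULL, map = NULL, loc = NULL, tss = NULL,
                              subset = "ALL") {
  subset <- unique(toupper(subset))
  if (identical(subset, "ALL"))
    subset <- c("RAW", "MAP", "LOC", "TSS")[!vapply(
      list(raw, map, loc, tss), is.null, TRUE)]
  bad <- setdiff(subset, c("RAW", "MAP", "LOC", "TSS"))
  if (length(bad)) stop_ngsqc("unknown feature subset: ", bad[1L])
  if (!length(subset)) stop_ngsqc("at least one feature set is required")
  provided <- c(RAW = !is.null(raw), MAP = !is.null(map),
                LOC = !is.null(loc), TSS = !is.null(tss))
  absent <- subset[!provided[subset]]
  if (length(absent))
    stop_ngsqc("selector requests absent feature set(s): ",
               paste(absent, collapse = ", "))

  vals <- numeric(0); prov <- character(0)
  if ("RAW" %in% subset) {
    stopifnot(inherits(raw, "qc_raw_features"))
    oh <- as.vector(vapply(as.character(raw),
                           function(f) as.numeric(QC_FLAG_LEVELS == f),
                           numeric(3L)))
    names(oh) <- raw_onehot_names()
    vals <- c(vals, oh); prov <- c(prov, rep("RAW", length(oh)))
  }
  if ("MAP" %in% subset) {
    stopifnot(inherits(map, "qc_map_features"))
    m <- map$values
    names(m) <- paste0("MAP_", names(m), "_", map$layout)
    m <- c(m, MAP_is_paired = as.numeric(map$layout == "paired"))
    vals <- c(vals, m); prov <- c(prov, rep("MAP", length(m)))
  }
  if ("LOC" %in% subset) {
    stopifnot(inherits(loc, "qc_loc_features"))
    l <- as.numeric(loc)
    names(l) <- paste0("LOC_", gsub(" ", "_", REGION_CATEGORIES))
    vals <- c(vals, l); prov <- c(prov, rep("LOC", length(l)))
  }
  if ("TSS" %in% subset) {
    stopifnot(inherits(tss, "qc_tss_features"))
    t_ <- as.numeric(tss)
    names(t_) <- names(unclass(tss))
    vals <- c(vals, t_); prov <- c(prov, rep("TSS", length(t_)))
  }
  attr(vals, "feature_set") <- stats::setNames(prov, names(vals))
  vals
}

#' Bind feature rows into a matrix with a union schema
#'
#' Aligns rows from [assemble_features()] (possibly mixing single- and
#' paired-end layouts) into one numeric matrix. Columns absent from a row
#' -- the other layout's MAP percentages -- are filled with 0; the
#' `MAP_is_paired` indicator marks which layout each row carries.
#'
#' @param rows list of named numeric vectors.
#' @param sample_ids optional row names.
#' @return numeric matrix, no missing values.
#' @export
bind_feature_rows <- function(rows, sample_ids = NULL) {
  stopifnot(length(rows) >= 1L)
  cols <- Reduce(union, lapply(rows, names))
  m <- matrix(0, nrow = length(rows), ncol = length(cols),
              dimnames = list(sample_ids %||% paste0("sample_", seq_along(rows)),
                              cols))
  for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
  m
}

#' Read a feature table with labels
#'
#' Reads a TSV/CSV of samples x named features. The label column (1 = low
#' quality / revoked, 0 = high quality / released) is split off; an
#' optional experiment-id column is returned alongside.
#'
#' @param path delimited text file; the delimiter is inferred from the
#'   extension (`.csv` = comma, otherwise tab).
#' @param label_col label column name (default `"label"`); `NULL` for an
#'   unlabeled table.
#' @param id_col optional sample-id column used for row names.
#' @param experiment_col optional experiment-id column.
#' @return list with `x` (numeric matrix), `y` (numeric or NULL),
#'   `experiment` (character or NULL).
#' @export
read_feature_table <- function(path, label_col = "label", id_col = NULL,
                               experiment_col = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(id_col) && id_col %in% names(df)) {
    rownames(df) <- df[[id_col]]
    df[[id_col]] <- NULL
  }
  y <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df))
      stop_ngsqc("label column '", label_col, "' not found")
    y <- check_labels(df[[label_col]], require_both = FALSE)
    df[[label_col]] <- NULL
  }
  expt <- NULL
  if (!is.null(experiment_col) && experiment_col %in% names(df)) {
    expt <- as.character(df[[experiment_col]])
    df[[experiment_col]] <- NULL
  }
  list(x = as.matrix(df), y = y, experiment = expt)
}
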