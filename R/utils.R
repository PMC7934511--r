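# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb user-level
#' random streams. A `NULL` seed evaluates the code under the current state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and a stream index.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + index * 1009) %% 2147483647)
}

stop_ngsqc <- function(...) stop(..., call. = FALSE)

is_binary_labels <- function(labels) {
  is.numeric(labels) && all(labels %in% c(0, 1))
}

check_labels <- function(labels, require_both = TRUE) {
  if (is.logical(labels)) labels <- as.numeric(labels)
  if (is.factor(labels)) labels <- as.numeric(as.character(labels))
  if (!is_binary_labels(labels))
    stop_ngsqc("labels must be binary (1 = low quality, 0 = high quality)")
  if (require_both && length(unique(labels)) < 2L)
    stop_ngsqc("both quality classes must be present")
  labels
}
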