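## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the
#' session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

## complement / reverse complement on plain character vectors (ACGTN)
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}
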