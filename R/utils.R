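#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so simulation helpers are deterministic without clobbering the
#' session's random stream.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed)) {
    stop("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# single-string sprintf-style stop/warning helpers
.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.checkColumns <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing) > 0L) {
    .stopf("%s is missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# deterministic ordering used by every writer: chromosome lexicographic,
# then start coordinate
.canonicalOrder <- function(chrom, start) order(as.character(chrom), start)
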