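# internal helpers shared across modules

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  All exported functions taking a `seed` argument go
# through here so library use never clobbers the user's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` (and anything that is not `ACGT`)
#' complements to `N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, NULL), function(ch) paste(rev(ch), collapse = ""), "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
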