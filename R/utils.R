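# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible 32-bit sub-seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws its RNG state from a
#' sub-seed derived from the run's master seed and a stage label, so that
#' stages can be re-run independently and the full pipeline is
#' deterministic under a fixed master seed.
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. `"te"`, `"cell_12"`).
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, label) {
  h <- rlang::hash(list(as.integer(master), as.character(label)))
  # fold the first 12 hex digits into a 31-bit integer
  v <- strtoi(substr(h, 1L, 6L), 16L) * 4096 + strtoi(substr(h, 7L, 9L), 16L)
  as.integer(v %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

rrow_log <- function(..., level = "info") {
  if (isTRUE(getOption("rrowflow.quiet", TRUE))) return(invisible(NULL))
  message(sprintf("[rrowflow:%s] %s", level, paste0(...)))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# round to the event-log resolution (1 ms)
snap_ms <- function(t) round(t * 1000) / 1000
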