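#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one configured seed; independent
#' stages draw from named substreams so that changing one stage's draws does
#' not perturb another's.  The substream seed is a deterministic hash of the
#' master seed and the stream name, kept below 2^31.
#'
#' @param seed master integer seed
#' @param name substream name, e.g. `"species_tree"`
#' @return an integer seed
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a named substream
#'
#' Sets the RNG seed to [substream_seed()] for the duration of `expr` and
#' restores the caller's RNG state afterwards.
#'
#' @param seed master seed
#' @param name substream name
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# stderr logging with a package-level quiet switch
.glidevol_state <- new.env(parent = emptyenv())
.glidevol_state$quiet <- FALSE

#' Silence or re-enable progress logging
#' @param quiet logical
#' @return the previous setting, invisibly
#' @export
set_quiet <- function(quiet = TRUE) {
  old <- .glidevol_state$quiet
  .glidevol_state$quiet <- isTRUE(quiet)
  invisible(old)
}

log_msg <- function(...) {
  if (!.glidevol_state$quiet) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
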