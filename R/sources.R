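# Sample sources: seedable generators of Boolean property outcomes.
#
# A source is an environment holding a private RNG state, a pushback buffer
# and a draw counter. Algorithms draw outcomes in batches for speed; any
# outcomes not consumed before a stopping boundary are pushed back, so the
# observable stream is identical to one-sample-at-a-time generation and the
# draw counter equals the number of outcomes actually consumed.

# Run expr under the source's private RNG stream, leaving the caller's
# .Random.seed untouched.
with_source_rng <- function(src, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  if (is.null(src$rng)) set.seed(src$seed)
  else assign(".Random.seed", src$rng, envir = genv)
  on.exit({
    src$rng <- get(".Random.seed", envir = genv)
    if (is.null(old)) rm(list = ".Random.seed", envir = genv)
    else assign(".Random.seed", old, envir = genv)
  })
  expr
}

new_sample_source <- function(generate, kind, seed = NULL, fields = list()) {
  src <- new.env(parent = emptyenv())
  src$buffer <- logical(0)
  src$drawn <- 0
  src$kind <- kind
  src$seed <- seed
  src$rng <- NULL
  src$generate <- generate
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = src)
  class(src) <- "sample_source"
  src
}

#' Bernoulli sample source
#'
#' The synthetic surrogate used throughout the replications: each draw is
#' TRUE iff a uniform random number is below \code{p}. Identical seeds give
#' identical outcome streams; the stream is private to the source and does
#' not disturb the session RNG.
#'
#' @param p true satisfaction probability, in [0, 1].
#' @param seed integer seed.
#' @return an object of class \code{"sample_source"}.
#' @export
bernoulli_source <- function(p, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  new_sample_source(
    generate = function(src, k) with_source_rng(src, stats::runif(k) < src$p),
    kind = sprintf("bernoulli(p=%g)", p), seed = seed,
    fields = list(p = p)
  )
}

#' Replay a fixed outcome vector as a sample source
#'
#' Serves two purposes: black-box verification against a pre-collected set of
#' trajectory verdicts, and deterministic streams in tests. Drawing past the
#' end errors unless \code{recycle = TRUE}.
#'
#' @param outcomes logical vector of pre-computed property verdicts.
#' @param recycle reuse the vector cyclically when exhausted.
#' @return an object of class \code{"sample_source"}.
#' @export
replay_source <- function(outcomes, recycle = FALSE) {
  outcomes <- as.logical(outcomes)
  stopifnot(!anyNA(outcomes))
  new_sample_source(
    generate = function(src, k) {
      if (src$pos + k > length(src$outcomes)) {
        if (!src$recycle) stop("replay source exhausted")
        while (src$pos + k > length(src$outcomes))
          src$outcomes <- c(src$outcomes, src$outcomes)
      }
      x <- src$outcomes[(src$pos + 1):(src$pos + k)]
      src$pos <- src$pos + k
      x
    },
    kind = "replay",
    fields = list(outcomes = outcomes, pos = 0L, recycle = recycle)
  )
}

#' Draw a batch of outcomes from a sample source
#'
#' Consumes \code{k} units of the sample budget; pushed-back outcomes are
#' re-served first.
#'
#' @param src a sample source.
#' @param k number of outcomes.
#' @return logical vector of length \code{k}.
#' @export
draw_samples <- function(src, k) {
  k <- as.integer(k)
  if (k <= 0L) return(logical(0))
  nb <- length(src$buffer)
  if (nb >= k) {
    x <- src$buffer[seq_len(k)]
    src$buffer <- src$buffer[-seq_len(k)]
  } else {
    x <- c(src$buffer, src$generate(src, k - nb))
    src$buffer <- logical(0)
  }
  src$drawn <- src$drawn + k
  x
}

#' Return unconsumed outcomes to a sample source
#'
#' Used by the chunked sequential loops: outcomes generated beyond a stopping
#' boundary are returned so they are served again by the next draw and do not
#' count against the sample budget.
#'
#' @param src a sample source.
#' @param x logical vector of outcomes, oldest first.
#' @export
pushback_samples <- function(src, x) {
  if (length(x) == 0L) return(invisible(src))
  src$buffer <- c(x, src$buffer)
  src$drawn <- src$drawn - length(x)
  invisible(src)
}

#' Number of outcomes consumed from a source
#' @param src a sample source.
#' @return numeric count of consumed draws.
#' @export
samples_drawn <- function(src) src$drawn

#' @export
print.sample_source <- function(x, ...) {
  cat(sprintf("<sample source> %s; drawn %g\n", x$kind, x$drawn))
  invisible(x)
}
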