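# Internal helpers shared across modules.

#' Derive a child seed from a root seed and a tag
#'
#' All randomised stages draw from seeds derived from one root seed and a
#' stage-specific tag, so inserting a new draw site never shifts the stream
#' feeding an existing one. The derivation is a simple 31-multiplier string
#' hash folded into the root seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param tag character scalar naming the draw site.
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 2)) + 1L
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# One structured log line per pipeline stage; silenced with
# options(rhythmnet.quiet = TRUE).
log_stage <- function(stage, fmt, ...) {
  if (isTRUE(getOption("rhythmnet.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Rhythm class labels
#'
#' The closed label vocabulary used throughout the package: `N` (normal
#' sinus rhythm), `AF` (atrial fibrillation), `NON_AF` (any other
#' arrhythmia collapsed into a third class).
#'
#' @return character vector of the three labels, in canonical order.
#' @export
rhythm_classes <- function() c("N", "AF", "NON_AF")
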