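#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom pnorm qnorm sd cor cor.test filter
#' @importFrom utils write.csv read.delim data head
NULL

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit hash of a string, used to derive per-protein/per-mode
# sub-seeds from a master seed.
hash31 <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Combine a master seed with string parts into a reproducible sub-seed.
derive_seed <- function(seed, ...) {
  h <- as.integer(seed) %% 2147483647
  for (part in list(...)) h <- (h * 69069 + hash31(as.character(part))) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
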