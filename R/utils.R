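#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rgamma rmultinom rlnorm quantile var cor lm coef setNames
#' @importFrom utils head
NULL

# Stable 31-bit string hash (polynomial, modulo 2^31 - 1). Used to derive
# independent generator substreams from one root seed so that adding a new
# generator never perturbs the draws of an existing one.
hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

#' Derive a substream seed from a root seed and a stream name
#'
#' All synthetic-data generators draw from substreams derived by hashing the
#' generator name together with the root seed, so each generator's output is a
#' pure function of `(seed, name)` and generators never share a stream.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + hash31(name)) %% m)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

# Normalize longitudes into [-180, 180).
wrap_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, format(min)))
  }
  invisible(as.integer(x))
}
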