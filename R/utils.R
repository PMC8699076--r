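#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd median lm pf pt setNames ave
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, then restore
# the caller's RNG. Keeps simulator determinism from leaking into user code.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed, staying inside the
# 32-bit integer range expected by set.seed().
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_eyec <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Maximal runs of TRUE in a logical vector (NA treated as FALSE).
# Returns a data.frame with 1-based inclusive start/end indices.
true_runs <- function(flags) {
  flags <- !is.na(flags) & flags
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
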