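# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Population (1/N) standard deviation.
.sdPop <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NaN)
  sqrt(mean((x - mean(x))^2))
}

# Expand per-marker values to per-coordinate (x,y,z marker-major) order.
.perCoord <- function(v) rep(v, each = 3L)

# Coordinate column names for a marker label vector.
.coordNames <- function(labels) {
  as.vector(t(outer(labels, c("x", "y", "z"), paste, sep = "_")))
}

.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)
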