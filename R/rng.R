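# Counter-based random numbers for stimulus rendering.
#
# Every stimulus sample is a pure function of (seed, stream, frame, unit), so
# re-rendering any frame is bit-identical and inserting frozen segments never
# consumes or shifts the random stream of the surrounding frames.  Implemented
# as a murmur3-style 32-bit finalizer; R lacks 64-bit integers, so 32-bit
# modular products are assembled from 16-bit halves in double arithmetic.

TWO32 <- 4294967296

# (a * b) mod 2^32 for vectors of non-negative doubles < 2^32
.mul32 <- function(a, b) {
  b_hi <- floor(b / 65536)
  b_lo <- b - b_hi * 65536
  (((a * b_hi) %% 65536) * 65536 + a * b_lo) %% TWO32
}

.xorshift <- function(h, k) {
  # h XOR (h >> k) on 32-bit values held in doubles
  s <- floor(h / 2^k)
  # xor via bitwXor on two 16-bit halves to stay within integer range
  h_hi <- floor(h / 65536); h_lo <- h - h_hi * 65536
  s_hi <- floor(s / 65536); s_lo <- s - s_hi * 65536
  bitwXor(as.integer(h_hi), as.integer(s_hi)) * 65536 +
    bitwXor(as.integer(h_lo), as.integer(s_lo))
}

.fmix32 <- function(h) {
  h <- .xorshift(h %% TWO32, 16)
  h <- .mul32(h, 2246822507)  # 0x85ebca6b
  h <- .xorshift(h, 13)
  h <- .mul32(h, 3266489909)  # 0xc2b2ae35
  .xorshift(h, 16)
}

#' Deterministic uniform variates keyed by integer counters
#'
#' Returns standard-uniform values that depend only on `(seed, stream, frame,
#' unit)`; all arguments are recycled to a common length.
#'
#' @param seed,stream,frame,unit non-negative integer keys.
#' @return numeric vector of uniforms in (0, 1).
#' @keywords internal
counter_uniform <- function(seed, frame, unit = 0, stream = 0) {
  h <- .fmix32((seed %% TWO32) + .mul32(frame %% TWO32, 2654435761))
  h <- .fmix32(h + .mul32(unit %% TWO32, 40503 * 65536 + 61129))
  h <- .fmix32(h + .mul32(stream %% TWO32, 3432918353))
  (h + 0.5) / TWO32
}

# Standard-normal variates from two counter streams (Box-Muller).
counter_normal <- function(seed, frame, unit = 0, stream = 0) {
  u1 <- counter_uniform(seed, frame, unit, stream = 2 * stream)
  u2 <- counter_uniform(seed, frame, unit, stream = 2 * stream + 1)
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

#' Derive a child seed from a top-level seed and a stage name
#'
#' Stable hashing of the stage label means adding a new pipeline stage never
#' perturbs the random stream of existing stages.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return integer in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- seed %% TWO32
  for (cc in utf8ToInt(stage)) h <- .fmix32(h + .mul32(cc, 2654435761))
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
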