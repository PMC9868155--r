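# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Unit conversions. I/O edges use mm / mm^2 (CT convention); internals are SI.
MM_PER_M <- 1e3
MM2_PER_M2 <- 1e6

lpm_to_m3s <- function(q_lpm) q_lpm / 6e4
mm2_to_m2 <- function(a) a / MM2_PER_M2
mm_to_m <- function(x) x / MM_PER_M

# Smooth monotone ramp on [0, 1] (cosine smoothstep).
smoothstep <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2
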