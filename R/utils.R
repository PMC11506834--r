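# Small shared numerics. Angle conversion lives here and nowhere else:
# every public interface speaks degrees, the dynamics integrate in radians.

DEG2RAD <- pi / 180

deg2rad <- function(x) x * DEG2RAD
rad2deg <- function(x) x / DEG2RAD

#' Logistic sigmoid
#'
#' The standard logistic function `1 / (1 + exp(-x))`, used by the muscle
#' activation map and by both feedback control models. Written to avoid
#' overflow for large negative arguments.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
sig <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed from a run seed so that independent random streams
# (initial postures, exploration noise, ...) never interleave. Kept below
# 2^31 - 1 because R seeds are 32-bit integers.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
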