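# Numerically guarded hyperbolic helpers shared by the 1D model and the
# 3N-mode solver.  Arguments lambda*t can reach several hundred for stiff
# modes, so everything is evaluated through exponentials of non-positive
# numbers.

#' Stable hyperbolic cotangent
#'
#' `coth(x)` evaluated without overflow: for large `|x|` the asymptote
#' `sign(x)` is used, and a series expansion covers the region near zero.
#'
#' @param x numeric vector.
#' @return `coth(x)`, elementwise.
#' @keywords internal
coth_stable <- function(x) {
  out <- numeric(length(x))
  ax <- abs(x)
  big <- ax > 30
  tiny <- ax < 1e-6
  mid <- !big & !tiny
  out[big] <- sign(x[big])
  # coth(x) = 1/x + x/3 - x^3/45 + ...
  out[tiny] <- ifelse(x[tiny] == 0, Inf, 1 / x[tiny] + x[tiny] / 3)
  e <- exp(-2 * ax[mid])
  out[mid] <- sign(x[mid]) * (1 + e) / (1 - e)
  out
}

#' Stable ratio sinh(k*t) / sinh(k*tref)
#'
#' Both `t` and `tref` must be non-negative with `t <= tref` in the intended
#' use (branch interpolation factors), but the formula is valid for any
#' non-negative pair.  Written as `exp(k*(t - tref)) * (1 - e^{-2kt}) /
#' (1 - e^{-2k tref})` so no intermediate overflows.
#'
#' @param k positive rate.
#' @param t,tref non-negative times.
#' @return the ratio, a scalar or vector following recycling.
#' @keywords internal
sinh_ratio <- function(k, t, tref) {
  stopifnot(all(k > 0))
  x <- k * t
  y <- k * tref
  small <- y < 1e-6
  out <- exp(x - y) * (1 - exp(-2 * x)) / (1 - exp(-2 * y))
  # k*tref ~ 0: sinh ratio degenerates to t/tref
  if (any(small)) out[small] <- rep_len(t / tref, length(out))[small]
  out[x == 0] <- 0
  out
}

# flatten an N x 3 coordinate matrix into (x1, y1, z1, x2, ...) order
coords_to_vec <- function(coords) as.vector(t(coords))

vec_to_coords <- function(vec) matrix(vec, ncol = 3, byrow = TRUE)

# coordinate RMSD between two 3N vectors (no fitting)
vec_rmsd <- function(u, v) sqrt(mean(rowSums((vec_to_coords(u) - vec_to_coords(v))^2)))
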