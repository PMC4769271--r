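# One-dimensional diatomic reference model: two scalar harmonic wells
# joined at a cusp.  Exact branch solutions and a bracketed root solve of
# the velocity-continuity balance make this the independent oracle for
# the 3N solver, and the model from which the convergence surface over
# (t_f, deltaE) is tabulated.

#' Construct a 1D double well
#'
#' @param a,b positions of the two well minima (must differ for a
#'   non-degenerate problem).
#' @param k_l,k_r positive force constants of the left and right wells.
#' @param offset optional energy offset of well `b` relative to well `a`
#'   (stored; the geometric energy gap is computed from the cusp).
#' @return a `double_well_1d` object.
#' @export
double_well_1d <- function(a, b, k_l, k_r, offset = 0) {
  if (k_l <= 0 || k_r <= 0) stop("force constants must be positive")
  structure(list(a = a, b = b, k_l = k_l, k_r = k_r, offset = offset),
            class = "double_well_1d")
}

#' Exact branch position of the 1D model
#'
#' Left branch (`t <= tbar`): `a + (xbar - a) sinh(k_l t)/sinh(k_l tbar)`.
#' Right branch (`t >= tbar`): `b + (b - xbar) sinh(k_r (t - t_f)) /
#' sinh(k_r (t_f - tbar))`.  Hyperbolic ratios are evaluated in log space.
#'
#' @param well a `double_well_1d`.
#' @param side `"left"` or `"right"`.
#' @param t evaluation time(s); must lie in the branch domain.
#' @param tbar barrier time, `0 < tbar < t_f`.
#' @param t_f total transition time.
#' @param xbar the transition-state position.
#' @return position(s) at `t`.
#' @export
branch_position_1d <- function(well, side = c("left", "right"), t, tbar, t_f, xbar) {
  side <- match.arg(side)
  if (tbar <= 0 || tbar >= t_f) stop("need 0 < tbar < t_f")
  if (side == "left") {
    if (any(t < 0 | t > tbar)) stop("left branch requires 0 <= t <= tbar")
    well$a + (xbar - well$a) * sinh_ratio(well$k_l, t, tbar)
  } else {
    if (any(t < tbar | t > t_f)) stop("right branch requires tbar <= t <= t_f")
    well$b - (well$b - xbar) * sinh_ratio(well$k_r, t_f - t, t_f - tbar)
  }
}

#' Solve the 1D transition state by velocity continuity
#'
#' Finds the cusp position balancing the branch velocities,
#' `k_l coth(k_l tbar) (xbar - a) = k_r coth(k_r (t_f - tbar)) (b - xbar)`,
#' by bracketed root search between the two minima (the residual is
#' monotone in `xbar`), then evaluates the scalar energy gap
#' `k_r (xbar - b)^2 / 2 - k_l (xbar - a)^2 / 2`.
#'
#' @param well a `double_well_1d`.
#' @param t_f total transition time.
#' @param tbar barrier time, `0 < tbar < t_f`.
#' @param tol root tolerance (default 1e-12).
#' @return a list with `xbar` and `delta_e`.
#' @export
solve_transition_1d <- function(well, t_f, tbar, tol = 1e-12) {
  if (tbar <= 0 || tbar >= t_f) stop("need 0 < tbar < t_f")
  a <- well$a; b <- well$b
  alpha <- well$k_l * coth_stable(well$k_l * tbar)
  beta <- well$k_r * coth_stable(well$k_r * (t_f - tbar))
  if (a == b) {
    xbar <- a
  } else {
    resid <- function(x) alpha * (x - a) - beta * (b - x)
    xbar <- stats::uniroot(resid, lower = min(a, b), upper = max(a, b),
                           tol = tol, extendInt = "no")$root
  }
  list(xbar = xbar,
       delta_e = well$k_r * (xbar - b)^2 / 2 - well$k_l * (xbar - a)^2 / 2)
}

#' Tabulate the convergence surface of the 1D model
#'
#' For each total time on `tf_grid` and each barrier-time fraction on
#' `tbar_fractions`, solves the 1D transition state and records the
#' implied energy gap, assembling the surface of barrier times over the
#' `(t_f, deltaE)` plane that enumerates every locally minimum-action
#' path of the model.
#'
#' @param well a `double_well_1d`.
#' @param tf_grid positive total-time grid.
#' @param tbar_fractions barrier-time fractions in (0, 1) (default 19
#'   points from 0.05 to 0.95).
#' @return a `convergence_surface`: a data frame with columns `t_f`,
#'   `tbar_frac`, `tbar`, `xbar`, `delta_e`.
#' @export
convergence_surface <- function(well, tf_grid,
                                tbar_fractions = seq(0.05, 0.95, by = 0.05)) {
  if (!length(tf_grid) || !length(tbar_fractions)) stop("empty grid")
  if (any(tf_grid <= 0)) stop("t_f grid must be positive")
  if (any(tbar_fractions <= 0 | tbar_fractions >= 1)) {
    stop("tbar fractions must lie in (0, 1)")
  }
  grid <- expand.grid(t_f = tf_grid, tbar_frac = tbar_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  grid$tbar <- grid$t_f * grid$tbar_frac
  sol <- mapply(function(tf, tb) unlist(solve_transition_1d(well, tf, tb)),
                grid$t_f, grid$tbar)
  grid$xbar <- sol["xbar", ]
  grid$delta_e <- sol["delta_e", ]
  structure(grid, class = c("convergence_surface", "data.frame"), well = well)
}

#' Fraction of path time dwelling near each minimum
#'
#' Diagnostic for the large-`t_f` regime: the share of each branch's time
#' during which the system has progressed less than `threshold` of the
#' way to the transition state.  At large `t_f` the narrower (stiffer)
#' well holds its branch near the minimum for a larger share of the time.
#'
#' @param well a `double_well_1d`.
#' @param t_f,tbar transition times.
#' @param threshold progress fraction (default 0.1).
#' @param n time samples per branch (default 2000).
#' @return named vector with dwell fractions `left` and `right`.
#' @export
dwell_fractions_1d <- function(well, t_f, tbar, threshold = 0.1, n = 2000) {
  sol <- solve_transition_1d(well, t_f, tbar)
  tl <- seq(0, tbar, length.out = n)
  tr <- seq(tbar, t_f, length.out = n)
  xl <- branch_position_1d(well, "left", tl, tbar, t_f, sol$xbar)
  xr <- branch_position_1d(well, "right", tr, tbar, t_f, sol$xbar)
  c(left = mean(abs(xl - well$a) < threshold * abs(sol$xbar - well$a)),
    right = mean(abs(xr - well$b) < threshold * abs(sol$xbar - well$b)))
}
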