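# Core transition-state solver: velocity continuity between the two
# Onsager-Machlup branches of a double harmonic (ANM) well, the
# non-iterative barrier-time estimate, the energy gap between wells, and
# the most-probable trajectory with truncation of its invariant ends.

# -ln(0.1) as conventionally quoted; sets the 10%-progress time offset
OM_TBAR_CONSTANT <- 2.302

#' Non-iterative optimal barrier time
#'
#' The time offset over which the asymptotic branch solution covers the
#' last 90% of the distance to the transition state is `2.302 / k` (from
#' `exp(-k (tbar - t)) = 0.1`).  Evaluating this at the average force
#' constant of a well gives a barrier time estimate directly from the
#' Hessian, with no iterative search over total transition time.
#'
#' @param kbar average force constant (see [average_force_constant()]).
#' @return `2.302 / kbar`.
#' @export
optimal_barrier_time <- function(kbar) {
  if (any(kbar <= 0)) stop("kbar must be positive")
  OM_TBAR_CONSTANT / kbar
}

# diagonal rate entries in mode space: lambda * coth(lambda * tau) with the
# zero-mode limit 1/tau.  tau > 0 on the left branch (tau = tbar) and
# tau < 0 on the right branch (tau = tbar - t_f).
rate_entries <- function(values, zero_modes, tau) {
  out <- values * coth_stable(values * tau)
  out[zero_modes] <- 1 / tau
  out
}

#' Branch rate matrix (diagonal, in mode space)
#'
#' The diagonal matrix applied to the mode amplitudes in the velocity-
#' continuity condition.  On the left branch each non-zero mode
#' contributes `lambda * coth(lambda * t)`; on the right branch the time
#' argument is `t - t_f` (negative), so entries are negative.  Zero modes
#' contribute `1/t` and `1/(t - t_f)` respectively.  Large arguments use
#' the `coth -> 1` asymptote so stiff modes cannot overflow.
#'
#' @param model an eigendecomposed `elastic_model`.
#' @param t evaluation time (the barrier time, for the continuity solve);
#'   must be positive.
#' @param side `"left"` or `"right"`.
#' @param t_f total transition time; required for `side = "right"` and
#'   must exceed `t`.
#' @return numeric vector of diagonal entries aligned with the model's
#'   eigenvalue order.
#' @export
branch_rate_matrix <- function(model, t, side = c("left", "right"), t_f = NULL) {
  side <- match.arg(side)
  if (t <= 0) stop("t must be positive")
  if (is.null(model$values)) stop("model must be eigendecomposed first")
  tau <- if (side == "left") t else {
    if (is.null(t_f)) stop("t_f is required for the right branch")
    if (t_f <= t) stop("t_f must exceed t on the right branch")
    t - t_f
  }
  rate_entries(model$values, model$zero_modes, tau)
}

as_state_vec <- function(x) {
  if (inherits(x, "molecular_state")) coords_to_vec(x$coords) else as.numeric(x)
}

#' Solve for the transition state by velocity continuity
#'
#' The cusp `xbar` where the two branches meet with continuous velocity
#' solves the linear system
#' `(V L V' - W R W') xbar = V L V' a - W R W' b`,
#' where `V`, `W` are the eigenvector matrices of the initial and final
#' wells and `L`, `R` the branch rate matrices at the branch times.  The
#' system is solved directly (never by explicit inversion); zero modes
#' contribute `1/tbar_l + 1/tbar_r > 0`, so generic inputs are
#' non-singular.
#'
#' @param model_a,model_b eigendecomposed `elastic_model`s of the initial
#'   and final wells.
#' @param a,b the well minima: `molecular_state`s or 3N coordinate
#'   vectors, already expressed in a common frame (superposed).
#' @param tbar_l time from `a` to the transition state.
#' @param tbar_r time from the transition state to `b`
#'   (`t_f = tbar_l + tbar_r`).
#' @return a `transition_state` with `xbar`, the branch times, the energy
#'   gap slot (filled by [delta_energy()]), per-mode amplitudes
#'   `psi_bar = V'(xbar - a)` and `phi_bar = W'(xbar - b)`, the relative
#'   velocity-continuity residual and the condition number of the solve.
#' @export
solve_transition_state <- function(model_a, model_b, a, b, tbar_l, tbar_r) {
  if (tbar_l <= 0 || tbar_r <= 0) stop("branch times must be positive")
  av <- as_state_vec(a); bv <- as_state_vec(b)
  if (length(av) != length(bv)) stop("dimension mismatch between a and b")
  if (is.null(model_a$values) || is.null(model_b$values)) {
    stop("both models must be eigendecomposed")
  }
  lrate <- rate_entries(model_a$values, model_a$zero_modes, tbar_l)
  rrate <- rate_entries(model_b$values, model_b$zero_modes, -tbar_r)
  ml <- model_a$vectors %*% (lrate * t(model_a$vectors))
  mr <- model_b$vectors %*% (rrate * t(model_b$vectors))
  m <- ml - mr
  rhs <- ml %*% av - mr %*% bv
  cond <- kappa(m, exact = FALSE)
  xbar <- tryCatch(as.numeric(solve(m, rhs)),
                   error = function(e) {
                     stop(sprintf("singular velocity-continuity system (condition number %.3g): %s",
                                  cond, conditionMessage(e)), call. = FALSE)
                   })
  lv <- as.numeric(ml %*% (xbar - av))
  rv <- as.numeric(mr %*% (xbar - bv))
  scale <- max(sqrt(sum(lv^2)), sqrt(sum(rv^2)), .Machine$double.eps)
  residual <- sqrt(sum((lv - rv)^2)) / scale
  structure(list(xbar = xbar,
                 tbar_l = tbar_l, tbar_r = tbar_r, t_f = tbar_l + tbar_r,
                 delta_e = NULL,
                 psi_bar = as.numeric(crossprod(model_a$vectors, xbar - av)),
                 phi_bar = as.numeric(crossprod(model_b$vectors, xbar - bv)),
                 residual = residual, condition = cond),
            class = "transition_state")
}

#' Energy gap between the two wells
#'
#' Evaluated at the cusp: `deltaE = (xbar-b)' H_b (xbar-b)/2 -
#' (xbar-a)' H_a (xbar-a)/2`, i.e. the difference between the
#' transition-state energies measured relative to each well minimum.
#'
#' @param ts a `transition_state`.
#' @param a,b well minima (states or 3N vectors) in the solve's frame.
#' @param model_a,model_b the wells' elastic models.
#' @return the scalar energy gap, also stored in `ts$delta_e` of the
#'   returned (modified) transition state when assigned back.
#' @export
delta_energy <- function(ts, a, b, model_a, model_b) {
  av <- as_state_vec(a); bv <- as_state_vec(b)
  if (length(ts$xbar) != length(av) || length(av) != length(bv)) {
    stop("dimension mismatch")
  }
  db <- ts$xbar - bv
  da <- ts$xbar - av
  as.numeric(crossprod(db, model_b$hessian %*% db) / 2 -
             crossprod(da, model_a$hessian %*% da) / 2)
}

branch_gain <- function(model, t, tref) {
  # interpolation factors g_i(t): t/tref for zero modes, else the
  # log-space sinh ratio; both equal 1 at t = tref and 0 at t = 0
  g <- numeric(length(model$values))
  nz <- setdiff(seq_along(model$values), model$zero_modes)
  if (length(nz)) g[nz] <- sinh_ratio(model$values[nz], t, tref)
  g[model$zero_modes] <- t / tref
  if (any(!is.finite(g))) {
    stop("overflow in branch interpolation at mode(s) ",
         paste(utils::head(which(!is.finite(g)), 3), collapse = ", "))
  }
  g
}

#' Generate the most-probable trajectory
#'
#' Samples both branches uniformly in time (frame counts split
#' proportionally to branch durations).  On the left branch each mode
#' follows `sinh(lambda t)/sinh(lambda tbar)` (linear `t/tbar` for zero
#' modes); the right branch mirrors this from `b`.  Boundary frames are
#' exact (`x(0) = a`, `x(t_f) = b`, `x(tbar) = xbar`) and position and
#' velocity are continuous at the cusp.
#'
#' @param ts a `transition_state`.
#' @param a,b well minima (states or 3N vectors) in the solve's frame.
#' @param model_a,model_b the wells' eigendecomposed elastic models.
#' @param n_frames total number of frames (default 100).
#' @return a `path_trajectory` with per-frame branch labels.
#' @export
generate_trajectory <- function(ts, a, b, model_a, model_b, n_frames = 100) {
  av <- as_state_vec(a); bv <- as_state_vec(b)
  n_l <- max(2L, round(n_frames * ts$tbar_l / ts$t_f))
  n_r <- max(2L, n_frames - n_l)
  t_left <- seq(0, ts$tbar_l, length.out = n_l + 1L)      # includes cusp
  t_right <- seq(ts$tbar_l, ts$t_f, length.out = n_r + 1L)[-1L]
  frames <- matrix(NA_real_, length(t_left) + length(t_right), length(av))
  for (i in seq_along(t_left)) {
    g <- branch_gain(model_a, t_left[i], ts$tbar_l)
    frames[i, ] <- as.numeric(model_a$vectors %*% (g * ts$psi_bar)) + av
  }
  for (i in seq_along(t_right)) {
    theta <- ts$t_f - t_right[i]                          # time remaining
    g <- branch_gain(model_b, theta, ts$tbar_r)
    frames[length(t_left) + i, ] <- as.numeric(model_b$vectors %*% (g * ts$phi_bar)) + bv
  }
  times <- c(t_left, t_right)
  atoms <- if (inherits(a, "molecular_state")) a$atoms else
    data.frame(chain = "A", resno = seq_len(length(av) / 3), resid = "GLY",
               elety = "CA", stringsAsFactors = FALSE)
  structure(list(times = times, frames = frames,
                 branch = ifelse(times <= ts$tbar_l, "left", "right"),
                 atoms = atoms, truncation = NULL,
                 a_vec = av, b_vec = bv, xbar = ts$xbar, tbar = ts$tbar_l),
            class = "path_trajectory")
}

#' Truncate the invariant ends of a trajectory
#'
#' The hyperbolic-sine time course spends most of its time vanishingly
#' close to the end states.  This drops the leading frames where the
#' system has progressed less than `fraction` of the distance from `a`
#' to the transition state, and the trailing frames symmetrically near
#' `b`.  Retained frames are unchanged; the discarded time spans are
#' recorded.
#'
#' @param traj a `path_trajectory` produced by [generate_trajectory()].
#' @param fraction progress threshold in (0, 1); default 0.1 (10%).
#' @return the truncated `path_trajectory` with `truncation` metadata.
#' @export
truncate_trajectory <- function(traj, fraction = 0.1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (is.null(traj$a_vec)) stop("trajectory lacks end-state metadata; was it generated by generate_trajectory()?")
  da <- sqrt(colSums((t(traj$frames) - traj$a_vec)^2))
  db <- sqrt(colSums((t(traj$frames) - traj$b_vec)^2))
  ra <- sqrt(sum((traj$xbar - traj$a_vec)^2))
  rb <- sqrt(sum((traj$xbar - traj$b_vec)^2))
  if (ra == 0 || rb == 0) {
    warning("degenerate trajectory: an end state coincides with the transition state")
    return(traj)
  }
  # retain from the last frame still below the threshold, so the kept path
  # starts just as the system reaches `fraction` progress; as fraction -> 0
  # nothing is dropped
  n_fr <- nrow(traj$frames)
  crossed <- which(da / ra >= fraction)
  keep_from <- if (length(crossed)) max(1L, min(crossed) - 1L) else 1L
  crossed_b <- which(db / rb >= fraction)
  keep_to <- if (length(crossed_b)) min(n_fr, max(crossed_b) + 1L) else n_fr
  idx <- keep_from:keep_to
  out <- traj
  out$times <- traj$times[idx]
  out$frames <- traj$frames[idx, , drop = FALSE]
  out$branch <- traj$branch[idx]
  out$truncation <- list(
    fraction = fraction,
    head_span = traj$times[keep_from] - traj$times[1L],
    tail_span = traj$times[length(traj$times)] - traj$times[keep_to]
  )
  out
}

#' @export
print.transition_state <- function(x, ...) {
  cat(sprintf("transition_state: %d coordinates\n", length(x$xbar)))
  cat(sprintf("  tbar_l = %.6g, tbar_r = %.6g, t_f = %.6g\n", x$tbar_l, x$tbar_r, x$t_f))
  if (!is.null(x$delta_e)) cat(sprintf("  deltaE = %.6g\n", x$delta_e))
  cat(sprintf("  velocity residual = %.3g, condition = %.3g\n", x$residual, x$condition))
  invisible(x)
}

#' End-to-end path computation between two structures
#'
#' Orchestrates the full non-iterative pipeline: atom pairing, optional
#' superposition of `state_b` onto `state_a`, ANM Hessians and their
#' eigendecompositions, average force constants, per-well barrier times
#' `tbar_l = 2.302 / kbar_a` and `tbar_r = 2.302 / kbar_b`, the
#' velocity-continuity solve, the energy gap, trajectory generation and
#' truncation.  There is no iteration over the barrier time.
#'
#' @param state_a,state_b the two equilibrium `molecular_state`s (same
#'   atoms, same order).
#' @param cutoff,gamma ANM parameters (defaults 15 Angstrom, 0.01).
#' @param n_frames frames in the generated trajectory (default 100).
#' @param truncation_fraction progress threshold for
#'   [truncate_trajectory()]; default 0.1.
#' @param superpose superpose `state_b` onto `state_a` first (default
#'   `TRUE`) so the branch displacements carry no rigid-body offset.
#' @return an `ompath_result` list: `transition_state` (with `delta_e`
#'   filled and an `xbar_state` molecular state), `trajectory`
#'   (truncated), `trajectory_full`, `state_a`, `state_b` (as used), and
#'   `report` (kbar values, barrier times, energy gap, superposition
#'   RMSD, residual, condition number, truncation spans).
#' @export
compute_path <- function(state_a, state_b, cutoff = 15, gamma = 0.01,
                         n_frames = 100, truncation_fraction = 0.1,
                         superpose = TRUE) {
  stop_if_unpaired(state_a, state_b, "compute_path/pairing")
  fit_rmsd <- NA_real_
  if (superpose) {
    fit <- ompath::superpose(state_b, state_a)
    state_b <- fit$state
    fit_rmsd <- fit$rmsd
  } else {
    fit_rmsd <- rmsd_states(state_a, state_b)
  }
  model_a <- eigendecompose(build_hessian(state_a, cutoff = cutoff, gamma = gamma))
  model_b <- eigendecompose(build_hessian(state_b, cutoff = cutoff, gamma = gamma))
  kbar_a <- average_force_constant(model_a)
  kbar_b <- average_force_constant(model_b)
  tbar_l <- optimal_barrier_time(kbar_a)
  tbar_r <- optimal_barrier_time(kbar_b)
  ts <- solve_transition_state(model_a, model_b, state_a, state_b, tbar_l, tbar_r)
  ts$delta_e <- delta_energy(ts, state_a, state_b, model_a, model_b)
  identical_inputs <- fit_rmsd < 1e-8
  if (identical_inputs) {
    warning("compute_path/trajectory: input structures are identical; the trajectory is degenerate")
  }
  traj_full <- generate_trajectory(ts, state_a, state_b, model_a, model_b, n_frames)
  traj <- if (identical_inputs) traj_full else truncate_trajectory(traj_full, truncation_fraction)
  ts$xbar_state <- molecular_state(vec_to_coords(ts$xbar),
                                   chain = state_a$atoms$chain,
                                   resno = state_a$atoms$resno,
                                   resid = state_a$atoms$resid,
                                   elety = state_a$atoms$elety,
                                   label = "transition state")
  structure(list(
    transition_state = ts,
    trajectory = traj,
    trajectory_full = traj_full,
    state_a = state_a, state_b = state_b,
    model_a = model_a, model_b = model_b,
    report = list(kbar_a = kbar_a, kbar_b = kbar_b,
                  tbar_l = tbar_l, tbar_r = tbar_r, t_f = tbar_l + tbar_r,
                  delta_e = ts$delta_e,
                  rmsd_ab = fit_rmsd,
                  velocity_residual = ts$residual,
                  condition = ts$condition,
                  n_zero_modes_a = model_a$n_zero_modes,
                  n_zero_modes_b = model_b$n_zero_modes,
                  truncation = traj$truncation)
  ), class = "ompath_result")
}

#' @export
print.ompath_result <- function(x, ...) {
  r <- x$report
  cat("ompath result\n")
  cat(sprintf("  kbar (wells a, b):    %.6g, %.6g\n", r$kbar_a, r$kbar_b))
  cat(sprintf("  barrier times:        tbar_l = %.6g, tbar_r = %.6g (t_f = %.6g)\n",
              r$tbar_l, r$tbar_r, r$t_f))
  cat(sprintf("  energy gap deltaE:    %.6g\n", r$delta_e))
  cat(sprintf("  superposition RMSD:   %.4g A\n", r$rmsd_ab))
  cat(sprintf("  velocity residual:    %.3g (condition %.3g)\n", r$velocity_residual, r$condition))
  cat(sprintf("  trajectory:           %d frames retained", nrow(x$trajectory$frames)))
  if (!is.null(r$truncation)) {
    cat(sprintf(" (truncated %.3g + %.3g time units at %.0f%%)",
                r$truncation$head_span, r$truncation$tail_span, 100 * r$truncation$fraction))
  }
  cat("\n")
  invisible(x)
}
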