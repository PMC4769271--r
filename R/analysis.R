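# Validation analytics: energy/RMSD profiling of a transition state
# against a trajectory (ours or an external method's), and free-energy
# surfaces over two collective variables -- Boltzmann-inverted binning
# and a two-Gaussian-plus-quadratic-background fit whose stationary
# point locates the saddle.

#' Profile a reference state against a trajectory
#'
#' For every frame: the RMSD to `reference` (after rigid-body
#' superposition of the frame onto the reference), and the harmonic
#' energies of the frame in each well, `(x-a)' H_a (x-a)/2` and
#' `(x-b)' H_b (x-b)/2`, with their absolute difference.  The frame
#' minimizing `|PE_a - PE_b|` is the trajectory's implied transition
#' state: at the cusp the two well energies differ exactly by the energy
#' gap, so for near-symmetric transitions this frame sits at the barrier.
#'
#' @param reference a `molecular_state` (typically a transition state).
#' @param traj a `path_trajectory` (from [generate_trajectory()] or
#'   [read_trajectory()]).
#' @param model_a,model_b elastic models of the two wells.
#' @param a,b the well minima (states or 3N vectors) in the models' frame.
#' @param superpose_frames superpose each frame onto `a` before the
#'   energy evaluation (needed for external trajectories in a different
#'   frame; default `FALSE`).
#' @return an `energy_profile` data frame with columns `frame`, `time`,
#'   `rmsd`, `pe_a`, `pe_b`, `abs_dpe`, and attributes `ts_frame` (index
#'   of minimal `|dPE|`) and `min_rmsd_frame`.
#' @export
profile_against_trajectory <- function(reference, traj, model_a, model_b, a, b,
                                       superpose_frames = FALSE) {
  if (3 * n_atoms(reference) != ncol(traj$frames)) {
    stop("unpairable frames: trajectory and reference atom counts differ")
  }
  av <- as_state_vec(a); bv <- as_state_vec(b)
  ref <- coords_to_vec(reference$coords)
  nf <- nrow(traj$frames)
  rmsd <- pe_a <- pe_b <- numeric(nf)
  for (i in seq_len(nf)) {
    x <- traj$frames[i, ]
    fit <- suppressWarnings(bio3d::fit.xyz(fixed = ref, mobile = x,
                                           fixed.inds = seq_along(ref),
                                           mobile.inds = seq_along(x)))
    rmsd[i] <- vec_rmsd(as.numeric(fit), ref)
    if (superpose_frames) {
      x <- as.numeric(suppressWarnings(
        bio3d::fit.xyz(fixed = av, mobile = x,
                       fixed.inds = seq_along(av), mobile.inds = seq_along(x))))
    }
    da <- x - av; db <- x - bv
    pe_a[i] <- as.numeric(crossprod(da, model_a$hessian %*% da)) / 2
    pe_b[i] <- as.numeric(crossprod(db, model_b$hessian %*% db)) / 2
  }
  out <- data.frame(frame = seq_len(nf), time = traj$times,
                    rmsd = rmsd, pe_a = pe_a, pe_b = pe_b,
                    abs_dpe = abs(pe_a - pe_b))
  attr(out, "ts_frame") <- which.min(out$abs_dpe)
  attr(out, "min_rmsd_frame") <- which.min(out$rmsd)
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Bin samples into a free-energy surface
#'
#' Segregates `(X, Y)` samples into an equal-size bin grid spanning the
#' sample range (default 15 x 15 = 225 bins) and Boltzmann-inverts the
#' occupancies: `deltaG = -kT * ln(100 * n_i / N)`.  Temperature enters
#' only as a scale factor; energies are in units of `k_B T` when
#' `kT = 1`.  Empty bins carry `NA` (masked) free energies.
#'
#' @param samples two-column matrix or data frame of collective-variable
#'   samples.
#' @param n_bins bins per axis (default 15).
#' @param kT energy scale (default 1).
#' @param xlim,ylim optional explicit bin ranges; by default the grid
#'   spans the sample range.
#' @return a `free_energy_surface`: list with bin mid/break vectors,
#'   `counts` and `delta_g` matrices (X along rows), sample size `n` and
#'   `kT`.
#' @export
bin_free_energy <- function(samples, n_bins = 15, kT = 1,
                            xlim = NULL, ylim = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 2L) stop("samples must have two columns (X, Y)")
  if (nrow(samples) < 1L) stop("need at least one sample")
  rx <- if (is.null(xlim)) range(samples[, 1]) else xlim
  ry <- if (is.null(ylim)) range(samples[, 2]) else ylim
  if (diff(rx) == 0 || diff(ry) == 0) {
    stop("degenerate sample range: all samples identical along one axis")
  }
  bx <- seq(rx[1], rx[2], length.out = n_bins + 1L)
  by <- seq(ry[1], ry[2], length.out = n_bins + 1L)
  ix <- findInterval(samples[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(samples[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_len(nrow(samples))) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  n <- nrow(samples)
  dg <- matrix(NA_real_, n_bins, n_bins)
  occ <- counts > 0L
  dg[occ] <- -kT * log(100 * counts[occ] / n)
  structure(list(x_breaks = bx, y_breaks = by,
                 x_mid = (bx[-1] + bx[-length(bx)]) / 2,
                 y_mid = (by[-1] + by[-length(by)]) / 2,
                 counts = counts, delta_g = dg, n = n, kT = kT,
                 fit = NULL),
            class = "free_energy_surface")
}

#' Evaluate the two-basin free-energy model
#'
#' The surface model: an offset plus two anisotropic Gaussian basins with
#' cross terms, over a quadratic background centered on the saddle,
#' \deqn{G = C + A e^{-q_1} + B e^{-q_2} + D(X-Twt) + F(X-Twt)^2 +
#'       G_y(Y-Ht) + H_y(Y-Ht)^2}
#' with `q_1 = (X-Tw1)^2/(2 SigTw1) + (Y-H1)^2/(2 SigH1) +
#' J (X-Tw1)(Y-H1) / (2 (SigTw1^2 + SigH1^2))` and `q_2` the same with
#' the second basin's parameters and cross coefficient `J2`.  The `Sig`
#' parameters play the role of variances (they enter the quadratic terms
#' at first power).
#'
#' @param par named list/vector: `C`, `A`, `B`, `Tw1`, `H1`, `Tw2`, `H2`,
#'   `SigTw1`, `SigH1`, `SigTw2`, `SigH2`, `J`, `J2`, `D`, `F`, `G`,
#'   `Hq`, `Twt`, `Ht`.  Missing `D`, `G`, `J`, `J2` default to 0.
#' @param x,y coordinates at which to evaluate.
#' @return the model surface at `(x, y)`.
#' @export
fes_model <- function(par, x, y) {
  par <- as.list(par)
  for (nm in c("D", "G", "J", "J2")) if (is.null(par[[nm]])) par[[nm]] <- 0
  q1 <- (x - par$Tw1)^2 / (2 * par$SigTw1) + (y - par$H1)^2 / (2 * par$SigH1) +
    par$J * (x - par$Tw1) * (y - par$H1) / (2 * (par$SigTw1^2 + par$SigH1^2))
  q2 <- (x - par$Tw2)^2 / (2 * par$SigTw2) + (y - par$H2)^2 / (2 * par$SigH2) +
    par$J2 * (x - par$Tw2) * (y - par$H2) / (2 * (par$SigTw2^2 + par$SigH2^2))
  par$C + par$A * exp(-q1) + par$B * exp(-q2) +
    par$D * (x - par$Twt) + par$F * (x - par$Twt)^2 +
    par$G * (y - par$Ht) + par$Hq * (y - par$Ht)^2
}

# deterministic initialization: deepest two local minima of the binned
# surface seed the basin centers
fes_fit_start <- function(surface) {
  dg <- surface$delta_g
  nb <- nrow(dg)
  is_min <- matrix(FALSE, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    v <- dg[i, j]
    if (is.na(v)) next
    nb_i <- max(1, i - 1):min(nb, i + 1)
    nb_j <- max(1, j - 1):min(nb, j + 1)
    neigh <- dg[nb_i, nb_j]
    is_min[i, j] <- v <= min(neigh, na.rm = TRUE)
  }
  cand <- which(is_min, arr.ind = TRUE)
  cand <- cand[order(dg[cand]), , drop = FALSE]
  if (nrow(cand) < 2L) {
    ord <- order(dg)[seq_len(min(2L, sum(!is.na(dg))))]
    cand <- arrayInd(ord, dim(dg))
  }
  # keep the two deepest minima separated by at least 2 bins; if the
  # surface offers no second separated minimum, seed the second basin at
  # the farthest occupied bin so the Jacobian columns stay independent
  c1 <- cand[1, ]
  c2 <- NULL
  for (r in seq_len(nrow(cand))[-1]) {
    if (max(abs(cand[r, ] - c1)) >= 2) { c2 <- cand[r, ]; break }
  }
  if (is.null(c2)) {
    occ <- which(!is.na(dg), arr.ind = TRUE)
    c2 <- occ[which.max(rowSums(sweep(occ, 2, c1)^2)), ]
  }
  bw_x <- diff(surface$x_breaks[1:2]); bw_y <- diff(surface$y_breaks[1:2])
  med <- stats::median(dg, na.rm = TRUE)
  dat <- fes_bin_data(surface)
  quad <- stats::lm(g ~ x + I(x^2) + y + I(y^2), data = dat)
  cf <- stats::coef(quad)
  f0 <- if (abs(cf[["I(x^2)"]]) > 1e-12) cf[["I(x^2)"]] else 1e-3
  h0 <- if (abs(cf[["I(y^2)"]]) > 1e-12) cf[["I(y^2)"]] else 1e-3
  twt0 <- -cf[["x"]] / (2 * f0)
  ht0 <- -cf[["y"]] / (2 * h0)
  twt0 <- min(max(twt0, min(surface$x_mid)), max(surface$x_mid))
  ht0 <- min(max(ht0, min(surface$y_mid)), max(surface$y_mid))
  list(C = med,
       A = min(dg[c1[1], c1[2]] - med, -1e-3),
       B = min(dg[c2[1], c2[2]] - med, -1e-3),
       Tw1 = surface$x_mid[c1[1]], H1 = surface$y_mid[c1[2]],
       Tw2 = surface$x_mid[c2[1]], H2 = surface$y_mid[c2[2]],
       SigTw1 = (2 * bw_x)^2, SigH1 = (2 * bw_y)^2,
       SigTw2 = (2 * bw_x)^2, SigH2 = (2 * bw_y)^2,
       J = 0, J2 = 0, F = f0, Hq = h0, Twt = twt0, Ht = ht0)
}

fes_bin_data <- function(surface) {
  grid <- expand.grid(x = surface$x_mid, y = surface$y_mid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$g <- as.vector(surface$delta_g)
  grid[!is.na(grid$g), , drop = FALSE]
}

#' Fit the two-basin model to a binned surface
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nls.lm()]) of [fes_model()] to the unmasked bins.  The
#' background is estimated in a centered convention with the linear
#' coefficients `D = G = 0`, which makes the saddle `(Twt, Ht)` the
#' stationary point of the quadratic background and removes the
#' degeneracy between offset, linear terms and saddle position that the
#' uncentered parameterization suffers from.  Initialization is
#' deterministic: the two deepest local minima of the binned surface seed
#' the basin centers, widths start at two bin widths (squared), and a
#' quadratic regression seeds the background.
#'
#' @param surface a `free_energy_surface` from [bin_free_energy()].
#' @param start optional named list overriding the deterministic starts.
#' @return the surface with a `fit` element: `par` (full parameter set,
#'   including `D = G = 0`), `saddle = c(Twt, Ht)`, `centers` (2 x 2),
#'   `converged`, `residual_norm`, and the `nls.lm` object as `fit_obj`.
#'   On non-convergence the last iterate and residual norm are still
#'   reported, with a warning (no silent fallback).
#' @export
fit_fes <- function(surface, start = NULL) {
  dat <- fes_bin_data(surface)
  init <- fes_fit_start(surface)
  if (!is.null(start)) init[names(start)] <- start
  if (nrow(dat) < length(init)) {
    stop(sprintf("only %d unmasked bins for %d free parameters", nrow(dat), length(init)))
  }
  eps <- 1e-8
  lm_ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  run_lm <- function(start_par) {
    lower <- rep(-Inf, length(start_par)); names(lower) <- names(start_par)
    lower[intersect(c("SigTw1", "SigH1", "SigTw2", "SigH2"), names(start_par))] <- eps
    resid_fn <- function(p) {
      pl <- as.list(p)
      if (is.null(pl$B)) { pl$B <- 0; pl$Tw2 <- 0; pl$H2 <- 0; pl$SigTw2 <- 1; pl$SigH2 <- 1 }
      dat$g - fes_model(pl, dat$x, dat$y)
    }
    minpack.lm::nls.lm(par = unlist(start_par), fn = resid_fn,
                       lower = lower, control = lm_ctrl)
  }
  fit_obj <- tryCatch(run_lm(init), error = function(e) e)
  if (inherits(fit_obj, "error") || !(fit_obj$info %in% 1:4)) {
    msg <- if (inherits(fit_obj, "error")) conditionMessage(fit_obj) else fit_obj$message
    warning("FES fit did not converge: ", msg,
            "; reporting the last iterate")
    par <- if (inherits(fit_obj, "error")) c(init, D = 0, G = 0) else
      c(as.list(fit_obj$par), D = 0, G = 0)
    resid <- dat$g - fes_model(par, dat$x, dat$y)
    surface$fit <- list(par = par, saddle = c(Twt = par$Twt, Ht = par$Ht),
                        centers = rbind(c(par$Tw1, par$H1), c(par$Tw2, par$H2)),
                        converged = FALSE,
                        residual_norm = sqrt(sum(resid^2)), fit_obj = NULL)
    return(surface)
  }
  par <- as.list(fit_obj$par)
  par$D <- 0; par$G <- 0
  residual_norm <- sqrt(fit_obj$deviance)

  # model nesting check: if dropping the second Gaussian entirely fits the
  # surface just as well, the input is effectively single-basin and the
  # second amplitude is reported as zero rather than left free to mimic
  # the background
  nested <- tryCatch(
    run_lm(init[c("C", "A", "Tw1", "H1", "SigTw1", "SigH1", "J",
                  "F", "Hq", "Twt", "Ht")]),
    error = function(e) NULL
  )
  if (!is.null(nested) && nested$info %in% 1:4) {
    nres <- sqrt(nested$deviance)
    slack <- max(1e-3 * residual_norm, 1e-7 * sqrt(nrow(dat)) * stats::sd(dat$g))
    if (nres <= residual_norm + slack) {
      message("second basin amplitude is effectively zero: surface is single-basin")
      np <- as.list(nested$par)
      par[names(np)] <- np
      par$B <- 0
      par[c("Tw2", "H2")] <- list(NA_real_, NA_real_)
      residual_norm <- nres
      fit_obj <- nested
    }
  }
  centers <- rbind(c(par$Tw1, par$H1), c(par$Tw2, par$H2))
  surface$fit <- list(par = par,
                      saddle = c(Twt = par$Twt, Ht = par$Ht),
                      centers = centers,
                      converged = TRUE,
                      residual_norm = residual_norm,
                      fit_obj = fit_obj)
  surface
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface: %d x %d bins, N = %d samples, %d occupied\n",
              nrow(x$counts), ncol(x$counts), x$n, sum(x$counts > 0)))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted (%s): saddle at (%.4g, %.4g), residual norm %.4g\n",
                if (x$fit$converged) "converged" else "NOT converged",
                x$fit$saddle[1], x$fit$saddle[2], x$fit$residual_norm))
  }
  invisible(x)
}

#' Distance between the fitted saddle and a projected transition state
#'
#' @param surface a fitted `free_energy_surface`.
#' @param ts_projection length-2 vector: the transition state projected
#'   into the same collective variables (by the caller).
#' @return list with `distance` (Euclidean, CV units),
#'   `normalized_distance` (componentwise division by the bin widths),
#'   `saddle` and `ts`.
#' @export
saddle_vs_transition_state <- function(surface, ts_projection) {
  if (is.null(surface$fit)) stop("surface has not been fitted; call fit_fes() first")
  ts_projection <- as.numeric(ts_projection)
  if (length(ts_projection) != 2L) stop("ts_projection must be length 2")
  saddle <- as.numeric(surface$fit$saddle)
  d <- ts_projection - saddle
  bw <- c(diff(surface$x_breaks[1:2]), diff(surface$y_breaks[1:2]))
  list(distance = sqrt(sum(d^2)),
       normalized_distance = sqrt(sum((d / bw)^2)),
       saddle = saddle, ts = ts_projection)
}
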