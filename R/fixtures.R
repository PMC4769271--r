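# Seeded synthetic fixtures: two-state bead structures with controlled
# displacement and symmetry, and collective-variable samples drawn from a
# two-basin density.  Everything is reproducible from the seed and runs
# without downloads; these toys emulate coarse-grained (Calpha-like)
# protein geometry, not real force fields.

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

toy_template <- function(n_atoms, template) {
  i <- seq_len(n_atoms) - 1
  switch(template,
    chain = cbind(3.8 * i, 1.9 * sin(i * 1.0), 1.9 * cos(i * 0.6)),
    helix = cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180),
                  1.5 * i),
    ring = {
      r <- 3.8 / (2 * sin(pi / n_atoms))
      th <- 2 * pi * i / n_atoms
      cbind(r * cos(th), r * sin(th), 0)  # deliberately planar (degenerate ANM)
    },
    stop("unknown template '", template, "'")
  )
}

rotate_about <- function(coords, pivot, axis, angle_deg) {
  th <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(coords, 2, pivot) %*% t(R), 2, pivot, `+`)
}

#' Generate a synthetic two-state structure pair
#'
#' Builds a bead structure (3.8 Angstrom spacing, so the default 15
#' Angstrom ANM cutoff yields realistic connectivity) and derives the
#' second state from the first by a controlled displacement:
#' \describe{
#'   \item{hinge}{rotates the beads past the midpoint about an axis
#'     through the midpoint bead by `angle` degrees -- a domain motion.}
#'   \item{translate}{rigidly translates the whole structure by
#'     `translation` Angstrom along x (a degenerate pair: pure rigid-body
#'     displacement).}
#'   \item{mirror}{point inversion through the centroid.  The Hessians of
#'     the two states are exact conjugates (identical spectra), making
#'     the transition state the exact per-coordinate midpoint -- the
#'     canonical symmetric test case.}
#' }
#' Gaussian positional noise of sd `noise` is applied to the template
#' before the displacement, so the two states remain exactly related by
#' the chosen map.  The same seed always returns bit-identical output.
#'
#' @param n_atoms number of beads (>= 3; default 20).
#' @param template `"chain"`, `"helix"` or `"ring"` (the ring is planar,
#'   hence deliberately ANM-degenerate).
#' @param mode `"hinge"`, `"translate"` or `"mirror"`.
#' @param angle hinge angle in degrees (default 20).
#' @param translation rigid shift in Angstrom (default 3).
#' @param noise template jitter sd in Angstrom (default 0).
#' @param seed RNG seed (default 1); the global RNG state is restored.
#' @return list with `molecular_state`s `a` and `b` (identical atom ids
#'   and ordering).
#' @export
make_two_state_pair <- function(n_atoms = 20, template = c("chain", "helix", "ring"),
                                mode = c("hinge", "translate", "mirror"),
                                angle = 20, translation = 3, noise = 0, seed = 1) {
  template <- match.arg(template)
  mode <- match.arg(mode)
  if (n_atoms < 3L) stop("need at least 3 atoms for a non-collinear toy")
  coords_a <- toy_template(n_atoms, template)
  if (noise > 0) {
    coords_a <- coords_a + with_seed(seed, matrix(stats::rnorm(3 * n_atoms, sd = noise),
                                                  ncol = 3))
  }
  coords_b <- switch(mode,
    hinge = {
      pivot_idx <- max(2L, n_atoms %/% 2L)
      moving <- seq_len(n_atoms) > pivot_idx
      out <- coords_a
      out[moving, ] <- rotate_about(coords_a[moving, , drop = FALSE],
                                    pivot = coords_a[pivot_idx, ],
                                    axis = c(0, 0, 1), angle_deg = angle)
      out
    },
    translate = sweep(coords_a, 2, c(translation, 0, 0), `+`),
    mirror = sweep(-coords_a, 2, 2 * colMeans(coords_a), `+`)
  )
  mk <- function(coords, lab) molecular_state(coords, chain = "A",
                                              resno = seq_len(n_atoms),
                                              resid = "GLY", elety = "CA",
                                              label = lab)
  list(a = mk(coords_a, sprintf("%s/%s state a (seed %d)", template, mode, seed)),
       b = mk(coords_b, sprintf("%s/%s state b (seed %d)", template, mode, seed)))
}

#' Draw collective-variable samples from a two-basin density
#'
#' Inverts the two-basin free-energy model for testing: samples `(X, Y)`
#' from a mixture of two bivariate normal basins centered at
#' `(Tw1, H1)` and `(Tw2, H2)` with variances `SigTw*`/`SigH*` (cross
#' terms are not used in sampling).  Mixture weights derive from the
#' basin depths `A` and `B` (Boltzmann weights `exp(-A)`, `exp(-B)`;
#' equal depths give equal occupancy).  Binning these samples with
#' [bin_free_energy()] converges to a two-basin surface whose minima sit
#' at the generating centers.
#'
#' @param par named list with `Tw1`, `H1`, `Tw2`, `H2`, `SigTw1`,
#'   `SigH1`, `SigTw2`, `SigH2` and basin depths `A`, `B` (negative =
#'   deep), as in [fes_model()].
#' @param n_samples number of samples.
#' @param seed RNG seed (default 1); global RNG state is restored.
#' @return data frame with columns `X`, `Y`.
#' @export
make_fes_samples <- function(par, n_samples, seed = 1) {
  par <- as.list(par)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  sds <- c(par$SigTw1, par$SigH1, par$SigTw2, par$SigH2)
  if (any(sds <= 0)) stop("basin widths must be positive")
  w1 <- exp(-par$A) / (exp(-par$A) + exp(-par$B))
  with_seed(seed, {
    from1 <- stats::runif(n_samples) < w1
    x <- ifelse(from1,
                stats::rnorm(n_samples, par$Tw1, sqrt(par$SigTw1)),
                stats::rnorm(n_samples, par$Tw2, sqrt(par$SigTw2)))
    y <- ifelse(from1,
                stats::rnorm(n_samples, par$H1, sqrt(par$SigH1)),
                stats::rnorm(n_samples, par$H2, sqrt(par$SigH2)))
    data.frame(X = x, Y = y)
  })
}
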