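# Anisotropic network model of one equilibrium well: a uniform spring
# constant gamma connects every heavy-atom pair within a distance cutoff,
# giving the standard 3N x 3N ANM Hessian whose eigenmodes drive the
# Onsager-Machlup branch equations.

#' Build the ANM Hessian for one equilibrium well
#'
#' For every atom pair within `cutoff`, the off-diagonal 3x3 super-element
#' is `-gamma * u %o% u` with `u` the unit inter-atom vector; diagonal
#' blocks are the negative sum of the off-diagonal blocks in their row,
#' which enforces translational invariance (all row sums zero).
#'
#' @param state a [molecular_state()].
#' @param cutoff interaction cutoff in Angstrom (default 15).
#' @param gamma uniform spring constant (default 0.01, the value used for
#'   both wells by the non-iterative barrier-time estimator).
#' @return an `elastic_model` with the Hessian and its provenance; call
#'   [eigendecompose()] to complete it.
#' @export
build_hessian <- function(state, cutoff = 15, gamma = 0.01) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  coords <- state$coords
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 atoms")
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff & upper.tri(d)
  pairs <- which(adj, arr.ind = TRUE)
  connected <- rep(FALSE, n)
  h <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    u <- (coords[j, ] - coords[i, ]) / d[i, j]
    blk <- gamma * (u %o% u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- h[ii, jj] - blk
    h[jj, ii] <- h[jj, ii] - blk
    h[ii, ii] <- h[ii, ii] + blk
    h[jj, jj] <- h[jj, jj] + blk
    connected[c(i, j)] <- TRUE
  }
  if (!all(connected)) {
    warning(sprintf("%d atom(s) have no neighbour within the %.3g A cutoff: %s",
                    sum(!connected), cutoff,
                    paste(utils::head(atom_ids(state)[!connected], 5), collapse = ", ")))
  }
  structure(list(hessian = h, gamma = gamma, cutoff = cutoff,
                 n_atoms = n, label = state$label,
                 values = NULL, vectors = NULL, zero_modes = NULL,
                 n_zero_modes = NULL),
            class = "elastic_model")
}

#' Eigendecompose an elastic model
#'
#' Computes the full symmetric eigendecomposition of the Hessian with
#' eigenvalues sorted ascending.  Rigid-body modes are flagged by a
#' relative threshold: eigenvalues below `zero_tol * max(lambda)` count
#' as zero.  A 3D non-collinear connected structure has exactly six; more
#' indicates structural degeneracy (collinear, planar or disconnected
#' input) and triggers a warning.
#'
#' @param model an `elastic_model` from [build_hessian()].
#' @param zero_tol relative zero-mode threshold (default 1e-8).
#' @return the completed `elastic_model` with `values`, `vectors` (columns,
#'   orthonormal), `zero_modes` (indices) and `n_zero_modes`.
#' @export
eigendecompose <- function(model, zero_tol = 1e-8) {
  e <- eigen(model$hessian, symmetric = TRUE)
  ord <- order(e$values)
  model$values <- e$values[ord]
  model$vectors <- e$vectors[, ord, drop = FALSE]
  lmax <- max(abs(model$values))
  if (lmax == 0) stop("empty network: all eigenvalues are zero")
  model$zero_modes <- which(abs(model$values) < zero_tol * lmax)
  model$n_zero_modes <- length(model$zero_modes)
  if (model$n_zero_modes > 6L) {
    warning(sprintf("%d zero modes (expected 6): structure is degenerate (collinear, planar or disconnected)",
                    model$n_zero_modes))
  }
  model
}

#' Average force constant of a well
#'
#' The trace of the ANM Hessian divided by 3N.  This single scalar
#' summarizes the stiffness of the well and sets the non-iterative
#' barrier-time estimate via [optimal_barrier_time()].
#'
#' @param model an `elastic_model` (eigendecomposition not required).
#' @return the average force constant, strictly positive for connected
#'   structures.
#' @export
average_force_constant <- function(model) {
  tr <- sum(diag(model$hessian))
  if (tr <= 0) stop("zero Hessian trace: empty elastic network")
  tr / (3 * model$n_atoms)
}

#' @export
print.elastic_model <- function(x, ...) {
  cat(sprintf("elastic_model: %d atoms, gamma = %.4g, cutoff = %.4g A, kbar = %.6g\n",
              x$n_atoms, x$gamma, x$cutoff, average_force_constant(x)))
  if (!is.null(x$values)) {
    cat(sprintf("  eigendecomposed: %d modes, %d zero modes, lambda_max = %.6g\n",
                length(x$values), x$n_zero_modes, max(x$values)))
  }
  invisible(x)
}
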