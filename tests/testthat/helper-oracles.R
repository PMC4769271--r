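# Independent oracles used by the tests.  These deliberately avoid the
# package's own closed-form machinery: the action oracle discretizes the
# Onsager-Machlup Lagrangian on a time grid and solves the resulting
# sparse normal equations; the superposition oracle searches rotation
# space parameterized by Euler angles.

# Minimize the discretized OM action over a double harmonic well.
# Left branch on [0, tbar_l] (m intervals), right on [tbar_l, t_f].
# Action = sum |dx|^2/(2 dt) + trapezoid of (x-min)' H^2 (x-min) / 2.
# The stationarity conditions are linear; the cusp node of the solution
# is returned.  Error is O(dt^2); callers Richardson-extrapolate.
om_action_cusp_oracle <- function(hess_a, hess_b, a, b, tbar_l, tbar_r, m = 200) {
  ga <- hess_a %*% hess_a
  gb <- hess_b %*% hess_b
  d <- length(a)
  dl <- tbar_l / m
  dr <- tbar_r / m
  n_nodes <- 2 * m - 1                      # interior nodes, cusp at index m
  blocks_i <- list(); blocks_j <- list(); blocks_x <- list()
  rhs <- numeric(d * n_nodes)
  idx <- function(j) ((j - 1) * d + 1):(j * d)
  add_block <- function(j, k, mat) {
    ii <- rep(idx(j), times = d)
    jj <- rep(idx(k), each = d)
    blocks_i[[length(blocks_i) + 1]] <<- ii
    blocks_j[[length(blocks_j) + 1]] <<- jj
    blocks_x[[length(blocks_x) + 1]] <<- as.vector(mat)
  }
  eye <- diag(d)
  for (j in seq_len(n_nodes)) {
    if (j < m) {                            # left interior
      add_block(j, j, (2 / dl) * eye + dl * ga)
      if (j > 1) add_block(j, j - 1, -eye / dl)
      add_block(j, j + 1, -eye / dl)
      rhs[idx(j)] <- dl * (ga %*% a)
      if (j == 1) rhs[idx(j)] <- rhs[idx(j)] + a / dl
    } else if (j == m) {                    # cusp
      add_block(j, j, (1 / dl + 1 / dr) * eye + (dl / 2) * ga + (dr / 2) * gb)
      add_block(j, j - 1, -eye / dl)
      add_block(j, j + 1, -eye / dr)
      rhs[idx(j)] <- (dl / 2) * (ga %*% a) + (dr / 2) * (gb %*% b)
    } else {                                # right interior
      add_block(j, j, (2 / dr) * eye + dr * gb)
      add_block(j, j - 1, -eye / dr)
      if (j < n_nodes) add_block(j, j + 1, -eye / dr)
      rhs[idx(j)] <- dr * (gb %*% b)
      if (j == n_nodes) rhs[idx(j)] <- rhs[idx(j)] + b / dr
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(blocks_i), j = unlist(blocks_j),
                            x = unlist(blocks_x),
                            dims = c(d * n_nodes, d * n_nodes))
  sol <- as.numeric(Matrix::solve(K, rhs))
  sol[idx(m)]
}

# Richardson-extrapolated cusp (error O(dt^2) -> O(dt^4))
om_action_cusp_extrapolated <- function(hess_a, hess_b, a, b, tbar_l, tbar_r, m = 200) {
  x1 <- om_action_cusp_oracle(hess_a, hess_b, a, b, tbar_l, tbar_r, m)
  x2 <- om_action_cusp_oracle(hess_a, hess_b, a, b, tbar_l, tbar_r, 2 * m)
  (4 * x2 - x1) / 3
}

# Brute-force rigid-body fit: coarse Euler-angle grid, then Nelder-Mead
# refinement; translation handled by centering.  Returns the minimal RMSD.
grid_superpose_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((mc %*% t(rot(ang)) - rc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); best_val <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) { best_val <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# embed a 1D diatomic along the x axis as a 2-atom 3D state pair; the
# mode coordinate (projection on the stretch eigenvector) carries force
# constant 2*gamma
embedded_diatomic <- function(bond_a, bond_b, gamma_a, gamma_b, cutoff = 10) {
  A <- molecular_state(rbind(c(0, 0, 0), c(bond_a, 0, 0)))
  B <- molecular_state(rbind(c(0, 0, 0), c(bond_b, 0, 0)))
  list(a = A, b = B,
       model_a = eigendecompose(build_hessian(A, cutoff = cutoff, gamma = gamma_a)),
       model_b = eigendecompose(build_hessian(B, cutoff = cutoff, gamma = gamma_b)))
}

# stretch-mode coordinate of a 2-atom 3N vector (projection on the
# normalized relative-displacement direction along x)
stretch_coord <- function(vec) (vec[4] - vec[1]) / sqrt(2)

# small helper: default hinge fixture with precomputed models
hinge_fixture <- function(n_atoms = 12, angle = 25, seed = 3, gamma = 0.01,
                          cutoff = 15, noise = 0) {
  pair <- make_two_state_pair(n_atoms = n_atoms, template = "chain",
                              mode = "hinge", angle = angle, noise = noise,
                              seed = seed)
  list(a = pair$a, b = pair$b,
       model_a = eigendecompose(build_hessian(pair$a, cutoff = cutoff, gamma = gamma)),
       model_b = eigendecompose(build_hessian(pair$b, cutoff = cutoff, gamma = gamma)))
}

# reference FES parameter set used by generate-and-refit tests: two
# well-separated basins over a gentle saddle-centered background
fes_truth <- function() {
  list(C = 2.0, A = -3.0, B = -2.2,
       Tw1 = -1.0, H1 = -0.8, Tw2 = 1.2, H2 = 1.0,
       SigTw1 = 0.12, SigH1 = 0.10, SigTw2 = 0.15, SigH2 = 0.12,
       J = 0.05, J2 = -0.04, F = 0.3, Hq = 0.25,
       Twt = 0.1, Ht = 0.05, D = 0, G = 0)
}

# bin grid surface built directly from the model (no sampling noise)
fes_surface_from_model <- function(par, n_bins = 15, lim = c(-2, 2), noise_sd = 0,
                                   seed = NULL) {
  bx <- seq(lim[1], lim[2], length.out = n_bins + 1)
  mid <- (bx[-1] + bx[-length(bx)]) / 2
  g <- outer(mid, mid, function(x, y) fes_model(par, x, y))
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    set.seed(seed)
    g <- g + matrix(rnorm(length(g), sd = noise_sd * stats::sd(g)), nrow(g))
  }
  structure(list(x_breaks = bx, y_breaks = bx, x_mid = mid, y_mid = mid,
                 counts = matrix(1L, n_bins, n_bins), delta_g = g,
                 n = n_bins^2, kT = 1, fit = NULL),
            class = "free_energy_surface")
}
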