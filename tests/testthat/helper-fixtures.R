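# Shared fixtures, all built in code.

# a single nucleosome pose at the origin, symmetry axis +z
origin_pose <- function() {
  tibble::tibble(nucleosome = 0L, cx = 0, cy = 0, cz = 0,
                 ax = 0, ay = 0, az = 1, rx = 1, ry = 0, rz = 0)
}

# random unique lattice sites on a small grid
random_sites <- function(n, range = 0:9, seed = 1) {
  withr::with_seed(seed, {
    s <- unique(matrix(sample(range, 12L * n, replace = TRUE), ncol = 3L))
    stopifnot(nrow(s) >= n)
    s[seq_len(n), , drop = FALSE]
  })
}

# random complex N x 3 dipole moments
random_moments <- function(n, seed = 1) {
  withr::with_seed(seed, matrix(
    complex(real = stats::rnorm(3 * n), imaginary = stats::rnorm(3 * n)),
    ncol = 3L))
}

# orthogonal linear polarization pair along a given direction/basis
basis_waves <- function(lambda_vac = 300, host_index = 1.33,
                        direction = c(0, 0, 1), basis = NULL) {
  list(plane_wave(lambda_vac, host_index, direction, c(1, 0), basis = basis),
       plane_wave(lambda_vac, host_index, direction, c(0, 1), basis = basis))
}

# full fixed-orientation Mueller matrix of a model (both basis solves)
mueller_of <- function(model, wave = plane_wave(), theta_deg = 0:359,
                       tol = 1e-8, ...) {
  scatter_fixed(model, wave, theta_deg = theta_deg, tol = tol, ...)$mueller
}

# brute-force voxel-count oracle: counts lattice centers of `model`'s own
# lattice that fall inside the posed solids, written independently of
# voxelize()'s occupancy loop
brute_force_count <- function(model, poses, shape) {
  rng <- lapply(1:3, function(a) {
    seq(min(model$sites[, a]) - 2L, max(model$sites[, a]) + 2L)
  })
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  pts <- sweep(g * model$spacing, 2L, model$origin, "+")
  inside <- rep(FALSE, nrow(pts))
  for (r in seq_len(nrow(poses))) {
    c0 <- c(poses$cx[r], poses$cy[r], poses$cz[r])
    a0 <- c(poses$ax[r], poses$ay[r], poses$az[r])
    d <- sweep(pts, 2L, c0)
    if (shape$kind == "sphere") {
      inside <- inside | (rowSums(d * d) <= (shape$diameter / 2)^2)
    } else {
      t_ax <- d %*% a0
      inside <- inside | (abs(t_ax) <= shape$height / 2 &
                            rowSums(d * d) - t_ax^2 <= (shape$diameter / 2)^2)
    }
  }
  sum(inside)
}
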