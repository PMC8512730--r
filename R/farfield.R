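# Scattering geometry for a wave: directions n(theta) in the plane spanned by
# the propagation direction and the parallel basis vector e1, plus the
# scattered-field analyzer basis. For the default laboratory wave (+z, e1 =
# x, e2 = y) this is the fixed xz scattering plane with
# n(theta) = (sin theta, 0, cos theta).
scattering_directions <- function(wave, theta_deg) {
  th <- theta_deg * pi / 180
  d <- wave$direction; e1 <- wave$e1; e2 <- wave$e2
  nhat <- outer(sin(th), e1) + outer(cos(th), d)
  epar <- outer(cos(th), e1) - outer(sin(th), d)
  eperp <- matrix(e2, nrow = length(th), ncol = 3L, byrow = TRUE)
  list(nhat = nhat, epar = epar, eperp = eperp, theta_deg = theta_deg)
}

#' Far-field amplitude matrices
#'
#' Sums the phased radiation of all dipoles into the 2 x 2 complex amplitude
#' scattering matrix `[S2 S3; S4 S1]` (Bohren-Huffman layout: columns are
#' incident parallel/perpendicular states, rows scattered parallel/
#' perpendicular) on a scattering-angle grid. The scattering plane is spanned
#' by the incidence direction and the parallel polarization basis vector;
#' normalization follows the convention `dC_sca/dOmega = |S|^2 / k^2`.
#'
#' @param model A [dipole_model()].
#' @param waves List of two [plane_wave()]s sharing direction and basis, with
#'   Jones vectors (1, 0) and (0, 1) (parallel and perpendicular incident
#'   states).
#' @param solutions List of two `dipole_solution`s for `waves`.
#' @param theta_deg Scattering angles in degrees (strictly increasing);
#'   `0:359` covers both half-planes of the fixed scattering plane.
#' @return An `amplitude_set`: list with `theta_deg`, complex array `S`
#'   (2 x 2 x n_theta) and wavenumber `k`.
#' @export
amplitude_set <- function(model, waves, solutions, theta_deg = 0:359) {
  stopifnot(length(waves) == 2L, length(solutions) == 2L,
            inherits(waves[[1]], "plane_wave"),
            inherits(waves[[2]], "plane_wave"))
  if (max(abs(waves[[1]]$direction - waves[[2]]$direction)) > 1e-12 ||
      max(abs(waves[[1]]$e1 - waves[[2]]$e1)) > 1e-12) {
    stop("the two waves must share direction and basis", call. = FALSE)
  }
  if (max(Mod(waves[[1]]$jones - c(1, 0))) > 1e-12 ||
      max(Mod(waves[[2]]$jones - c(0, 1))) > 1e-12) {
    stop("waves must carry the (1,0) and (0,1) Jones states", call. = FALSE)
  }
  if (is.unsorted(theta_deg, strictly = TRUE)) {
    stop("theta_deg must be strictly increasing", call. = FALSE)
  }
  k <- k_medium(waves[[1]])
  geom <- scattering_directions(waves[[1]], theta_deg)
  r <- dipole_positions(model)
  # phase matrix exp(-i k n . r): n_theta x N
  ph <- exp(-1i * k * (geom$nhat %*% t(r)))
  nth <- length(theta_deg)
  S <- array(0i, c(2L, 2L, nth))
  pref <- -1i * k * k^2
  for (col in 1:2) {
    Tm <- ph %*% solutions[[col]]$P            # n_theta x 3
    S[1L, col, ] <- pref * rowSums(geom$epar * Tm)
    S[2L, col, ] <- pref * rowSums(geom$eperp * Tm)
  }
  structure(list(theta_deg = theta_deg, S = S, k = k),
            class = "amplitude_set")
}

#' @export
print.amplitude_set <- function(x, ...) {
  cat(sprintf("<amplitude_set> %d angles, k = %.5g 1/nm\n",
              length(x$theta_deg), x$k))
  invisible(x)
}

# Coherency-to-Stokes map for the (E_par, E_perp) field pair, with
# I = |E1|^2 + |E2|^2, Q = |E1|^2 - |E2|^2, U = 2 Re(E1 E2*),
# V = 2 Im(E1* E2) (left circular (1, +i)/sqrt(2) has V = +1).
stokes_A <- function() {
  matrix(c(1, 0, 0, 1,
           1, 0, 0, -1,
           0, 1, 1, 0,
           0, 1i, -1i, 0), nrow = 4L, byrow = TRUE)
}

# 16 x 16 coefficient matrix mapping the products J[a,c] Conj(J[b,d]) to the
# 16 Mueller elements, derived once from M = A (J (x) J*) A^{-1}.
mueller_coefficients <- function() {
  A <- stokes_A()
  Ainv <- solve(A)
  C <- matrix(0i, 16L, 16L)
  # product vector index for (a, b, c, d): coherency row (a,b), col (c,d)
  rowi <- function(a, b) 2L * (a - 1L) + b
  for (i in 1:4) for (j in 1:4) {
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) for (dd in 1:2) {
      p <- 4L * (rowi(a, cc) - 1L) + rowi(b, dd)
      C[4L * (i - 1L) + j, p] <- C[4L * (i - 1L) + j, p] +
        A[i, rowi(a, b)] * Ainv[rowi(cc, dd), j]
    }
  }
  C
}

.mueller_C <- NULL

get_mueller_C <- function() {
  if (is.null(.mueller_C)) {
    utils::assignInMyNamespace(".mueller_C", mueller_coefficients())
  }
  .mueller_C
}

#' Mueller matrix from amplitude matrices
#'
#' Quadratic map from the 2 x 2 complex amplitude matrix to the 4 x 4 real
#' Mueller matrix relating incident to scattered Stokes vectors, per angle.
#' A global phase on the amplitude matrix leaves the Mueller matrix
#' unchanged; `m11` is the total scattered intensity for unpolarized
#' incidence, `m14` the circular-polarization/intensity coupling read by
#' CIDS.
#'
#' @param amps An [amplitude_set()].
#' @return A tibble of class `mueller_angular`: columns `theta_deg` and
#'   `m11` ... `m44`.
#' @export
mueller_from_amplitudes <- function(amps) {
  stopifnot(inherits(amps, "amplitude_set"))
  nth <- length(amps$theta_deg)
  # J element vectors over theta: J[a, c]
  Jv <- list()
  for (a in 1:2) for (cc in 1:2) {
    Jv[[2L * (a - 1L) + cc]] <- amps$S[a, cc, ]
  }
  # products P[(a,c),(b,d)] = J[a,c] * Conj(J[b,d]) as n_theta x 16
  Pm <- matrix(0i, nth, 16L)
  for (ac in 1:4) for (bd in 1:4) {
    Pm[, 4L * (ac - 1L) + bd] <- Jv[[ac]] * Conj(Jv[[bd]])
  }
  Mm <- Re(Pm %*% t(get_mueller_C()))
  cols <- as.vector(t(outer(1:4, 1:4, function(i, j) paste0("m", i, j))))
  colnames(Mm) <- cols
  out <- tibble::as_tibble(Mm)
  out <- tibble::add_column(out, theta_deg = amps$theta_deg, .before = 1L)
  class(out) <- c("mueller_angular", class(out))
  out
}

#' Cross sections and efficiencies
#'
#' Extinction from the optical theorem over dipole moments,
#' `C_ext = 4 pi k sum_i Im(conj(E_inc,i) . P_i)` (unit incident amplitude);
#' absorption from the per-dipole formula with the radiative-reaction
#' correction, `C_abs = 4 pi k sum_i (-Im(1/alpha_i) - (2/3) k^3) |P_i|^2`;
#' scattering as the difference. Efficiencies are normalized by the
#' geometric cross section of the equal-volume sphere, `pi a_eff^2` with
#' `a_eff = (3 N d^3 / 4 pi)^(1/3)`.
#'
#' @param model A [dipole_model()].
#' @param wave The [plane_wave()] used for the solution.
#' @param solution A converged `dipole_solution`.
#' @return A one-row tibble: `C_ext`, `C_sca`, `C_abs` (nm^2), `Q_ext`,
#'   `Q_sca`, `Q_abs`, `a_eff` (nm).
#' @export
cross_sections <- function(model, wave, solution) {
  stopifnot(inherits(solution, "dipole_solution"))
  if (!isTRUE(solution$converged)) {
    stop("cross_sections() requires a converged solution", call. = FALSE)
  }
  k <- k_medium(wave)
  c_ext <- 4 * pi * k * sum(Im(rowSums(Conj(solution$E_inc) * solution$P)))
  inv_a <- 1 / solution$alpha
  pw <- rowSums(Mod(solution$P)^2)
  c_abs <- 4 * pi * k *
    sum(ifelse(pw > 0, (-Im(inv_a) - (2 / 3) * k^3) * pw, 0))
  a_eff <- a_effective(model)
  geo <- pi * a_eff^2
  tibble::tibble(
    C_ext = c_ext, C_sca = c_ext - c_abs, C_abs = c_abs,
    Q_ext = c_ext / geo, Q_sca = (c_ext - c_abs) / geo, Q_abs = c_abs / geo,
    a_eff = a_eff
  )
}

#' Scattering cross section by angular integration
#'
#' Integrates the far-field pattern `|F(n)|^2` of a solution over the full
#' sphere with a Gauss-Legendre (polar) x uniform (azimuth) product rule.
#' Used for energy-conservation checks against the optical-theorem
#' extinction.
#'
#' @param model A [dipole_model()].
#' @param wave The [plane_wave()] of the solution.
#' @param solution A `dipole_solution`.
#' @param n_polar,n_azimuth Quadrature sizes.
#' @return Scattering cross section in nm^2.
#' @export
integrate_scattered_power <- function(model, wave, solution,
                                      n_polar = 64L, n_azimuth = 64L) {
  k <- k_medium(wave)
  gl <- pracma::gaussLegendre(n_polar, -1, 1)
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(n_azimuth) - 1L) / n_azimuth
  nhat <- cbind(as.vector(outer(st, cos(phi))),
                as.vector(outer(st, sin(phi))),
                rep(ct, times = n_azimuth))
  w <- rep(gl$w, times = n_azimuth) * (2 * pi / n_azimuth)
  r <- dipole_positions(model)
  ph <- exp(-1i * k * (nhat %*% t(r)))
  Tm <- ph %*% solution$P
  dotp <- rowSums(nhat * Tm)
  F2 <- k^4 * (rowSums(Mod(Tm)^2) - Mod(dotp)^2)
  sum(w * F2)
}
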