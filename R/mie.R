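#' Lorenz-Mie series for a homogeneous sphere
#'
#' Independent reference computation (oracle) for the coupled-dipole engine:
#' efficiencies and angular amplitude functions of a sphere with relative
#' refractive index `m` and size parameter `x = k a` from the standard
#' series, truncated at `ceiling(x + 4 x^(1/3) + 2)` terms. The logarithmic
#' derivative is evaluated by downward recurrence, so complex `m` is
#' supported.
#'
#' @param m Complex relative refractive index.
#' @param x Size parameter (> 0).
#' @param theta_deg Angles at which to evaluate the amplitude functions
#'   `S1`, `S2`.
#' @return An object of class `mie_result`: list with `x`, `m`, `Q_ext`,
#'   `Q_sca`, `Q_abs`, `n_terms`, and a tibble `angular`
#'   (`theta_deg`, complex `S1`, `S2`, real `S11`).
#' @examples
#' mie_sphere(1.68 / 1.33, 0.5)$Q_ext
#' @export
mie_sphere <- function(m, x, theta_deg = 0:180) {
  m <- as.complex(m)
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x

  # logarithmic derivative D_n(mx), downward recurrence; after the loop
  # D[i] holds D_{i-1}, so shift to expose D_1 ... D_nmax
  nstart <- nmax + 15L
  D <- complex(nstart + 1L)
  for (n in nstart:1) {
    D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)
  }
  D <- D[1L + seq_len(nmax)]

  # Riccati-Bessel psi_n(x) = x j_n(x): downward recurrence, normalized
  jdown <- numeric(nstart + 2L)
  jdown[nstart + 2L] <- 0
  jdown[nstart + 1L] <- 1e-30
  for (n in nstart:1) {
    jdown[n] <- (2 * n + 1) / x * jdown[n + 1L] - jdown[n + 2L]
  }
  # jdown[n] ~ c * j_{n-1}(x); normalize with j_0 = sin(x)/x
  scale <- (sin(x) / x) / jdown[1L]
  jn <- jdown * scale
  psi <- x * jn[seq_len(nmax + 1L)]      # psi[n+1] = psi_n, n = 0..nmax
  chi <- numeric(nmax + 1L)
  chi[1L] <- cos(x)
  if (nmax >= 1L) chi[2L] <- cos(x) / x + sin(x)
  if (nmax >= 2L) {
    for (n in 2:nmax) {
      chi[n + 1L] <- (2 * n - 1) / x * chi[n] - chi[n - 1L]
    }
  }
  xi <- psi - 1i * chi

  n <- seq_len(nmax)
  fa <- D / m + n / x
  fb <- D * m + n / x
  an <- (fa * psi[n + 1L] - psi[n]) / (fa * xi[n + 1L] - xi[n])
  bn <- (fb * psi[n + 1L] - psi[n]) / (fb * xi[n + 1L] - xi[n])
  if (any(!is.finite(Mod(an))) || any(!is.finite(Mod(bn)))) {
    stop("Mie series produced non-finite coefficients", call. = FALSE)
  }
  q_ext <- (2 / x^2) * sum((2 * n + 1) * Re(an + bn))
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))

  mu <- cos(theta_deg * pi / 180)
  nth <- length(mu)
  S1 <- S2 <- complex(nth)
  pi_nm1 <- numeric(nth)       # pi_{n-1}, starts at pi_0 = 0
  pi_n <- rep(1, nth)          # pi_1
  for (nn in n) {
    tau_n <- nn * mu * pi_n - (nn + 1) * pi_nm1
    f <- (2 * nn + 1) / (nn * (nn + 1))
    S1 <- S1 + f * (an[nn] * pi_n + bn[nn] * tau_n)
    S2 <- S2 + f * (an[nn] * tau_n + bn[nn] * pi_n)
    pi_next <- ((2 * nn + 1) * mu * pi_n - (nn + 1) * pi_nm1) / nn
    pi_nm1 <- pi_n
    pi_n <- pi_next
  }
  structure(
    list(x = x, m = m, Q_ext = q_ext, Q_sca = q_sca,
         Q_abs = q_ext - q_sca, n_terms = nmax,
         angular = tibble::tibble(theta_deg = theta_deg, S1 = S1, S2 = S2,
                                  S11 = (Mod(S1)^2 + Mod(S2)^2) / 2)),
    class = "mie_result"
  )
}

#' @export
print.mie_result <- function(x, ...) {
  cat(sprintf("<mie_result> x = %g, m = %s: Q_ext = %.6g, Q_sca = %.6g\n",
              x$x, format(x$m, digits = 5), x$Q_ext, x$Q_sca))
  invisible(x)
}

#' Closed-form solution of the two-dipole system
#'
#' Dense oracle for [solve_dipoles()]: the coupled equations for two
#' identical dipoles (polarizability `alpha`) at positions `0` and
#' `separation` are solved exactly by inverting the 6 x 6 block system.
#'
#' @param separation Non-zero 3-vector (nm) from dipole 1 to dipole 2.
#' @param alpha Complex polarizability (nm^3).
#' @param wave A [plane_wave()].
#' @return A `dipole_solution` with 2 x 3 dipole moments.
#' @export
two_dipole_closed_form <- function(separation, alpha, wave) {
  stopifnot(is.numeric(separation), length(separation) == 3L)
  if (sum(separation^2) == 0) stop("separation must be non-zero", call. = FALSE)
  k <- k_medium(wave)
  G <- green_tensor(separation, k)
  A <- rbind(cbind(diag(3) / alpha, -G),
             cbind(-G, diag(3) / alpha))
  pos <- rbind(c(0, 0, 0), separation)
  pol <- wave$jones[1] * wave$e1 + wave$jones[2] * wave$e2
  E <- outer(exp(1i * k * drop(pos %*% wave$direction)), pol)
  x <- tryCatch(solve(A, c(t(E))), error = function(e)
    stop("singular two-dipole coupling matrix", call. = FALSE))
  P <- rbind(x[1:3], x[4:6])
  new_dipole_solution(P, E, rep(alpha, 2L), wave, residual = 0,
                      iterations = 1L, method = "closed_form",
                      converged = TRUE)
}

#' Compare the dipole engine against the Mie oracle
#'
#' Voxelizes a homogeneous sphere at a given number of dipoles per diameter,
#' solves the coupled system, and reports relative errors of the extinction
#' efficiency and of the pointwise angular intensity `S11(theta)` against
#' [mie_sphere()].
#'
#' @param m Complex relative refractive index (default 1.68/1.33).
#' @param x Size parameter of the sphere.
#' @param dipoles_per_diameter Discretization (>= 8).
#' @param wave Laboratory [plane_wave()] fixing wavelength and host index;
#'   the sphere radius is derived as `x / k`.
#' @param theta_deg Angle grid for the pointwise comparison.
#' @param tol Solver tolerance.
#' @return A tibble of class `mie_comparison`: columns `quantity`, `oracle`,
#'   `engine`, `rel_error` (rows `Q_ext`, `S11_max_dev`, plus worst-angle
#'   metadata in the attribute `detail`).
#' @export
compare_mie_dda <- function(m = 1.68 / 1.33, x, dipoles_per_diameter = 16L,
                            wave = plane_wave(), theta_deg = seq(0, 180, 5),
                            tol = 1e-6) {
  stopifnot(dipoles_per_diameter >= 8L)
  k <- k_medium(wave)
  a <- x / k
  pose <- tibble::tibble(nucleosome = 0L, cx = 0, cy = 0, cz = 0,
                         ax = 0, ay = 0, az = 1, rx = 1, ry = 0, rz = 0)
  model <- voxelize(pose, nucleosome_shape("sphere", diameter = 2 * a),
                    dipoles_per_longest = dipoles_per_diameter,
                    rel_index = m, host_index = wave$host_index)
  waves <- list(
    plane_wave(wave$lambda_vac, wave$host_index, wave$direction, c(1, 0)),
    plane_wave(wave$lambda_vac, wave$host_index, wave$direction, c(0, 1))
  )
  sols <- lapply(waves, function(w) solve_dipoles(model, w, tol = tol))
  amps <- amplitude_set(model, waves, sols, theta_deg)
  M <- mueller_from_amplitudes(amps)
  cs <- lapply(seq_along(waves),
               function(i) cross_sections(model, waves[[i]], sols[[i]]))
  q_dda <- mean(c(cs[[1]]$Q_ext, cs[[2]]$Q_ext))
  # compare at equal volume: the voxelized sphere's a_eff, not the nominal a
  x_eff <- k * a_effective(model)
  mie <- mie_sphere(m, x_eff, theta_deg)
  s11_mie <- mie$angular$S11
  s11_dda <- M$m11
  rel <- abs(s11_dda - s11_mie) / pmax(abs(s11_mie), .Machine$double.xmin)
  out <- tibble::tibble(
    quantity = c("Q_ext", "S11_max_rel_dev"),
    oracle = c(mie$Q_ext, NA_real_),
    engine = c(q_dda, NA_real_),
    rel_error = c(abs(q_dda - mie$Q_ext) / abs(mie$Q_ext), max(rel))
  )
  attr(out, "detail") <- tibble::tibble(theta_deg = theta_deg,
                                        S11_mie = s11_mie,
                                        S11_dda = s11_dda,
                                        rel_error = rel)
  attr(out, "n_dipoles") <- n_dipoles(model)
  class(out) <- c("mie_comparison", class(out))
  out
}
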