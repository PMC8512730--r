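wave300 <- plane_wave()

test_that("Clausius-Mossotti polarizability matches its closed form", {
  expect_identical(cm_polarizability(1, 2), 0 + 0i)
  # m^2 = 2, d = 1: (3/4pi) * 1/4 = 3/(16 pi)
  expect_equal(cm_polarizability(sqrt(2), 1), complex(real = 3 / (16 * pi)),
               tolerance = 1e-12)
  # chromatin contrast value, frozen from direct evaluation of the formula
  expect_equal(Re(cm_polarizability(1.68 / 1.33, 1)), 0.039543505,
               tolerance = 1e-7)
  expect_error(cm_polarizability(complex(imaginary = sqrt(2)), 1), "resonance")
  expect_warning(cm_polarizability(3.5, 1), "accuracy")
})

test_that("LDR polarizability has the right limits and radiative term", {
  m <- 1.68 / 1.33
  # long-wavelength limit: alpha_LDR -> alpha_CM
  w_long <- plane_wave(lambda_vac = 3e7)
  expect_equal(ldr_polarizability(m, 1, w_long), cm_polarizability(m, 1),
               tolerance = 1e-9)
  # exact radiative reaction: Im(1/alpha) = -(2/3) k^3 for real m
  for (d in c(0.3, 1, 2)) {
    k <- k_medium(wave300)
    a <- ldr_polarizability(m, d, wave300)
    expect_equal(Im(1 / a), -(2 / 3) * k^3, tolerance = 1e-12)
  }
  # finite and continuous in kd on (0, 1)
  ks <- seq(0.02, 0.99, length.out = 40)
  vals <- vapply(ks, function(kd) {
    w <- plane_wave(lambda_vac = 2 * pi * 1.33 / kd)   # d = 1 => kd as given
    ldr_polarizability(m, 1, w)
  }, complex(1))
  expect_true(all(is.finite(Mod(vals))))
  expect_lt(max(Mod(diff(vals))), 0.01 * max(Mod(vals)))
  # the polarization-averaged direction factor is basis-invariant: oblique
  # incidence gives the same value for any transverse basis
  dirs <- c(1, 2, 2) / 3
  b1 <- list(e1 = c(2, -1, 0) / sqrt(5),
             e2 = pracma::cross(dirs, c(2, -1, 0) / sqrt(5)))
  a1 <- ldr_polarizability(m, 1, plane_wave(direction = dirs, basis = b1))
  a2 <- ldr_polarizability(m, 1, plane_wave(direction = dirs))
  expect_equal(a1, a2, tolerance = 1e-14)
})

test_that("interaction product matches the dyadic Green's tensor", {
  k <- k_medium(wave300)
  # single dipole: no self term
  one <- dipole_model(1, c(0, 0, 0), matrix(c(0L, 0L, 0L), 1))
  P1 <- matrix(c(1 + 1i, 0, 0), 1)
  expect_equal(apply_interaction(one, k, P1, "direct"),
               matrix(0i, 1, 3))
  # two sites along z, moments along z: longitudinal term
  # 2 (1 - ikr) e^{ikr} / r^3
  r <- 7
  two <- dipole_model(r, c(0, 0, 0), rbind(c(0L, 0L, 0L), c(0L, 0L, 1L)))
  Pz <- rbind(c(0, 0, 1 + 0i), c(0, 0, 0i))
  E <- apply_interaction(two, k, Pz, "direct")
  expect_equal(E[2, 3], 2 * (1 - 1i * k * r) * exp(1i * k * r) / r^3,
               tolerance = 1e-12)
  expect_equal(E[2, 1], 0i)
  # transverse closed form: k^2/r + (ik/r^2 - 1/r^3), times phase
  Px <- rbind(c(1 + 0i, 0, 0), c(0i, 0, 0))
  Ex <- apply_interaction(two, k, Px, "direct")
  expect_equal(Ex[2, 1],
               exp(1i * k * r) * (k^2 / r - 1 / r^3 + 1i * k / r^2),
               tolerance = 1e-12)
  expect_error(dipole_model(1, c(0, 0, 0),
                            rbind(c(0L, 0L, 0L), c(0L, 0L, 0L))), "duplicate")
})

test_that("accelerated interaction product agrees with the direct sum", {
  k <- k_medium(wave300)
  for (seed in 1:3) {
    sites <- random_sites(50, seed = seed)
    m <- dipole_model(0.8, c(-1, 2, 0.5), sites)
    P <- random_moments(50, seed = seed)
    e_dir <- apply_interaction(m, k, P, "direct")
    e_fft <- apply_interaction(m, k, P, "fft")
    expect_lt(max(Mod(e_dir - e_fft)) / max(Mod(e_dir)), 1e-10)
  }
})

test_that("coupled solve satisfies its residual contract", {
  # N = 1: P = alpha E exactly, and identical to the Born mode
  one <- dipole_model(1, c(0, 0, 0), matrix(c(0L, 0L, 0L), 1))
  s1 <- solve_dipoles(one, wave300)
  a1 <- ldr_polarizability(1.68 / 1.33, 1, wave300)
  expect_equal(s1$P, a1 * s1$E_inc, tolerance = 1e-12)
  expect_equal(born_dipoles(one, wave300)$P, s1$P, tolerance = 1e-12)

  # N = 2 matches the closed-form block solve
  sep <- c(0, 2.4, 1.6)
  two <- dipole_model(0.8, c(0, 0, 0), rbind(c(0L, 0L, 0L), c(0L, 3L, 2L)))
  a <- ldr_polarizability(1.68 / 1.33, 0.8, wave300)
  oracle <- two_dipole_closed_form(sep, a, wave300)
  s2 <- solve_dipoles(two, wave300, tol = 1e-10)
  expect_equal(s2$P, oracle$P, tolerance = 1e-8)

  # converged medium model: reported residual verifiable from the operator
  m <- voxelize(solenoid_spec(), dipoles_per_longest = 10)
  s <- solve_dipoles(m, wave300, tol = 1e-6, method = "bicgstab")
  expect_lte(s$residual, 1e-6)
  k <- k_medium(wave300)
  lhs <- s$P / s$alpha - apply_interaction(m, k, s$P)
  rel <- sqrt(sum(Mod(lhs - s$E_inc)^2)) / sqrt(sum(Mod(s$E_inc)^2))
  expect_lte(rel, 1e-6)
  # Born mode solves the uncoupled equation exactly
  b <- born_dipoles(m, wave300)
  expect_equal(b$P, b$alpha * b$E_inc, tolerance = 1e-14)
})

test_that("iterative and dense solutions agree for small systems", {
  m <- voxelize(solenoid_spec(), dipoles_per_longest = 9)
  expect_lte(n_dipoles(m), 200L)
  s_it <- solve_dipoles(m, wave300, tol = 1e-8, method = "bicgstab")
  s_de <- solve_dipoles(m, wave300, method = "dense")
  expect_lt(max(Mod(s_it$P - s_de$P)) / max(Mod(s_de$P)), 1e-7)
})

test_that("single-dipole far field is the Rayleigh pattern", {
  one <- dipole_model(1, c(0, 0, 0), matrix(c(0L, 0L, 0L), 1))
  waves <- basis_waves()
  sols <- lapply(waves, function(w) solve_dipoles(one, w))
  th <- seq(0, 350, 10)
  am <- amplitude_set(one, waves, sols, th)
  S1 <- am$S[2, 2, ]; S2 <- am$S[1, 1, ]
  expect_lt(max(Mod(S1 - S1[1])), 1e-14 * Mod(S1[1]))
  expect_lt(max(Mod(S2 - S1[1] * cos(th * pi / 180))), 1e-12 * Mod(S1[1]))
  expect_lt(max(Mod(am$S[1, 2, ])), 1e-14 * Mod(S1[1]))
  M <- mueller_from_amplitudes(am)
  expect_lt(max(abs(M$m14)), 1e-14 * max(M$m11))
})

test_that("rigid translation changes amplitudes only by phase", {
  m <- voxelize(solenoid_spec(), dipoles_per_longest = 8)
  shifted <- dipole_model(m$spacing, m$origin + c(3.2, -1.1, 0.7), m$sites,
                          m$rel_index, m$host_index)
  th <- seq(0, 350, 10)
  waves <- basis_waves()
  sols_a <- lapply(waves, function(w) solve_dipoles(m, w, tol = 1e-9))
  sols_b <- lapply(waves, function(w) solve_dipoles(shifted, w, tol = 1e-9))
  am_a <- amplitude_set(m, waves, sols_a, th)
  am_b <- amplitude_set(shifted, waves, sols_b, th)
  # per-angle global phase: ratios of matched elements are unimodular ...
  ratio <- am_b$S[2, 2, ] / am_a$S[2, 2, ]
  expect_equal(Mod(ratio), rep(1, length(th)), tolerance = 1e-6)
  # ... hence identical Mueller matrices
  Ma <- mueller_from_amplitudes(am_a)
  Mb <- mueller_from_amplitudes(am_b)
  expect_lt(max(abs(as.matrix(Mb[-1]) - as.matrix(Ma[-1]))) / max(Ma$m11),
            1e-6)
})

test_that("Mueller map is the quadratic Stokes transfer of the amplitudes", {
  # independent construction: M = A (J kron Conj(J)) A^-1 per angle
  A <- rbind(c(1, 0, 0, 1), c(1, 0, 0, -1), c(0, 1, 1, 0), c(0, 1i, -1i, 0))
  S <- array(random_moments(4, seed = 7), c(2, 2, 3)) # arbitrary finite
  S[, , 2] <- S[, , 2] * exp(0.83i)   # add a pure global phase case
  amps <- structure(list(theta_deg = c(5, 10, 15), S = S,
                         k = k_medium(wave300)),
                    class = "amplitude_set")
  M <- mueller_from_amplitudes(amps)
  for (t in 1:3) {
    ref <- Re(A %*% (S[, , t] %x% Conj(S[, , t])) %*% solve(A))
    got <- matrix(as.numeric(M[t, -1]), 4, byrow = TRUE)
    expect_equal(got, ref, tolerance = 1e-12)
  }
  # global phase invariance and positivity bound
  M2 <- mueller_from_amplitudes(structure(
    list(theta_deg = 1:3, S = S * exp(1.2i), k = amps$k),
    class = "amplitude_set"))
  expect_equal(as.matrix(M2[-1]), as.matrix(M[-1]), tolerance = 1e-10)
  expect_true(all(M$m11 + 1e-12 * max(M$m11) >= abs(as.matrix(M[-1]))))
})

test_that("cross sections obey the optical theorem and energy conservation", {
  # single dipole with LDR alpha: C_ext equals the integrated far field
  one <- dipole_model(1, c(0, 0, 0), matrix(c(0L, 0L, 0L), 1))
  s1 <- solve_dipoles(one, wave300)
  cs1 <- cross_sections(one, wave300, s1)
  c_int <- integrate_scattered_power(one, wave300, s1)
  expect_lt(abs(cs1$C_ext - c_int) / cs1$C_ext, 1e-6)
  # real refractive index: no absorption
  expect_lt(abs(cs1$C_abs) / cs1$C_ext, 1e-12)
  # multi-dipole converged solution: C_ext - C_abs equals the angular
  # integral of the scattered power to quadrature accuracy
  m <- voxelize(solenoid_spec(), dipoles_per_longest = 10)
  s <- solve_dipoles(m, wave300, tol = 1e-8)
  cs <- cross_sections(m, wave300, s)
  ci <- integrate_scattered_power(m, wave300, s)
  expect_lt(abs(cs$C_ext - cs$C_abs - ci) / ci, 0.01)
  expect_equal(cs$Q_ext, cs$C_ext / (pi * a_effective(m)^2))
  expect_error(cross_sections(m, wave300, born_dipoles(m, wave300)), NA)
})

test_that("Mie discrepancy shrinks as the sphere discretization refines", {
  k <- k_medium(wave300)
  x <- k * 5.5
  errs <- vapply(c(8, 16), function(dd) {
    compare_mie_dda(x = x, dipoles_per_diameter = dd)$rel_error[1]
  }, numeric(1))
  expect_lt(errs[1], 0.05)
  expect_lte(errs[2], errs[1])
})

test_that("reciprocity holds for exchanged incidence and scattering", {
  m <- voxelize(solenoid_spec(), dipoles_per_longest = 9)
  th <- 73
  rad <- th * pi / 180
  M1 <- mueller_of(m, theta_deg = c(0, th), tol = 1e-10, s_mode = "iso")
  nrev <- -c(sin(rad), 0, cos(rad))
  b2 <- list(e1 = c(cos(rad), 0, -sin(rad)), e2 = c(0, 1, 0))
  waves <- basis_waves(direction = nrev, basis = b2)
  sols <- lapply(waves, function(w)
    solve_dipoles(m, w, tol = 1e-10, s_mode = "iso"))
  M2 <- mueller_from_amplitudes(amplitude_set(m, waves, sols, c(0, th)))
  expect_equal(M2$m11[2], M1$m11[2], tolerance = 1e-7)
})
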