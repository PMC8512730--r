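test_that("direct CIDS ratio behaves as the defining formula", {
  th <- 0:10
  expect_equal(cids_direct(th, rep(2, 11), rep(2, 11))$cids, rep(0, 11))
  expect_equal(cids_direct(th, rep(3, 11), rep(0, 11))$cids, rep(1, 11))
  a <- cids_direct(th, 1 + th, rep(1, 11))
  b <- cids_direct(th, rep(1, 11), 1 + th)
  expect_equal(b$cids, -a$cids)
  expect_true(all(abs(a$cids) <= 1))
  expect_error(cids_direct(th, rep(0, 11), rep(0, 11)), "undefined")
  expect_error(cids_direct(th, rep(-1, 11), rep(1, 11)), "non-negative")
})

test_that("Mueller-element CIDS equals the two-illumination ratio", {
  wave <- plane_wave()
  model <- voxelize(solenoid_spec(), dipoles_per_longest = 10)
  res <- scatter_fixed(model, wave, tol = 1e-9)
  direct <- scatter_circular(model, wave, tol = 1e-9)
  expect_lt(max(abs(res$cids$cids - direct$cids)), 1e-8)
  # an isotropic sphere has no circular-differential signal
  sph <- voxelize(origin_pose(), nucleosome_shape("sphere"),
                  dipoles_per_longest = 9)
  res_s <- scatter_fixed(sph, wave, tol = 1e-9)
  expect_lt(max(abs(res_s$cids$cids)), 1e-12)
  # m11 = 0 anywhere is rejected
  bad <- tibble::tibble(theta_deg = 0:1, m11 = c(1, 0), m14 = c(0, 0))
  expect_error(cids_from_mueller(bad), "m11")
})

test_that("total intensity is m11 with its symmetry and scaling", {
  wave <- plane_wave()
  mR <- voxelize(solenoid_spec(), dipoles_per_longest = 10)
  mL <- mirror_model(mR, "xz")
  MR <- mueller_of(mR, tol = 1e-9)
  ML <- mueller_of(mL, tol = 1e-9)
  expect_equal(total_intensity(MR)$intensity, MR$m11)
  expect_true(all(MR$m11 >= 0))
  # opposite-handed model: identical unpolarized intensity
  expect_lt(max(abs(MR$m11 - ML$m11)) / max(MR$m11), 1e-10)
  # doubling every dipole moment quadruples the intensity
  waves <- basis_waves()
  sols <- lapply(waves, function(w) solve_dipoles(mR, w, tol = 1e-9))
  amps <- amplitude_set(mR, waves, sols, 0:359)
  amps2 <- amps
  amps2$S <- 2 * amps$S
  expect_equal(mueller_from_amplitudes(amps2)$m11, 4 * MR$m11,
               tolerance = 1e-12)
})

test_that("Euler quadrature has unit weight and exactness for constants", {
  q1 <- make_quadrature(1, 1, 1)
  expect_equal(nrow(q1), 1L)
  expect_equal(q1$weight, 1)
  for (counts in list(c(3, 2, 1), c(8, 8, 4), c(5, 7, 2))) {
    q <- make_quadrature(counts[1], counts[2], counts[3])
    expect_equal(sum(q$weight), 1, tolerance = 1e-13)
    expect_true(all(q$weight > 0))
    # averaging a rotation-invariant integrand returns it exactly
    expect_equal(sum(q$weight * 42), 42)
  }
  # gamma grid closed under gamma -> gamma + pi for even counts
  q <- make_quadrature(2, 2, 4)
  g <- sort(unique(round(q$gamma, 12)))
  expect_true(all(round((g + pi) %% (2 * pi), 12) %in%
                    round(g %% (2 * pi), 12)))
})

test_that("orientation averaging is inert for a quasi-isotropic scatterer", {
  wave <- plane_wave()
  sph <- voxelize(origin_pose(), nucleosome_shape("sphere"),
                  dipoles_per_longest = 9)
  th <- seq(0, 180, 15)
  Mavg <- orientation_average(sph, wave, make_quadrature(2, 2, 1),
                              theta_deg = th)
  waves <- basis_waves()
  sols <- lapply(waves, function(w)
    solve_dipoles(sph, w, method = "dense", s_mode = "iso"))
  Mfix <- mueller_from_amplitudes(amplitude_set(sph, waves, sols, th))
  # residual anisotropy is the cubic-lattice discretization, not the solver
  expect_lt(max(abs(as.matrix(Mavg[-1]) - as.matrix(Mfix[-1]))) /
              max(Mfix$m11), 5e-3)
})

test_that("averaged CIDS equals the ensemble-intensity ratio", {
  wave <- plane_wave()
  model <- voxelize(solenoid_spec(), dipoles_per_longest = 10)
  q <- make_quadrature(2, 2, 2)
  th <- seq(0, 180, 30)
  M <- orientation_average(model, wave, q, theta_deg = th)
  cids_elements <- cids_from_mueller(M)$cids
  # independent route: per-node left/right circular intensities, summed
  IL <- IR <- numeric(length(th))
  for (i in seq_len(nrow(q))) {
    Qt <- t(euler_rotation(q$alpha[i], q$beta[i], q$gamma[i]))
    b <- list(e1 = drop(Qt %*% c(1, 0, 0)), e2 = drop(Qt %*% c(0, 1, 0)))
    dirp <- drop(Qt %*% c(0, 0, 1))
    for (pol in c("L", "R")) {
      w <- plane_wave(300, 1.33, dirp, pol, basis = b)
      sol <- solve_dipoles(model, w, tol = 1e-9, s_mode = "iso")
      geom <- cidscatter:::scattering_directions(w, th)
      k <- k_medium(w)
      ph <- exp(-1i * k * (geom$nhat %*% t(dipole_positions(model))))
      Tm <- ph %*% sol$P
      inten <- k^6 * (rowSums(Mod(Tm)^2) - Mod(rowSums(geom$nhat * Tm))^2)
      if (pol == "L") IL <- IL + q$weight[i] * inten
      else IR <- IR + q$weight[i] * inten
    }
  }
  expect_lt(max(abs(cids_elements - (IL - IR) / (IL + IR))), 1e-7)
})

test_that("mirror reflection flips CIDS and preserves intensity", {
  wave <- plane_wave()
  mR <- voxelize(solenoid_spec(), dipoles_per_longest = 10)
  mL <- mirror_model(mR, "xz")
  rR <- scatter_fixed(mR, wave, tol = 1e-9)
  rL <- scatter_fixed(mL, wave, tol = 1e-9)
  expect_lt(max(abs(rR$cids$cids + rL$cids$cids)), 1e-9)
  expect_lt(max(abs(rR$mueller$m11 - rL$mueller$m11)) / max(rR$mueller$m11),
            1e-9)
  expect_true(all(abs(rR$cids$cids) <= 1))
})

test_that("averaged m11 is stable under quadrature refinement", {
  wave <- plane_wave()
  model <- voxelize(solenoid_spec(), dipoles_per_longest = 8)
  th <- seq(0, 180, 20)
  m_a <- orientation_average(model, wave, make_quadrature(6, 6, 4),
                             theta_deg = th)
  m_b <- orientation_average(model, wave, make_quadrature(12, 12, 8),
                             theta_deg = th)
  expect_lt(max(abs(m_a$m11 - m_b$m11)) / max(m_b$m11), 0.01)
})

test_that("orientation averaging validates its quadrature", {
  model <- voxelize(solenoid_spec(), dipoles_per_longest = 8)
  q <- make_quadrature(2, 2, 1)
  q$weight <- q$weight * 2
  expect_error(orientation_average(model, quadrature = q), "sum to 1")
})
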