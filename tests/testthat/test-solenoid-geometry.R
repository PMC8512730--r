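test_that("nucleosome poses follow the helix parameterization", {
  p <- nucleosome_poses(solenoid_spec())
  # k = 3: azimuth pi, height 11 * 3/6
  expect_equal(c(p$cx[4], p$cy[4], p$cz[4]), c(-10, 0, 5.5), tolerance = 1e-12)
  expect_equal(c(p$ax[4], p$ay[4], p$az[4]), c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(nrow(p), 6L)
  # consecutive rise P/n, all centers at distance R from the z axis
  expect_equal(diff(p$cz), rep(11 / 6, 5L))
  expect_equal(sqrt(p$cx^2 + p$cy^2), rep(10, 6L))
  # unit orthonormal frames
  expect_equal(p$ax^2 + p$ay^2 + p$az^2, rep(1, 6L))
  expect_equal(p$rx^2 + p$ry^2 + p$rz^2, rep(1, 6L))
  expect_equal(p$ax * p$rx + p$ay * p$ry + p$az * p$rz, rep(0, 6L))
  # multi-turn count
  expect_equal(nrow(nucleosome_poses(solenoid_spec(turns = 3L))), 18L)
})

test_that("degenerate radius gives an on-axis achiral chain", {
  p <- nucleosome_poses(solenoid_spec(radius = 0, pitch = 11))
  expect_equal(p$cx, rep(0, 6L))
  expect_equal(p$cy, rep(0, 6L))
  expect_equal(p$cz, 11 * (0:5) / 6)
  # identical frames (axis +x), so the stack has no screw sense
  expect_equal(p$ax, rep(1, 6L))
  expect_equal(p$ay, rep(0, 6L))
  p_rot <- nucleosome_poses(solenoid_spec(radius = 0, rotating_frame_at_r0 = TRUE))
  expect_gt(max(abs(diff(p_rot$ax))), 0.1)
})

test_that("flipping handedness mirrors the poses exactly through xz", {
  for (pitch in c(0, 11, 22)) {
    pr <- nucleosome_poses(solenoid_spec(pitch = pitch, phase0 = 0.3))
    pl <- nucleosome_poses(solenoid_spec(pitch = pitch, phase0 = 0.3,
                                         handedness = "left"))
    expect_identical(pl$cx, pr$cx)
    expect_identical(pl$cy, -pr$cy)
    expect_identical(pl$cz, pr$cz)
    expect_identical(pl$ay, -pr$ay)
    expect_identical(pl$ax, pr$ax)
  }
})

test_that("pose rotation is a proper rigid motion", {
  p <- nucleosome_poses(solenoid_spec())
  expect_equal(rotate_poses(p, 0, 0, 0), p)
  twice <- rotate_poses(rotate_poses(p, 0, pi, 0), 0, pi, 0)
  expect_equal(as.matrix(twice[-1]), as.matrix(p[-1]), tolerance = 1e-12)
  r <- rotate_poses(p, 0.4, 1.1, -0.7)
  d0 <- dist(as.matrix(p[, c("cx", "cy", "cz")]))
  d1 <- dist(as.matrix(r[, c("cx", "cy", "cz")]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
})

test_that("opposite-handed stack is an exact mirror composite", {
  stack <- stack_opposite_handed(solenoid_spec())
  expect_length(stack$segments, 2L)
  expect_equal(nrow(stack$poses), 12L)
  expect_equal(sum(stack$poses$segment == 1L), 6L)
  expect_identical(stack$segments[[2]]$spec$handedness, "left")
  expect_equal(stack$segments[[2]]$axial_offset, 11)
  # pose set invariant under reflection through the stored mirror plane
  zm <- stack$mirror_plane_z
  mirrored <- stack$poses
  mirrored$cz <- 2 * zm - mirrored$cz
  key <- function(df) {
    m <- round(as.matrix(df[, c("cx", "cy", "cz")]), 9)
    m[order(m[, 1], m[, 2], m[, 3]), ]
  }
  expect_equal(key(mirrored), key(stack$poses))
  # negative control: two right-handed turns stacked are not mirror symmetric
  p0 <- nucleosome_poses(solenoid_spec(turns = 2L))
  m2 <- p0
  m2$cz <- 2 * zm - m2$cz
  expect_gt(max(abs(key(m2) - key(p0))), 1)
  expect_error(stack_opposite_handed(solenoid_spec(turns = 2L)), "one-turn")
})

test_that("voxel occupancy equals the brute-force point-in-solid count", {
  sphere <- nucleosome_shape("sphere")
  ms <- voxelize(origin_pose(), sphere, dipoles_per_longest = 11)
  expect_equal(ms$spacing, 1)
  expect_equal(n_dipoles(ms), brute_force_count(ms, origin_pose(), sphere))
  cyl <- nucleosome_shape("cylinder")
  mc <- voxelize(origin_pose(), cyl, dipoles_per_longest = 22)
  expect_equal(mc$spacing, 0.5)
  expect_equal(n_dipoles(mc), brute_force_count(mc, origin_pose(), cyl))
  # continuum volume agreement at moderate resolution: pi/6 d^3 and
  # pi r^2 h to within 5%
  ms16 <- voxelize(origin_pose(), sphere, dipoles_per_longest = 16)
  expect_lt(abs(n_dipoles(ms16) * ms16$spacing^3 / (pi / 6 * 11^3) - 1), 0.05)
  expect_lt(abs(n_dipoles(mc) * mc$spacing^3 / (pi * 5.5^2 * 5.5) - 1), 0.05)
})

test_that("lattice constant is the longest extent over dipoles_per_longest", {
  m60 <- voxelize(solenoid_spec(), dipoles_per_longest = 60)
  # independent closed form for the default one-turn solenoid: the widest
  # axis-aligned span is set by the nucleosomes at azimuth 60/120 (240/300)
  # degrees, center offset R sin(60) plus the tilted-cylinder half width
  # h/2 |a_y| + D/2 sqrt(1 - a_y^2) with a_y = sin(60)
  ay <- sin(pi / 3)
  extent <- 2 * (10 * ay + 5.5 / 2 * ay + 11 / 2 * sqrt(1 - ay^2))
  expect_equal(m60$spacing, extent / 60, tolerance = 1e-12)
})

test_that("voxel volume converges as resolution doubles", {
  v <- vapply(c(16, 32), function(dpl) {
    m <- voxelize(solenoid_spec(), dipoles_per_longest = dpl)
    n_dipoles(m) * m$spacing^3
  }, numeric(1))
  expect_lt(abs(v[2] / v[1] - 1), 0.1)
})

test_that("voxelize is deterministic and validates input", {
  a <- voxelize(solenoid_spec(), dipoles_per_longest = 12)
  b <- voxelize(solenoid_spec(), dipoles_per_longest = 12)
  expect_identical(a$sites, b$sites)
  expect_identical(a$origin, b$origin)
  expect_error(voxelize(origin_pose(), nucleosome_shape(),
                        dipoles_per_longest = 2), ">= 4")
  # solids much thinner than one lattice cell capture no site centers
  tiny <- solenoid_spec(shape = nucleosome_shape("sphere", diameter = 0.5))
  expect_error(voxelize(tiny, dipoles_per_longest = 4), "thinner")
  expect_error(solenoid_spec(radius = -1), "radius")
  expect_error(solenoid_spec(pitch = NaN))
  expect_error(nucleosome_shape(diameter = 0), "positive")
})

test_that("zero-pitch radial model voxelizes mirror-symmetrically", {
  m <- voxelize(solenoid_spec(pitch = 0), dipoles_per_longest = 16)
  pos <- dipole_positions(m)
  key <- function(p) {
    p <- round(p, 9)
    p[order(p[, 1], p[, 2], p[, 3]), ]
  }
  flip <- function(p, ax) { p[, ax] <- -p[, ax]; p }
  expect_equal(key(flip(pos, 2L)), key(pos))   # y -> -y
  expect_equal(key(flip(pos, 3L)), key(pos))   # z -> -z
})

test_that("mirror_model reflects physical positions exactly", {
  m <- dipole_model(0.5, c(0.1, 0.25, -0.3),
                    rbind(c(0L, 4L, 1L), c(2L, -1L, 3L)))
  mm <- mirror_model(m, "xz")
  expect_identical(dipole_positions(mm)[, 2], -dipole_positions(m)[, 2])
  expect_identical(dipole_positions(mm)[, c(1, 3)],
                   dipole_positions(m)[, c(1, 3)])
  expect_identical(mirror_model(mm, "xz")$sites, m$sites)
  expect_identical(mirror_model(mm, "xz")$origin, m$origin)
  mxy <- mirror_model(m, "xy")
  expect_identical(dipole_positions(mxy)[, 3], -dipole_positions(m)[, 3])
  # single site at y = +2 lands at y = -2
  one <- dipole_model(1, c(0, 0, 0), matrix(c(0L, 2L, 0L), 1))
  expect_identical(dipole_positions(mirror_model(one, "xz"))[, 2], -2)
})

test_that("orientation modes and tilt orient the nucleosome axis as named", {
  pr <- nucleosome_poses(solenoid_spec(pitch = 0))
  # radial mode at zero pitch: axis is the outward radial direction
  expect_equal(c(pr$ax[1], pr$ay[1], pr$az[1]), c(1, 0, 0))
  pt <- nucleosome_poses(solenoid_spec(pitch = 0,
                                       orientation_mode = "tangential"))
  expect_equal(abs(pt$ax * pr$ax + pt$ay * pr$ay + pt$az * pr$az),
               rep(0, 6L), tolerance = 1e-12)
  pa <- nucleosome_poses(solenoid_spec(orientation_mode = "axial"))
  expect_equal(pa$az, rep(1, 6L))
  # tilt = 90 deg about the reference takes the radial axis into the
  # tangent-orthogonal complement
  ptl <- nucleosome_poses(solenoid_spec(pitch = 0, tilt = pi / 2))
  expect_equal(abs(ptl$ax * pr$ax + ptl$ay * pr$ay + ptl$az * pr$az),
               rep(0, 6L), tolerance = 1e-12)
})
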