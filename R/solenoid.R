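#' Solenoid fiber specification
#'
#' The chiral parameter set of a chromatin solenoid: a one-start helical array
#' of nucleosomes. Defaults reproduce the canonical 30 nm fiber model: helix
#' radius 10 nm, pitch 11 nm per turn, right-handed, one turn of six
#' cylindrical nucleosomes (11 nm diameter x 5.5 nm height).
#'
#' @param radius Helix radius R in nm (distance of nucleosome centers from the
#'   fiber axis). `radius = 0` degenerates to a linear chain.
#' @param pitch Axial rise P per turn in nm. `pitch = 0` degenerates to a
#'   planar ring (achiral).
#' @param handedness `"right"` or `"left"`. Mirror reflection through the xz
#'   plane exchanges the two.
#' @param turns Number of helical turns (positive integer).
#' @param nucleosomes_per_turn Nucleosomes per turn (default 6).
#' @param phase0 Azimuth of nucleosome 0, radians.
#' @param orientation_mode How the nucleosome symmetry axis is oriented:
#'   `"radial"` (default; the cylinder axis points along the local outward
#'   radial direction, so the planar faces contain the helical tangent and
#'   their normal is perpendicular to the helix axis), `"tangential"` (axis
#'   along the local tangent) or `"axial"` (axis along the helix axis).
#' @param tilt Extra rotation of the nucleosome axis about the local reference
#'   direction, radians (default 0). Exposes the orientation degree of freedom
#'   between the named modes.
#' @param shape A [nucleosome_shape()].
#' @param rotating_frame_at_r0 Logical; when `radius = 0` the default
#'   (`FALSE`) gives all nucleosomes an identical frame (axis along +x), which
#'   makes the chain genuinely achiral. Set `TRUE` to keep the
#'   azimuth-rotating frames of the helical parameterization (a screw-chiral
#'   stack).
#'
#' @return An object of class `solenoid_spec`.
#' @examples
#' solenoid_spec()
#' solenoid_spec(pitch = 0)           # planar ring
#' solenoid_spec(radius = 0)          # linear chain of nucleosomes
#' @export
solenoid_spec <- function(radius = 10,
                          pitch = 11,
                          handedness = c("right", "left"),
                          turns = 1L,
                          nucleosomes_per_turn = 6L,
                          phase0 = 0,
                          orientation_mode = c("radial", "tangential", "axial"),
                          tilt = 0,
                          shape = nucleosome_shape(),
                          rotating_frame_at_r0 = FALSE) {
  handedness <- match.arg(handedness)
  orientation_mode <- match.arg(orientation_mode)
  for (v in list(radius = radius, pitch = pitch, phase0 = phase0, tilt = tilt)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  }
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (pitch < 0) stop("pitch must be >= 0", call. = FALSE)
  turns <- as.integer(turns)
  nucleosomes_per_turn <- as.integer(nucleosomes_per_turn)
  if (is.na(turns) || turns < 1L) stop("turns must be >= 1", call. = FALSE)
  if (is.na(nucleosomes_per_turn) || nucleosomes_per_turn < 1L) {
    stop("nucleosomes_per_turn must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(shape, "nucleosome_shape"))
  structure(
    list(radius = radius, pitch = pitch, handedness = handedness,
         turns = turns, nucleosomes_per_turn = nucleosomes_per_turn,
         phase0 = phase0, orientation_mode = orientation_mode, tilt = tilt,
         shape = shape, rotating_frame_at_r0 = isTRUE(rotating_frame_at_r0)),
    class = "solenoid_spec"
  )
}

#' @export
print.solenoid_spec <- function(x, ...) {
  cat(sprintf(
    "<solenoid_spec> R = %g nm, P = %g nm, %s-handed, %d turn(s), %d/turn, %s\n",
    x$radius, x$pitch, x$handedness, x$turns, x$nucleosomes_per_turn,
    x$orientation_mode))
  print(x$shape)
  invisible(x)
}

flip_handedness <- function(spec) {
  spec$handedness <- if (spec$handedness == "right") "left" else "right"
  spec
}

# Rodrigues rotation of row-vectors `v` (n x 3) about unit axis `u` by `ang`.
rotate_about <- function(v, u, ang) {
  c1 <- cos(ang); s1 <- sin(ang)
  dotp <- drop(v %*% u)
  cross <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
                 u[3] * v[, 1] - u[1] * v[, 3],
                 u[1] * v[, 2] - u[2] * v[, 1])
  v * c1 + cross * s1 + outer(dotp * (1 - c1), u)
}

#' Nucleosome poses of a solenoid
#'
#' Places the `turns * nucleosomes_per_turn` nucleosomes of a solenoid on the
#' helical trajectory. Nucleosome k (k = 0, 1, ...) sits at azimuth
#' `phase0 + 2*pi*k/n` and height `pitch * k / n`; its center is at distance
#' `radius` from the helix (z) axis. Right- and left-handed specs give pose
#' sets that are exact mirror images through the xz plane.
#'
#' @param spec A [solenoid_spec()].
#' @return A tibble with one row per nucleosome: center `cx, cy, cz` (nm),
#'   unit symmetry axis `ax, ay, az`, and a unit reference direction
#'   `rx, ry, rz` orthogonal to the axis (the tangent direction for the
#'   default radial mode).
#' @examples
#' nucleosome_poses(solenoid_spec())
#' @export
nucleosome_poses <- function(spec) {
  stopifnot(inherits(spec, "solenoid_spec"))
  n <- spec$nucleosomes_per_turn
  N <- spec$turns * n
  k <- seq_len(N) - 1L
  h <- if (spec$handedness == "right") 1 else -1
  phi <- spec$phase0 + 2 * pi * k / n
  cphi <- cos(phi); sphi <- sin(phi)
  centers <- cbind(spec$radius * cphi, h * spec$radius * sphi,
                   spec$pitch * k / n)

  radial <- cbind(cphi, h * sphi, rep(0, N))
  # tangent of (R cos t, h R sin t, P t / (2 pi)) wrt t, normalized; at R = 0
  # it degenerates to +z.
  tx <- -spec$radius * sphi
  ty <- h * spec$radius * cphi
  tz <- rep(spec$pitch / (2 * pi), N)
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  tangent <- if (all(tn > 0)) cbind(tx, ty, tz) / tn else
    cbind(rep(0, N), rep(0, N), rep(1, N))
  axial <- cbind(rep(0, N), rep(0, N), rep(1, N))

  if (spec$radius == 0 && !spec$rotating_frame_at_r0) {
    # identical frames: a genuinely achiral stack of nucleosomes
    radial <- cbind(rep(1, N), rep(0, N), rep(0, N))
    tangent <- axial
  }

  or <- switch(spec$orientation_mode,
    radial = list(axis = radial, ref = tangent_perp(tangent, radial)),
    tangential = list(axis = tangent, ref = tangent_perp(radial, tangent)),
    axial = list(axis = axial, ref = radial)
  )
  axis <- or$axis; ref <- or$ref
  if (spec$tilt != 0) {
    axis <- t(vapply(seq_len(N), function(i) {
      drop(rotate_about(axis[i, , drop = FALSE], ref[i, ], spec$tilt))
    }, numeric(3)))
  }
  tibble::tibble(
    nucleosome = k,
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    ax = axis[, 1], ay = axis[, 2], az = axis[, 3],
    rx = ref[, 1], ry = ref[, 2], rz = ref[, 3]
  )
}

# Component of `v` orthogonal to unit rows `axis`, renormalized. Falls back to
# any perpendicular when v is (numerically) parallel to axis.
tangent_perp <- function(v, axis) {
  dotp <- rowSums(v * axis)
  w <- v - axis * dotp
  nrm <- sqrt(rowSums(w * w))
  bad <- nrm < 1e-12
  if (any(bad)) {
    for (i in which(bad)) {
      a <- axis[i, ]
      cand <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w[i, ] <- cand - a * sum(cand * a)
      nrm[i] <- sqrt(sum(w[i, ]^2))
    }
  }
  w / nrm
}

#' Intrinsic z-y-z Euler rotation matrix
#'
#' `R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`. The identity at
#' `(0, 0, 0)`; applied to a particle whose helix axis is +z while the
#' laboratory incidence stays fixed along +z, `(0, 0, 0)` means illumination
#' along the helix axis.
#'
#' @param alpha,beta,gamma Euler angles in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rigidly rotate nucleosome poses
#'
#' Applies the intrinsic z-y-z Euler rotation [euler_rotation()] to all
#' centers, axes and reference directions.
#'
#' @param poses A pose tibble from [nucleosome_poses()].
#' @param alpha,beta,gamma Euler angles in radians.
#' @return The rotated pose tibble.
#' @export
rotate_poses <- function(poses, alpha = 0, beta = 0, gamma = 0) {
  R <- euler_rotation(alpha, beta, gamma)
  rot <- function(m) t(R %*% t(m))
  ctr <- rot(as.matrix(poses[, c("cx", "cy", "cz")]))
  ax <- rot(as.matrix(poses[, c("ax", "ay", "az")]))
  rf <- rot(as.matrix(poses[, c("rx", "ry", "rz")]))
  poses$cx <- ctr[, 1]; poses$cy <- ctr[, 2]; poses$cz <- ctr[, 3]
  poses$ax <- ax[, 1]; poses$ay <- ax[, 2]; poses$az <- ax[, 3]
  poses$rx <- rf[, 1]; poses$ry <- rf[, 2]; poses$rz <- rf[, 3]
  poses
}

#' Stack a turn of opposite handedness on top of a one-turn solenoid
#'
#' Builds the two-turn composite of one right-handed and one left-handed turn:
#' segment 2 is the exact mirror image of segment 1 through the horizontal
#' plane lying midway between the last nucleosome of turn 1 and the first
#' nucleosome of turn 2 (segment 2's axial offset is exactly one pitch, so the
#' per-nucleosome rise continues uninterrupted across the junction). The
#' composite pose set is exactly mirror-symmetric through that plane, hence
#' achiral; equivalently, segment 2 is the handedness-flipped spec with
#' azimuth offset `2*pi/n - 2*phase0`.
#'
#' @param spec A one-turn [solenoid_spec()].
#' @return An object of class `composite_model` with elements `segments`
#'   (list of per-segment metadata), `poses` (pose tibble with a `segment`
#'   column), `shape`, and `mirror_plane_z` (nm).
#' @export
stack_opposite_handed <- function(spec) {
  stopifnot(inherits(spec, "solenoid_spec"))
  if (spec$turns != 1L) {
    stop("stack_opposite_handed() requires a one-turn spec", call. = FALSE)
  }
  p0 <- nucleosome_poses(spec)
  n <- spec$nucleosomes_per_turn
  # mirror plane midway between the top pose (z = P(n-1)/n) and z = P
  zm <- spec$pitch * (2 * n - 1) / (2 * n)
  p1 <- p0
  p1$cz <- 2 * zm - p0$cz
  p1$az <- -p0$az
  p1$rz <- -p0$rz
  p1$nucleosome <- p1$nucleosome + n
  poses <- dplyr::bind_rows(
    dplyr::mutate(p0, segment = 1L, .before = 1L),
    dplyr::mutate(p1, segment = 2L, .before = 1L)
  )
  structure(
    list(
      segments = list(
        list(spec = spec, axial_offset = 0, azimuth_offset = 0),
        list(spec = flip_handedness(spec), axial_offset = spec$pitch,
             azimuth_offset = 2 * pi / n - 2 * spec$phase0)
      ),
      poses = poses,
      shape = spec$shape,
      mirror_plane_z = zm
    ),
    class = "composite_model"
  )
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model> %d segments, %d poses, mirror plane z = %g nm\n",
              length(x$segments), nrow(x$poses), x$mirror_plane_z))
  invisible(x)
}
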