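#' CIDS profile from a Mueller matrix
#'
#' Circular intensity differential scattering:
#' `CIDS(theta) = (IL - IR) / (IL + IR) = m14(theta) / m11(theta)` under the
#' package's circular-polarization convention (left circular is
#' `(1, +1i)/sqrt(2)`, Stokes V = +1), since the scattered total intensity for
#' circular incidence is `m11 + V * m14`.
#'
#' @param M A `mueller_angular` tibble ([mueller_from_amplitudes()]).
#' @return A tibble of class `cids_profile`: `theta_deg`, `cids`.
#' @export
cids_from_mueller <- function(M) {
  stopifnot(is.data.frame(M), all(c("theta_deg", "m11", "m14") %in% names(M)))
  if (any(M$m11 <= 0)) {
    stop("m11 must be positive on the whole angle grid", call. = FALSE)
  }
  out <- tibble::tibble(theta_deg = M$theta_deg, cids = M$m14 / M$m11)
  class(out) <- c("cids_profile", class(out))
  out
}

#' CIDS from two intensity profiles
#'
#' The defining ratio `(IL - IR) / (IL + IR)` from scattered intensities under
#' left- and right-circular illumination on a shared angle grid.
#'
#' @param theta_deg Scattering angles (degrees).
#' @param IL,IR Non-negative intensity profiles.
#' @return A tibble of class `cids_profile`: `theta_deg`, `cids`, `IL`, `IR`.
#' @export
cids_direct <- function(theta_deg, IL, IR) {
  stopifnot(length(IL) == length(theta_deg), length(IR) == length(theta_deg))
  if (any(IL < 0) || any(IR < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  tot <- IL + IR
  if (any(tot == 0)) {
    stop("IL + IR = 0: CIDS undefined at some angles", call. = FALSE)
  }
  out <- tibble::tibble(theta_deg = theta_deg, cids = (IL - IR) / tot,
                        IL = IL, IR = IR)
  class(out) <- c("cids_profile", class(out))
  out
}

#' Total scattered intensity profile
#'
#' The unpolarized-light observable: `m11(theta)`. Identical for
#' opposite-handed fibers (reflection leaves it unchanged) while CIDS flips
#' sign.
#'
#' @param M A `mueller_angular` tibble.
#' @return A tibble: `theta_deg`, `intensity`.
#' @export
total_intensity <- function(M) {
  stopifnot(is.data.frame(M), all(c("theta_deg", "m11") %in% names(M)))
  tibble::tibble(theta_deg = M$theta_deg, intensity = M$m11)
}

#' Euler-angle quadrature for orientation averaging
#'
#' Product rule over the rotation group with the uniform (Haar) weight:
#' uniform grid in alpha over [0, 2 pi), Gauss-Legendre nodes in cos(beta)
#' over [-1, 1], uniform grid in gamma over [0, 2 pi); weights are positive
#' and sum to one. Even `n_alpha` (with Gauss-Legendre beta) closes the node
#' set under the reflection-conjugation that maps an orientation to its
#' mirror image, which is what makes the orientation-averaged CIDS of an
#' achiral particle cancel exactly; even `n_gamma` keeps the set closed under
#' `gamma -> gamma + pi`.
#'
#' @param n_alpha,n_beta,n_gamma Node counts (>= 1).
#' @return A tibble: `alpha`, `beta`, `gamma` (radians), `weight`.
#' @examples
#' q <- make_quadrature(4, 4, 2)
#' sum(q$weight)
#' @export
make_quadrature <- function(n_alpha, n_beta, n_gamma) {
  stopifnot(n_alpha >= 1, n_beta >= 1, n_gamma >= 1)
  alpha <- 2 * pi * (seq_len(n_alpha) - 1L) / n_alpha
  gamma <- 2 * pi * (seq_len(n_gamma) - 1L) / n_gamma
  if (n_beta == 1L) {
    beta <- pi / 2
    wb <- 1
  } else {
    gl <- pracma::gaussLegendre(n_beta, -1, 1)
    beta <- acos(gl$x)
    wb <- gl$w / 2
  }
  grid <- expand.grid(alpha = alpha, beta = beta, gamma = gamma,
                      KEEP.OUT.ATTRS = FALSE)
  wbeta <- rep(rep(wb, each = n_alpha), times = n_gamma)
  tibble::tibble(alpha = grid$alpha, beta = grid$beta, gamma = grid$gamma,
                 weight = wbeta / (n_alpha * n_gamma))
}

#' Orientation-averaged Mueller matrix
#'
#' Averages the angle-resolved Mueller matrix over particle orientations
#' drawn from an Euler-angle quadrature, for a fixed laboratory incidence and
#' scattering plane. Implementation detail: instead of re-voxelizing a
#' rotated particle, the laboratory frame (incidence direction, polarization
#' basis, scattering directions) is rotated into the particle frame by the
#' inverse rotation — physically identical, and it reuses one voxelization
#' and one factorized interaction operator for every node. Averaged CIDS
#' should then be formed from the averaged elements
#' ([cids_from_mueller()]), which equals the ratio of ensemble intensities
#' `(<IL> - <IR>) / (<IL> + <IR>)`.
#'
#' @param x A `solenoid_spec`, `composite_model`, pose tibble, or
#'   [dipole_model()].
#' @param wave Laboratory [plane_wave()] (its Jones vector is ignored; both
#'   basis states are solved).
#' @param quadrature A tibble from [make_quadrature()].
#' @param dipoles_per_longest Discretization used when `x` is not already a
#'   dipole model.
#' @param theta_deg Scattering-angle grid; the customary averaged range is
#'   0-180 degrees.
#' @param solver `"auto"` (dense multi-right-hand-side factorization for
#'   small systems, Krylov + FFT otherwise), `"dense"` or `"bicgstab"`.
#' @param tol Krylov stopping tolerance.
#' @param s_mode LDR direction-factor mode; the default `"iso"` (S = 1/5,
#'   the isotropic average) keeps the coupling matrix identical across
#'   orientation nodes so it can be factorized once.
#' @param shape Nucleosome shape when `x` is a bare pose tibble.
#' @param rel_index,host_index Optical constants for voxelization.
#' @return An averaged `mueller_angular` tibble.
#' @export
orientation_average <- function(x, wave = plane_wave(),
                                quadrature = make_quadrature(8, 8, 4),
                                dipoles_per_longest = 16L,
                                theta_deg = 0:180,
                                solver = c("auto", "dense", "bicgstab"),
                                tol = 1e-6, s_mode = "iso",
                                shape = nucleosome_shape(),
                                rel_index = 1.68 / 1.33, host_index = 1.33) {
  solver <- match.arg(solver)
  model <- if (inherits(x, "dipole_model")) x else
    voxelize(x, shape = shape, dipoles_per_longest = dipoles_per_longest,
             rel_index = rel_index, host_index = host_index)
  stopifnot(is.data.frame(quadrature),
            all(c("alpha", "beta", "gamma", "weight") %in% names(quadrature)))
  if (any(quadrature$weight <= 0)) {
    stop("quadrature weights must be positive", call. = FALSE)
  }
  if (abs(sum(quadrature$weight) - 1) > 1e-10) {
    stop("quadrature weights must sum to 1", call. = FALSE)
  }
  n <- n_dipoles(model)
  if (solver == "auto") solver <- if (3L * n <= 4200L) "dense" else "bicgstab"
  k <- k_medium(wave)
  nodes <- nrow(quadrature)

  node_waves <- lapply(seq_len(nodes), function(i) {
    Qt <- t(euler_rotation(quadrature$alpha[i], quadrature$beta[i],
                           quadrature$gamma[i]))
    dirp <- drop(Qt %*% wave$direction)
    dirp <- dirp / sqrt(sum(dirp^2))
    b <- list(e1 = drop(Qt %*% wave$e1), e2 = drop(Qt %*% wave$e2))
    list(
      plane_wave(wave$lambda_vac, wave$host_index, dirp, c(1, 0), basis = b),
      plane_wave(wave$lambda_vac, wave$host_index, dirp, c(0, 1), basis = b)
    )
  })

  acc <- NULL
  if (solver == "dense") {
    if (!identical(s_mode, "iso") && nodes > 1L) {
      stop("dense multi-node path requires the shared s_mode = \"iso\" polarizability",
           call. = FALSE)
    }
    alpha <- model_alpha(model, wave, "ldr", "iso")
    Eall <- matrix(0i, 3L * n, 2L * nodes)
    for (i in seq_len(nodes)) {
      Eall[, 2L * i - 1L] <- flatten_blocks(incident_field(model, node_waves[[i]][[1]]))
      Eall[, 2L * i] <- flatten_blocks(incident_field(model, node_waves[[i]][[2]]))
    }
    X <- solve_dense_multi(model, k, alpha, Eall)
    for (i in seq_len(nodes)) {
      sols <- list(
        new_dipole_solution(unflatten_blocks(X[, 2L * i - 1L]),
                            NULL, alpha, node_waves[[i]][[1]], 0, 1L, "dense", TRUE),
        new_dipole_solution(unflatten_blocks(X[, 2L * i]),
                            NULL, alpha, node_waves[[i]][[2]], 0, 1L, "dense", TRUE)
      )
      amps <- amplitude_set(model, node_waves[[i]], sols, theta_deg)
      Mi <- as.matrix(mueller_from_amplitudes(amps)[, -1L])
      acc <- if (is.null(acc)) quadrature$weight[i] * Mi else
        acc + quadrature$weight[i] * Mi
    }
  } else {
    kernel <- interaction_kernel(model, k)
    for (i in seq_len(nodes)) {
      sols <- lapply(node_waves[[i]], function(w) {
        tryCatch(
          solve_dipoles(model, w, tol = tol, method = "bicgstab",
                        s_mode = s_mode, kernel = kernel),
          error = function(e) stop(sprintf(
            "orientation node %d (alpha=%.3f, beta=%.3f, gamma=%.3f): %s",
            i, quadrature$alpha[i], quadrature$beta[i], quadrature$gamma[i],
            conditionMessage(e)), call. = FALSE)
        )
      })
      amps <- amplitude_set(model, node_waves[[i]], sols, theta_deg)
      Mi <- as.matrix(mueller_from_amplitudes(amps)[, -1L])
      acc <- if (is.null(acc)) quadrature$weight[i] * Mi else
        acc + quadrature$weight[i] * Mi
    }
  }
  out <- tibble::as_tibble(acc)
  out <- tibble::add_column(out, theta_deg = theta_deg, .before = 1L)
  class(out) <- c("mueller_angular", class(out))
  out
}
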