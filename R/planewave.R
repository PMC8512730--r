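#' Incident plane wave
#'
#' Monochromatic plane wave in the host medium. The polarization is a Jones
#' vector in the transverse basis `(e1, e2)`; for propagation along +z the
#' default basis is `e1 = x` (parallel to the fixed xz scattering plane) and
#' `e2 = y`. The derived medium wavenumber is `k = 2 pi host_index /
#' lambda_vac`. Time convention `exp(-i omega t)`; left-circular polarization
#' is `(1, +1i)/sqrt(2)` (Stokes V = +1).
#'
#' @param lambda_vac Vacuum wavelength in nm (default 300).
#' @param host_index Refractive index of the host medium (default 1.33,
#'   water).
#' @param direction Unit propagation direction (default +z).
#' @param jones Complex length-2 Jones vector (normalized internally), or one
#'   of the shorthand strings `"x"`, `"y"`, `"L"`, `"R"`.
#' @param basis Optional list with unit 3-vectors `e1`, `e2` orthogonal to
#'   `direction`; chosen automatically when `NULL`.
#' @return An object of class `plane_wave`.
#' @examples
#' plane_wave()                   # 300 nm in water, x-polarized, along +z
#' plane_wave(jones = "L")        # left-circular
#' @export
plane_wave <- function(lambda_vac = 300, host_index = 1.33,
                       direction = c(0, 0, 1), jones = "x", basis = NULL) {
  stopifnot(is.numeric(lambda_vac), length(lambda_vac) == 1L, lambda_vac > 0,
            is.numeric(host_index), length(host_index) == 1L, host_index > 0,
            is.numeric(direction), length(direction) == 3L)
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-8) stop("direction must be a unit vector", call. = FALSE)
  direction <- direction / nd
  jones <- jones_vector(jones)
  if (is.null(basis)) basis <- transverse_basis(direction)
  e1 <- basis$e1 / sqrt(sum(Mod(basis$e1)^2))
  e2 <- basis$e2 / sqrt(sum(Mod(basis$e2)^2))
  if (abs(sum(e1 * direction)) > 1e-8 || abs(sum(e2 * direction)) > 1e-8) {
    stop("basis vectors must be orthogonal to direction", call. = FALSE)
  }
  structure(
    list(lambda_vac = lambda_vac, host_index = host_index,
         direction = direction, jones = jones, e1 = e1, e2 = e2),
    class = "plane_wave"
  )
}

#' @export
print.plane_wave <- function(x, ...) {
  cat(sprintf(
    "<plane_wave> lambda = %g nm (vacuum), host n = %g, k = %.5g 1/nm\n",
    x$lambda_vac, x$host_index, k_medium(x)))
  invisible(x)
}

jones_vector <- function(jones) {
  if (is.character(jones)) {
    jones <- switch(match.arg(jones, c("x", "y", "L", "R")),
      x = c(1 + 0i, 0i),
      y = c(0i, 1 + 0i),
      L = c(1 + 0i, 1i) / sqrt(2),
      R = c(1 + 0i, -1i) / sqrt(2)
    )
  }
  jones <- as.complex(jones)
  stopifnot(length(jones) == 2L, all(is.finite(Mod(jones))))
  nrm <- sqrt(sum(Mod(jones)^2))
  if (nrm == 0) stop("jones vector must be non-zero", call. = FALSE)
  jones / nrm
}

transverse_basis <- function(direction) {
  zxd <- c(-direction[2], direction[1], 0)    # z cross d
  if (sqrt(sum(zxd^2)) < 1e-12) {
    return(list(e1 = c(1, 0, 0), e2 = c(0, 1, 0) * sign(direction[3])^0))
  }
  e2 <- zxd / sqrt(sum(zxd^2))
  e1 <- c(e2[2] * direction[3] - e2[3] * direction[2],
          e2[3] * direction[1] - e2[1] * direction[3],
          e2[1] * direction[2] - e2[2] * direction[1])
  list(e1 = e1, e2 = e2)
}

#' Medium wavenumber of a plane wave
#'
#' @param wave A [plane_wave()].
#' @return `2 * pi * host_index / lambda_vac`, in 1/nm.
#' @export
k_medium <- function(wave) 2 * pi * wave$host_index / wave$lambda_vac

# Incident field at the dipole positions: N x 3 complex matrix.
incident_field <- function(model, wave) {
  r <- dipole_positions(model)
  k <- k_medium(wave)
  phase <- exp(1i * k * drop(r %*% wave$direction))
  pol <- wave$jones[1] * wave$e1 + wave$jones[2] * wave$e2
  outer(phase, pol)
}
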