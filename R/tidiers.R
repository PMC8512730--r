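#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dipole model into a site table
#'
#' @param x A [dipole_model()].
#' @param ... Unused.
#' @return A tibble: lattice indices `i, j, k` and physical positions
#'   `x_nm, y_nm, z_nm`.
#' @export
tidy.dipole_model <- function(x, ...) {
  pos <- dipole_positions(x)
  tibble::tibble(i = x$sites[, 1], j = x$sites[, 2], k = x$sites[, 3],
                 x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3])
}

#' One-row summary of a dipole model
#'
#' @param x A [dipole_model()].
#' @param ... Unused.
#' @return A tibble: `n_dipoles`, `spacing_nm`, `a_eff_nm`, `rel_index`,
#'   `host_index`.
#' @export
glance.dipole_model <- function(x, ...) {
  tibble::tibble(n_dipoles = n_dipoles(x), spacing_nm = x$spacing,
                 a_eff_nm = a_effective(x),
                 rel_index = x$rel_index[1], host_index = x$host_index)
}

#' One-row summary of a coupled-dipole solution
#'
#' @param x A `dipole_solution`.
#' @param ... Unused.
#' @return A tibble: `n_dipoles`, `method`, `residual`, `iterations`,
#'   `converged`.
#' @export
glance.dipole_solution <- function(x, ...) {
  tibble::tibble(n_dipoles = nrow(x$P), method = x$method,
                 residual = x$residual, iterations = x$iterations,
                 converged = x$converged)
}

#' Tidy an amplitude set
#'
#' @param x An [amplitude_set()].
#' @param ... Unused.
#' @return A long tibble: `theta_deg`, `element` (S1-S4), complex `value`.
#' @export
tidy.amplitude_set <- function(x, ...) {
  tibble::tibble(
    theta_deg = rep(x$theta_deg, 4L),
    element = rep(c("S2", "S3", "S4", "S1"), each = length(x$theta_deg)),
    value = c(x$S[1, 1, ], x$S[1, 2, ], x$S[2, 1, ], x$S[2, 2, ])
  )
}

#' One-row summary of a Mie computation
#'
#' @param x A `mie_result`.
#' @param ... Unused.
#' @return A tibble: `x`, `m`, `Q_ext`, `Q_sca`, `Q_abs`, `n_terms`.
#' @export
glance.mie_result <- function(x, ...) {
  tibble::tibble(x = x$x, m = x$m, Q_ext = x$Q_ext, Q_sca = x$Q_sca,
                 Q_abs = x$Q_abs, n_terms = x$n_terms)
}

#' Tidy a fixed-orientation scattering result
#'
#' @param x A `scatter_result` from [scatter_fixed()].
#' @param ... Unused.
#' @return A tibble: `theta_deg`, `cids`, `m11`, `m14`.
#' @export
tidy.scatter_result <- function(x, ...) {
  tibble::tibble(theta_deg = x$mueller$theta_deg, cids = x$cids$cids,
                 m11 = x$mueller$m11, m14 = x$mueller$m14)
}

#' One-row summary of a fixed-orientation scattering result
#'
#' @param x A `scatter_result`.
#' @param ... Unused.
#' @return A tibble with the cross sections, peak |CIDS| and solver
#'   diagnostics.
#' @export
glance.scatter_result <- function(x, ...) {
  dplyr::bind_cols(
    x$cross_sections,
    tibble::tibble(
      max_abs_cids = max(abs(x$cids$cids)),
      n_dipoles = n_dipoles(x$model),
      residual = max(vapply(x$solutions, function(s) s$residual, 0)),
      mode = x$mode
    )
  )
}
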