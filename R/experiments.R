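sweep_kinds <- c("pitch", "radius", "orientation", "handedness", "rl_stack",
                 "turns", "nucleosome_orientation", "shape", "wavelength")

# rebuild through the constructor so per-value overrides are re-validated
spec_update <- function(spec, ...) {
  args <- list(radius = spec$radius, pitch = spec$pitch,
               handedness = spec$handedness, turns = spec$turns,
               nucleosomes_per_turn = spec$nucleosomes_per_turn,
               phase0 = spec$phase0, orientation_mode = spec$orientation_mode,
               tilt = spec$tilt, shape = spec$shape,
               rotating_frame_at_r0 = spec$rotating_frame_at_r0)
  args[names(list(...))] <- list(...)
  do.call(solenoid_spec, args)
}

spec_for_value <- function(kind, value, base_spec) {
  switch(kind,
    pitch = spec_update(base_spec, pitch = value),
    radius = spec_update(base_spec, radius = value),
    turns = spec_update(base_spec, turns = as.integer(value)),
    handedness = spec_update(base_spec, handedness = value),
    nucleosome_orientation = {
      if (is.numeric(value)) spec_update(base_spec, tilt = value)
      else spec_update(base_spec, orientation_mode = value)
    },
    shape = {
      dia <- base_spec$shape$diameter
      hgt <- base_spec$shape$height
      new_shape <- if (value == "sphere") {
        nucleosome_shape("sphere", diameter = dia)
      } else {
        nucleosome_shape("cylinder", diameter = dia,
                         height = if (is.na(hgt)) 5.5 else hgt)
      }
      spec_update(base_spec, shape = new_shape)
    },
    base_spec
  )
}

value_label <- function(kind, value) {
  if (kind == "orientation") paste(signif(unlist(value), 4), collapse = "/")
  else as.character(value)
}

#' Run a parameter sweep over a chiral degree of freedom
#'
#' Configuration-driven pipeline: for every sweep value, build the solenoid
#' geometry, voxelize, solve both polarization states, and record the CIDS
#' profile, total scattered intensity and efficiencies in one long-form
#' table. Deterministic: identical inputs reproduce the table bit-identically
#' (there is no randomness anywhere in the pipeline).
#'
#' @param sweep_kind One of `"pitch"`, `"radius"`, `"orientation"`,
#'   `"handedness"`, `"rl_stack"`, `"turns"`, `"nucleosome_orientation"`,
#'   `"shape"`, `"wavelength"`.
#' @param values Vector (or, for `"orientation"`, list of `c(alpha, beta,
#'   gamma)` triples) of sweep values. Units: nm for pitch/radius, count for
#'   turns, radians for orientation and numeric nucleosome tilts, nm for
#'   wavelength.
#' @param base_spec Base [solenoid_spec()] modified per value.
#' @param wave Laboratory [plane_wave()].
#' @param mode `"fixed"` (full-circle angle grid) or `"averaged"`
#'   (orientation average on 0-180 degrees).
#' @param dipoles_per_longest Discretization.
#' @param theta_deg Angle grid override; defaults to `0:359` for fixed and
#'   `0:180` for averaged mode.
#' @param quadrature Euler quadrature for averaged mode.
#' @param tol Solver tolerance.
#' @param on_error `"stop"` or `"continue"` (per-value failures are recorded
#'   as `failed = TRUE` rows and the sweep continues).
#' @return A tibble of class `sweep_result`: one row per (value, angle) with
#'   `sweep`, `value`, `value_label`, `theta_deg`, `cids`, `m11`, `Q_ext`,
#'   `Q_abs`, `n_dipoles`, `spacing_nm`, `failed`.
#' @export
run_sweep <- function(sweep_kind, values, base_spec = solenoid_spec(),
                      wave = plane_wave(), mode = c("fixed", "averaged"),
                      dipoles_per_longest = 24L, theta_deg = NULL,
                      quadrature = make_quadrature(6, 6, 2), tol = 1e-5,
                      on_error = c("stop", "continue")) {
  sweep_kind <- match.arg(sweep_kind, sweep_kinds)
  mode <- match.arg(mode)
  on_error <- match.arg(on_error)
  if (length(values) < 1L) stop("values must be non-empty", call. = FALSE)
  if (is.null(theta_deg)) theta_deg <- if (mode == "fixed") 0:359 else 0:180

  run_one <- function(value) {
    wave_v <- if (sweep_kind == "wavelength") {
      plane_wave(value, wave$host_index, wave$direction, wave$jones,
                 basis = list(e1 = wave$e1, e2 = wave$e2))
    } else wave
    target <- if (sweep_kind == "rl_stack") stack_opposite_handed(base_spec)
    else spec_for_value(sweep_kind, value, base_spec)
    orientation <- if (sweep_kind == "orientation") unlist(value) else c(0, 0, 0)
    if (mode == "fixed") {
      res <- scatter_fixed(target, wave_v, theta_deg = theta_deg,
                           orientation = orientation,
                           dipoles_per_longest = dipoles_per_longest,
                           tol = tol)
      M <- res$mueller
      cs <- res$cross_sections
      model <- res$model
    } else {
      model <- voxelize(target, dipoles_per_longest = dipoles_per_longest)
      M <- orientation_average(model, wave_v, quadrature = quadrature,
                               theta_deg = theta_deg, tol = tol)
      # efficiencies at the reference orientation for the metadata columns
      cs <- scatter_fixed(model, wave_v, theta_deg = c(0, 90),
                          tol = tol)$cross_sections
    }
    vlab <- value_label(sweep_kind, value)
    vnum <- if (sweep_kind == "orientation") NA_real_ else
      suppressWarnings(as.numeric(value))
    tibble::tibble(
      sweep = sweep_kind,
      value = vnum,
      value_label = vlab,
      theta_deg = M$theta_deg,
      cids = M$m14 / M$m11,
      m11 = M$m11,
      Q_ext = cs$Q_ext, Q_abs = cs$Q_abs,
      n_dipoles = n_dipoles(model), spacing_nm = model$spacing,
      failed = FALSE
    )
  }

  vals <- if (is.list(values)) values else as.list(values)
  out <- purrr::map(vals, function(v) {
    if (on_error == "stop") return(run_one(v))
    tryCatch(run_one(v), error = function(e) {
      warning(sprintf("sweep value %s failed: %s", value_label(sweep_kind, v),
                      conditionMessage(e)), call. = FALSE)
      tibble::tibble(sweep = sweep_kind, value = NA_real_,
                     value_label = value_label(sweep_kind, v),
                     theta_deg = NA_real_, cids = NA_real_, m11 = NA_real_,
                     Q_ext = NA_real_, Q_abs = NA_real_,
                     n_dipoles = NA_integer_, spacing_nm = NA_real_,
                     failed = TRUE)
    })
  })
  out <- dplyr::bind_rows(out)
  attr(out, "mode") <- mode
  class(out) <- c("sweep_result", class(out))
  out
}

#' Cylinder versus sphere nucleosome contrast
#'
#' Paired runs of the default solenoid with cylindrical and spherical
#' nucleosomes (sphere diameter equal to the cylinder diameter), under the
#' full coupled solve and under the first Born approximation. The Born run on
#' isotropic (spherical or otherwise uniformly polarizable) units is the
#' classic null control: without inter-dipole coupling the CIDS signal
#' vanishes identically.
#'
#' @param base_spec Base [solenoid_spec()] (cylinder shape; the sphere
#'   variant is derived from it).
#' @param wave Laboratory [plane_wave()].
#' @param dipoles_per_longest Discretization.
#' @param theta_deg Angle grid.
#' @param modes Which solver modes to run (`"dda"`, `"born"`).
#' @param tol Solver tolerance.
#' @return A `sweep_result`-style tibble with `shape`, `mode`, `theta_deg`,
#'   `cids`, `m11`, `Q_ext`, `Q_abs` columns.
#' @export
run_shape_contrast <- function(base_spec = solenoid_spec(),
                               wave = plane_wave(),
                               dipoles_per_longest = 24L, theta_deg = 0:359,
                               modes = c("dda", "born"), tol = 1e-5) {
  shapes <- list(
    cylinder = base_spec,
    sphere = spec_for_value("shape", "sphere", base_spec)
  )
  out <- purrr::map(names(shapes), function(sh) {
    model <- voxelize(shapes[[sh]], dipoles_per_longest = dipoles_per_longest)
    purrr::map(modes, function(md) {
      res <- scatter_fixed(model, wave, theta_deg = theta_deg, mode = md,
                           tol = tol)
      tibble::tibble(shape = sh, mode = md, theta_deg = res$cids$theta_deg,
                     cids = res$cids$cids, m11 = res$mueller$m11,
                     Q_ext = res$cross_sections$Q_ext,
                     Q_abs = res$cross_sections$Q_abs,
                     n_dipoles = n_dipoles(model))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(out) <- c("sweep_result", class(out))
  out
}

#' Extinction and absorption versus wavelength
#'
#' `Q_ext(lambda)` and `Q_abs(lambda)` of the solenoid at fixed orientation
#' (illumination along the helix axis), optionally for several pitch values.
#' With the purely real refractive-index contrast used here the absorption
#' efficiency is zero to round-off at every wavelength: all extinction is
#' scattering.
#'
#' @param lambda_nm Vacuum wavelengths (default 250-750 nm in 50 nm steps).
#' @param pitches Pitch values (nm) to run; default just the base spec's.
#' @param base_spec Base [solenoid_spec()].
#' @param host_index Host refractive index.
#' @param dipoles_per_longest Discretization.
#' @param tol Solver tolerance.
#' @return A tibble: `lambda_nm`, `pitch_nm`, `Q_ext`, `Q_abs`, `Q_sca`,
#'   `a_eff`.
#' @export
run_wavelength_scan <- function(lambda_nm = seq(250, 750, by = 50),
                                pitches = NULL,
                                base_spec = solenoid_spec(),
                                host_index = 1.33,
                                dipoles_per_longest = 24L, tol = 1e-5) {
  if (is.null(pitches)) pitches <- base_spec$pitch
  grid <- expand.grid(lambda_nm = lambda_nm, pitch_nm = pitches,
                      KEEP.OUT.ATTRS = FALSE)
  purrr::pmap(grid, function(lambda_nm, pitch_nm) {
    spec <- base_spec
    spec$pitch <- pitch_nm
    model <- voxelize(spec, dipoles_per_longest = dipoles_per_longest,
                      host_index = host_index)
    wave <- plane_wave(lambda_nm, host_index)
    cs <- scatter_fixed(model, wave, theta_deg = c(0, 90), tol = tol)$cross_sections
    tibble::tibble(lambda_nm = lambda_nm, pitch_nm = pitch_nm,
                   Q_ext = cs$Q_ext, Q_abs = cs$Q_abs, Q_sca = cs$Q_sca,
                   a_eff = cs$a_eff)
  }) |> dplyr::bind_rows()
}
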