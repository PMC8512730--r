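#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a CIDS profile
#'
#' @param object A `cids_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cids_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta_deg, y = .data$cids)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(x = "scattering angle θ (deg)", y = "CIDS") +
    ggplot2::theme_minimal()
}

#' Plot Mueller-matrix elements versus scattering angle
#'
#' @param object A `mueller_angular` tibble.
#' @param elements Which elements to draw (default `m11` and `m14`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mueller_angular <- function(object, elements = c("m11", "m14"), ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(elements),
                              names_to = "element", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta_deg, y = .data$value)) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = "scattering angle θ (deg)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' CIDS versus scattering angle, one curve per sweep value (or per
#' shape/mode combination for shape-contrast tables).
#'
#' @param object A `sweep_result` tibble.
#' @param y Column to draw (default `"cids"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, y = "cids", ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      !isTRUE(.data$failed %||% FALSE))
  grp <- if ("value_label" %in% names(df)) "value_label" else "shape"
  if ("mode" %in% names(df) && grp == "shape") {
    df$value_label <- paste(df$shape, df$mode)
    grp <- "value_label"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_deg, y = .data[[y]],
                                   colour = .data[[grp]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "scattering angle θ (deg)", y = y,
                  colour = unique(df$sweep %||% "case")[1]) +
    ggplot2::theme_minimal()
}

#' Plot nucleosome poses
#'
#' Quick-look projection of the continuous model: nucleosome centers in the
#' xy plane (view along the helix axis) and xz plane.
#'
#' @param poses A pose tibble, `solenoid_spec` or `composite_model`.
#' @return A ggplot.
#' @export
plot_poses <- function(poses) {
  if (inherits(poses, "solenoid_spec")) poses <- nucleosome_poses(poses)
  if (inherits(poses, "composite_model")) poses <- poses$poses
  long <- dplyr::bind_rows(
    tibble::tibble(view = "xy (along axis)", h = poses$cx, v = poses$cy),
    tibble::tibble(view = "xz (side)", h = poses$cx, v = poses$cz)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(size = 2, colour = "#2166AC") +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "nm", y = "nm") +
    ggplot2::theme_minimal()
}
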