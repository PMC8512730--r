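#' Nucleosome shape
#'
#' Describes the solid used for a single nucleosome: a cylinder (the default
#' model of the nucleosome core particle, 11 nm diameter x 5.5 nm height) or a
#' sphere (11 nm diameter). All lengths are nanometres.
#'
#' @param kind `"cylinder"` or `"sphere"`.
#' @param diameter Diameter in nm. Defaults to 11 for both kinds.
#' @param height Cylinder height in nm (ignored for spheres). Default 5.5.
#'
#' @return An object of class `nucleosome_shape`.
#' @examples
#' nucleosome_shape()
#' nucleosome_shape("sphere")
#' @export
nucleosome_shape <- function(kind = c("cylinder", "sphere"),
                             diameter = 11,
                             height = 5.5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(diameter), length(diameter) == 1L, is.finite(diameter))
  if (diameter <= 0) stop("nucleosome diameter must be positive", call. = FALSE)
  if (kind == "cylinder") {
    stopifnot(is.numeric(height), length(height) == 1L, is.finite(height))
    if (height <= 0) stop("cylinder height must be positive", call. = FALSE)
  } else {
    height <- NA_real_
  }
  structure(
    list(kind = kind, diameter = diameter, height = height),
    class = "nucleosome_shape"
  )
}

#' @export
print.nucleosome_shape <- function(x, ...) {
  if (x$kind == "cylinder") {
    cat(sprintf("<nucleosome_shape> cylinder %g nm diameter x %g nm height\n",
                x$diameter, x$height))
  } else {
    cat(sprintf("<nucleosome_shape> sphere %g nm diameter\n", x$diameter))
  }
  invisible(x)
}

# Largest extent of the solid along any axis given its symmetry axis `axis`
# (unit vector). For a sphere this is the diameter regardless of axis.
shape_halfwidths <- function(shape, axis) {
  if (shape$kind == "sphere") {
    rep(shape$diameter / 2, 3L)
  } else {
    # axis-aligned half extent of a cylinder with unit axis a:
    # h/2*|a_i| + r*sqrt(1-a_i^2) along lab axis i
    a <- abs(axis)
    a <- pmin(a, 1)
    shape$height / 2 * a + shape$diameter / 2 * sqrt(pmax(0, 1 - a^2))
  }
}

# Vectorized point-membership test: points (n x 3) against one posed solid.
# Boundary points count as inside (closed solids) for determinism.
points_in_solid <- function(points, center, axis, shape) {
  dp <- sweep(points, 2L, center)
  if (shape$kind == "sphere") {
    rowSums(dp * dp) <= (shape$diameter / 2)^2
  } else {
    t_ax <- dp %*% axis            # axial coordinate
    r2 <- rowSums(dp * dp) - t_ax^2
    (abs(t_ax) <= shape$height / 2) & (r2 <= (shape$diameter / 2)^2)
  }
}
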