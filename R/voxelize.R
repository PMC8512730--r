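#' Dipole model constructor
#'
#' A cubic-lattice voxelization of a scatterer: lattice constant `spacing`
#' (nm), physical `origin` of lattice index (0, 0, 0), integer lattice `sites`
#' and the per-site complex refractive index relative to the host medium.
#' Physical position of site (i, j, k) is `origin + spacing * c(i, j, k)`.
#'
#' @param spacing Lattice constant d in nm.
#' @param origin Numeric 3-vector, nm.
#' @param sites Integer matrix (N x 3) of unique lattice index triples.
#' @param rel_index Complex relative refractive index m (scalar, applied to
#'   every site, or length-N vector). Default 1.68/1.33.
#' @param host_index Real refractive index of the host medium (default 1.33).
#' @return An object of class `dipole_model`.
#' @export
dipole_model <- function(spacing, origin, sites, rel_index = 1.68 / 1.33,
                         host_index = 1.33) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0,
            is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  sites <- as.matrix(sites)
  if (ncol(sites) != 3L || nrow(sites) < 1L) {
    stop("sites must be an N x 3 matrix", call. = FALSE)
  }
  storage.mode(sites) <- "integer"
  if (anyDuplicated(sites)) stop("duplicate lattice sites", call. = FALSE)
  rel_index <- as.complex(rel_index)
  if (!length(rel_index) %in% c(1L, nrow(sites))) {
    stop("rel_index must be scalar or one value per site", call. = FALSE)
  }
  if (any(Mod(rel_index - 1) >= 2)) {
    warning("|m - 1| >= 2: outside the accuracy domain of the dipole lattice")
  }
  structure(
    list(spacing = spacing, origin = as.numeric(origin), sites = sites,
         rel_index = rel_index, host_index = as.numeric(host_index)),
    class = "dipole_model"
  )
}

#' @export
print.dipole_model <- function(x, ...) {
  cat(sprintf("<dipole_model> %d dipoles, d = %.4g nm, m = %s, host n = %g\n",
              nrow(x$sites), x$spacing,
              format(x$rel_index[1], digits = 5), x$host_index))
  invisible(x)
}

#' Physical dipole positions
#'
#' @param model A [dipole_model()].
#' @return Numeric N x 3 matrix of positions in nm.
#' @export
dipole_positions <- function(model) {
  sweep(model$sites * model$spacing, 2L, model$origin, "+")
}

#' Number of dipoles
#' @param model A [dipole_model()].
#' @return Integer count of occupied lattice sites.
#' @export
n_dipoles <- function(model) nrow(model$sites)

#' Equal-volume-sphere radius of a dipole model
#'
#' `a_eff = (3 N d^3 / (4 pi))^(1/3)`, the radius of the sphere with the same
#' volume as the N occupied lattice cells; used to normalize efficiencies.
#'
#' @param model A [dipole_model()].
#' @return Effective radius in nm.
#' @export
a_effective <- function(model) {
  (3 * n_dipoles(model) * model$spacing^3 / (4 * pi))^(1 / 3)
}

poses_matrix <- function(poses) {
  list(centers = as.matrix(poses[, c("cx", "cy", "cz")]),
       axes = as.matrix(poses[, c("ax", "ay", "az")]))
}

# Axis-aligned bounding box of the union of posed solids. Per-axis centers
# that are numerically zero are snapped to 0 so that mirror-symmetric
# continuous models get exactly mirror-symmetric lattices.
union_bbox <- function(poses, shape) {
  pm <- poses_matrix(poses)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (i in seq_len(nrow(pm$centers))) {
    hw <- shape_halfwidths(shape, pm$axes[i, ])
    lo <- pmin(lo, pm$centers[i, ] - hw)
    hi <- pmax(hi, pm$centers[i, ] + hw)
  }
  ext <- hi - lo
  ctr <- (hi + lo) / 2
  snap <- abs(ctr) < 1e-9 * pmax(ext, 1)
  ctr[snap] <- 0
  list(lo = ctr - ext / 2, hi = ctr + ext / 2, extent = ext, center = ctr)
}

#' Voxelize posed nucleosomes onto a cubic dipole lattice
#'
#' The lattice constant is `d = max(bounding extent) / dipoles_per_longest`,
#' following the convention of specifying the number of dipoles across the
#' longest dimension of the object. A lattice site is occupied iff its center
#' lies inside at least one nucleosome solid (union semantics; points exactly
#' on a surface count as inside). The lattice is centered on the bounding-box
#' center per axis, so mirror symmetries of the continuous model (y -> -y,
#' z -> -z about the box center) carry over exactly to the site set.
#'
#' @param poses Pose tibble ([nucleosome_poses()]), or a `solenoid_spec`, or a
#'   `composite_model` (its own shape is then used).
#' @param shape A [nucleosome_shape()]; ignored when `poses` carries one.
#' @param dipoles_per_longest Number of lattice cells across the longest
#'   bounding-box extent (>= 4). The canonical production resolution is 60.
#' @param rel_index Complex relative refractive index of every occupied site.
#' @param host_index Host refractive index.
#' @return A [dipole_model()].
#' @examples
#' m <- voxelize(solenoid_spec(), dipoles_per_longest = 16)
#' n_dipoles(m)
#' @export
voxelize <- function(poses, shape = nucleosome_shape(),
                     dipoles_per_longest = 60L,
                     rel_index = 1.68 / 1.33, host_index = 1.33) {
  if (inherits(poses, "solenoid_spec")) {
    shape <- poses$shape
    poses <- nucleosome_poses(poses)
  } else if (inherits(poses, "composite_model")) {
    shape <- poses$shape
    poses <- poses$poses
  }
  stopifnot(is.data.frame(poses), nrow(poses) >= 1L)
  dipoles_per_longest <- as.integer(dipoles_per_longest)
  if (is.na(dipoles_per_longest) || dipoles_per_longest < 4L) {
    stop("dipoles_per_longest must be an integer >= 4", call. = FALSE)
  }
  bb <- union_bbox(poses, shape)
  d <- max(bb$extent) / dipoles_per_longest
  # per-axis symmetric index range about the box center; for exact divisions
  # the extreme centers sit half a cell inside the box faces, so closed-solid
  # boundaries never coincide with lattice centers
  ncell <- pmax(1L, as.integer(ceiling(bb$extent / d - 1e-12)))
  ax_coords <- lapply(1:3, function(a) {
    bb$center[a] + (seq_len(ncell[a]) - 1 - (ncell[a] - 1) / 2) * d
  })
  # thinner than one lattice cell: no center can fall inside
  thin <- which(bb$extent < d)
  grid <- as.matrix(expand.grid(x = ax_coords[[1]], y = ax_coords[[2]],
                                z = ax_coords[[3]], KEEP.OUT.ATTRS = FALSE))
  pm <- poses_matrix(poses)
  occupied <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(pm$centers))) {
    todo <- which(!occupied)
    if (!length(todo)) break
    occupied[todo] <- points_in_solid(grid[todo, , drop = FALSE],
                                      pm$centers[i, ], pm$axes[i, ], shape)
  }
  if (!any(occupied)) {
    dim_names <- c("x", "y", "z")
    off <- if (length(thin)) paste(dim_names[thin], collapse = ", ") else "all"
    stop(sprintf(
      "empty voxelization: model thinner than one lattice cell (d = %.3g nm) along %s",
      d, off), call. = FALSE)
  }
  # integer indices relative to the first lattice node on each axis
  idx <- arrayInd(which(occupied), .dim = ncell)
  origin <- vapply(1:3, function(a) ax_coords[[a]][1], numeric(1))
  dipole_model(spacing = d, origin = origin, sites = idx - 1L,
               rel_index = rel_index, host_index = host_index)
}

#' Mirror a dipole model through a coordinate plane
#'
#' Reflects the physical positions exactly: site (i, j, k) maps to
#' (i, -j, k) for the xz plane (or (i, j, -k) for xy) and the origin is
#' adjusted so positions are exact reflections of the originals. Reflection
#' reverses chirality, so the mirror of a right-handed voxelized solenoid is a
#' left-handed dipole model with bit-identical geometry otherwise.
#'
#' @param model A [dipole_model()].
#' @param plane `"xz"` (y -> -y) or `"xy"` (z -> -z).
#' @return The mirrored [dipole_model()].
#' @export
mirror_model <- function(model, plane = c("xz", "xy")) {
  plane <- match.arg(plane)
  ax <- if (plane == "xz") 2L else 3L
  sites <- model$sites
  sites[, ax] <- -sites[, ax]
  origin <- model$origin
  origin[ax] <- -origin[ax]
  dipole_model(spacing = model$spacing, origin = origin, sites = sites,
               rel_index = model$rel_index, host_index = model$host_index)
}
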