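config_schema <- list(
  geometry = list(
    radius_nm = 10, pitch_nm = 11, handedness = "right", turns = 1L,
    nucleosomes_per_turn = 6L, shape = "cylinder", diameter_nm = 11,
    height_nm = 5.5, orientation_mode = "radial", phase0_rad = 0,
    tilt_rad = 0
  ),
  optics = list(n_particle = 1.68, n_host = 1.33, lambda_vac_nm = 300),
  discretization = list(dipoles_per_longest = 60L),
  observables = list(theta_min_deg = 0, theta_max_deg = 359,
                     theta_step_deg = 1, mode = "fixed"),
  quadrature = list(n_alpha = 8L, n_beta = 8L, n_gamma = 4L)
)

#' Read a run configuration
#'
#' Parses a structured-text (YAML) configuration with blocks `geometry`,
#' `optics`, `discretization`, `observables` and `quadrature`; every key
#' carries its unit in its name (`_nm`, `_rad`, `_deg`). Missing keys are
#' filled with the canonical defaults (pitch 11 nm, radius 10 nm, 6
#' nucleosomes per turn, cylinder 11 x 5.5 nm, n = 1.68 in host 1.33,
#' lambda = 300 nm, 60 dipoles per longest dimension); an empty file yields
#' the full default configuration. Unknown blocks or keys are rejected with
#' their path.
#'
#' @param path Path to the YAML file.
#' @return A list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown_blocks <- setdiff(names(raw), names(config_schema))
  if (length(unknown_blocks)) {
    stop("unknown config block(s): ", paste(unknown_blocks, collapse = ", "),
         call. = FALSE)
  }
  cfg <- config_schema
  for (block in names(raw)) {
    bad <- setdiff(names(raw[[block]]), names(config_schema[[block]]))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste(paste0(block, "$", bad), collapse = ", "), call. = FALSE)
    }
    cfg[[block]][names(raw[[block]])] <- raw[[block]]
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (!g$handedness %in% c("right", "left")) {
    stop("geometry$handedness must be 'right' or 'left'", call. = FALSE)
  }
  if (!g$shape %in% c("cylinder", "sphere")) {
    stop("geometry$shape must be 'cylinder' or 'sphere'", call. = FALSE)
  }
  if (!g$orientation_mode %in% c("radial", "tangential", "axial")) {
    stop("geometry$orientation_mode invalid", call. = FALSE)
  }
  if (!cfg$observables$mode %in% c("fixed", "averaged")) {
    stop("observables$mode must be 'fixed' or 'averaged'", call. = FALSE)
  }
  num_pos <- c("geometry$radius_nm" = g$radius_nm >= 0,
               "geometry$pitch_nm" = g$pitch_nm >= 0,
               "geometry$diameter_nm" = g$diameter_nm > 0,
               "optics$lambda_vac_nm" = cfg$optics$lambda_vac_nm > 0,
               "optics$n_host" = cfg$optics$n_host > 0,
               "discretization$dipoles_per_longest" =
                 cfg$discretization$dipoles_per_longest >= 4)
  if (!all(num_pos)) {
    stop("invalid config value(s): ",
         paste(names(num_pos)[!num_pos], collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Write a run configuration
#'
#' Deterministic YAML writer; `read_config(write_config(cfg, path))` is the
#' identity.
#'
#' @param config A `run_config` (or compatible nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Solenoid spec from a configuration
#' @param config A `run_config` from [read_config()].
#' @return A [solenoid_spec()].
#' @export
as_solenoid_spec <- function(config) {
  g <- config$geometry
  shape <- if (g$shape == "sphere") {
    nucleosome_shape("sphere", diameter = g$diameter_nm)
  } else {
    nucleosome_shape("cylinder", diameter = g$diameter_nm,
                     height = g$height_nm)
  }
  solenoid_spec(radius = g$radius_nm, pitch = g$pitch_nm,
                handedness = g$handedness, turns = g$turns,
                nucleosomes_per_turn = g$nucleosomes_per_turn,
                phase0 = g$phase0_rad, orientation_mode = g$orientation_mode,
                tilt = g$tilt_rad, shape = shape)
}

#' Plane wave from a configuration
#' @param config A `run_config` from [read_config()].
#' @return A [plane_wave()].
#' @export
as_plane_wave <- function(config) {
  plane_wave(config$optics$lambda_vac_nm, config$optics$n_host)
}

#' Export a dipole model as a plain-text geometry file
#'
#' `dialect = "adda"` writes one `i j k` integer triple per line with a
#' '#'-prefixed comment header recording the lattice spacing, origin, host
#' index and relative refractive index at full precision (loadable by
#' solvers of the ADDA family). `dialect = "ddscat"` writes the DDSCAT-style
#' seven-column shape table (`JA IX IY IZ ICOMP = 1 1 1`) with the same
#' metadata in the description line.
#'
#' @param model A [dipole_model()].
#' @param path Output path.
#' @param dialect `"adda"` (default) or `"ddscat"`.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(model, path, dialect = c("adda", "ddscat")) {
  dialect <- match.arg(dialect)
  fmt <- function(x) sprintf("%.17g", x)
  meta <- c(
    sprintf("spacing_nm: %s", fmt(model$spacing)),
    sprintf("origin_nm: %s %s %s", fmt(model$origin[1]),
            fmt(model$origin[2]), fmt(model$origin[3])),
    sprintf("host_index: %s", fmt(model$host_index)),
    sprintf("rel_index: %s %s", fmt(Re(model$rel_index[1])),
            fmt(Im(model$rel_index[1])))
  )
  s <- model$sites
  if (dialect == "adda") {
    lines <- c("#cidscatter dipole geometry", paste0("#", meta),
               sprintf("%d %d %d", s[, 1], s[, 2], s[, 3]))
  } else {
    lines <- c(
      paste0("cidscatter shape; ", paste(meta, collapse = "; ")),
      sprintf("%d = NAT", nrow(s)),
      "1 0 0 = A_1 vector", "0 1 0 = A_2 vector",
      "1 1 1 = lattice spacings (d_x,d_y,d_z)/d",
      "0 0 0 = lattice offset",
      "JA IX IY IZ ICOMP(x,y,z)",
      sprintf("%d %d %d %d 1 1 1", seq_len(nrow(s)), s[, 1], s[, 2], s[, 3])
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text geometry file
#'
#' Inverse of [write_geometry()]: reproduces sites, spacing, origin and
#' indices exactly. Malformed lines are rejected with their line numbers.
#'
#' @param path Input path.
#' @param dialect `"adda"` or `"ddscat"`; detected from the header when
#'   `NULL`.
#' @return A [dipole_model()].
#' @export
read_geometry <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty geometry file", call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("^#", lines[1])) "adda" else "ddscat"
  }
  meta_text <- if (dialect == "adda") {
    sub("^#", "", grep("^#", lines, value = TRUE))
  } else {
    strsplit(sub("^[^;]*; ", "", lines[1]), "; ")[[1]]
  }
  get_meta <- function(key) {
    hit <- grep(paste0("^", key, ":"), meta_text, value = TRUE)
    if (!length(hit)) stop("geometry header missing '", key, "'", call. = FALSE)
    as.numeric(strsplit(trimws(sub("^[^:]*:", "", hit[1])), "\\s+")[[1]])
  }
  spacing <- get_meta("spacing_nm")
  origin <- get_meta("origin_nm")
  host <- get_meta("host_index")
  mi <- get_meta("rel_index")
  if (dialect == "adda") {
    body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    parts <- strsplit(trimws(lines[body_idx]), "\\s+")
    bad <- which(vapply(parts, length, 1L) != 3L |
                   vapply(parts, function(p) anyNA(suppressWarnings(as.integer(p))), TRUE))
    if (length(bad)) {
      stop("malformed geometry line(s): ",
           paste(body_idx[bad], collapse = ", "), call. = FALSE)
    }
    sites <- do.call(rbind, lapply(parts, as.integer))
  } else {
    hdr <- grep("^JA ", lines)
    if (!length(hdr)) stop("DDSCAT table header not found", call. = FALSE)
    body_idx <- seq.int(hdr[1] + 1L, length(lines))
    body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
    parts <- strsplit(trimws(lines[body_idx]), "\\s+")
    bad <- which(vapply(parts, length, 1L) != 7L |
                   vapply(parts, function(p) anyNA(suppressWarnings(as.integer(p))), TRUE))
    if (length(bad)) {
      stop("malformed geometry line(s): ",
           paste(body_idx[bad], collapse = ", "), call. = FALSE)
    }
    sites <- do.call(rbind, lapply(parts, function(p) as.integer(p[2:4])))
  }
  dipole_model(spacing = spacing, origin = origin, sites = sites,
               rel_index = complex(real = mi[1], imaginary = mi[2]),
               host_index = host)
}

#' Write a result table as delimited text
#'
#' Deterministic tab-separated writer ('.' decimal separator, fixed column
#' order, no locale dependence) for sweep results, Mueller matrices and CIDS
#' profiles, so reruns diff bit-stably.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  df <- as.data.frame(x)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.12g", df[[nm]])
  }
  old <- options(scipen = 100)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
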