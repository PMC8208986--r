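# File formats: contour / centerline / lumen-series CSV dialects (headers
# with unit suffixes mandatory), legacy-ASCII VTK surface export, JSON
# reports and run configuration files. All readers and writers round-trip
# exactly.

check_header <- function(df, expected, path) {
  have <- names(df)
  for (i in seq_along(expected))
    if (i > length(have) || have[i] != expected[i])
      stop(sprintf(paste0("%s: malformed header: expected column %d to be ",
                          "'%s' (units are part of the name), found '%s'"),
                   path, i, expected[i],
                   if (i <= length(have)) have[i] else "<missing>"))
  invisible(TRUE)
}

#' Write / read contour frames as CSV
#'
#' Dialect: one row per `(frame_index, s_mm, theta_rad, radius_mm)` with a
#' mandatory header; azimuths must form the uniform grid `2*pi*k/M`.
#'
#' @param frames list of [contour_frame()]s.
#' @param path file path.
#' @return `read_contours` returns the list of frames.
#' @export
write_contours <- function(frames, path) {
  rows <- do.call(rbind, lapply(frames, function(f) {
    data.frame(frame_index = f$index, s_mm = f$s,
               theta_rad = frame_thetas(f), radius_mm = f$radii)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_header(df, c("frame_index", "s_mm", "theta_rad", "radius_mm"), path)
  idx <- unique(df$frame_index)
  lapply(idx, function(i) {
    sub <- df[df$frame_index == i, ]
    sub <- sub[order(sub$theta_rad), ]
    M <- nrow(sub)
    th_ref <- 2 * pi * (0:(M - 1)) / M
    if (max(abs(sub$theta_rad - th_ref)) > 1e-6)
      stop(path, ": frame ", i, ": azimuths are not the uniform grid ",
           "2*pi*k/M")
    contour_frame(i, sub$s_mm[1], sub$radius_mm)
  })
}

#' Write / read a centerline as CSV
#'
#' Dialect: rows `(s_mm, x_mm, y_mm, z_mm)` with mandatory header.
#'
#' @param cl an [centerline()].
#' @param path file path.
#' @export
write_centerline <- function(cl, path) {
  df <- data.frame(s_mm = cl$s, x_mm = cl$points[, 1],
                   y_mm = cl$points[, 2], z_mm = cl$points[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_header(df, c("s_mm", "x_mm", "y_mm", "z_mm"), path)
  centerline(cbind(df$x_mm, df$y_mm, df$z_mm))
}

#' Write / read a lumen-area series as CSV
#'
#' Dialect: rows `(s_mm, area_baseline_mm2, area_followup_mm2)`.
#'
#' @param series a [lumen_series()].
#' @param path file path.
#' @export
write_lumen_series <- function(series, path) {
  df <- data.frame(s_mm = series$s,
                   area_baseline_mm2 = series$area_baseline,
                   area_followup_mm2 = series$area_followup)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lumen_series
#' @export
read_lumen_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_header(df, c("s_mm", "area_baseline_mm2", "area_followup_mm2"),
               path)
  lumen_series(df$s_mm, df$area_baseline_mm2, df$area_followup_mm2)
}

#' Export an artery surface as legacy-ASCII VTK structured grid
#'
#' The `(s, theta)` quadrilateral mesh with the azimuth seam closed;
#' optional per-station point data (e.g. sectional WSS) are attached as
#' scalars for rendering.
#'
#' @param surf an `artery_surface`.
#' @param path output `.vtk` file.
#' @param point_data named list of per-station or per-point numeric
#'   vectors.
#' @export
write_surface_vtk <- function(surf, path, point_data = list()) {
  sp <- surface_points(surf)
  M <- length(surf$theta); ns <- length(sp$s)
  # close the seam by repeating the first azimuth
  sel <- c(seq_len(M), 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "artery lumen surface", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", M + 1, ns),
               sprintf("POINTS %d float", (M + 1) * ns)), con)
  for (j in seq_len(ns)) {
    ring <- sp$P[(j - 1) * M + sel, , drop = FALSE]
    writeLines(sprintf("%.6g %.6g %.6g", ring[, 1], ring[, 2], ring[, 3]),
               con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", (M + 1) * ns), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (length(v) == ns) v <- rep(v, each = M + 1)
      else if (length(v) == ns * M)
        v <- as.numeric(t(matrix(v, ns, M)[, sel]))
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.6g", v)), con)
    }
  }
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param report named list.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# run configuration (JSON): schema-validated, unknown keys rejected

config_schema <- list(
  geometry = c("source", "ideal", "contours_path", "centerline_path",
               "synthetic", "straighten", "extensions"),
  fluid = c("density_kg_m3", "viscosity_pa_s"),
  waveform = c("type", "u_mean", "period", "path", "u_bulk"),
  grid = c("cells_per_diameter", "margin_cells"),
  solver = c("cfl", "cycles", "discard", "poisson_rtol",
             "records_per_cycle"),
  species = NULL,   # list of species blocks
  analysis = c("followup_path", "lumen_series_path"),
  top = c("geometry", "fluid", "waveform", "grid", "solver", "species",
          "analysis", "output_dir", "seed"))

#' Read and validate a run configuration (JSON)
#'
#' Unknown keys anywhere in the file are rejected before any computation.
#'
#' @param path JSON configuration file.
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_schema$top)
  if (length(unknown))
    stop("run config: unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  for (blk in c("geometry", "fluid", "waveform", "grid", "solver",
                "analysis")) {
    if (is.null(cfg[[blk]])) next
    unknown <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
    if (length(unknown))
      stop("run config: unknown key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$geometry$source) ||
      !cfg$geometry$source %in% c("ideal", "contours", "synthetic"))
    stop("run config: geometry$source must be one of ",
         "'ideal', 'contours', 'synthetic'")
  if (!is.null(cfg$species)) {
    sp_keys <- c("name", "rho_ref", "wss_th", "k_max", "law", "mode")
    spl <- cfg$species
    if (is.data.frame(spl)) spl <- split(spl, seq_len(nrow(spl)))
    for (sp in spl) {
      unknown <- setdiff(names(sp), sp_keys)
      if (length(unknown))
        stop("run config: unknown species key(s): ",
             paste(unknown, collapse = ", "))
    }
  }
  cfg
}
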