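# Computational domains: an artery surface immersed in a Cartesian grid,
# or a planar (2D) channel analog for fast validation runs.
# Grid spacing is uniform; the solver works in SI units.

MM <- 1e-3  # mm -> m

#' Immerse an artery surface in a Cartesian flow grid
#'
#' Builds the uniform staggered grid covering the surface bounding box,
#' samples the signed distance at grid nodes, and prepares the inlet
#' profile and wall sample points for the solver. The inlet plane must be
#' normal to the x axis (guaranteed for surfaces built along x or through
#' [add_extensions()] on centerlines that start x-parallel).
#'
#' @param surf an `artery_surface` (typically after [add_extensions()]).
#' @param cells_per_diameter grid resolution across the mean diameter D.
#' @param margin_cells solid-cell padding around the transverse bounding
#'   box.
#' @param wall_stations stations (mm) at which wall shear is sampled;
#'   default: all surface stations.
#' @param n_theta_samples azimuthal wall-sample count; default: the
#'   surface azimuthal resolution, capped at 32.
#' @return an object of class `flow_domain`.
#' @export
flow_domain <- function(surf, cells_per_diameter = 12, margin_cells = 4L,
                        wall_stations = NULL, n_theta_samples = NULL) {
  stopifnot(inherits(surf, "artery_surface"))
  h <- surf$D / cells_per_diameter  # mm
  if (cells_per_diameter < 8)
    warning("flow_domain: fewer than 8 cells across the mean diameter")
  sg <- surf$s_grid
  dense_s <- seq(sg[1], sg[length(sg)], by = h / 2)
  sp <- surface_points(surf, dense_s)
  f0 <- fine_at(surf$cl, sg[1])
  if (abs(f0$T[1, 1]) < 0.996)
    stop("flow_domain: inlet tangent must be x-parallel (within 5 degrees); ",
         "extend or re-orient the geometry")
  x0 <- f0$P[1, 1]
  x1 <- fine_at(surf$cl, sg[length(sg)])$P[1, 1]
  nx <- max(8L, as.integer(ceiling((x1 - x0) / h - 1e-9)))
  ymin <- min(sp$P[, 2]); ymax <- max(sp$P[, 2])
  zmin <- min(sp$P[, 3]); zmax <- max(sp$P[, 3])
  ny <- as.integer(ceiling((ymax - ymin) / h)) + 2L * margin_cells
  nz <- as.integer(ceiling((zmax - zmin) / h)) + 2L * margin_cells
  origin <- c(x0, ymin - margin_cells * h, zmin - margin_cells * h)

  # node signed distance (mm -> SI)
  xs <- origin[1] + (0:nx) * h
  ys <- origin[2] + (0:ny) * h
  zs <- origin[3] + (0:nz) * h
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  phi <- signed_distance(surf, nodes) * MM

  # inlet: circular, centred on the centerline start
  r_in <- if (!is.null(surf$inlet_radius)) surf$inlet_radius else
    mean(surf$R[1, ])
  cy <- f0$P[1, 2]; cz <- f0$P[1, 3]
  yj <- origin[2] + ((1:ny) - 0.5) * h
  zk <- origin[3] + ((1:nz) - 0.5) * h
  rr <- sqrt(outer((yj - cy)^2, (zk - cz)^2, "+"))
  prof <- 2 * pmax(0, 1 - (rr / r_in)^2)
  tot <- sum(prof) * h^2
  A_in <- pi * r_in^2
  prof <- prof * (A_in / tot)  # discrete flux = U_bulk * A_in exactly

  area_prof <- surface_area_profile(surf)
  wall <- surface_wall_samples(
    surf,
    stations = if (is.null(wall_stations)) surf$s_grid else wall_stations,
    n_theta = if (is.null(n_theta_samples))
      min(32L, length(surf$theta)) else n_theta_samples)

  structure(list(
    type = "artery3d", surface = surf,
    nx = nx, ny = ny, nz = nz, h = h * MM, h_mm = h, origin = origin,
    periodic_x = FALSE, periodic_z = FALSE,
    phi = phi, inlet_profile = as.numeric(prof),
    inlet_area = A_in * MM^2, inlet_radius = r_in,
    section_area = NULL,
    area_profile = area_prof, area_min = min(area_prof),
    wall = wall, D = surf$D), class = "flow_domain")
}

#' Planar channel domain (2D analog)
#'
#' A plane channel of gap H with an optional smooth two-sided constriction,
#' solved in planar mode (one periodic cell in z). Used for fast
#' qualitative runs and analytic validation against plane Poiseuille flow.
#'
#' @param gap channel gap H (mm).
#' @param length channel length (mm).
#' @param cells_per_gap grid resolution across the gap.
#' @param severity fractional gap reduction of the constriction in
#'   `[0, 1)`; 0 for a plain channel.
#' @param sten_center,sten_extent centre and axial extent of the
#'   constriction (mm).
#' @param margin_cells solid padding below/above the walls.
#' @param wall_offset fractional sub-cell offset of the lower wall.
#' @param n_wall_stations number of axial wall-sample stations.
#' @return a `flow_domain` of type `"channel2d"`.
#' @export
channel_domain <- function(gap = 2, length = 24, cells_per_gap = 16,
                           severity = 0, sten_center = length / 3,
                           sten_extent = 2 * gap, margin_cells = 3L,
                           wall_offset = 0.3, n_wall_stations = 64L) {
  if (severity < 0 || severity >= 1)
    stop("channel_domain: severity must be in [0, 1)")
  h <- gap / cells_per_gap
  nx <- as.integer(ceiling(length / h))
  ny <- as.integer(cells_per_gap) + 2L * margin_cells
  nz <- 1L
  y0 <- (margin_cells + wall_offset %% 1) * h  # lower wall
  bump <- function(x) {
    xi <- (x - sten_center) / sten_extent
    a <- numeric(base::length(x))
    inside <- abs(xi) < 0.5
    a[inside] <- 0.5 * severity * gap * cos(pi * xi[inside])^2
    a
  }
  ylo <- function(x) y0 + bump(x)
  yhi <- function(x) y0 + gap - bump(x)
  xs <- (0:nx) * h
  ys <- (0:ny) * h
  phi <- matrix(0, nx + 1, ny + 1)
  for (i in seq_along(xs))
    phi[i, ] <- pmax(ylo(xs[i]) - ys, ys - yhi(xs[i]))
  phi <- array(rep(as.numeric(phi), nz + 1), c(nx + 1, ny + 1, nz + 1))

  yj <- ((1:ny) - 0.5) * h
  prof <- 6 * pmax(0, (yj - y0) * (y0 + gap - yj)) / gap^2
  prof <- prof * (gap / (sum(prof) * h))  # discrete flux = U * gap * h

  # wall samples: two walls, theta bin 1 = lower, 2 = upper
  sx <- seq(1.5 * h, length - 1.5 * h, length.out = n_wall_stations)
  eps <- 1e-4
  dlo <- (bump(sx + eps) - bump(sx - eps)) / (2 * eps)
  nlo <- cbind(-dlo, 1, 0); nlo <- nlo / sqrt(rowSums(nlo^2))
  nup <- cbind(-dlo, -1, 0); nup <- nup / sqrt(rowSums(nup^2))
  pts <- rbind(cbind(sx, ylo(sx), 0.5 * h), cbind(sx, yhi(sx), 0.5 * h))
  nrm <- rbind(nlo, nup)
  wall <- list(points = pts, normals = nrm,
               s_bin = rep(seq_along(sx), 2),
               theta_bin = rep(1:2, each = base::length(sx)),
               stations = sx, thetas = c(pi * 1.5, pi * 0.5))
  gap_prof <- yhi(sx) - ylo(sx)

  structure(list(
    type = "channel2d",
    nx = nx, ny = ny, nz = nz, h = h * MM, h_mm = h, origin = c(0, 0, 0),
    periodic_x = FALSE, periodic_z = TRUE,
    phi = as.numeric(phi) * MM, inlet_profile = as.numeric(prof),
    inlet_area = gap * h * MM^2, gap = gap, gap_profile = gap_prof,
    section_area = NULL,
    area_profile = gap_prof * h, area_min = min(gap_prof) * h,
    wall = wall, D = gap, ylo = ylo, yhi = yhi), class = "flow_domain")
}

#' Periodic straight-tube domain
#'
#' An axially periodic circular pipe driven at a prescribed bulk velocity
#' (equivalent to a uniform pulsatile pressure gradient). Used for the
#' analytic Poiseuille and Womersley validations where entrance effects
#' are not wanted.
#'
#' @param radius pipe radius (mm).
#' @param cells_per_diameter transverse resolution.
#' @param nx axial cells (the solution is axially invariant).
#' @param margin_cells solid padding around the pipe.
#' @param center_offset sub-cell offset of the pipe axis, avoids
#'   grid-aligned symmetry artefacts.
#' @param n_theta_samples azimuthal wall-sample count.
#' @return a `flow_domain` of type `"pipe_periodic"`.
#' @export
periodic_pipe_domain <- function(radius = 1, cells_per_diameter = 24,
                                 nx = 8L, margin_cells = 4L,
                                 center_offset = c(0.37, 0.13),
                                 n_theta_samples = 16L) {
  h <- 2 * radius / cells_per_diameter
  ny <- nz <- as.integer(cells_per_diameter) + 2L * margin_cells
  yc <- (ny / 2 + center_offset[1]) * h
  zc <- (nz / 2 + center_offset[2]) * h
  ys <- (0:ny) * h; zs <- (0:nz) * h
  rr <- sqrt(outer((ys - yc)^2, (zs - zc)^2, "+")) - radius
  phi <- aperm(array(rr, c(ny + 1, nz + 1, nx + 1)), c(3, 1, 2))
  th <- 2 * pi * (0:(n_theta_samples - 1)) / n_theta_samples
  sx <- (nx / 2) * h
  wall <- list(points = cbind(sx, yc + radius * cos(th), zc + radius * sin(th)),
               normals = cbind(0, -cos(th), -sin(th)),
               s_bin = rep(1L, n_theta_samples),
               theta_bin = seq_len(n_theta_samples),
               stations = sx, thetas = th)
  structure(list(
    type = "pipe_periodic",
    nx = as.integer(nx), ny = ny, nz = nz, h = h * MM, h_mm = h,
    origin = c(0, 0, 0),
    periodic_x = TRUE, periodic_z = FALSE,
    phi = as.numeric(phi) * MM, inlet_profile = NULL,
    inlet_area = pi * radius^2 * MM^2,
    section_area = pi * radius^2 * MM^2,
    area_profile = pi * radius^2, area_min = pi * radius^2,
    radius = radius, center = c(yc, zc),
    wall = wall, D = 2 * radius), class = "flow_domain")
}

# convert wall sample coordinates (mm, surface frame) to solver SI coords
wall_to_solver <- function(domain) {
  w <- domain$wall
  if (is.null(w)) return(NULL)
  pts <- sweep(w$points, 2, domain$origin)
  list(points = pts * MM, normals = w$normals)
}
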