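# Artery lumen geometry: contour frames, centerlines, surface stacking,
# ideal stenoses, inlet/outlet extensions and point-membership queries.
# All lengths in millimetres.

#' Lumen contour frame
#'
#' A single cross-sectional lumen contour as acquired from one pullback
#' image: `M` radial distances from the frame centroid at uniform azimuth
#' angles `theta_k = 2*pi*k/M`.
#'
#' @param index integer frame index (acquisition order).
#' @param s arclength position along the centerline (mm).
#' @param radii numeric vector of `M >= 16` positive radii (mm).
#' @return an object of class `contour_frame`.
#' @export
contour_frame <- function(index, s, radii) {
  radii <- as.numeric(radii)
  if (length(radii) < 16L)
    stop("contour_frame: need at least 16 radial samples, got ",
         length(radii))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("contour_frame: all radii must be finite and positive")
  structure(list(index = as.integer(index), s = as.numeric(s),
                 radii = radii),
            class = "contour_frame")
}

frame_thetas <- function(frame) {
  M <- length(frame$radii)
  2 * pi * (seq_len(M) - 1L) / M
}

#' Cross-sectional lumen area of a contour frame
#'
#' Area of the closed polygon through the `M` contour points (shoelace
#' formula). Contours are star-shaped around the centroid by construction
#' (positive radii at monotone azimuths), so the polygon is always simple.
#'
#' @param frame a [contour_frame()].
#' @return area in mm^2.
#' @export
frame_area <- function(frame) {
  if (!inherits(frame, "contour_frame")) frame <- do.call(contour_frame, frame)
  th <- frame_thetas(frame)
  x <- frame$radii * cos(th)
  y <- frame$radii * sin(th)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * abs(sum(x * yn - xn * y))
}

frame_perimeter <- function(frame) {
  th <- frame_thetas(frame)
  x <- frame$radii * cos(th)
  y <- frame$radii * sin(th)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

frame_mean_radius <- function(frame) mean(frame$radii)

#' Artery centerline
#'
#' An ordered 3D polyline with cumulative arclength and spline-interpolated
#' unit tangents. A finely resampled copy with parallel-transport frames
#' (`e1`, `e2` spanning each normal plane) is attached for surface
#' construction and distance queries; parallel transport is used instead of
#' a Frenet frame because the latter is undefined at inflection points.
#'
#' @param points n x 3 matrix of points (mm), n >= 2.
#' @param ds resampling step for the fine copy (mm).
#' @return an object of class `artery_centerline`.
#' @export
centerline <- function(points, ds = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("centerline: need an n x 3 matrix with n >= 2")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) stop("centerline: arclength must be strictly increasing")
  s <- c(0, cumsum(seg))
  if (is.null(ds)) ds <- max(min(0.05, s[length(s)] / 50), s[length(s)] / 8000)
  fine <- resample_polyline(points, s, ds)
  structure(list(points = points, s = s, fine = fine),
            class = "artery_centerline")
}

# cubic-spline resampling with unit tangents and parallel-transport frames
resample_polyline <- function(points, s, ds) {
  n <- nrow(points)
  sf <- seq(0, s[n], by = ds)
  if (sf[length(sf)] < s[n]) sf <- c(sf, s[n])
  P <- matrix(0, length(sf), 3)
  T <- matrix(0, length(sf), 3)
  for (d in 1:3) {
    if (n >= 4) {
      f <- stats::splinefun(s, points[, d], method = "natural")
      P[, d] <- f(sf)
      T[, d] <- f(sf, deriv = 1L)
    } else {
      P[, d] <- stats::approx(s, points[, d], xout = sf)$y
      # piecewise-linear tangent
      T[, d] <- stats::approx(s, points[, d], xout = pmin(sf + 1e-6, s[n]))$y -
                stats::approx(s, points[, d], xout = pmax(sf - 1e-6, 0))$y
    }
  }
  T <- T / sqrt(rowSums(T^2))
  fr <- transport_frames(T)
  list(s = sf, P = P, T = T, e1 = fr$e1, e2 = fr$e2)
}

# rotation-minimizing frames by incremental rotation between tangents
transport_frames <- function(T) {
  n <- nrow(T)
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  ref <- if (abs(T[1, 2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  v <- ref - sum(ref * T[1, ]) * T[1, ]
  e1[1, ] <- v / sqrt(sum(v^2))
  e2[1, ] <- cross3(T[1, ], e1[1, ])
  for (i in 2:n) {
    ax <- cross3(T[i - 1, ], T[i, ])
    sa <- sqrt(sum(ax^2))
    ca <- sum(T[i - 1, ] * T[i, ])
    if (sa < 1e-12) {
      e1[i, ] <- e1[i - 1, ]
    } else {
      ax <- ax / sa
      e1[i, ] <- rotate_about(e1[i - 1, ], ax, atan2(sa, ca))
    }
    # re-orthogonalize against the tangent
    v <- e1[i, ] - sum(e1[i, ] * T[i, ]) * T[i, ]
    e1[i, ] <- v / sqrt(sum(v^2))
    e2[i, ] <- cross3(T[i, ], e1[i, ])
  }
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_about <- function(v, ax, ang) {
  v * cos(ang) + cross3(ax, v) * sin(ang) +
    ax * sum(ax * v) * (1 - cos(ang))
}

#' Centerline tortuosity
#'
#' Arc length divided by the endpoint chord length (1 for a straight
#' segment).
#'
#' @param cl an [centerline()] object.
#' @return tortuosity ratio, >= 1.
#' @export
tortuosity <- function(cl) {
  stopifnot(inherits(cl, "artery_centerline"))
  chord <- sqrt(sum((cl$points[nrow(cl$points), ] - cl$points[1, ])^2))
  if (chord <= 0) stop("tortuosity: coincident endpoints")
  cl$s[length(cl$s)] / chord
}

# interpolate fine centerline quantities at arbitrary s
fine_at <- function(fine, sq) {
  sq <- pmin(pmax(sq, fine$s[1]), fine$s[length(fine$s)])
  out <- list()
  for (nm in c("P", "T", "e1", "e2")) {
    m <- matrix(0, length(sq), 3)
    for (d in 1:3)
      m[, d] <- stats::approx(fine$s, fine[[nm]][, d], xout = sq)$y
    out[[nm]] <- m
  }
  out$T <- out$T / sqrt(rowSums(out$T^2))
  out$e1 <- out$e1 / sqrt(rowSums(out$e1^2))
  out$e2 <- out$e2 / sqrt(rowSums(out$e2^2))
  out
}

#' Ideal stenosis specification
#'
#' A straight circular pipe with an axisymmetric constriction. Severity is
#' the fractional area reduction `1 - A_min / A_healthy`; the radius
#' profile is a cosine-squared reduction over the axial extent, C1-smooth
#' at the junctions, with the minimum lumen area at `x = 0` by convention.
#'
#' @param diameter healthy-tract diameter D (mm).
#' @param severity fractional area reduction in `[0, 1)`.
#' @param extent axial extent of the constriction (mm).
#' @param position axial position of the minimum lumen area (mm).
#' @param length total length of the pipe (mm), centred on `position`
#'   unless `x_range` is given.
#' @param x_range optional explicit axial range `c(x0, x1)` (mm).
#' @return an object of class `ideal_stenosis_spec`.
#' @export
ideal_stenosis_spec <- function(diameter = 2, severity = 0.5, extent = 4,
                                position = 0, length = 16, x_range = NULL) {
  if (severity < 0 || severity >= 1)
    stop("ideal_stenosis_spec: severity must be in [0, 1); a severity of 1 ",
         "is full occlusion")
  if (extent <= 0) stop("ideal_stenosis_spec: extent must be positive")
  if (diameter <= 0) stop("ideal_stenosis_spec: diameter must be positive")
  if (is.null(x_range)) x_range <- position + c(-length / 2, length / 2)
  structure(list(diameter = diameter, severity = severity, extent = extent,
                 position = position, x_range = x_range),
            class = "ideal_stenosis_spec")
}

stenosis_radius <- function(spec, x) {
  R0 <- spec$diameter / 2
  rmin <- R0 * sqrt(1 - spec$severity)
  xi <- (x - spec$position) / spec$extent  # -1/2 .. 1/2 inside constriction
  r <- rep(R0, length(x))
  inside <- abs(xi) < 0.5
  r[inside] <- R0 - (R0 - rmin) * cos(pi * xi[inside])^2
  r
}

#' Build an idealized stenotic artery surface
#'
#' @param spec an [ideal_stenosis_spec()].
#' @param frame_spacing axial spacing of the generated stations (mm),
#'   defaulting to the pullback spacing of 0.5 mm.
#' @param n_theta azimuthal resolution of the generated contours.
#' @return an `artery_surface`.
#' @export
build_ideal_stenosis <- function(spec, frame_spacing = 0.5, n_theta = 64L) {
  stopifnot(inherits(spec, "ideal_stenosis_spec"))
  if (frame_spacing <= 0) stop("build_ideal_stenosis: frame_spacing must be > 0")
  xs <- seq(spec$x_range[1], spec$x_range[2], by = frame_spacing)
  frames <- lapply(seq_along(xs), function(j)
    contour_frame(j, xs[j] - xs[1],
                  rep(stenosis_radius(spec, xs[j]), n_theta)))
  cl <- centerline(cbind(c(xs[1], xs[length(xs)]), 0, 0))
  surf <- stack_frames(frames, cl)
  surf$x_offset <- xs[1]  # station j sits at x = s_grid + x_offset
  surf
}

#' Stack contour frames along a centerline into an artery surface
#'
#' Each contour is embedded in the plane normal to the centerline tangent
#' at its arclength position; in-plane orientation is propagated by a
#' rotation-minimizing (parallel transport) frame.
#'
#' @param frames list of [contour_frame()]s ordered by `s`.
#' @param cl an [centerline()] whose arclength range covers the frames.
#' @return an object of class `artery_surface`: a parametric `(s, theta)`
#'   radius table bound to the centerline's transported frames.
#' @export
stack_frames <- function(frames, cl) {
  stopifnot(inherits(cl, "artery_centerline"))
  frames <- lapply(frames, function(f)
    if (inherits(f, "contour_frame")) f else do.call(contour_frame, f))
  sj <- vapply(frames, function(f) f$s, 0)
  if (any(diff(sj) <= 0)) stop("stack_frames: frames out of order in s")
  rng <- range(cl$fine$s)
  if (sj[1] < rng[1] - 1e-9 || sj[length(sj)] > rng[2] + 1e-9)
    stop("stack_frames: frame positions outside centerline arclength range")
  M <- length(frames[[1]]$radii)
  if (!all(vapply(frames, function(f) length(f$radii), 0L) == M))
    stop("stack_frames: all frames must share the same azimuthal resolution")
  R <- t(vapply(frames, function(f) f$radii, numeric(M)))
  # adjacent normal planes must not intersect inside the lumen
  fa <- fine_at(cl$fine, sj)
  for (j in seq_len(length(sj) - 1)) {
    ca <- sum(fa$T[j, ] * fa$T[j + 1, ])
    ang <- acos(pmin(1, pmax(-1, ca)))
    if (ang > 1e-9) {
      rmax <- max(R[j, ], R[j + 1, ])
      if ((sj[j + 1] - sj[j]) < 2 * sin(ang / 2) * rmax)
        stop(sprintf(paste0("stack_frames: centerline curvature too high ",
                            "near s = %.3f mm; adjacent frame planes ",
                            "intersect inside the lumen"), sj[j]))
    }
  }
  structure(list(s_grid = sj, theta = 2 * pi * (0:(M - 1)) / M, R = R,
                 cl = cl$fine, segment = rep("clinical", length(sj)),
                 D = mean(2 * sqrt(vapply(frames, frame_area, 0) / pi)),
                 frames = frames),
            class = "artery_surface")
}

#' Stack frames along a straight axis
#'
#' The control-experiment geometry: the same contours as [stack_frames()]
#' but embedded along a straight x-parallel axis at their original
#' arclength positions, removing all centerline tortuosity while keeping
#' every cross-sectional area unchanged.
#'
#' @param frames list of [contour_frame()]s.
#' @return an `artery_surface` with tortuosity exactly 1.
#' @export
straighten <- function(frames) {
  frames <- lapply(frames, function(f)
    if (inherits(f, "contour_frame")) f else do.call(contour_frame, f))
  sj <- vapply(frames, function(f) f$s, 0)
  cl <- centerline(cbind(c(sj[1], sj[length(sj)]), 0, 0))
  stack_frames(frames, cl)
}

# evaluate surface vertices; returns list(P = ns*M x 3, stations, thetas)
surface_points <- function(surf, s = surf$s_grid) {
  fa <- fine_at(surf$cl, s)
  M <- length(surf$theta)
  R <- interp_radius_table(surf, s)
  P <- matrix(0, length(s) * M, 3)
  for (j in seq_along(s)) {
    ring <- fa$P[rep(j, M), ] +
      R[j, ] * (cos(surf$theta) %o% c(1, 1, 1) * fa$e1[rep(j, M), ] +
                sin(surf$theta) %o% c(1, 1, 1) * fa$e2[rep(j, M), ])
    P[(j - 1) * M + seq_len(M), ] <- ring
  }
  list(P = P, s = s, theta = surf$theta)
}

interp_radius_table <- function(surf, s) {
  s <- pmin(pmax(s, surf$s_grid[1]), surf$s_grid[length(surf$s_grid)])
  out <- matrix(0, length(s), ncol(surf$R))
  for (k in seq_len(ncol(surf$R)))
    out[, k] <- stats::approx(surf$s_grid, surf$R[, k], xout = s)$y
  out
}

surface_area_profile <- function(surf) {
  vapply(seq_along(surf$s_grid), function(j)
    frame_area(contour_frame(j, surf$s_grid[j], surf$R[j, ])), 0)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Append inlet and outlet flow extensions to an artery surface
#'
#' A straight inflow channel (default length 5D) with a circular inlet
#' cross-section whose radius equals the mean radius of the first frame,
#' blending into the first frame over its final 2D; and an outflow channel
#' (default 8D) that bends the centerline until the tangent is parallel to
#' the x axis while the cross-section relaxes to circular, to accommodate
#' the radiative outlet boundary condition.
#'
#' @param surf an `artery_surface`.
#' @param inlet_length,outlet_length extension lengths (mm); defaults 5D
#'   and 8D with D the mean lumen diameter.
#' @param spacing station spacing inside the extensions (mm).
#' @return an extended `artery_surface`; the clinical stations keep their
#'   `s` coordinates (inlet stations have negative offsets from the first
#'   clinical frame).
#' @export
add_extensions <- function(surf, inlet_length = NULL, outlet_length = NULL,
                           spacing = NULL) {
  stopifnot(inherits(surf, "artery_surface"))
  D <- surf$D
  if (is.null(inlet_length)) inlet_length <- 5 * D
  if (is.null(outlet_length)) outlet_length <- 8 * D
  if (inlet_length <= 0 || outlet_length <= 0)
    stop("add_extensions: extension lengths must be positive")
  if (is.null(spacing))
    spacing <- if (length(surf$s_grid) > 1) min(diff(surf$s_grid)) else 0.5
  M <- length(surf$theta)
  s0 <- surf$s_grid[1]; s1 <- surf$s_grid[length(surf$s_grid)]
  f0 <- fine_at(surf$cl, s0); f1 <- fine_at(surf$cl, s1)
  r_in <- mean(surf$R[1, ]); r_out <- mean(surf$R[nrow(surf$R), ])

  # ---- inlet: straight back along the first tangent
  n_in <- max(2L, ceiling(inlet_length / spacing))
  s_in <- s0 - rev(seq_len(n_in)) * (inlet_length / n_in)
  P_in <- matrix(rep(f0$P[1, ], n_in), n_in, 3, byrow = TRUE) +
    (s_in - s0) %o% f0$T[1, ]
  blend_in <- smoothstep((s0 - s_in) / min(2 * D, inlet_length))
  R_in <- matrix(0, n_in, M)
  for (j in seq_len(n_in))
    R_in[j, ] <- (1 - blend_in[j]) * surf$R[1, ] + blend_in[j] * r_in

  # ---- outlet: cubic-eased bend of the tangent toward +x
  n_out <- max(2L, ceiling(outlet_length / spacing))
  ds_f <- min(0.05, outlet_length / (20 * n_out))
  s_f <- seq(0, outlet_length, by = ds_f)
  if (s_f[length(s_f)] < outlet_length) s_f <- c(s_f, outlet_length)
  Tn <- f1$T[1, ]; xhat <- c(1, 0, 0)
  Tb <- matrix(0, length(s_f), 3)
  for (m in seq_along(s_f)) {
    wgt <- smoothstep(s_f[m] / outlet_length)
    tv <- (1 - wgt) * Tn + wgt * xhat
    Tb[m, ] <- tv / sqrt(sum(tv^2))
  }
  Pb <- matrix(0, length(s_f), 3)
  Pb[1, ] <- f1$P[1, ]
  for (m in 2:length(s_f))
    Pb[m, ] <- Pb[m - 1, ] + 0.5 * (Tb[m - 1, ] + Tb[m, ]) * (s_f[m] - s_f[m - 1])
  # transport e1 through the bend starting from the last clinical frame
  e1b <- matrix(0, length(s_f), 3); e2b <- matrix(0, length(s_f), 3)
  e1b[1, ] <- f1$e1[1, ]; e2b[1, ] <- f1$e2[1, ]
  for (m in 2:length(s_f)) {
    ax <- cross3(Tb[m - 1, ], Tb[m, ]); sa <- sqrt(sum(ax^2))
    e1b[m, ] <- if (sa < 1e-12) e1b[m - 1, ] else
      rotate_about(e1b[m - 1, ], ax / sa,
                   atan2(sa, sum(Tb[m - 1, ] * Tb[m, ])))
    v <- e1b[m, ] - sum(e1b[m, ] * Tb[m, ]) * Tb[m, ]
    e1b[m, ] <- v / sqrt(sum(v^2))
    e2b[m, ] <- cross3(Tb[m, ], e1b[m, ])
  }
  s_out <- s1 + seq_len(n_out) * (outlet_length / n_out)
  fout <- list(s = s1 + s_f, P = Pb, T = Tb, e1 = e1b, e2 = e2b)
  fo <- fine_at(fout, s_out)
  blend_out <- smoothstep((s_out - s1) / min(2 * D, outlet_length))
  R_out <- matrix(0, n_out, M)
  for (j in seq_len(n_out))
    R_out[j, ] <- (1 - blend_out[j]) * surf$R[nrow(surf$R), ] +
                  blend_out[j] * r_out

  # ---- splice fine centerlines
  keep <- surf$cl$s >= s0 - 1e-9 & surf$cl$s <= s1 + 1e-9
  s_fine_in <- seq(s_in[1], s0 - 1e-9, by = min(0.05, spacing / 2))
  P_fine_in <- matrix(rep(f0$P[1, ], length(s_fine_in)), ncol = 3,
                      byrow = TRUE) + (s_fine_in - s0) %o% f0$T[1, ]
  rep_row <- function(v, n) matrix(rep(v, n), n, 3, byrow = TRUE)
  cl2 <- list(
    s = c(s_fine_in, surf$cl$s[keep], fout$s[-1]),
    P = rbind(P_fine_in, surf$cl$P[keep, , drop = FALSE], fout$P[-1, , drop = FALSE]),
    T = rbind(rep_row(f0$T[1, ], length(s_fine_in)),
              surf$cl$T[keep, , drop = FALSE], fout$T[-1, , drop = FALSE]),
    e1 = rbind(rep_row(f0$e1[1, ], length(s_fine_in)),
               surf$cl$e1[keep, , drop = FALSE], fout$e1[-1, , drop = FALSE]),
    e2 = rbind(rep_row(f0$e2[1, ], length(s_fine_in)),
               surf$cl$e2[keep, , drop = FALSE], fout$e2[-1, , drop = FALSE]))

  out <- surf
  out$s_grid <- c(s_in, surf$s_grid, s_out)
  out$R <- rbind(R_in, surf$R, R_out)
  out$cl <- cl2
  out$segment <- c(rep("inlet", n_in), surf$segment, rep("outlet", n_out))
  out$inlet_radius <- r_in
  out
}

#' Signed distance from points to the lumen surface
#'
#' Negative inside the lumen, positive in the wall, zero on the surface.
#' Distances are evaluated radially in the normal plane of the nearest
#' centerline point, which is exact for circular cross-sections and
#' accurate to the contour deviation from circularity otherwise.
#'
#' @param surf an `artery_surface`.
#' @param pts n x 3 matrix of query points (mm).
#' @return numeric vector of signed distances (mm).
#' @export
signed_distance <- function(surf, pts) {
  stopifnot(inherits(surf, "artery_surface"))
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_tube_signed_distance(pts, surf$cl$P, surf$cl$e1, surf$cl$e2,
                           surf$cl$s, surf$s_grid, surf$R)
}

# wall sample points, inward normals and (s, theta) bin ids for the solver
# and the WSS module.  Normals from the parametric surface derivatives.
surface_wall_samples <- function(surf, stations = surf$s_grid,
                                 n_theta = length(surf$theta)) {
  M <- length(surf$theta)
  kk <- if (n_theta == M) seq_len(M) else
    round(seq(1, M + 1 - M / n_theta, length.out = n_theta))
  th <- surf$theta[kk]
  fa <- fine_at(surf$cl, stations)
  Rt <- interp_radius_table(surf, stations)
  ns <- length(stations)
  pts <- matrix(0, ns * n_theta, 3)
  nrm <- matrix(0, ns * n_theta, 3)
  sbin <- integer(ns * n_theta); tbin <- integer(ns * n_theta)
  eps_s <- max(diff(range(stations)) / (10 * ns), 1e-3)
  fa_p <- fine_at(surf$cl, stations + eps_s)
  fa_m <- fine_at(surf$cl, stations - eps_s)
  Rp <- interp_radius_table(surf, stations + eps_s)
  Rm <- interp_radius_table(surf, stations - eps_s)
  dth <- 1e-3
  Rt_p <- theta_interp(surf, stations, th + dth)
  Rt_m <- theta_interp(surf, stations, th - dth)
  for (j in seq_len(ns)) {
    cdir <- cos(th) %o% fa$e1[j, ] + sin(th) %o% fa$e2[j, ]
    P <- matrix(rep(fa$P[j, ], n_theta), n_theta, 3, byrow = TRUE) +
      Rt[j, kk] * cdir
    # d/dtheta
    ddth <- (Rt_p[j, ] - Rt_m[j, ]) / (2 * dth)
    tdir <- -sin(th) %o% fa$e1[j, ] + cos(th) %o% fa$e2[j, ]
    dPdt <- ddth * cdir + Rt[j, kk] * tdir
    # d/ds
    Pp <- matrix(rep(fa_p$P[j, ], n_theta), n_theta, 3, byrow = TRUE) +
      Rp[j, kk] * (cos(th) %o% fa_p$e1[j, ] + sin(th) %o% fa_p$e2[j, ])
    Pm <- matrix(rep(fa_m$P[j, ], n_theta), n_theta, 3, byrow = TRUE) +
      Rm[j, kk] * (cos(th) %o% fa_m$e1[j, ] + sin(th) %o% fa_m$e2[j, ])
    dPds <- (Pp - Pm) / (2 * eps_s)
    for (k in seq_len(n_theta)) {
      nn <- cross3(dPdt[k, ], dPds[k, ])
      nn <- nn / sqrt(sum(nn^2))
      if (sum(nn * (fa$P[j, ] - P[k, ])) < 0) nn <- -nn  # point inward
      idx <- (j - 1) * n_theta + k
      pts[idx, ] <- P[k, ]; nrm[idx, ] <- nn
      sbin[idx] <- j; tbin[idx] <- k
    }
  }
  list(points = pts, normals = nrm, s_bin = sbin, theta_bin = tbin,
       stations = stations, thetas = th)
}

theta_interp <- function(surf, stations, th) {
  M <- length(surf$theta)
  Rt <- interp_radius_table(surf, stations)
  out <- matrix(0, length(stations), length(th))
  dtheta <- 2 * pi / M
  for (k in seq_along(th)) {
    t1 <- floor((th[k] %% (2 * pi)) / dtheta)
    f <- (th[k] %% (2 * pi)) / dtheta - t1
    i1 <- (t1 %% M) + 1; i2 <- (t1 + 1) %% M + 1
    out[, k] <- Rt[, i1] * (1 - f) + Rt[, i2] * f
  }
  out
}
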