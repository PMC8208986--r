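# Wall shear stress extraction and the azimuthal / temporal averages.
#
# Notation follows the field convention: <WSS> is the time-only average at
# a wall point; WSS-bar is additionally averaged along the lumen contour in
# each cross-section, with the printed weighting (1/C) * integral of
# <WSS> r dtheta, C being the contour perimeter.

#' Instantaneous wall shear stress on the lumen surface
#'
#' At each wall sample point the tangential velocity is sampled at one and
#' two grid spacings along the inward normal and differentiated with a
#' one-sided second-order stencil (zero velocity at the wall);
#' `WSS = mu * |dU_t/dn|`. Samples whose probes leave the fluid region are
#' flagged invalid (`NA`).
#'
#' @param state a [flow_state()] (or `flow_history`, using its final
#'   fields).
#' @param fluid a [fluid_properties()].
#' @param domain optional `flow_domain` (defaults to the state's).
#' @return a data.frame with `s_mm`, `theta_rad`, `wss_pa`, `valid`.
#' @export
instantaneous_wss <- function(state, fluid, domain = state$domain) {
  wallS <- wall_to_solver(domain)
  if (is.null(wallS)) stop("instantaneous_wss: domain has no wall samples")
  res <- cpp_wall_wss(state$u, state$v, state$w, domain$phi,
                      domain$nx, domain$ny, domain$nz, domain$h,
                      domain$periodic_x, domain$periodic_z, fluid$mu,
                      wallS$points, wallS$normals)
  wss <- res$wss
  wss[res$valid == 0L] <- NA_real_
  data.frame(s_mm = domain$wall$stations[domain$wall$s_bin],
             theta_rad = domain$wall$thetas[domain$wall$theta_bin],
             wss_pa = wss, valid = res$valid == 1L)
}

#' Time-average wall shear stress over full periods
#'
#' Mean of the instantaneous magnitude per wall point over the largest
#' whole number of periods contained in the record (counting back from the
#' final sample). Partial-period records are rejected.
#'
#' @param wss matrix of WSS samples (wall points x record instants) as
#'   stored in a `flow_history`, or the history itself.
#' @param times record times (s); taken from the history when omitted.
#' @param period averaging period T (s); taken from the history waveform.
#' @return vector of time-averaged WSS per wall point (`<WSS>`).
#' @export
time_average_wss <- function(wss, times = NULL, period = NULL) {
  if (inherits(wss, "flow_history")) {
    times <- wss$wss_times
    period <- wss$waveform$period
    wss <- wss$wss
  }
  if (is.null(times) || is.null(period))
    stop("time_average_wss: need record times and the period")
  span <- max(times) - min(times)
  dtr <- if (length(times) > 1) stats::median(diff(times)) else Inf
  n_per <- floor((span + dtr + 1e-9) / period)
  if (n_per < 1)
    stop("time_average_wss: record spans less than one full period")
  sel <- times > max(times) - n_per * period + 1e-12
  rowMeans(wss[, sel, drop = FALSE])
}

#' Azimuthal average of time-averaged wall shear stress (one section)
#'
#' Implements the printed sectional average
#' `WSS_bar = (1/C) * integral_0^2pi <WSS> r dtheta`
#' by the trapezoid rule on the azimuth grid, with `C` the polygon
#' perimeter of the contour. Note that `r dtheta` is not the arclength
#' element for non-circular contours; the exact-arclength variant is
#' available via `weighting = "arclength"`.
#'
#' @param wss_theta `<WSS>` values at the contour azimuths (may contain
#'   `NA` for invalid samples).
#' @param radii contour radii at the same azimuths (any length unit).
#' @param weighting `"r_dtheta"` (printed form, default) or
#'   `"arclength"`.
#' @param max_invalid maximum tolerated fraction of invalid samples before
#'   the result is flagged (`NA` with attribute `flagged`).
#' @return scalar `WSS_bar`.
#' @export
azimuthal_average_wss <- function(wss_theta, radii,
                                  weighting = c("r_dtheta", "arclength"),
                                  max_invalid = 0.1) {
  weighting <- match.arg(weighting)
  M <- length(wss_theta)
  stopifnot(length(radii) == M)
  bad <- !is.finite(wss_theta)
  if (mean(bad) > max_invalid) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  dth <- 2 * pi / M
  # perimeter by periodic trapezoid quadrature of sqrt(r^2 + r'^2) dtheta
  # (consistent with the r dtheta weighting: a circle averages exactly)
  drdth <- (radii[c(2:M, 1)] - radii[c(M, 1:(M - 1))]) / (2 * dth)
  C <- sum(sqrt(radii^2 + drdth^2)) * dth
  if (weighting == "r_dtheta") {
    w <- radii * dth
  } else {
    w <- sqrt(radii^2 + drdth^2) * dth
  }
  # invalid samples contribute the weighted mean of the valid ones
  (sum(w[!bad] * wss_theta[!bad]) / sum(w[!bad])) * (sum(w) / C)
}

#' Sectional wall shear stress profile of a run
#'
#' Combines the per-sample time averages of a `flow_history` into the
#' per-section average `WSS_bar(s)` and returns the `(s, theta)` resolved
#' time averages alongside.
#'
#' @param history a `flow_history`.
#' @param weighting passed to [azimuthal_average_wss()].
#' @return a list with `profile` (data.frame `s_mm`, `wss_bar_pa`) and
#'   `time_avg` (matrix stations x azimuths of `<WSS>`).
#' @export
wss_profile <- function(history, weighting = "r_dtheta") {
  domain <- history$domain
  wall <- domain$wall
  tavg <- time_average_wss(history)
  tavg[history$wss_valid == 0L] <- NA_real_
  ns <- length(wall$stations)
  nt <- length(wall$thetas)
  m <- matrix(NA_real_, ns, nt)
  m[cbind(wall$s_bin, wall$theta_bin)] <- tavg
  wb <- numeric(ns)
  for (j in seq_len(ns)) {
    rad <- sample_radii(domain, j)
    wb[j] <- azimuthal_average_wss(m[j, ], rad, weighting = weighting)
  }
  list(profile = data.frame(s_mm = wall$stations, wss_bar_pa = wb),
       time_avg = m)
}

# contour radii at the wall-sample azimuths of station j
sample_radii <- function(domain, j) {
  wall <- domain$wall
  nt <- length(wall$thetas)
  if (domain$type == "channel2d") return(rep(domain$gap_profile[j] / 2, nt))
  if (domain$type == "pipe_periodic") return(rep(domain$radius, nt))
  surf <- domain$surface
  as.numeric(theta_interp(surf, wall$stations[j], wall$thetas))
}

# wall bin areas (m^2): station spacing times local contour arc per sample
wall_bin_areas <- function(domain) {
  wall <- domain$wall
  st <- wall$stations
  ds <- if (length(st) > 1) {
    d <- diff(st)
    c(d[1], (d[-1] + d[-length(d)]) / 2, d[length(d)])
  } else domain$h_mm
  nt <- length(wall$thetas)
  areas <- numeric(length(wall$s_bin))
  for (j in seq_along(st)) {
    arc <- if (domain$type == "channel2d") domain$h_mm else {
      rad <- sample_radii(domain, j)
      th <- 2 * pi * (0:(length(rad) - 1)) / length(rad)
      x <- rad * cos(th); y <- rad * sin(th)
      sum(sqrt((c(x[-1], x[1]) - x)^2 + (c(y[-1], y[1]) - y)^2)) / nt
    }
    areas[wall$s_bin == j] <- ds[j] * arc * MM^2
  }
  areas
}
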