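# Fluid properties and the pulsatile inflow waveform.

#' Blood fluid properties
#'
#' Newtonian fluid model. Defaults are standard whole-blood values
#' (density 1060 kg/m^3, dynamic viscosity 3.5 mPa s); both are
#' configurable.
#'
#' @param density_kg_m3 fluid density (kg/m^3).
#' @param viscosity_pa_s dynamic viscosity (Pa s).
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 3.5e-3) {
  if (density_kg_m3 <= 0) stop("fluid_properties: density must be positive")
  if (viscosity_pa_s <= 0) stop("fluid_properties: viscosity must be positive")
  structure(list(rho = density_kg_m3, mu = viscosity_pa_s,
                 nu = viscosity_pa_s / density_kg_m3),
            class = "fluid_properties")
}

#' Pulsatile bulk-velocity waveform
#'
#' A periodic table of bulk velocity versus time over one cardiac period,
#' evaluated by periodic linear interpolation. The first and last samples
#' must agree (periodicity); the tabulated mean over the period must match
#' `u_mean` within 0.1% (the table is rescaled to the exact mean when
#' `rescale = TRUE`).
#'
#' @param times sample times (s), strictly increasing, spanning `[0, T]`.
#' @param velocities bulk velocities (m/s) at `times`.
#' @param u_mean target mean bulk velocity (m/s); `NULL` keeps the
#'   tabulated mean.
#' @param rescale rescale velocities so the interpolant mean is exactly
#'   `u_mean`.
#' @return an object of class `pulsatile_waveform`.
#' @export
pulsatile_waveform <- function(times, velocities, u_mean = NULL,
                               rescale = !is.null(u_mean)) {
  times <- as.numeric(times); velocities <- as.numeric(velocities)
  if (length(times) != length(velocities) || length(times) < 2)
    stop("pulsatile_waveform: need matching times/velocities, length >= 2")
  if (any(diff(times) <= 0))
    stop("pulsatile_waveform: times must be strictly increasing")
  if (abs(velocities[1] - velocities[length(velocities)]) >
      1e-9 * max(1e-12, max(abs(velocities))))
    stop("pulsatile_waveform: first and last samples must agree (periodic)")
  period <- times[length(times)] - times[1]
  times <- times - times[1]
  # trapezoid mean of the linear interpolant
  tab_mean <- sum(diff(times) * (velocities[-1] + velocities[-length(velocities)]) / 2) / period
  if (!is.null(u_mean)) {
    if (rescale) {
      velocities <- velocities * (u_mean / tab_mean)
      tab_mean <- u_mean
    } else if (abs(tab_mean - u_mean) > 1e-3 * abs(u_mean)) {
      stop("pulsatile_waveform: tabulated mean ", signif(tab_mean, 6),
           " differs from u_mean ", u_mean, " by more than 0.1%")
    }
  }
  structure(list(times = times, velocities = velocities, period = period,
                 u_mean = tab_mean),
            class = "pulsatile_waveform")
}

#' Default triphasic coronary waveform
#'
#' A three-phase coronary pulse over one cardiac period: a moderate
#' systolic peak, a brief reversal at end-systole, and the dominant
#' diastolic peak. The published study states only the period
#' (T = 0.8 s) and the mean bulk velocity (0.384 m/s); the tabulated
#' shape here is a representative left-coronary pulse rescaled so that
#' its interpolant mean is exactly `u_mean`.
#'
#' @param u_mean mean bulk velocity over the cycle (m/s).
#' @param period cardiac period (s).
#' @return a [pulsatile_waveform()].
#' @export
default_waveform <- function(u_mean = 0.384, period = 0.8) {
  frac <- c(0.00, 0.04, 0.10, 0.16, 0.21, 0.245, 0.27, 0.30, 0.34,
            0.40, 0.48, 0.56, 0.66, 0.76, 0.86, 0.94, 1.00)
  shape <- c(0.35, 0.72, 1.05, 0.78, 0.22, -0.12, -0.18, 0.05, 0.55,
             1.30, 1.72, 1.80, 1.55, 1.18, 0.80, 0.50, 0.35)
  pulsatile_waveform(frac * period, shape, u_mean = u_mean, rescale = TRUE)
}

#' Steady (constant) waveform
#' @param u_bulk constant bulk velocity (m/s).
#' @param period nominal period used for averaging windows (s).
#' @return a [pulsatile_waveform()].
#' @export
constant_waveform <- function(u_bulk, period = 0.8) {
  pulsatile_waveform(c(0, period), c(u_bulk, u_bulk))
}

#' Evaluate a waveform at arbitrary times
#'
#' Periodic linear interpolation: `waveform_eval(w, t)` equals
#' `waveform_eval(w, t + T)` for any `t`.
#'
#' @param w a [pulsatile_waveform()].
#' @param t time or vector of times (s).
#' @return bulk velocity (m/s).
#' @export
waveform_eval <- function(w, t) {
  stopifnot(inherits(w, "pulsatile_waveform"))
  tm <- t - w$period * floor(t / w$period)
  stats::approx(w$times, w$velocities, xout = tm)$y
}

#' Parabolic inlet velocity profile
#'
#' Axial velocity on a circular inlet cross-section enforcing the given
#' bulk velocity: `u(r) = 2 U_bulk (1 - (r/R)^2)`, zero transverse
#' components; the sectional mean equals `U_bulk`.
#'
#' @param u_bulk bulk velocity (m/s).
#' @param radius inlet radius R (same length unit as `r`).
#' @param r radial coordinate(s), `0 <= r`.
#' @return axial velocity at `r` (0 outside the lumen).
#' @export
inlet_profile <- function(u_bulk, radius, r) {
  if (radius <= 0) stop("inlet_profile: radius must be positive")
  ifelse(r <= radius, 2 * u_bulk * (1 - (r / radius)^2), 0)
}
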