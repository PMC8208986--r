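# Synthetic study generator: baseline contour frames with a localized
# stenosis on a tortuous centerline, and follow-up frames whose area
# change is a controlled function of a supplied adhesion profile plus
# noise. Emulates a 0.5 mm motorized-pullback acquisition so every
# pipeline stage is testable without clinical data.

#' Synthetic study specification
#'
#' The stated world of the generator: a coronary-sized vessel (mean
#' diameter 2 mm) imaged every 0.5 mm, with one localized stenosis, a
#' smooth tortuous centerline, mild contour non-circularity, and
#' follow-up growth proportional to adhesion plus Gaussian noise.
#'
#' @param diameter mean healthy diameter D (mm).
#' @param n_frames number of pullback frames.
#' @param frame_spacing pullback spacing (mm).
#' @param sten_center arclength of minimum lumen area (mm).
#' @param severity fractional area reduction in `[0, 1)`.
#' @param sten_extent axial extent of the stenosis (mm).
#' @param tort_amplitude lateral centerline amplitude (mm); 0 gives a
#'   straight vessel.
#' @param tort_wavelength lateral wavelength (mm).
#' @param contour_noise relative amplitude of smooth low-order contour
#'   perturbations (0 gives circles).
#' @param n_theta contour azimuthal resolution.
#' @param growth_gain alpha: follow-up area loss per unit (nondimensional)
#'   adhesion rate (mm^2).
#' @param growth_noise sigma of the Gaussian area noise (mm^2).
#' @param seed RNG seed; identical seeds give identical studies.
#' @return an object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(diameter = 2, n_frames = 40L,
                                 frame_spacing = 0.5, sten_center = 10,
                                 severity = 0.4, sten_extent = 6,
                                 tort_amplitude = 0.4,
                                 tort_wavelength = 10,
                                 contour_noise = 0.03, n_theta = 64L,
                                 growth_gain = 1, growth_noise = 0.1,
                                 seed = 1L) {
  if (severity < 0 || severity >= 1)
    stop("synthetic_study_spec: severity must be in [0, 1)")
  if (contour_noise < 0 || growth_noise < 0)
    stop("synthetic_study_spec: noise amplitudes must be non-negative")
  structure(list(diameter = diameter, n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, sten_center = sten_center,
                 severity = severity, sten_extent = sten_extent,
                 tort_amplitude = tort_amplitude,
                 tort_wavelength = tort_wavelength,
                 contour_noise = contour_noise, n_theta = as.integer(n_theta),
                 growth_gain = growth_gain, growth_noise = growth_noise,
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate the synthetic baseline study
#'
#' Frames are smoothly perturbed circles rescaled so each polygon area
#' matches the prescribed healthy-stenotic-healthy area profile exactly;
#' the centerline is a smooth 3D curve that starts x-parallel (so the
#' inlet extension is axis-aligned) with the prescribed lateral
#' amplitude. Deterministic under the spec seed.
#'
#' @param spec a [synthetic_study_spec()].
#' @return list with `frames` (list of [contour_frame()]), `centerline`
#'   (an [centerline()]), and `area` (the target area profile, mm^2).
#' @export
synth_baseline <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  sj <- (seq_len(n) - 1L) * spec$frame_spacing
  A0 <- pi * (spec$diameter / 2)^2
  xi <- (sj - spec$sten_center) / spec$sten_extent
  shape <- ifelse(abs(xi) < 0.5, cos(pi * xi)^2, 0)
  area <- A0 * (1 - spec$severity * shape)

  # smooth low-order Fourier contour perturbations, coherent along s
  M <- spec$n_theta
  th <- 2 * pi * (0:(M - 1)) / M
  modes <- 2:4
  amp <- matrix(stats::rnorm(length(modes) * 2), length(modes), 2)
  phase_drift <- stats::runif(length(modes), 0, 2 * pi)
  frames <- vector("list", n)
  for (j in seq_len(n)) {
    pert <- rep(0, M)
    if (spec$contour_noise > 0) {
      for (mi in seq_along(modes)) {
        m <- modes[mi]
        wob <- sin(2 * pi * sj[j] / (4 * spec$tort_wavelength) +
                   phase_drift[mi])
        pert <- pert + spec$contour_noise *
          (amp[mi, 1] * cos(m * th) + amp[mi, 2] * sin(m * th)) *
          (0.6 + 0.4 * wob)
      }
    }
    if (min(1 + pert) <= 0.25)
      stop("synth_baseline: contour noise so large the contour ",
           "self-degenerates; reduce contour_noise")
    radii <- sqrt(area[j] / pi) * (1 + pert)
    f <- contour_frame(j, sj[j], radii)
    # rescale so the polygon area matches the target exactly
    radii <- radii * sqrt(area[j] / frame_area(f))
    frames[[j]] <- contour_frame(j, sj[j], radii)
  }

  # centerline: lateral offsets with zero slope at x = 0 (inlet stays
  # x-parallel); the x extent is padded so the arclength range covers all
  # frame positions (frames sit at exact 0.5 mm arclength spacing)
  L <- sj[n]
  xs <- seq(0, 1.2 * L + 1, by = min(0.1, spec$frame_spacing / 2))
  y <- spec$tort_amplitude * sin(pi * xs / spec$tort_wavelength)^2
  z <- 0.6 * spec$tort_amplitude *
    sin(pi * xs / (1.45 * spec$tort_wavelength))^2
  cl <- centerline(cbind(xs, y, z))
  list(frames = frames, centerline = cl, area = area, s = sj)
}

#' Generate follow-up frames from an adhesion profile
#'
#' Follow-up areas are `A_b(s) - alpha * Rbar(s) - eps`, with Gaussian
#' noise `eps ~ N(0, sigma_g)` truncated so areas stay above 5% of
#' baseline; contours shrink isotropically. With `alpha = 0` and zero
#' noise the follow-up equals the baseline.
#'
#' @param frames baseline frames (list of [contour_frame()]).
#' @param adhesion data.frame with `s_mm` and `rate_nondim` (or a numeric
#'   vector on the frame grid) covering the frame range.
#' @param spec a [synthetic_study_spec()] (supplies `growth_gain`,
#'   `growth_noise`, and the seed offset).
#' @param seed RNG seed for the growth noise; defaults to `spec$seed + 1`.
#' @return list of follow-up [contour_frame()]s.
#' @export
synth_followup <- function(frames, adhesion, spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  if (spec$growth_gain < 0) stop("synth_followup: alpha must be >= 0")
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  sj <- vapply(frames, function(f) f$s, 0)
  rbar <- if (is.numeric(adhesion)) {
    if (length(adhesion) != length(sj))
      stop("synth_followup: adhesion vector length must match frames")
    adhesion
  } else {
    if (min(adhesion$s_mm) > min(sj) + 1e-6 ||
        max(adhesion$s_mm) < max(sj) - 1e-6)
      stop("synth_followup: adhesion profile does not cover the frames")
    stats::approx(adhesion$s_mm, adhesion$rate_nondim, xout = sj,
                  rule = 2)$y
  }
  ab <- vapply(frames, frame_area, 0)
  eps <- stats::rnorm(length(sj), 0, spec$growth_noise)
  af <- ab - spec$growth_gain * rbar - eps
  floor_a <- 0.05 * ab
  truncated <- af < floor_a
  af[truncated] <- floor_a[truncated]
  if (mean(truncated) > 0.2)
    warning("synth_followup: growth gain so large that the area floor ",
            "was hit at more than 20% of frames")
  lapply(seq_along(frames), function(j) {
    f <- frames[[j]]
    contour_frame(f$index, f$s, f$radii * sqrt(af[j] / ab[j]))
  })
}
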