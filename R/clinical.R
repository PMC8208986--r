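# Baseline vs follow-up lumen-area comparison and the correlation between
# predicted adhesion and lumen-area change.
#
# Sign convention: delta_A = A_baseline - A_followup, positive where the
# lumen narrowed (plaque growth). The correlation coefficient uses the
# population (1/N) normalization in the mean and standard deviation, as
# printed; the ratio is unaffected but the reported sigmas differ from the
# 1/(N-1) sample convention.

#' Baseline / follow-up lumen-area series
#'
#' @param s frame positions (mm), strictly increasing, N >= 3.
#' @param area_baseline,area_followup lumen areas (mm^2), positive.
#' @return an object of class `lumen_series` with the `delta` component
#'   `A_baseline - A_followup`.
#' @export
lumen_series <- function(s, area_baseline, area_followup) {
  s <- as.numeric(s)
  if (length(s) < 3) stop("lumen_series: need at least 3 frames")
  if (any(diff(s) <= 0)) stop("lumen_series: s must be strictly increasing")
  if (length(area_baseline) != length(s) ||
      length(area_followup) != length(s))
    stop("lumen_series: length mismatch")
  if (any(area_baseline <= 0) || any(area_followup <= 0))
    stop("lumen_series: areas must be positive")
  structure(list(s = s, area_baseline = as.numeric(area_baseline),
                 area_followup = as.numeric(area_followup),
                 delta = as.numeric(area_baseline - area_followup)),
            class = "lumen_series")
}

#' Lumen-area change between two contour-frame series
#'
#' Areas are evaluated with [frame_area()]; follow-up areas are
#' interpolated linearly in `s` onto the baseline frame positions over the
#' overlapping range.
#'
#' @param baseline,followup lists of [contour_frame()]s.
#' @return a [lumen_series()] on the (overlapping) baseline positions.
#' @export
delta_lumen <- function(baseline, followup) {
  sb <- vapply(baseline, function(f) f$s, 0)
  sf <- vapply(followup, function(f) f$s, 0)
  ab <- vapply(baseline, frame_area, 0)
  af <- vapply(followup, frame_area, 0)
  lo <- max(min(sb), min(sf)); hi <- min(max(sb), max(sf))
  keep <- sb >= lo - 1e-9 & sb <= hi + 1e-9
  if (sum(keep) < 3)
    stop("delta_lumen: fewer than 3 baseline frames in the overlapping ",
         "s range")
  af_i <- stats::approx(sf, af, xout = sb[keep])$y
  lumen_series(sb[keep], ab[keep], af_i)
}

#' Correlation between predicted adhesion and lumen-area change
#'
#' Pearson correlation with population (1/N) mean and standard deviation,
#' computed over all frames along the artery. The adhesion profile is
#' first registered to the frame positions by averaging within each
#' frame's s-bin (+-half frame spacing); frames whose bin contains no
#' adhesion sample fall back to linear interpolation.
#'
#' @param adhesion data.frame with `s_mm` and a rate column (output of
#'   [adhesion_profile()]), or a numeric vector already on the frame grid.
#' @param series a [lumen_series()].
#' @param rate_col column of `adhesion` to use.
#' @return an object of class `correlation_result`: `rho`, means, sigmas
#'   (1/N convention), `n`.
#' @export
correlate_adhesion <- function(adhesion, series, rate_col = "rate") {
  stopifnot(inherits(series, "lumen_series"))
  sj <- series$s
  if (is.numeric(adhesion)) {
    if (length(adhesion) != length(sj))
      stop("correlate_adhesion: adhesion vector length must match frames")
    rbar <- as.numeric(adhesion)
  } else {
    sa <- adhesion$s_mm
    ra <- adhesion[[rate_col]]
    half <- if (length(sj) > 1) stats::median(diff(sj)) / 2 else Inf
    rbar <- vapply(sj, function(s0) {
      sel <- abs(sa - s0) <= half
      if (any(sel)) mean(ra[sel]) else
        stats::approx(sa, ra, xout = s0, rule = 2)$y
    }, 0)
  }
  pearson_population(rbar, series$delta)
}

# Pearson coefficient with explicit 1/N moments; errors on zero variance
pearson_population <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  if (sx == 0 || sy == 0)
    stop("correlate_adhesion: zero variance in an input; ",
         "the correlation coefficient is undefined")
  rho <- sum((x - mx) * (y - my)) / n / (sx * sy)
  structure(list(rho = rho, mean_x = mx, mean_y = my,
                 sd_x = sx, sd_y = sy, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation rho = %.4f (N = %d)\n", x$rho, x$n))
  cat(sprintf("  adhesion: mean %.4g, sigma %.4g (1/N)\n", x$mean_x, x$sd_x))
  cat(sprintf("  delta A:  mean %.4g, sigma %.4g (1/N)\n", x$mean_y, x$sd_y))
  invisible(x)
}

#' Summary statistics of a lumen-area change series
#'
#' @param series a [lumen_series()].
#' @return list with `mean_delta` (average along the centerline) and
#'   `max_delta` (mm^2).
#' @export
summarize_change <- function(series) {
  stopifnot(inherits(series, "lumen_series"))
  list(mean_delta = mean(series$delta), max_delta = max(series$delta))
}
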