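# Temporal and azimuthal wall shear averaging.

test_that("time averaging: constants, sinusoids, periodic idempotence", {
  TT <- 0.8
  tt <- seq(TT / 200, 4 * TT, by = TT / 200)
  # constant signal
  m <- matrix(3.2, 1, length(tt))
  expect_equal(time_average_wss(m, tt, TT), 3.2, tolerance = 1e-12)
  # sinusoid a + b sin over whole periods -> a
  a <- 2; b <- 1.2
  m2 <- rbind(a + b * sin(2 * pi * tt / TT))
  expect_equal(time_average_wss(m2, tt, TT), a, tolerance = 1e-6)
  # two periods of identical data give the same result as one
  one <- tt <= TT
  expect_equal(time_average_wss(m2[, one, drop = FALSE], tt[one], TT),
               time_average_wss(m2[, tt <= 2 * TT, drop = FALSE],
                                tt[tt <= 2 * TT], TT),
               tolerance = 1e-12)
  # partial-period records rejected
  expect_error(time_average_wss(m2[, 1:50, drop = FALSE], tt[1:50], TT),
               "less than one full period")
})

test_that("azimuthal average: circle closed forms and ellipse quadrature", {
  M <- 256
  th <- 2 * pi * (0:(M - 1)) / M
  # circular contour, constant field -> the constant
  expect_equal(azimuthal_average_wss(rep(2.5, M), rep(1.3, M)), 2.5,
               tolerance = 1e-9)
  # circular contour, a + b cos(theta) -> a
  expect_equal(azimuthal_average_wss(3 + 0.8 * cos(th), rep(1, M)), 3,
               tolerance = 1e-9)
  # elliptical contour, constant c: (1/C) * int c r dtheta != c;
  # oracle by dense quadrature of the printed weighting
  aa <- 1.5; bb <- 0.7
  r_ell <- function(t) aa * bb / sqrt((bb * cos(t))^2 + (aa * sin(t))^2)
  num <- stats::integrate(function(t) 4.0 * r_ell(t), 0, 2 * pi,
                          subdivisions = 2000L)$value
  Cper <- stats::integrate(function(t) {
    # arclength element of the polar curve
    eps <- 1e-6
    dr <- (r_ell(t + eps) - r_ell(t - eps)) / (2 * eps)
    sqrt(r_ell(t)^2 + dr^2)
  }, 0, 2 * pi, subdivisions = 2000L)$value
  oracle <- num / Cper
  got <- azimuthal_average_wss(rep(4.0, M), r_ell(th))
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_true(abs(got - 4.0) > 0.05)  # genuinely differs from c
  # arclength variant recovers the constant exactly
  expect_equal(azimuthal_average_wss(rep(4.0, M), r_ell(th),
                                     weighting = "arclength"),
               4.0, tolerance = 1e-9)
})

test_that("too many invalid samples flag the sectional average", {
  M <- 32
  w <- rep(1, M); w[1:5] <- NA  # > 10% invalid
  out <- azimuthal_average_wss(w, rep(1, M))
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "flagged")))
  # a single invalid sample is tolerated
  w2 <- rep(1, M); w2[3] <- NA
  expect_equal(azimuthal_average_wss(w2, rep(1, M)), 1, tolerance = 1e-9)
})

test_that("averaging commutes: time-then-azimuth equals azimuth-then-time", {
  set.seed(8)
  M <- 24; nt <- 40
  TT <- 1
  tt <- seq(TT / nt, TT, by = TT / nt)
  radii <- 1 + 0.1 * cos(2 * 2 * pi * (0:(M - 1)) / M)
  wss <- matrix(abs(rnorm(M * nt, 2, 0.5)), M, nt)
  t_then_a <- azimuthal_average_wss(time_average_wss(wss, tt, TT), radii)
  a_then_t <- mean(vapply(seq_len(nt), function(k)
    azimuthal_average_wss(wss[, k], radii), 0))
  expect_equal(t_then_a, a_then_t, tolerance = 1e-12)
})

test_that("instantaneous WSS matches closed forms on steady flows", {
  # plane Poiseuille: wall value 6 mu U / h on both walls
  hist <- channel_poiseuille(32L)
  fl <- fluid_properties()
  df <- instantaneous_wss(hist, fl)
  tau_ex <- channel_exact(hist$domain)$tau
  expect_lt(max(abs(df$wss_pa[df$valid] / tau_ex - 1)), 0.03)
  # pipe Poiseuille: 4 mu U / R within 5% at 24 cells per diameter
  ph <- pipe_poiseuille()
  tau_pipe <- 4 * fl$mu * 0.05 / 1e-3
  expect_lt(max(abs(ph$wss_mean / tau_pipe - 1)), 0.05)
  # zero-velocity state gives exactly zero
  dom <- channel_domain(gap = 2, length = 4, cells_per_gap = 8)
  z <- instantaneous_wss(flow_state(dom), fl)
  expect_identical(max(abs(z$wss_pa[z$valid])), 0)
})

test_that("wss_profile reduces a history to a sectional profile", {
  hist <- channel_poiseuille(32L)
  wp <- wss_profile(hist)
  tau_ex <- channel_exact(hist$domain)$tau
  expect_lt(max(abs(wp$profile$wss_bar_pa / tau_ex - 1)), 0.03)
  expect_equal(dim(wp$time_avg),
               c(length(hist$domain$wall$stations), 2L))
})
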