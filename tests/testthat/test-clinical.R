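# Lumen-area change and the correlation machinery.

test_that("delta_lumen: identity, closed-form shrink, interpolation", {
  mk <- function(s, r) lapply(seq_along(s), function(j)
    contour_frame(j, s[j], rep(r[j], 64)))
  s <- seq(0, 5, 0.5)
  base <- mk(s, rep(1, length(s)))
  # identical series: delta == 0
  ident <- delta_lumen(base, base)
  expect_equal(ident$delta, rep(0, length(s)), tolerance = 1e-12)
  # one frame shrinks 1.0 -> 0.9 mm: delta = pi(1 - 0.81) up to polygon
  r2 <- rep(1, length(s)); r2[4] <- 0.9
  shr <- delta_lumen(base, mk(s, r2))
  expect_equal(shr$delta[4], pi * (1 - 0.81), tolerance = 2e-3)
  expect_equal(sum(shr$delta[-4]), 0, tolerance = 1e-12)
  # follow-up offset by half a spacing: linear area profile interpolates
  # to midpoint averages
  a_lin <- 2 + 0.1 * s
  base_lin <- mk(s, sqrt(a_lin / pi))
  fup <- mk(s + 0.25, sqrt((2 + 0.1 * (s + 0.25)) / pi))
  dl <- delta_lumen(base_lin, fup)
  keep <- dl$s >= min(s + 0.25)
  # interpolated follow-up area at s_j = mean of areas at s_j +- 0.25
  a_f <- vapply(dl$s, function(x) 2 + 0.1 * x, 0)
  expect_equal(dl$area_followup, a_f, tolerance = 2e-3)
  # non-overlapping ranges rejected
  expect_error(delta_lumen(base, mk(s + 100, rep(1, length(s)))),
               "overlap")
})

test_that("correlation: exact limits and brute-force Pearson oracle", {
  s <- seq(0, 3, 0.5)
  x <- c(0.1, 0.5, 1.2, 0.8, 0.3, 0.9, 0.2)
  series <- lumen_series(s, rep(4, 7), 4 - x)  # delta = x
  expect_equal(correlate_adhesion(x, series)$rho, 1, tolerance = 1e-12)
  series_neg <- lumen_series(s, rep(4, 7), 4 + x)
  expect_equal(correlate_adhesion(x, series_neg)$rho, -1,
               tolerance = 1e-12)
  # printed-formula evaluation on a worked example
  r <- c(0, 1, 2, 1); d <- c(0.1, 0.9, 1.2, 0.2)
  mu_r <- mean(r); mu_d <- mean(d)
  sig_r <- sqrt(mean((r - mu_r)^2)); sig_d <- sqrt(mean((d - mu_d)^2))
  rho_hand <- mean((r - mu_r) * (d - mu_d)) / (sig_r * sig_d)
  got <- leukoflow:::pearson_population(r, d)
  expect_equal(got$rho, rho_hand, tolerance = 1e-15)
  expect_equal(got$sd_x, sig_r)   # 1/N convention, not 1/(N-1)
  expect_true(abs(got$sd_x - sd(r)) > 1e-6)
  # against R's textbook implementation on many random pairs
  set.seed(10)
  worst <- 0
  for (i in 1:10000) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    worst <- max(worst,
                 abs(leukoflow:::pearson_population(a, b)$rho - cor(a, b)))
  }
  expect_lt(worst, 1e-12)
})

test_that("correlation affine invariance and zero-variance error", {
  set.seed(11)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- leukoflow:::pearson_population(x, y)$rho
  expect_equal(leukoflow:::pearson_population(3 * x + 7, y)$rho, r0,
               tolerance = 1e-12)
  expect_equal(leukoflow:::pearson_population(-2 * x + 1, y)$rho, -r0,
               tolerance = 1e-12)
  s <- seq(0, 3, length.out = 25)
  series <- lumen_series(s, rep(4, 25), 4 - abs(y) - 0.1)
  expect_error(correlate_adhesion(rep(1, 25), series), "zero variance")
})

test_that("adhesion-to-frame registration averages within s bins", {
  # adhesion sampled 4x finer than the frames: bin means, not point values
  sf <- seq(0, 4, by = 0.125)
  prof <- data.frame(s_mm = sf, rate = sf^2)
  s <- seq(0, 4, by = 0.5)
  series <- lumen_series(s, rep(8, 9), 8 - (1 + s))
  res <- correlate_adhesion(prof, series)
  # bin-averaged s^2 is still monotone in s: strong positive correlation
  expect_gt(res$rho, 0.95)
  expect_equal(res$n, 9)
})

test_that("summarize_change", {
  s <- c(0, 1, 2)
  expect_equal(summarize_change(lumen_series(s, c(4, 4, 4), c(3, 3, 3))),
               list(mean_delta = 1, max_delta = 1))
  sc <- summarize_change(lumen_series(s, c(4, 5, 3), c(4, 4, 4)))
  expect_equal(sc$mean_delta, 0)
  expect_equal(sc$max_delta, 1)
})

test_that("lumen series validation", {
  expect_error(lumen_series(c(0, 1), c(1, 1), c(1, 1)), "at least 3")
  expect_error(lumen_series(c(0, 1, 0.5), rep(1, 3), rep(1, 3)),
               "increasing")
  expect_error(lumen_series(0:2, c(1, -1, 1), rep(1, 3)), "positive")
})
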