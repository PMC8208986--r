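# Synthetic study generator: determinism, construction identities, and
# parameter recovery through the correlation stage.

test_that("generator is deterministic under the seed", {
  spec <- synthetic_study_spec(seed = 123L)
  a <- synth_baseline(spec)
  b <- synth_baseline(spec)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- synth_baseline(synthetic_study_spec(seed = 124L))
  expect_false(identical(a$frames, c2$frames))
})

test_that("baseline construction identities", {
  # zero noise, zero tortuosity, severity 0: straight cylinder
  spec0 <- synthetic_study_spec(severity = 0, tort_amplitude = 0,
                                contour_noise = 0, n_frames = 10L)
  st0 <- synth_baseline(spec0)
  expect_equal(tortuosity(st0$centerline), 1, tolerance = 1e-9)
  areas <- vapply(st0$frames, frame_area, 0)
  expect_equal(areas, rep(areas[1], 10), tolerance = 1e-12)
  rr <- unlist(lapply(st0$frames, function(f) f$radii))
  expect_equal(range(rr), rep(rr[1], 2), tolerance = 1e-12)

  # severity 0.5: minimum area is half the healthy area, at the frame
  # nearest the stenosis centre (exact by construction, even with noise)
  spec1 <- synthetic_study_spec(severity = 0.5, contour_noise = 0.04,
                                sten_center = 10, seed = 2L)
  st1 <- synth_baseline(spec1)
  a1 <- vapply(st1$frames, frame_area, 0)
  A0 <- pi * (spec1$diameter / 2)^2
  expect_equal(min(a1), 0.5 * A0, tolerance = 1e-9)
  expect_equal(st1$s[which.min(a1)], 10, tolerance = 0.26)

  # positive tortuosity amplitude gives tortuosity > 1
  expect_gt(tortuosity(st1$centerline), 1)
})

test_that("follow-up: identity at alpha = 0, exact correlation at zero noise", {
  spec <- synthetic_study_spec(seed = 5L, contour_noise = 0.03)
  st <- synth_baseline(spec)
  rbar <- bump_profile(st$s)
  # alpha = 0, sigma = 0: follow-up identical to baseline
  spec0 <- synthetic_study_spec(seed = 5L, contour_noise = 0.03,
                                growth_gain = 0, growth_noise = 0)
  fup0 <- synth_followup(st$frames, rbar, spec0)
  expect_equal(vapply(fup0, frame_area, 0),
               vapply(st$frames, frame_area, 0), tolerance = 1e-12)
  # alpha > 0, sigma = 0: correlation exactly 1
  specA <- synthetic_study_spec(seed = 5L, contour_noise = 0.03,
                                growth_gain = 0.8, growth_noise = 0)
  fupA <- synth_followup(st$frames, rbar, specA)
  series <- delta_lumen(st$frames, fupA)
  expect_equal(correlate_adhesion(rbar, series)$rho, 1, tolerance = 1e-9)
  # truncation warning when alpha crushes most of the lumen
  specX <- synthetic_study_spec(seed = 5L, growth_gain = 50,
                                growth_noise = 0)
  expect_warning(synth_followup(st$frames, rbar, specX), "floor")
})

test_that("noise attenuates the correlation like 1/sqrt(1 + var ratio)", {
  spec <- synthetic_study_spec(seed = 1L, contour_noise = 0,
                               n_frames = 40L)
  st <- synth_baseline(spec)
  rbar <- bump_profile(st$s)
  alpha <- 1.0
  sig_signal <- sqrt(mean((alpha * rbar - mean(alpha * rbar))^2))
  sig_g <- 0.5 * sig_signal
  rhos <- vapply(1:200, function(sd) {
    sp <- synthetic_study_spec(seed = 1L, contour_noise = 0,
                               n_frames = 40L, growth_gain = alpha,
                               growth_noise = sig_g)
    fup <- synth_followup(st$frames, rbar, sp, seed = 1000L + sd)
    correlate_adhesion(rbar, delta_lumen(st$frames, fup))$rho
  }, 0)
  expected <- 1 / sqrt(1 + (sig_g / sig_signal)^2)
  expect_equal(mean(rhos), expected, tolerance = 0.02)
  # monotone attenuation: more noise, weaker recovered correlation
  rhos2 <- vapply(1:60, function(sd) {
    sp <- synthetic_study_spec(seed = 1L, contour_noise = 0,
                               n_frames = 40L, growth_gain = alpha,
                               growth_noise = 2 * sig_g)
    fup <- synth_followup(st$frames, rbar, sp, seed = 5000L + sd)
    correlate_adhesion(rbar, delta_lumen(st$frames, fup))$rho
  }, 0)
  expect_lt(mean(rhos2), mean(rhos))
})

test_that("full pipeline: generate, solve, adhere, grow, correlate", {
  sc <- synthetic_coupled()
  prof <- adhesion_profile(sc$hist, 1)
  # adhesion peaks downstream of the minimum-area frame
  s_min <- sc$study$s[which.min(sc$study$area)]
  expect_gt(prof$s_mm[which.max(prof$rate)], s_min)
  # follow-up driven by the computed adhesion with small noise: rho > 0.8
  clin <- prof$s_mm >= min(sc$study$s) & prof$s_mm <= max(sc$study$s)
  rb <- prof[clin, c("s_mm", "rate_nondim")]
  alpha <- 0.5 / max(rb$rate_nondim)
  sp <- synthetic_study_spec(n_frames = 16L, seed = 7L,
                             growth_gain = alpha,
                             growth_noise = 0.03)
  rhos <- vapply(1:20, function(k) {
    fup <- synth_followup(sc$study$frames, rb, sp, seed = 40L + k)
    correlate_adhesion(rb, delta_lumen(sc$study$frames, fup),
                       rate_col = "rate_nondim")$rho
  }, 0)
  expect_gt(mean(rhos), 0.8)
  # growth independent of adhesion: |rho| small on average
  sp0 <- synthetic_study_spec(n_frames = 16L, seed = 7L, growth_gain = 0,
                              growth_noise = 0.05)
  rhos0 <- vapply(1:20, function(k) {
    fup <- synth_followup(sc$study$frames, rb, sp0, seed = 80L + k)
    correlate_adhesion(rb, delta_lumen(sc$study$frames, fup),
                       rate_col = "rate_nondim")$rho
  }, 0)
  expect_lt(abs(mean(rhos0)), 0.2)
})

test_that("contour noise beyond the safe range is rejected", {
  expect_error(synthetic_study_spec(contour_noise = -1), "non-negative")
  spec <- synthetic_study_spec(contour_noise = 1.0, seed = 3L)
  expect_error(synth_baseline(spec), "self-degenerates")
})
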