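# Geometry: frames, areas, tortuosity, stacking, extensions, distance.

test_that("frame_area matches closed forms and a quadrature oracle", {
  # circle: polygon area -> pi r^2 as M grows
  circ <- contour_frame(1, 0, rep(1, 256))
  expect_equal(frame_area(circ), pi, tolerance = 1e-3)
  # unit square traced as radii samples at the polygon vertices
  M <- 256
  th <- 2 * pi * (0:(M - 1)) / M
  r_sq <- 0.5 / pmax(abs(cos(th)), abs(sin(th)))
  expect_equal(frame_area(contour_frame(1, 0, r_sq)), 1, tolerance = 2e-4)
  # random star-shaped contour vs dense quadrature of (1/2) int r^2 dtheta
  set.seed(42)
  for (rep in 1:3) {
    a <- runif(3, -0.15, 0.15)
    rfun <- function(t) 1 + a[1] * cos(2 * t) + a[2] * sin(3 * t) +
      a[3] * cos(5 * t)
    M <- 512
    th <- 2 * pi * (0:(M - 1)) / M
    f <- contour_frame(1, 0, rfun(th))
    oracle <- stats::integrate(function(t) 0.5 * rfun(t)^2, 0, 2 * pi,
                               subdivisions = 2000L)$value
    expect_equal(frame_area(f), oracle, tolerance = 1e-4)
  }
})

test_that("contour frame validation rejects degenerate input", {
  expect_error(contour_frame(1, 0, rep(1, 8)), "at least 16")
  expect_error(contour_frame(1, 0, c(rep(1, 20), -0.1)), "positive")
})

test_that("tortuosity matches closed forms", {
  straight <- centerline(cbind(seq(0, 10, 0.5), 0, 0))
  expect_equal(tortuosity(straight), 1, tolerance = 1e-12)
  # semicircular arc: arc/chord = pi/2
  t <- seq(0, pi, length.out = 400)
  semi <- centerline(cbind(cos(t), sin(t), 0))
  expect_equal(tortuosity(semi), pi / 2, tolerance = 1e-4)
  # helix x = R cos, y = R sin, z = p t: arc = t*sqrt(R^2+p^2),
  # chord = sqrt(R^2 |e^{it1}-e^{it0}|^2 + p^2 t^2)
  R <- 2; p <- 0.5; t <- seq(0, 1.5 * pi, length.out = 600)
  helix <- centerline(cbind(R * cos(t), R * sin(t), p * t))
  arc <- 1.5 * pi * sqrt(R^2 + p^2)
  chord <- sqrt(R^2 * abs(exp(1i * 1.5 * pi) - 1)^2 + (p * 1.5 * pi)^2)
  expect_equal(tortuosity(helix), arc / Mod(chord), tolerance = 1e-4)
  expect_error(tortuosity(centerline(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0, 0, 0)))),
               "coincident")
})

test_that("ideal stenosis geometry honors severity and minimum location", {
  # severity 0: constant-area circular tube
  s0 <- build_ideal_stenosis(ideal_stenosis_spec(diameter = 2, severity = 0))
  ap <- leukoflow:::surface_area_profile(s0)
  expect_equal(ap, rep(ap[1], length(ap)), tolerance = 1e-12)
  expect_equal(ap[1], pi, tolerance = 2e-3)  # inscribed-64-gon area
  # severity 0.5, D = 2: minimum radius = 1/sqrt(2)
  sp <- ideal_stenosis_spec(diameter = 2, severity = 0.5)
  s1 <- build_ideal_stenosis(sp)
  expect_equal(min(s1$R), 1 / sqrt(2), tolerance = 1e-9)
  # minimum area at the frame nearest x = 0
  xs <- s1$s_grid + s1$x_offset
  ap1 <- leukoflow:::surface_area_profile(s1)
  expect_equal(abs(xs[which.min(ap1)]), min(abs(xs)), tolerance = 1e-9)
  expect_error(ideal_stenosis_spec(severity = 1), "full occlusion")
})

test_that("stacking preserves frame areas and spacing (round trip)", {
  spec <- synthetic_study_spec(n_frames = 10L, contour_noise = 0.05,
                               tort_amplitude = 0.3, seed = 3L)
  study <- synth_baseline(spec)
  surf <- stack_frames(study$frames, study$centerline)
  # arclength grid reproduces the 0.5 mm pullback spacing exactly
  expect_equal(diff(surf$s_grid), rep(0.5, 9), tolerance = 1e-12)
  # areas of the stacked stations equal the input frame areas
  expect_equal(leukoflow:::surface_area_profile(surf),
               vapply(study$frames, frame_area, 0), tolerance = 1e-12)
  expect_error(stack_frames(rev(study$frames), study$centerline),
               "out of order")
})

test_that("straighten preserves areas, is idempotent for straight input", {
  spec <- synthetic_study_spec(n_frames = 8L, contour_noise = 0.04,
                               tort_amplitude = 0.5, seed = 5L)
  study <- synth_baseline(spec)
  st <- straighten(study$frames)
  real <- stack_frames(study$frames, study$centerline)
  expect_equal(leukoflow:::surface_area_profile(st),
               leukoflow:::surface_area_profile(real), tolerance = 1e-12)
  # straight input centerline: same surface point-for-point
  sj <- vapply(study$frames, function(f) f$s, 0)
  straight_cl <- centerline(cbind(c(sj[1], sj[length(sj)]), 0, 0))
  s2 <- stack_frames(study$frames, straight_cl)
  expect_equal(leukoflow:::surface_points(st)$P,
               leukoflow:::surface_points(s2)$P, tolerance = 1e-9)
  # straightened centerline has tortuosity exactly 1
  p1 <- leukoflow:::fine_at(st$cl, sj[1])$P
  pn <- leukoflow:::fine_at(st$cl, sj[length(sj)])$P
  expect_equal(sqrt(sum((pn - p1)^2)), sj[length(sj)] - sj[1],
               tolerance = 1e-9)
})

test_that("excessive curvature is reported with the offending s", {
  # frames 0.2 mm apart on an arc of radius 0.5 with lumen radius 0.8
  t <- seq(0, pi, length.out = 200)
  cl <- centerline(cbind(0.5 * cos(t), 0.5 * sin(t), 0))
  frames <- lapply(1:6, function(j)
    contour_frame(j, 0.4 + 0.2 * (j - 1), rep(0.8, 32)))
  expect_error(stack_frames(frames, cl), "curvature too high")
})

test_that("extensions: lengths, inlet radius, monotone blend, clinical part unchanged", {
  spec <- synthetic_study_spec(n_frames = 10L, contour_noise = 0.03,
                               tort_amplitude = 0.25, seed = 9L)
  study <- synth_baseline(spec)
  surf <- stack_frames(study$frames, study$centerline)
  D <- surf$D
  ext <- add_extensions(surf)  # defaults 5D and 8D
  s_in <- ext$s_grid[ext$segment == "inlet"]
  s_out <- ext$s_grid[ext$segment == "outlet"]
  expect_equal(surf$s_grid[1] - min(s_in), 5 * D, tolerance = 0.5)
  expect_equal(max(s_out) - surf$s_grid[length(surf$s_grid)], 8 * D,
               tolerance = 0.5)
  # inlet cross-section circular with the first frame's mean radius
  expect_equal(unname(ext$R[1, ]), rep(mean(surf$R[1, ]), ncol(ext$R)),
               tolerance = 1e-9)
  # blended inlet areas monotone between circle area and first-frame area
  ap <- leukoflow:::surface_area_profile(ext)
  ain <- ap[ext$segment == "inlet"]
  expect_true(all(diff(ain) * sign(ap[sum(ext$segment == "inlet") + 1] -
                                   ain[1]) >= -1e-9))
  # clinical stations byte-identical
  clin <- ext$segment == "clinical"
  expect_identical(ext$R[clin, ], surf$R)
  expect_equal(ext$s_grid[clin], surf$s_grid, tolerance = 1e-12)
  expect_error(add_extensions(surf, inlet_length = -1), "positive")
})

test_that("signed distance: cylinder and torus oracles, surface zero", {
  # straight cylinder radius 1
  frames <- lapply(1:21, function(j)
    contour_frame(j, 0.5 * (j - 1), rep(1, 48)))
  cyl <- straighten(frames)
  expect_equal(signed_distance(cyl, rbind(c(5, 0, 0))), -1,
               tolerance = 1e-6)
  # points on the surface
  sp <- leukoflow:::surface_points(cyl, s = c(3, 5, 7))
  d_surf <- signed_distance(cyl, sp$P)
  expect_lt(max(abs(d_surf)), 1e-6)
  # random points vs the analytic cylinder distance
  set.seed(1)
  pts <- cbind(runif(500, 1, 9), runif(500, -1.6, 1.6),
               runif(500, -1.6, 1.6))
  exact <- sqrt(pts[, 2]^2 + pts[, 3]^2) - 1
  expect_lt(max(abs(signed_distance(cyl, pts) - exact)), 2e-3)

  # torus segment: circular frames on a planar arc, vs analytic torus
  Rc <- 6; r0 <- 0.8
  tt <- seq(0.2, pi - 0.2, length.out = 240)
  arc <- centerline(cbind(Rc * cos(tt), Rc * sin(tt), 0))
  stot <- arc$s[length(arc$s)]
  tframes <- lapply(1:25, function(j)
    contour_frame(j, stot * (0.25 + 0.5 * (j - 1) / 24), rep(r0, 48)))
  tor <- stack_frames(tframes, arc)
  set.seed(2)
  ang <- runif(1000, 0.65 * pi / 2, 1.35 * pi / 2)  # mid-arc region
  rad <- Rc + runif(1000, -1.5, 1.5)
  zz <- runif(1000, -1.5, 1.5)
  pts <- cbind(rad * cos(ang), rad * sin(ang), zz)
  inside_true <- sqrt((sqrt(pts[, 1]^2 + pts[, 2]^2) - Rc)^2 +
                      pts[, 3]^2) < r0
  d <- signed_distance(tor, pts)
  expect_true(all((d < 0) == inside_true))
  # magnitude agrees with the analytic torus distance
  exact <- sqrt((sqrt(pts[, 1]^2 + pts[, 2]^2) - Rc)^2 + pts[, 3]^2) - r0
  expect_lt(max(abs(d - exact)), 0.05)
})
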