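# Waveform, inlet profile and core solver behavior.

test_that("default waveform has the stated mean, period and periodicity", {
  w <- default_waveform()
  expect_equal(w$period, 0.8)
  # trapezoid mean of the interpolant on a fine grid
  tt <- seq(0, w$period, length.out = 40001)
  v <- waveform_eval(w, tt)
  m <- sum((v[-1] + v[-length(v)]) / 2) * diff(tt)[1] / w$period
  expect_equal(m, 0.384, tolerance = 1e-6)
  # periodicity: value at t equals value at t + T
  ts <- c(0.03, 0.17, 0.55, 0.79)
  expect_equal(waveform_eval(w, ts), waveform_eval(w, ts + w$period),
               tolerance = 1e-12)
  # linear interpolation midway between two table samples
  tm <- (w$times[4] + w$times[5]) / 2
  expect_equal(waveform_eval(w, tm),
               (w$velocities[4] + w$velocities[5]) / 2, tolerance = 1e-12)
  # triphasic shape: a reversal phase exists and diastole dominates
  expect_lt(min(w$velocities), 0)
  expect_gt(max(w$velocities), 1.7 * 0.384)
  expect_gt(w$times[which.max(w$velocities)], 0.35 * w$period)
})

test_that("waveform validation", {
  expect_error(pulsatile_waveform(c(0, 0.4, 0.8), c(1, 2, 1.5)),
               "periodic")
  expect_error(pulsatile_waveform(c(0, 0.5, 0.4), c(1, 2, 1)),
               "strictly increasing")
  expect_error(pulsatile_waveform(c(0, 0.4, 0.8), c(1, 2, 1),
                                  u_mean = 2, rescale = FALSE),
               "0.1%")
})

test_that("parabolic inlet profile: apex, rim and discrete mean", {
  expect_equal(inlet_profile(0.3, 1, 0), 0.6)
  expect_equal(inlet_profile(0.3, 1, 1), 0)
  expect_error(inlet_profile(0.3, -1, 0.5), "positive")
  # discrete sectional average over a 16-cells-per-diameter grid
  dom <- periodic_pipe_domain(radius = 1, cells_per_diameter = 16)
  h <- dom$h_mm
  yj <- ((1:dom$ny) - 0.5) * h; zk <- ((1:dom$nz) - 0.5) * h
  rr <- sqrt(outer((yj - dom$center[1])^2, (zk - dom$center[2])^2, "+"))
  u <- inlet_profile(0.3, 1, rr)
  expect_equal(sum(u) * h^2 / (pi * 1^2), 0.3, tolerance = 0.01)
})

test_that("zero inflow with zero initial velocity stays exactly zero", {
  dom <- channel_domain(gap = 2, length = 4, cells_per_gap = 8,
                        margin_cells = 2L)
  st <- flow_state(dom)
  st2 <- flow_step(st, fluid_properties(), constant_waveform(0),
                   dt = 1e-4, n_steps = 5L)
  expect_identical(max(abs(st2$u)), 0)
  expect_identical(max(abs(st2$v)), 0)
})

test_that("flow_step enforces the diffusive stability bound", {
  dom <- channel_domain(gap = 2, length = 4, cells_per_gap = 8)
  st <- flow_state(dom)
  expect_error(flow_step(st, fluid_properties(), constant_waveform(0.01),
                         dt = 1), "stability")
})

test_that("steady channel flow converges to plane Poiseuille at 2nd order", {
  fl <- fluid_properties()
  errs <- vapply(c(16L, 32L), function(nc) {
    hist <- channel_poiseuille(nc)
    dom <- hist$domain
    yj <- seq(dom$ylo(3) + 0.02, dom$yhi(3) - 0.02, length.out = 64)
    u <- sample_velocity(hist, cbind(4.5, yj, 0.5 * dom$h_mm))[, 1]
    ex <- channel_exact(dom)$u(yj)
    sqrt(sum((u - ex)^2) / sum(ex^2))
  }, 0)
  expect_lt(errs[2], 0.02)   # 32 cells/gap: L2 error < 2%
  order <- log2(errs[1] / errs[2])
  expect_gt(order, 1.5)      # observed convergence order
})

test_that("solver conservation invariants hold on the steady channel", {
  hist <- channel_poiseuille(32L)
  # discrete divergence below the projection tolerance every step
  u_scale <- max(hist$log$u_max) / hist$domain$h
  expect_lt(max(hist$log$max_div), 1e-5 * u_scale)
  # inlet and outlet flow rates match at every stored instant
  mism <- abs(hist$log$q_in - hist$log$q_out) / abs(hist$log$q_in)
  expect_lt(max(mism), 0.01)
})

test_that("steady waveform reaches a periodicity residual below 1e-6", {
  hist <- channel_steady_limit()
  expect_lt(hist$periodicity_residual, 1e-6)
})

test_that("run_cycles rejects invalid configuration", {
  expect_error(solver_config(cycles = 1, discard = 1), "exceed")
  expect_error(fluid_properties(viscosity_pa_s = 0), "positive")
  expect_error(solver_config(cfl = 1.4), "cfl")
})

test_that("pulsatile stenotic run shows downstream flow reversal", {
  st <- stenosis2d()
  # recorded near-wall axial velocity downstream of the throat reverses
  # during part of the cycle while the centerline stays mostly forward
  u_wall <- st$hist$probe_velocity[1, ]
  u_core <- st$hist$probe_velocity[4, ]
  expect_lt(min(u_wall), 0)
  expect_gt(mean(u_core > 0), 0.6)
  # recirculation signature: throat wall shear far exceeds the value in
  # the downstream separation zone
  prof <- wss_profile(st$hist)$profile
  thr <- prof$wss_bar_pa[which.min(abs(prof$s_mm - st$sten_center))]
  x0 <- st$sten_center + st$sten_extent
  down <- prof$wss_bar_pa[prof$s_mm > x0 & prof$s_mm < x0 + 4]
  expect_gt(thr, 2 * max(down))
})
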