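# Species parameters, rate law, transport and the adhesion sink.

test_that("rate law: threshold, apex and ramp midpoint", {
  n <- leukocyte_species("neutrophil", k_max = 1)
  expect_identical(rate_coefficient(2.0, n), 0)        # above 1.2 Pa
  expect_identical(rate_coefficient(0, n), 1)          # k_max at zero shear
  expect_equal(rate_coefficient(n$wss_th / 2, n), 0.5) # linear ramp
  # the threshold itself is inside the adhesive regime (<=)
  expect_gt(rate_coefficient(n$wss_th, n), -1e-15)
  expect_identical(rate_coefficient(n$wss_th + 1e-9, n), 0)
  # step law
  st <- leukocyte_species("neutrophil", k_max = 2, law = "step")
  expect_identical(rate_coefficient(1.0, st), 2)
  expect_error(rate_coefficient(-0.1, n), "negative")
  # vectorized
  expect_equal(rate_coefficient(c(0, 0.6, 2.4), n), c(1, 0.5, 0))
})

test_that("species validation and defaults", {
  expect_error(leukocyte_species("neutrophil", wss_th = -1), "positive")
  expect_error(leukocyte_species("neutrophil", k_max = -1), "non-negative")
  n <- leukocyte_species("neutrophil")
  expect_equal(n$rho_ref, 4.34e9)
  expect_equal(n$wss_th, 1.2)
})

test_that("advection: constants preserved, zero velocity, plug-flow front", {
  dom <- channel_domain(gap = 2, length = 8, cells_per_gap = 8,
                        margin_cells = 2L)
  conc <- concentration_state(dom)
  # zero velocity: field unchanged
  st0 <- flow_state(dom)
  out <- advect_concentration(conc, st0, 1e-3)
  expect_identical(out$rho, conc$rho)
  # uniform rho = 1 with a solenoidal velocity stays exactly 1
  hist <- cached("chan_adv", {
    run_cycles(dom, fluid_properties(), constant_waveform(0.05, period = 0.05),
               solver_config(cycles = 4L, discard = 3L,
                             records_per_cycle = 10L))
  })
  st <- flow_state(dom, hist$u, hist$v, hist$w, hist$p)
  cc <- conc
  for (i in 1:10) cc <- advect_concentration(cc, st, 2e-4)
  # exact away from the immersed wall; wall-adjacent cells drift only by
  # the (tiny) no-slip residual of the forced faces
  mask <- leukoflow:::cell_fluid_mask(dom)
  expect_equal(range(cc$rho[mask == 1L]), c(1, 1), tolerance = 1e-6)
  # 1D plug flow: a step front advances U*dt per step within one cell
  U <- 0.1
  stp <- flow_state(dom)
  stp$u <- rep(U, length(stp$u))
  rho0 <- array(0, c(dom$nx, dom$ny, 1))
  front0 <- 20L
  rho0[1:front0, , 1] <- 1
  cc <- concentration_state(dom, as.numeric(rho0))
  nsteps <- 10L
  dt <- 0.5 * dom$h / U  # CFL 0.5
  for (i in seq_len(nsteps)) cc <- advect_concentration(cc, stp, dt)
  arr <- array(cc$rho, c(dom$nx, dom$ny, 1))
  jmid <- dom$ny %/% 2
  front_now <- max(which(arr[, jmid, 1] > 0.5))
  expect_equal(front_now, front0 + nsteps * 0.5, tolerance = 1)
  # positivity preserved
  expect_gte(min(cc$rho), 0)
  # CFL guard
  expect_error(advect_concentration(cc, stp, 1), "CFL")
})

test_that("sink: exponential depletion conserves mass into the ledger", {
  dom <- channel_domain(gap = 2, length = 4, cells_per_gap = 8,
                        margin_cells = 2L, n_wall_stations = 8L)
  conc <- concentration_state(dom)
  sp <- leukocyte_species("neutrophil", k_max = 3)
  cells <- leukoflow:::wall_cells(dom)
  nsamp <- length(dom$wall$s_bin)
  wss0 <- rep(0.6, nsamp)  # below threshold: k = k_max/2 under the ramp
  dt <- 0.05
  out <- apply_sink(conc, wss0, sp, dt, cells = cells)
  k <- rate_coefficient(0.6, sp)
  h3 <- dom$h^3
  # every wall-adjacent cell decays exactly exponentially
  expect_equal(unique(round(out$conc$rho[cells$cell], 12)),
               round(exp(-k * dt), 12))
  # removed mass equals the ledger total; concentration + adhered conserved
  expect_equal(sum(out$ledger), out$removed, tolerance = 1e-12)
  expect_equal(out$removed,
               length(cells$cell) * (1 - exp(-k * dt)) * h3,
               tolerance = 1e-12)
  # repeated application: exp(-k t) after n steps
  cc <- conc
  for (i in 1:4) cc <- apply_sink(cc, wss0, sp, dt, cells = cells)$conc
  expect_equal(unique(round(cc$rho[cells$cell], 12)),
               round(exp(-k * 4 * dt), 12))
  # k = 0 everywhere (all WSS above threshold): nothing happens
  out0 <- apply_sink(conc, rep(5, nsamp), sp, dt, cells = cells)
  expect_identical(out0$conc$rho, conc$rho)
  expect_identical(sum(out0$ledger), 0)
  # uniform mode: ledger accrues k*dt, concentration untouched
  un <- apply_sink(conc, wss0, sp, dt, mode = "uniform", cells = cells)
  expect_identical(un$conc$rho, conc$rho)
  expect_equal(sum(un$ledger), length(cells$cell) * k * dt * h3,
               tolerance = 1e-12)
  # unsynchronized inputs rejected
  expect_error(apply_sink(conc, wss0[-1], sp, dt), "unsynchronized")
})

test_that("adhesion_profile reduces a ledger to a sectional rate", {
  dom <- channel_domain(gap = 2, length = 4, cells_per_gap = 8,
                        margin_cells = 2L, n_wall_stations = 8L)
  wall <- dom$wall
  nsamp <- length(wall$s_bin)
  TT <- 0.8
  # uniform constant sink R0 per unit area per time
  areas <- leukoflow:::wall_bin_areas(dom)
  R0 <- 2.5e-6
  led <- R0 * areas * TT
  prof <- adhesion_profile(led, domain = dom, period = TT)
  expect_equal(prof$rate, rep(R0, length(wall$stations)),
               tolerance = 1e-12)
  # sink concentrated in one s-bin: zero elsewhere
  led2 <- numeric(nsamp); led2[wall$s_bin == 3] <- 1e-9
  prof2 <- adhesion_profile(led2, domain = dom, period = TT)
  expect_true(all(prof2$rate[-3] == 0) && prof2$rate[3] > 0)
  # known analytic time course: per-area sink a + b sin(2 pi t / T)
  # accrues (by trapezoid quadrature) to a*T over one period
  tt <- seq(0, TT, length.out = 2001)
  kt <- 2 + 1.5 * sin(2 * pi * tt / TT)
  accr <- sum(diff(tt) * (kt[-1] + kt[-length(kt)]) / 2)
  prof3 <- adhesion_profile(accr * areas, domain = dom, period = TT)
  expect_equal(prof3$rate, rep(accr / TT, length(wall$stations)),
               tolerance = 1e-9)
  expect_equal(accr / TT, 2, tolerance = 1e-6)  # closed-form mean
})

test_that("species ordering: a lower threshold adheres no more than a higher one", {
  dom <- channel_domain(gap = 2, length = 4, cells_per_gap = 8,
                        margin_cells = 2L, n_wall_stations = 8L)
  cells <- leukoflow:::wall_cells(dom)
  nsamp <- length(dom$wall$s_bin)
  set.seed(4)
  spA <- leukocyte_species("neutrophil", wss_th = 0.6, k_max = 1,
                           law = "step")
  spB <- leukocyte_species("neutrophil", wss_th = 1.2, k_max = 1,
                           law = "step")
  totA <- totB <- 0
  for (rep in 1:20) {
    wss <- abs(rnorm(nsamp, 0.9, 0.5))
    conc <- concentration_state(dom)
    totA <- totA + apply_sink(conc, wss, spA, 0.01, cells = cells)$removed
    totB <- totB + apply_sink(conc, wss, spB, 0.01, cells = cells)$removed
  }
  expect_lte(totA, totB)
})
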