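# Shared fixtures: flow runs are expensive, so each is computed once per
# test session and cached. All runs are deliberately scaled down (coarse
# grids, short periods, reduced Reynolds numbers) to keep the whole suite
# inside a desk-scale budget; the assertions are chosen to be meaningful
# at these scales.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache)) {
    assign(name, force(expr), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

# steady plane Poiseuille channel (2D planar mode)
channel_poiseuille <- function(cells = 32L) {
  cached(paste0("chan", cells), {
    dom <- channel_domain(gap = 2, length = 6, cells_per_gap = cells,
                          margin_cells = 3L, wall_offset = 0.3,
                          n_wall_stations = 16L)
    fl <- fluid_properties()
    # species exercise the threshold-exactness and balance criteria:
    # wall shear is ~0.5 Pa everywhere, so th = 0.1 Pa never adheres
    sp <- list(
      leukocyte_species("neutrophil", k_max = 2, mode = "tracked"),
      leukocyte_species("neutrophil", wss_th = 0.1, k_max = 2,
                        mode = "tracked"))
    # run to ~0.85 s so the diffusive start-up transient (decay rate
    # nu*pi^2/H^2 ~ 8/s) is well below the discretization error
    run_cycles(dom, fl, constant_waveform(0.05, period = 0.05),
               solver_config(cycles = 17L, discard = 16L,
                             records_per_cycle = 20L),
               species = sp)
  })
}

# small, viscous channel run reaching machine-level steady state fast
channel_steady_limit <- function() {
  cached("chan_steady", {
    dom <- channel_domain(gap = 2, length = 5, cells_per_gap = 12,
                          margin_cells = 3L, n_wall_stations = 8L)
    fl <- fluid_properties(viscosity_pa_s = 3.5e-2)  # 10x viscosity
    run_cycles(dom, fl, constant_waveform(0.05, period = 0.05),
               solver_config(cycles = 5L, discard = 4L,
                             records_per_cycle = 10L))
  })
}

channel_exact <- function(dom, u_bulk = 0.05) {
  # analytic plane Poiseuille on the wall-sample stations
  list(u = function(y) {
    ylo <- dom$ylo(3); yhi <- dom$yhi(3)
    ifelse(y > ylo & y < yhi,
           6 * u_bulk * (y - ylo) * (yhi - y) / (yhi - ylo)^2, 0)
  },
  tau = 6 * fluid_properties()$mu * u_bulk / (dom$gap * 1e-3))
}

# steady pipe Poiseuille, periodic axial mode, 24 cells per diameter
pipe_poiseuille <- function() {
  cached("pipe24", {
    dom <- periodic_pipe_domain(radius = 1, cells_per_diameter = 24)
    run_cycles(dom, fluid_properties(), constant_waveform(0.05, period = 0.06),
               solver_config(cycles = 6L, discard = 5L,
                             records_per_cycle = 20L))
  })
}

# oscillatory pipe flow at Womersley number 2.5
womersley_run <- function() {
  cached("womersley", {
    alpha <- 2.5; TT <- 0.8; om <- 2 * pi / TT; R0 <- 1e-3
    nu <- R0^2 * om / alpha^2
    fl <- fluid_properties(viscosity_pa_s = nu * 1060)
    dom <- periodic_pipe_domain(radius = 1, cells_per_diameter = 24)
    tt <- seq(0, TT, length.out = 201)
    wf <- pulsatile_waveform(tt, 0.05 * sin(om * tt))
    hist <- run_cycles(dom, fl, wf,
                       solver_config(cycles = 4L, discard = 3L,
                                     records_per_cycle = 400L),
                       probes = rbind(c(dom$nx / 2 * dom$h_mm,
                                        dom$center[1], dom$center[2])))
    list(hist = hist, alpha = alpha, om = om, U0 = 0.05, R0 = R0)
  })
}

# pulsatile stenotic channel with coupled tracked/uniform transport
stenosis2d <- function() {
  cached("sten2d", {
    dom <- channel_domain(gap = 2, length = 24, cells_per_gap = 16,
                          severity = 0.6, sten_center = 8,
                          sten_extent = 4, margin_cells = 3L,
                          n_wall_stations = 48L)
    fl <- fluid_properties()
    wf <- default_waveform(u_mean = 0.1, period = 0.4)
    sp <- list(leukocyte_species("neutrophil", k_max = 5, mode = "tracked"),
               leukocyte_species("neutrophil", k_max = 5, mode = "uniform"))
    # probes just downstream of the throat: near-wall and centerline
    x0 <- 8 + 4 / 2 + 1
    probes <- rbind(c(x0, dom$ylo(x0) + 1.5 * dom$h_mm, 0.5 * dom$h_mm),
                    c(x0, (dom$ylo(x0) + dom$yhi(x0)) / 2, 0.5 * dom$h_mm))
    hist <- run_cycles(dom, fl, wf,
                       solver_config(cycles = 3L, discard = 1L,
                                     records_per_cycle = 60L),
                       species = sp, probes = probes)
    list(dom = dom, hist = hist, sten_center = 8, sten_extent = 4)
  })
}

# identical circular-ish frames on a tortuous vs straight centerline
tortuous_pair <- function() {
  cached("tortpair", {
    spec <- synthetic_study_spec(n_frames = 12L, severity = 0.3,
                                 sten_center = 3, sten_extent = 3,
                                 tort_amplitude = 0.35,
                                 tort_wavelength = 6,
                                 contour_noise = 0, seed = 11L)
    study <- synth_baseline(spec)
    fl <- fluid_properties()
    wv <- constant_waveform(0.05, period = 0.1)
    cfg <- solver_config(cycles = 8L, discard = 7L,
                         records_per_cycle = 10L, poisson_rtol = 1e-7)
    runs <- lapply(list(stack_frames(study$frames, study$centerline),
                        straighten(study$frames)), function(s) {
      ext <- add_extensions(s, inlet_length = 6, outlet_length = 9)
      dom <- flow_domain(ext, cells_per_diameter = 10, margin_cells = 3L)
      run_cycles(dom, fl, wv, cfg)
    })
    list(real = runs[[1]], straight = runs[[2]], study = study)
  })
}

# slowly tapering tube at fixed flow rate (WSS ~ R^-3 scaling)
tapered_run <- function() {
  cached("tapered", {
    sj <- seq(0, 16, by = 0.5)
    rad <- 1.05 - (1.05 - 0.75) * sj / 16
    frames <- lapply(seq_along(sj), function(j)
      contour_frame(j, sj[j], rep(rad[j], 48)))
    surf <- straighten(frames)
    ext <- add_extensions(surf, inlet_length = 4, outlet_length = 6)
    dom <- flow_domain(ext, cells_per_diameter = 12, margin_cells = 3L)
    hist <- run_cycles(dom, fluid_properties(),
                       constant_waveform(0.05, period = 0.1),
                       solver_config(cycles = 8L, discard = 7L,
                                     records_per_cycle = 10L,
                                     poisson_rtol = 1e-7))
    list(hist = hist, s = sj, rad = rad)
  })
}

# coarse coupled run on the synthetic 3D geometry (full-pipeline smoke)
synthetic_coupled <- function() {
  cached("syncoupled", {
    spec <- synthetic_study_spec(n_frames = 16L, severity = 0.5,
                                 sten_center = 4, sten_extent = 3,
                                 tort_amplitude = 0.3,
                                 contour_noise = 0.02, seed = 7L)
    study <- synth_baseline(spec)
    ext <- add_extensions(stack_frames(study$frames, study$centerline),
                          inlet_length = 4, outlet_length = 6)
    dom <- flow_domain(ext, cells_per_diameter = 10, margin_cells = 3L)
    hist <- run_cycles(dom, fluid_properties(),
                       constant_waveform(0.08, period = 0.1),
                       solver_config(cycles = 4L, discard = 3L,
                                     records_per_cycle = 20L,
                                     poisson_rtol = 1e-7),
                       species = list(leukocyte_species("neutrophil",
                                                        k_max = 2)))
    list(spec = spec, study = study, dom = dom, hist = hist)
  })
}

# deterministic bump profile used as a stand-in adhesion signal
bump_profile <- function(s, center = 10, width = 4) {
  exp(-((s - center) / width)^2)
}
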