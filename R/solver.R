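# Driver for the immersed-boundary Navier-Stokes core: time-step
# selection, cycle management, wall shear recording, species transport
# and result packaging.

#' Solver configuration
#'
#' @param cfl advective CFL target (<= 1).
#' @param cycles number of cardiac cycles to run.
#' @param discard cycles discarded as start-up transient before wall shear
#'   and adhesion statistics accumulate.
#' @param poisson_rtol relative residual tolerance of the pressure Poisson
#'   solve; the post-step divergence is bounded by this times the
#'   divergence scale of the predictor field.
#' @param records_per_cycle wall shear / probe sampling instants per cycle.
#' @param cg_maxit conjugate-gradient iteration cap.
#' @param viscous_safety fraction of the explicit diffusive stability
#'   limit used for the time step.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(cfl = 0.7, cycles = 3L, discard = 1L,
                          poisson_rtol = 1e-8, records_per_cycle = 100L,
                          cg_maxit = 5000L, viscous_safety = 0.4) {
  if (cfl <= 0 || cfl > 1) stop("solver_config: cfl must be in (0, 1]")
  if (cycles < discard + 1L)
    stop("solver_config: cycles must exceed discarded transient cycles")
  structure(list(cfl = cfl, cycles = as.integer(cycles),
                 discard = as.integer(discard),
                 poisson_rtol = poisson_rtol,
                 records_per_cycle = as.integer(records_per_cycle),
                 cg_maxit = as.integer(cg_maxit),
                 viscous_safety = viscous_safety),
            class = "solver_config")
}

# advective velocity scale estimate: peak waveform amplified by the
# parabolic profile factor and the worst constriction of the geometry
estimate_umax <- function(domain, waveform) {
  wmax <- max(abs(waveform$velocities), 1e-12)
  A_in <- if (!is.null(domain$inlet_area)) domain$inlet_area else
    domain$area_min * MM^2
  constr <- max(1, (A_in / MM^2) / domain$area_min)
  wmax * 2 * constr * 1.4
}

select_dt <- function(domain, fluid, waveform, config) {
  h <- domain$h
  u_est <- estimate_umax(domain, waveform)
  dt_adv <- config$cfl * h / u_est
  dt_vis <- config$viscous_safety * h^2 / (6 * fluid$nu)
  min(dt_adv, dt_vis)
}

#' Run pulsatile flow cycles
#'
#' Advances the incompressible immersed-boundary solver over a number of
#' cardiac cycles, discarding the start-up transient, while recording wall
#' shear stress time series at the wall sample points and, when species
#' are given, transporting leukocyte concentration with its adhesion sink.
#'
#' @param domain a `flow_domain`.
#' @param fluid a [fluid_properties()].
#' @param waveform a [pulsatile_waveform()].
#' @param config a [solver_config()].
#' @param species list of [leukocyte_species()]; each is transported in
#'   its configured mode (`tracked` or `uniform`).
#' @param probes optional n x 3 matrix of probe points (mm, domain frame)
#'   whose velocity time series are recorded.
#' @return an object of class `flow_history`.
#' @export
run_cycles <- function(domain, fluid, waveform, config = solver_config(),
                       species = list(), probes = NULL) {
  stopifnot(inherits(domain, "flow_domain"),
            inherits(fluid, "fluid_properties"),
            inherits(waveform, "pulsatile_waveform"))
  dt <- select_dt(domain, fluid, waveform, config)
  TT <- waveform$period
  spc <- as.integer(ceiling(TT / dt))
  dt <- TT / spc
  n_steps <- config$cycles * spc
  ledger_start <- config$discard * spc + 1L
  stride <- max(1L, spc %/% config$records_per_cycle)
  wallS <- wall_to_solver(domain)
  sp_cfg <- lapply(species, function(sp) list(
    k_max = sp$k_max, wss_th = sp$wss_th,
    law = if (identical(sp$law, "step")) 1L else 0L,
    tracked = if (identical(sp$mode, "tracked")) 1L else 0L))
  cfg <- list(
    nx = domain$nx, ny = domain$ny, nz = domain$nz, h = domain$h,
    periodic_x = domain$periodic_x, periodic_z = domain$periodic_z,
    phi = domain$phi, rho_f = fluid$rho, mu = fluid$mu,
    dt = dt, n_steps = n_steps, t0 = 0,
    waveform = cbind(waveform$times, waveform$velocities),
    inlet_profile = domain$inlet_profile,
    section_area = domain$section_area,
    cg_rtol = config$poisson_rtol, cg_maxit = config$cg_maxit,
    uconv_min = 0.05 * max(abs(waveform$velocities)),
    record_stride = stride, record_start = ledger_start,
    ledger_start = ledger_start,
    species = if (length(sp_cfg)) sp_cfg else NULL,
    wall_points = if (is.null(wallS)) NULL else wallS$points,
    wall_normals = if (is.null(wallS)) NULL else wallS$normals,
    probes = if (is.null(probes)) NULL else
      sweep(matrix(probes, ncol = 3), 2, domain$origin) * MM,
    snapshot_steps = spc * seq_len(config$cycles))
  res <- cpp_run(cfg)
  if (isTRUE(res$blowup))
    stop("run_cycles: solver diverged (NaN/overflow) at step ",
         res$blowup_step, " of ", n_steps,
         "; check CFL and geometry resolution")
  log <- data.frame(t = res$log[, 1], max_div = res$log[, 2],
                    q_in = res$log[, 3], q_out = res$log[, 4],
                    u_bulk = res$log[, 5], cg_iters = res$log[, 6],
                    u_max = res$log[, 7])
  # cycle-to-cycle periodicity residual on the final velocity fields
  per_res <- NA_real_
  ns <- length(res$snapshots)
  if (ns >= 2) {
    ua <- res$snapshots[[ns - 1]]$u; ub <- res$snapshots[[ns]]$u
    per_res <- sqrt(mean((ua - ub)^2)) / max(abs(waveform$u_mean), 1e-12)
  }
  ledger <- res$ledger
  names(ledger) <- vapply(species, function(sp) sp$name, "")
  structure(list(
    domain = domain, fluid = fluid, waveform = waveform, config = config,
    species = species, dt = dt, steps_per_cycle = spc,
    log = log, wss = res$wss, wss_times = res$rec_times,
    wss_mean = res$wss_mean, wss_valid = res$wss_valid,
    ledger = ledger, rho = res$rho, scalar_balance = res$scalar_balance,
    probe_velocity = res$probe_vel, snapshots = res$snapshots,
    retained_time = (config$cycles - config$discard) * TT,
    periodicity_residual = per_res,
    u = res$u, v = res$v, w = res$w, p = res$p, t = res$t,
    cell_fluid = res$cell_fluid), class = "flow_history")
}

#' @export
print.flow_history <- function(x, ...) {
  cat("<flow_history>\n")
  cat(sprintf("  grid %d x %d x %d (h = %.3g mm), %d steps/cycle, dt = %.3g s\n",
              x$domain$nx, x$domain$ny, x$domain$nz, x$domain$h / MM,
              x$steps_per_cycle, x$dt))
  cat(sprintf("  cycles: %d (%d discarded); periodicity residual %.3g\n",
              x$config$cycles, x$config$discard, x$periodicity_residual))
  cat(sprintf("  max |div u| = %.3g 1/s; flow-rate mismatch %.3g%%\n",
              max(x$log$max_div),
              100 * max(abs(x$log$q_in - x$log$q_out) /
                        pmax(abs(x$log$q_in), 1e-300))))
  invisible(x)
}

#' Flow state at one instant
#'
#' Staggered velocity components and cell-centred pressure, as used by
#' [flow_step()].
#'
#' @param domain a `flow_domain`.
#' @param u,v,w,p optional flat field vectors (SI); zero-initialized when
#'   omitted.
#' @param t time (s).
#' @return an object of class `flow_state`.
#' @export
flow_state <- function(domain, u = NULL, v = NULL, w = NULL, p = NULL,
                       t = 0) {
  nx <- domain$nx; ny <- domain$ny; nz <- domain$nz
  zeros <- function(n) rep(0, n)
  structure(list(
    u = if (is.null(u)) zeros((nx + 1) * ny * nz) else u,
    v = if (is.null(v)) zeros(nx * (ny + 1) * nz) else v,
    w = if (is.null(w)) zeros(nx * ny * (nz + 1)) else w,
    p = if (is.null(p)) zeros(nx * ny * nz) else p,
    t = t, domain = domain), class = "flow_state")
}

#' Advance a flow state by one (or more) time steps
#'
#' One fractional-step update: explicit RK3 advection-diffusion predictor,
#' direct immersed-boundary forcing of the no-slip condition, and a
#' pressure-Poisson projection returning a discretely divergence-free
#' field.
#'
#' @param state a [flow_state()].
#' @param fluid a [fluid_properties()].
#' @param waveform a [pulsatile_waveform()] (evaluated at the state time).
#' @param dt time step (s); must satisfy the advective CFL and diffusive
#'   stability bounds.
#' @param n_steps number of steps to take.
#' @param config a [solver_config()].
#' @return the advanced [flow_state()].
#' @export
flow_step <- function(state, fluid, waveform, dt, n_steps = 1L,
                      config = solver_config()) {
  stopifnot(inherits(state, "flow_state"))
  domain <- state$domain
  dt_vis <- 0.6 * domain$h^2 / (6 * fluid$nu)
  if (dt > dt_vis)
    stop("flow_step: dt exceeds the explicit diffusive stability bound ",
         signif(dt_vis, 4), " s")
  cfg <- list(
    nx = domain$nx, ny = domain$ny, nz = domain$nz, h = domain$h,
    periodic_x = domain$periodic_x, periodic_z = domain$periodic_z,
    phi = domain$phi, rho_f = fluid$rho, mu = fluid$mu,
    dt = dt, n_steps = as.integer(n_steps), t0 = state$t,
    waveform = cbind(waveform$times, waveform$velocities),
    inlet_profile = domain$inlet_profile,
    section_area = domain$section_area,
    cg_rtol = config$poisson_rtol, cg_maxit = config$cg_maxit,
    uconv_min = 0.05 * max(abs(waveform$velocities)),
    record_stride = 1000000L, record_start = 1L, ledger_start = 1L,
    species = NULL, wall_points = NULL, wall_normals = NULL,
    probes = NULL, snapshot_steps = integer(0),
    u0 = state$u, v0 = state$v, w0 = state$w, p0 = state$p)
  res <- cpp_run(cfg)
  if (isTRUE(res$blowup))
    stop("flow_step: solver diverged at step ", res$blowup_step)
  out <- flow_state(domain, res$u, res$v, res$w, res$p, res$t)
  attr(out, "max_div") <- max(res$log[, 2])
  out
}

#' Sample the velocity field of a state or history at points
#'
#' @param x a `flow_state` or `flow_history`.
#' @param pts n x 3 points (mm, domain frame).
#' @return n x 3 matrix of velocity components (m/s).
#' @export
sample_velocity <- function(x, pts) {
  domain <- x$domain
  pts <- sweep(matrix(pts, ncol = 3), 2, domain$origin) * MM
  cpp_sample_velocity(x$u, x$v, x$w, domain$nx, domain$ny, domain$nz,
                      domain$h, domain$periodic_x, domain$periodic_z, pts)
}
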