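# Leukocyte concentration transport and shear-thresholded adhesion.
#
# The governing transport equation advects the normalized concentration
# rho_l with the blood velocity and removes it at the wall through a sink
# whose rate depends on the instantaneous wall shear stress: adhesion is
# possible only where |WSS| <= WSS_th (threshold depending on the
# species), and the realized sink scales with the local free-flowing
# concentration, R_l = k_l(WSS) * rho_l, so that upstream adhesion
# depletes the supply available downstream. The comparison mode with
# uniform concentration (rho = 1 everywhere, no depletion) is retained.

#' Leukocyte species parameters
#'
#' Only the neutrophil threshold (1.2 Pa) and reference concentration
#' (4.34e9 cells/l) are anchored to published values; monocyte and
#' lymphocyte defaults are provisional placeholders at physiological
#' reference concentrations and must be configured for quantitative use.
#' The adhesion rate law `k_l(WSS)` is pluggable: the default is a linear
#' ramp from `k_max` at zero shear to 0 at the threshold (inclusive).
#'
#' @param name `"neutrophil"`, `"monocyte"` or `"lymphocyte"`.
#' @param rho_ref reference blood concentration (cells per liter).
#' @param wss_th adhesion shear threshold (Pa); above it no adhesion
#'   occurs.
#' @param k_max maximal adhesion rate coefficient (1/s); scales the sink
#'   but not its spatial pattern for the linear law.
#' @param law `"ramp"` (default) or `"step"` (constant `k_max` below the
#'   threshold).
#' @param mode `"tracked"` (concentration transported and depleted) or
#'   `"uniform"` (concentration held at 1; sink recorded only).
#' @return an object of class `leukocyte_species`.
#' @export
leukocyte_species <- function(name = c("neutrophil", "monocyte",
                                       "lymphocyte"),
                              rho_ref = NULL, wss_th = NULL, k_max = 1,
                              law = c("ramp", "step"),
                              mode = c("tracked", "uniform")) {
  name <- match.arg(name)
  law <- match.arg(law)
  mode <- match.arg(mode)
  defaults <- list(
    neutrophil = list(rho_ref = 4.34e9, wss_th = 1.2),   # published values
    monocyte   = list(rho_ref = 0.5e9,  wss_th = 1.0),   # provisional
    lymphocyte = list(rho_ref = 2.0e9,  wss_th = 0.8))   # provisional
  if (is.null(rho_ref)) rho_ref <- defaults[[name]]$rho_ref
  if (is.null(wss_th)) wss_th <- defaults[[name]]$wss_th
  if (rho_ref <= 0) stop("leukocyte_species: rho_ref must be positive")
  if (wss_th <= 0) stop("leukocyte_species: wss_th must be positive")
  if (k_max < 0) stop("leukocyte_species: k_max must be non-negative")
  structure(list(name = name, rho_ref = rho_ref, wss_th = wss_th,
                 k_max = k_max, law = law, mode = mode),
            class = "leukocyte_species")
}

#' Adhesion rate coefficient k_l(WSS)
#'
#' Zero for `WSS > WSS_th`; at or below the threshold (the boundary is
#' inside the adhesive regime) a non-increasing function of WSS with
#' `k_l(0) = k_max`: a linear ramp by default, or a constant step.
#'
#' @param wss wall shear stress magnitude(s), Pa; must be non-negative.
#' @param species a [leukocyte_species()].
#' @return rate coefficient(s), 1/s.
#' @export
rate_coefficient <- function(wss, species) {
  stopifnot(inherits(species, "leukocyte_species"))
  if (any(wss < 0)) stop("rate_coefficient: negative WSS rejected")
  k <- numeric(length(wss))
  adh <- wss <= species$wss_th
  k[adh] <- if (species$law == "step") species$k_max else
    species$k_max * (1 - wss[adh] / species$wss_th)
  k
}

#' Concentration state on the flow grid
#'
#' Normalized (by `rho_ref`) leukocyte concentration at cell centres;
#' non-negative everywhere, held at 1 on the inlet boundary.
#'
#' @param domain a `flow_domain`.
#' @param rho optional flat vector of cell values; defaults to 1 in fluid
#'   cells.
#' @param t time (s).
#' @return an object of class `concentration_state`.
#' @export
concentration_state <- function(domain, rho = NULL, t = 0) {
  nc <- domain$nx * domain$ny * domain$nz
  if (is.null(rho)) {
    rho <- rep(1, nc)
    rho[cell_fluid_mask(domain) == 0L] <- 0
  }
  if (any(rho < 0)) stop("concentration_state: negative concentration")
  structure(list(rho = rho, domain = domain, t = t),
            class = "concentration_state")
}

cell_fluid_mask <- function(domain) {
  if (!is.null(domain$.fluid_mask)) return(domain$.fluid_mask)
  phi <- array(domain$phi, c(domain$nx + 1, domain$ny + 1, domain$nz + 1))
  cc <- (phi[-1, -1, -1, drop = FALSE] +
         phi[-(domain$nx + 1), -1, -1, drop = FALSE] +
         phi[-1, -(domain$ny + 1), -1, drop = FALSE] +
         phi[-1, -1, -(domain$nz + 1), drop = FALSE] +
         phi[-(domain$nx + 1), -(domain$ny + 1), -1, drop = FALSE] +
         phi[-(domain$nx + 1), -1, -(domain$nz + 1), drop = FALSE] +
         phi[-1, -(domain$ny + 1), -(domain$nz + 1), drop = FALSE] +
         phi[-(domain$nx + 1), -(domain$ny + 1), -(domain$nz + 1), drop = FALSE]) / 8
  as.integer(cc < 0)
}

#' Advect a concentration state with a flow field
#'
#' Conservative first-order upwind update (positivity preserving); the
#' inlet boundary carries the normalized value 1 into the domain and the
#' outlet is convective. Scalar flux through wall-adjacent faces into
#' solid cells is suppressed.
#'
#' @param conc a [concentration_state()].
#' @param state a [flow_state()] (or `flow_history`; final fields used).
#' @param dt time step (s); must satisfy the scalar CFL bound.
#' @return the updated [concentration_state()], with attributes `influx`,
#'   `outflux`, `clamped` (boundary-flux bookkeeping for mass balance).
#' @export
advect_concentration <- function(conc, state, dt) {
  stopifnot(inherits(conc, "concentration_state"))
  domain <- conc$domain
  usum <- max(abs(state$u)) + max(abs(state$v)) + max(abs(state$w))
  if (dt * usum / domain$h > 1.0)
    stop("advect_concentration: scalar CFL violated (dt too large)")
  res <- cpp_scalar_step(conc$rho, state$u, state$v, state$w, domain$phi,
                         domain$nx, domain$ny, domain$nz, domain$h,
                         domain$periodic_x, domain$periodic_z, dt)
  out <- concentration_state(domain, res$rho, conc$t + dt)
  attr(out, "influx") <- res$influx
  attr(out, "outflux") <- res$outflux
  attr(out, "clamped") <- res$clamped
  out
}

# wall-adjacent fluid cells and their governing wall sample (cached)
wall_cells <- function(domain) {
  mask <- array(cell_fluid_mask(domain),
                c(domain$nx, domain$ny, domain$nz))
  nx <- domain$nx; ny <- domain$ny; nz <- domain$nz
  pad <- array(0L, c(nx + 2, ny + 2, nz + 2))
  pad[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- mask
  if (domain$periodic_x) {
    pad[1, 2:(ny + 1), 2:(nz + 1)] <- mask[nx, , ]
    pad[nx + 2, 2:(ny + 1), 2:(nz + 1)] <- mask[1, , ]
  } else {
    pad[1, , ] <- pad[2, , ]; pad[nx + 2, , ] <- pad[nx + 1, , ]
  }
  if (domain$periodic_z) {
    pad[2:(nx + 1), 2:(ny + 1), 1] <- mask[, , nz]
    pad[2:(nx + 1), 2:(ny + 1), nz + 2] <- mask[, , 1]
  }
  nsolid <- (1L - pad[1:nx, 2:(ny + 1), 2:(nz + 1), drop = FALSE]) +
            (1L - pad[3:(nx + 2), 2:(ny + 1), 2:(nz + 1), drop = FALSE]) +
            (1L - pad[2:(nx + 1), 1:ny, 2:(nz + 1), drop = FALSE]) +
            (1L - pad[2:(nx + 1), 3:(ny + 2), 2:(nz + 1), drop = FALSE]) +
            (1L - pad[2:(nx + 1), 2:(ny + 1), 1:nz, drop = FALSE]) +
            (1L - pad[2:(nx + 1), 2:(ny + 1), 3:(nz + 2), drop = FALSE])
  idx <- which(mask == 1L & nsolid > 0L)
  if (length(idx) == 0)
    return(list(cell = integer(0), sample = integer(0)))
  ijk <- arrayInd(idx, c(nx, ny, nz))
  ctr <- cbind((ijk[, 1] - 0.5) * domain$h_mm,
               (ijk[, 2] - 0.5) * domain$h_mm,
               (ijk[, 3] - 0.5) * domain$h_mm)
  wallS <- wall_to_solver(domain)
  wp <- wallS$points / MM  # solver mm frame
  near <- integer(length(idx))
  for (m in seq_along(idx)) {
    d2 <- (wp[, 1] - ctr[m, 1])^2 + (wp[, 2] - ctr[m, 2])^2 +
          (wp[, 3] - ctr[m, 3])^2
    near[m] <- which.min(d2)
  }
  list(cell = idx, sample = near)
}

#' Apply the wall adhesion sink to a concentration state
#'
#' In `tracked` mode each wall-adjacent fluid cell is depleted by its
#' governing sample's rate coefficient with exact exponential decay over
#' the step, and the removed amount is credited to the sample's `(s,
#' theta)` ledger bin. In `uniform` mode the ledger accrues
#' `k_l * 1 * dt` per bin and the concentration is untouched.
#'
#' @param conc a [concentration_state()].
#' @param wall_wss instantaneous WSS per wall sample (Pa), synchronized
#'   with `conc$t`.
#' @param species a [leukocyte_species()].
#' @param dt time step (s).
#' @param mode overrides the species mode if given.
#' @param cells optional precomputed [wall_cells()] mapping.
#' @return list with `conc` (updated state), `ledger` (removed amount per
#'   wall sample, normalized concentration x m^3) and `removed` (total).
#' @export
apply_sink <- function(conc, wall_wss, species, dt, mode = NULL,
                       cells = NULL) {
  stopifnot(inherits(conc, "concentration_state"),
            inherits(species, "leukocyte_species"))
  domain <- conc$domain
  if (is.null(mode)) mode <- species$mode
  if (is.null(cells)) cells <- wall_cells(domain)
  nsamp <- length(domain$wall$s_bin)
  if (length(wall_wss) != nsamp)
    stop("apply_sink: wall_wss length does not match the wall samples ",
         "(unsynchronized inputs)")
  ledger <- numeric(nsamp)
  h3 <- domain$h^3
  rho <- conc$rho
  kk <- rate_coefficient(pmax(wall_wss[cells$sample], 0), species)
  if (identical(mode, "uniform")) {
    acc <- kk * dt * h3
    ledger_inc <- tapply(acc, cells$sample, sum)
    ledger[as.integer(names(ledger_inc))] <- as.numeric(ledger_inc)
    return(list(conc = conc, ledger = ledger, removed = sum(acc)))
  }
  dec <- exp(-kk * dt)
  removed <- rho[cells$cell] * (1 - dec) * h3
  rho[cells$cell] <- rho[cells$cell] * dec
  ledger_inc <- tapply(removed, cells$sample, sum)
  ledger[as.integer(names(ledger_inc))] <- as.numeric(ledger_inc)
  list(conc = concentration_state(domain, rho, conc$t),
       ledger = ledger, removed = sum(removed))
}

#' Sectional adhesion-rate profile from an accrued ledger
#'
#' Reduces a per-(s, theta) adhesion ledger accrued over the retained
#' cardiac period(s) to the per-section average rate: accrued amount per
#' endothelial bin area per time, azimuthally averaged. Reported both as
#' a flux (normalized concentration x m/s) and nondimensionally as
#' `rate * T / D` with T the cardiac period and D the mean diameter.
#'
#' @param history a `flow_history` run with species, or a raw ledger
#'   vector (then `domain`, `period` must be supplied).
#' @param species species name or index selecting the ledger.
#' @param domain,period overrides when passing a raw ledger.
#' @return data.frame with `s_mm`, `rate` (m/s), `rate_nondim`.
#' @export
adhesion_profile <- function(history, species = 1L, domain = NULL,
                             period = NULL) {
  if (inherits(history, "flow_history")) {
    ledger <- history$ledger[[species]]
    domain <- history$domain
    period <- history$retained_time
  } else {
    ledger <- history
    if (is.null(domain) || is.null(period))
      stop("adhesion_profile: need domain and period for a raw ledger")
  }
  wall <- domain$wall
  areas <- wall_bin_areas(domain)
  st <- wall$stations
  rate <- numeric(length(st))
  for (j in seq_along(st)) {
    sel <- wall$s_bin == j
    rate[j] <- sum(ledger[sel]) / (sum(areas[sel]) * period)
  }
  TT <- if (inherits(history, "flow_history")) history$waveform$period else
    period
  data.frame(s_mm = st, rate = rate,
             rate_nondim = rate * TT / (domain$D * MM))
}
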