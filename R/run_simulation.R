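# Orchestration: build geometry from a validated config, run the coupled
# hemodynamics / transport stages, and write the artifact bundle.

`%||%` <- function(a, b) if (is.null(a)) b else a

build_geometry <- function(g, seed = 1L) {
  straightened <- isTRUE(g$straighten)
  if (g$source == "ideal") {
    spec <- do.call(ideal_stenosis_spec, as.list(g$ideal %||% list()))
    surf <- build_ideal_stenosis(spec)
    study <- NULL
  } else if (g$source == "contours") {
    frames <- read_contours(g$contours_path)
    surf <- if (straightened) straighten(frames) else
      stack_frames(frames, read_centerline(g$centerline_path))
    study <- NULL
  } else {  # synthetic
    sargs <- as.list(g$synthetic %||% list())
    if (is.null(sargs$seed)) sargs$seed <- seed
    spec <- do.call(synthetic_study_spec, sargs)
    study <- synth_baseline(spec)
    surf <- if (straightened) straighten(study$frames) else
      stack_frames(study$frames, study$centerline)
    study$spec <- spec
  }
  ext <- g$extensions
  if (!identical(ext, FALSE) && g$source != "ideal") {
    surf <- add_extensions(surf,
                           inlet_length = ext$inlet_length %||% NULL,
                           outlet_length = ext$outlet_length %||% NULL)
  }
  list(surface = surf, study = study, straightened = straightened)
}

build_waveform <- function(wcfg) {
  type <- wcfg$type %||% "default"
  switch(type,
    default = default_waveform(u_mean = wcfg$u_mean %||% 0.384,
                               period = wcfg$period %||% 0.8),
    constant = constant_waveform(u_bulk = wcfg$u_bulk %||% 0.384,
                                 period = wcfg$period %||% 0.8),
    file = {
      df <- utils::read.csv(wcfg$path, check.names = FALSE)
      check_header(df, c("t_s", "u_bulk_m_s"), wcfg$path)
      pulsatile_waveform(df$t_s, df$u_bulk_m_s,
                         u_mean = wcfg$u_mean %||% NULL)
    },
    stop("run config: unknown waveform type '", type, "'"))
}

build_species <- function(spcfg) {
  if (is.null(spcfg)) return(list())
  if (is.data.frame(spcfg)) spcfg <- split(spcfg, seq_len(nrow(spcfg)))
  lapply(spcfg, function(sp) {
    sp <- as.list(sp)
    leukocyte_species(name = sp$name %||% "neutrophil",
                      rho_ref = sp$rho_ref %||% NULL,
                      wss_th = sp$wss_th %||% NULL,
                      k_max = sp$k_max %||% 1,
                      law = sp$law %||% "ramp",
                      mode = sp$mode %||% "tracked")
  })
}

#' Run a full coupled simulation from a configuration
#'
#' Executes the geometry, flow, wall-shear and leukocyte stages described
#' by a validated run configuration (see [read_run_config()]) and, when
#' `output_dir` is set, writes the artifact bundle: sectional WSS and
#' adhesion profiles (CSV), the wall ledger, the per-step log, a VTK
#' surface, and a provenance-stamped JSON report.
#'
#' @param cfg configuration list (validated with [validate_run_config()]).
#' @param dry_run validate and report grid/step estimates without
#'   computing.
#' @return invisibly, a list with the surface, domain, flow history,
#'   per-species adhesion profiles and the report.
#' @export
run_simulation <- function(cfg, dry_run = FALSE) {
  cfg <- validate_run_config(cfg)
  seed <- as.integer(cfg$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  geo <- stage("geometry", build_geometry(cfg$geometry, seed))
  fluid <- stage("fluid", do.call(fluid_properties,
                                  as.list(cfg$fluid %||% list())))
  waveform <- stage("waveform", build_waveform(cfg$waveform %||% list()))
  gridcfg <- cfg$grid %||% list()
  config <- stage("solver", do.call(solver_config,
                                    as.list(cfg$solver %||% list())))
  species <- stage("species", build_species(cfg$species))

  if (dry_run) {
    h <- geo$surface$D / (gridcfg$cells_per_diameter %||% 12)
    sg <- geo$surface$s_grid
    sp <- surface_points(geo$surface,
                         seq(sg[1], sg[length(sg)], length.out = 40))
    ext <- apply(sp$P, 2, range)
    dims <- ceiling((ext[2, ] - ext[1, ]) / h) +
      c(0, 2, 2) * (gridcfg$margin_cells %||% 4)
    dt <- select_dt(list(h = h * MM, area_min = min(
      surface_area_profile(geo$surface)),
      inlet_area = pi * mean(geo$surface$R[1, ])^2 * MM^2),
      fluid, waveform, config)
    est <- list(valid = TRUE, grid = as.integer(dims),
                cells = prod(as.integer(dims)),
                steps_per_cycle = ceiling(waveform$period / dt))
    return(invisible(est))
  }

  domain <- stage("grid", flow_domain(
    geo$surface,
    cells_per_diameter = gridcfg$cells_per_diameter %||% 12,
    margin_cells = gridcfg$margin_cells %||% 4L))
  history <- stage("flow", run_cycles(domain, fluid, waveform, config,
                                      species = species))
  wssp <- stage("wall_shear", wss_profile(history))
  profiles <- stage("leukocyte", lapply(seq_along(species), function(i)
    adhesion_profile(history, i)))
  names(profiles) <- vapply(species, function(sp) sp$name, "")

  report <- list(
    package = "leukoflow",
    version = as.character(utils::packageVersion("leukoflow")),
    seed = seed,
    straightened = geo$straightened,
    grid = c(domain$nx, domain$ny, domain$nz),
    h_mm = domain$h_mm,
    dt_s = history$dt,
    steps_per_cycle = history$steps_per_cycle,
    cycles = config$cycles, discarded = config$discard,
    periodicity_residual = history$periodicity_residual,
    max_divergence = max(history$log$max_div),
    flow_rate_mismatch = max(abs(history$log$q_in - history$log$q_out) /
                             pmax(abs(history$log$q_in), 1e-300)),
    species = lapply(species, function(sp)
      sp[c("name", "rho_ref", "wss_th", "k_max", "law", "mode")]))

  out <- cfg$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out, "config.json")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    report$config_md5 <- as.character(tools::md5sum(cfg_path))
    utils::write.csv(wssp$profile, file.path(out, "wss_profile.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(history$log, file.path(out, "step_log.csv"),
                     row.names = FALSE, quote = FALSE)
    wall <- domain$wall
    for (nm in names(profiles)) {
      utils::write.csv(profiles[[nm]],
                       file.path(out, paste0("adhesion_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
      led <- data.frame(
        s_mm = wall$stations[wall$s_bin],
        theta_rad = wall$thetas[wall$theta_bin],
        adhered_per_area = history$ledger[[nm]] / wall_bin_areas(domain),
        stringsAsFactors = FALSE)
      utils::write.csv(led,
                       file.path(out, paste0("ledger_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    if (domain$type == "artery3d")
      write_surface_vtk(geo$surface, file.path(out, "surface.vtk"),
                        point_data = list(wss_bar = ifelse(
                          is.na(wssp$profile$wss_bar_pa), 0,
                          wssp$profile$wss_bar_pa)))
    write_report_json(report, file.path(out, "report.json"))
  }

  # optional analysis stage against a provided lumen series
  if (!is.null(cfg$analysis$lumen_series_path)) {
    series <- read_lumen_series(cfg$analysis$lumen_series_path)
    cors <- lapply(profiles, function(p)
      tryCatch(unclass(correlate_adhesion(p, series)),
               error = function(e) list(error = conditionMessage(e))))
    report$correlations <- cors
    if (!is.null(out)) write_report_json(report,
                                         file.path(out, "report.json"))
  }

  invisible(list(surface = geo$surface, study = geo$study,
                 domain = domain, history = history,
                 wss = wssp, adhesion = profiles, report = report))
}

#' Compare realistic-centerline and straightened geometries
#'
#' Runs the same contour frames stacked on their tortuous centerline and
#' on a straight axis under identical flow conditions, and compares the
#' sectional average WSS and its azimuthal variability.
#'
#' @param cfg a run configuration (geometry must be `contours` or
#'   `synthetic`).
#' @return list with both run results and a per-station comparison
#'   data.frame.
#' @export
compare_centerlines <- function(cfg) {
  cfg <- validate_run_config(cfg)
  cfg$output_dir <- NULL
  cfg_straight <- cfg
  cfg$geometry$straighten <- FALSE
  cfg_straight$geometry$straighten <- TRUE
  real <- run_simulation(cfg)
  straight <- run_simulation(cfg_straight)
  pr <- real$wss$profile; ps <- straight$wss$profile
  vr <- apply(real$wss$time_avg, 1, stats::var, na.rm = TRUE)
  vs <- apply(straight$wss$time_avg, 1, stats::var, na.rm = TRUE)
  seg <- real$domain$surface$segment
  comp <- data.frame(s_mm = pr$s_mm, segment = seg,
                     wss_bar_real = pr$wss_bar_pa,
                     wss_bar_straight = ps$wss_bar_pa,
                     var_theta_real = vr, var_theta_straight = vs)
  list(real = real, straight = straight, comparison = comp)
}
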