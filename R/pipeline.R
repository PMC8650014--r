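# Orchestration: run configuration (with lossless YAML round-trip),
# geometry generation, the steady/pulsatile delivery experiment, and the
# run-pair comparison. A thin command-line wrapper over these functions
# ships in inst/cli/nasoaero-cli.R.

#' Run configuration
#'
#' Nested configuration with defaults reproducing the reference delivery
#' setup: 1 um particles, 4 L/min mean flow, 45 Hz pulsation (in pulsatile
#' mode), 2.5 mg injected over 0.5 s, simulated to 1.98 s. Unknown keys are
#' rejected (a silent typo would change the physics).
#'
#' @param geometry list: `kind` ("surrogate", "duct" or "bend") plus
#'   generator parameters (`params` overrides for the surrogate; `radius`,
#'   `length`, `bend_radius`, `angle` for the benchmarks); `dx` optional
#'   voxel size (m).
#' @param flow list: `mean_L_per_min`, `mode` ("steady"/"sinusoidal"),
#'   `frequency_Hz`.
#' @param particle list: `diameter_um`, `density_kg_m3`, `n_parcels`,
#'   `mass_mg`, `injection_s`.
#' @param run list: `t_end_s`, `courant_max`, `seed`, `two_way`.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(geometry = list(), flow = list(), particle = list(),
                       run = list()) {
  def <- list(
    geometry = list(kind = "surrogate", dx = NULL, params = list(),
                    radius = NULL, length = NULL, bend_radius = NULL,
                    angle = NULL),
    flow = list(mean_L_per_min = 4, mode = "sinusoidal", frequency_Hz = 45),
    particle = list(diameter_um = 1, density_kg_m3 = 1000,
                    n_parcels = 2000L, mass_mg = 2.5, injection_s = 0.5),
    run = list(t_end_s = 1.98, courant_max = 0.9, seed = 1L,
               two_way = FALSE))
  merge_section <- function(d, o, name) {
    unknown <- setdiff(names(o), names(d))
    if (length(unknown))
      stop("unknown config key(s) in ", name, ": ",
           paste(unknown, collapse = ", "))
    d[names(o)] <- o
    d
  }
  cfg <- list(geometry = merge_section(def$geometry, geometry, "geometry"),
              flow = merge_section(def$flow, flow, "flow"),
              particle = merge_section(def$particle, particle, "particle"),
              run = merge_section(def$run, run, "run"))
  if (!cfg$flow$mode %in% c("steady", "sinusoidal"))
    stop("flow mode must be steady or sinusoidal")
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' Round-trips losslessly through the file.
#' @param cfg a `run_config`.
#' @param path file path.
#' @return `path` / the `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), c("geometry", "flow", "particle", "run"))
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  raw$particle$n_parcels <- as.integer(raw$particle$n_parcels)
  raw$run$seed <- as.integer(raw$run$seed)
  do.call(run_config, raw)
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  switch(g$kind,
         surrogate = build_nasal_surrogate(
           do.call(nasal_params, g$params %||% list()),
           seed = cfg$run$seed),
         duct = build_duct(g$radius %||% 0.005, g$length %||% 0.1),
         bend = build_bend(g$radius %||% 0.0025, g$bend_radius %||% 0.0125,
                           g$angle %||% (pi / 2)),
         stop("unknown geometry kind: ", g$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate geometry and grid files
#'
#' Builds the configured geometry, writes STL + legacy-VTK surface files and
#' the patch JSON sidecar, and logs the patch areas (with the
#' cavity/olfactory area ratio for the surrogate).
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return invisible list with the mesh and file paths.
#' @export
cmd_generate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- config_geometry(cfg)
  paths <- list(stl = file.path(out_dir, "surface.stl"),
                vtk = file.path(out_dir, "surface.vtk"),
                patches = file.path(out_dir, "patches.json"))
  write_stl_binary(mesh, paths$stl)
  write_vtk_polydata(mesh, paths$vtk)
  write_patch_json(mesh, paths$patches)
  pa <- patch_areas(mesh) * 1e6
  message(sprintf("geometry '%s': %d patches, total wall area %.1f mm^2",
                  cfg$geometry$kind, length(pa),
                  sum(pa[names(pa) != "inlet" & names(pa) != "outlet"])))
  if (cfg$geometry$kind == "surrogate") {
    s <- surrogate_area_summary(mesh)
    message(sprintf(
      "olfactory areas R/L: %.1f / %.1f mm^2; cavity/olfactory ratio %.1f",
      s$olfactory_R_mm2, s$olfactory_L_mm2, s$cavity_olfactory_ratio))
  }
  invisible(list(mesh = mesh, paths = paths))
}

#' Run the configured delivery experiment
#'
#' Voxelizes the geometry, prescribes the quasi-one-dimensional base flow at
#' the configured mean flow rate, runs parcel transport (and, optionally,
#' the ventilation tracer), and writes the deposition report (CSV + JSON),
#' the deposited-parcel cloud (VTK) and a manifest.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory.
#' @param scalar also advance the passive ventilation scalar (on a coarser
#'   grid; see `scalar_dx_factor`).
#' @param scalar_dx_factor coarsening factor of the scalar grid.
#' @param scalar_t_end tracer simulation time (s); defaults to `t_end_s`.
#' @return invisible list with the result, reports and file paths.
#' @export
cmd_run <- function(cfg, out_dir, scalar = FALSE, scalar_dx_factor = 2,
                    scalar_t_end = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- config_geometry(cfg)
  dx <- cfg$geometry$dx %||% (min(mesh$sweep$stations$b) / 4.2)
  grid <- voxelize(mesh, dx)
  Q0 <- lpm_to_m3s(cfg$flow$mean_L_per_min)
  grid <- sweep_velocity_field(grid, mesh, Q0)
  w <- waveform(cfg$flow$mode, Q0, pi * prod(mesh$sweep$inlet_ab),
                cfg$flow$frequency_Hz)
  spec <- injection_spec(cfg$particle$n_parcels, cfg$particle$mass_mg,
                         cfg$particle$injection_s, cfg$particle$diameter_um,
                         cfg$particle$density_kg_m3)
  res <- run_transport(mesh, grid, w, spec, t_end = cfg$run$t_end_s,
                       seed = cfg$run$seed, two_way = cfg$run$two_way,
                       courant_max = cfg$run$courant_max)
  rep <- deposition_efficiency(res)
  dose <- dose_per_area(res, patch_areas(mesh)[
    mesh$patch_table$patch[mesh$patch_table$role == "wall"]] * 1e6)
  message(sprintf("run complete: total DE %.3f %%, mass balance %.2e",
                  attr(rep, "total_de_pct"), mass_balance(res)))

  vent <- NULL
  if (scalar) {
    gsc <- voxelize(mesh, dx * scalar_dx_factor, check_resolution = FALSE)
    gsc <- sweep_velocity_field(gsc, mesh, Q0)
    gsc$C <- array(0, gsc$dims)
    inlet <- inlet_cell_mask(gsc, mesh)
    t_end_c <- scalar_t_end %||% cfg$run$t_end_s
    dtc <- 0.45 * gsc$dx / (max(abs(gsc$u)) *
                              (if (w$mode == "sinusoidal") 2 else 1))
    tt <- 0
    while (tt < t_end_c) {
      sc <- inlet_velocity(w, tt) / w$U0
      gsc <- advance_scalar(gsc, min(dtc, t_end_c - tt), inlet, scale = sc)
      tt <- tt + dtc
    }
    regions <- region_cell_masks(gsc, mesh)
    vent <- ventilation_report(gsc, regions, time = t_end_c)
  }

  paths <- list(report_csv = file.path(out_dir, "deposition_report.csv"),
                report_json = file.path(out_dir, "deposition_report.json"),
                parcels_vtk = file.path(out_dir, "deposited_parcels.vtk"),
                manifest = file.path(out_dir, "manifest.json"))
  tab <- merge(rep, dose, by.x = "region", by.y = "patch", all.x = TRUE)
  tab <- tab[order(tab$region),
             c("region", "side", "deposited_mg", "de_pct", "area_mm2",
               "dose_ng_mm2")]
  utils::write.csv(tab, paths$report_csv, row.names = FALSE)
  jsonlite::write_json(
    list(injected_mg = attr(rep, "injected_mg"),
         total_de_pct = attr(rep, "total_de_pct"),
         escaped_mg = attr(rep, "escaped_mg"),
         airborne_mg = attr(rep, "airborne_mg"),
         mass_balance_residual = mass_balance(res),
         volume_fraction = res$volume_fraction,
         regions = tab),
    paths$report_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_vtk_parcels(res, paths$parcels_vtk)
  if (!is.null(vent))
    jsonlite::write_json(vent, file.path(out_dir, "ventilation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("nasoaero")),
         seed = cfg$run$seed, config = unclass(cfg),
         mass_balance_residual = mass_balance(res)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(result = res, report = rep, dose = dose,
                 ventilation = vent, paths = paths, mesh = mesh))
}

#' Compare two run bundles (or two printed DE values)
#'
#' With two run directories, reads both deposition reports and emits the
#' [ratio_metrics()] table. With two numbers, returns the scalar fold
#' change (printed-values mode, e.g. `cmd_compare(50.9, 34.4)` = 1.48).
#'
#' @param a,b run output directories (from [cmd_run()]) or single numbers.
#' @return ratio table list, or a single fold change.
#' @export
cmd_compare <- function(a, b) {
  if (is.numeric(a) && is.numeric(b) && length(a) == 1L && length(b) == 1L)
    return(fold_change(a, b))
  ra <- read_run_report(a)
  rb <- read_run_report(b)
  if (!identical(sort(ra$region), sort(rb$region)))
    stop("mismatched region partitions between run bundles")
  ratio_metrics(ra, rb)
}

read_run_report <- function(dir) {
  path <- file.path(dir, "deposition_report.json")
  if (!file.exists(path)) stop("missing deposition report: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- js$regions
  attr(rep, "total_de_pct") <- js$total_de_pct
  attr(rep, "injected_mg") <- js$injected_mg
  class(rep) <- c("deposition_report", "data.frame")
  rep
}
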