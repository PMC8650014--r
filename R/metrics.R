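# Deposition endpoints: regional deposition efficiency (DE, % of injected
# mass), dose per epithelial area (ng/mm^2), right/left and
# steady/pulsatile ratio tables, the impaction parameter, and the
# mass-balance audit.

#' Regional deposition efficiency
#'
#' `DE_region = 100 * deposited mass in region / injected mass`, plus the
#' escaped and airborne complements. Regions default to the wall patches of
#' the run's geometry; a custom partition maps patch labels to region names.
#'
#' @param result a `simulation_result`.
#' @param partition optional named character vector `patch -> region`; the
#'   default uses each wall patch as its own region.
#' @return data.frame of class `deposition_report` with per-region deposited
#'   mass (mg), DE (%), and the patch areas (mm^2) when available.
#' @export
deposition_efficiency <- function(result, partition = NULL) {
  inj <- result$injected_mass_kg
  empty <- nrow(result$parcels) == 0L
  if (inj <= 0 && !empty) stop("domain error: zero injected mass")
  if (empty) inj <- NA_real_   # DEs defined as 0 for an empty run
  pt <- result$mesh_patches
  wall_patches <- pt$patch[pt$role == "wall"]
  if (is.null(partition)) {
    partition <- stats::setNames(wall_patches, wall_patches)
  }
  p <- result$parcels
  dep <- p[p$status == "deposited", , drop = FALSE]
  region <- unname(partition[dep$patch])
  rows <- lapply(unique(unname(partition)), function(rg) {
    m <- sum(dep$mass_kg[!is.na(region) & region == rg])
    data.frame(region = rg, deposited_mg = m * 1e6,
               de_pct = if (empty) 0 else 100 * m / inj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  side <- pt$side[match(names(partition), pt$patch)]
  out$side <- side[match(out$region, unname(partition))]
  attr(out, "injected_mg") <- if (empty) 0 else inj * 1e6
  attr(out, "escaped_mg") <- sum(p$mass_kg[p$status == "escaped"]) * 1e6
  attr(out, "airborne_mg") <- sum(p$mass_kg[p$status == "airborne"]) * 1e6
  attr(out, "total_de_pct") <- if (empty) 0 else 100 * sum(dep$mass_kg) / inj
  class(out) <- c("deposition_report", "data.frame")
  out
}

#' Total deposition efficiency of a run
#' @param result a `simulation_result`.
#' @return DE over all wall patches (% of injected mass).
#' @export
total_de <- function(result) {
  inj <- result$injected_mass_kg
  if (nrow(result$parcels) == 0L) return(0)
  if (inj <= 0) stop("domain error: zero injected mass")
  100 * sum(result$parcels$mass_kg[result$parcels$status == "deposited"]) / inj
}

#' Dose per unit epithelial area
#'
#' Deposited mass per patch divided by the patch area, in ng/mm^2 (the
#' therapeutically relevant local metric; 100 % drug loading assumed).
#'
#' @param result a `simulation_result`.
#' @param areas_mm2 named numeric vector of patch areas (mm^2); typically
#'   `patch_areas(mesh) * 1e6`.
#' @return data.frame with patch, deposited mass (ng), area (mm^2) and dose
#'   (ng/mm^2).
#' @export
dose_per_area <- function(result, areas_mm2) {
  if (any(areas_mm2 <= 0)) stop("domain error: zero patch area")
  p <- result$parcels
  dep <- p[p$status == "deposited", , drop = FALSE]
  rows <- lapply(names(areas_mm2), function(pa) {
    m_ng <- sum(dep$mass_kg[dep$patch == pa]) * 1e12
    data.frame(patch = pa, deposited_ng = m_ng, area_mm2 = areas_mm2[[pa]],
               dose_ng_mm2 = m_ng / areas_mm2[[pa]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dose per area from a deposited mass and an area
#'
#' Scalar convenience form: mass in kg over area in mm^2, in ng/mm^2.
#' @param mass_kg deposited mass (kg).
#' @param area_mm2 patch area (mm^2), > 0.
#' @export
dose_from_mass <- function(mass_kg, area_mm2) {
  if (any(area_mm2 <= 0)) stop("domain error: zero patch area")
  mass_kg * 1e12 / area_mm2
}

#' Fold change between two quantities
#'
#' `a / b`, with division by zero reported as `Inf` (never an error): the
#' building block of the right/left and steady/pulsatile ratio tables.
#' @param a,b numeric.
#' @export
fold_change <- function(a, b) ifelse(b == 0, ifelse(a == 0, 1, Inf), a / b)

#' Ratio table for a steady vs pulsatile run pair
#'
#' Per-report right/left DE ratios (over the sided regions) and per-region
#' steady/pulsatile fold changes. Ratios with a zero denominator are
#' reported as `Inf`.
#'
#' @param reportA `deposition_report` of the reference (e.g. steady) run.
#' @param reportB `deposition_report` of the comparison (e.g. pulsatile) run.
#' @return list with `right_left_A`, `right_left_B`, `olf_right_left_A/B`
#'   when olfactory regions are present, per-region `fold_change`
#'   (A over B), and `total_fold_change`.
#' @export
ratio_metrics <- function(reportA, reportB) {
  if (!identical(sort(reportA$region), sort(reportB$region)))
    stop("reports do not share a region partition")
  B <- reportB[match(reportA$region, reportB$region), ]
  rl <- function(rep) {
    r <- sum(rep$de_pct[!is.na(rep$side) & rep$side == "R"])
    l <- sum(rep$de_pct[!is.na(rep$side) & rep$side == "L"])
    fold_change(r, l)
  }
  olf_rl <- function(rep) {
    if (!all(c("olfactory_R", "olfactory_L") %in% rep$region)) return(NA_real_)
    fold_change(rep$de_pct[rep$region == "olfactory_R"],
                rep$de_pct[rep$region == "olfactory_L"])
  }
  list(right_left_A = rl(reportA),
       right_left_B = rl(reportB),
       olf_right_left_A = olf_rl(reportA),
       olf_right_left_B = olf_rl(reportB),
       fold_change = stats::setNames(fold_change(reportA$de_pct, B$de_pct),
                                     reportA$region),
       total_fold_change = fold_change(attr(reportA, "total_de_pct"),
                                       attr(reportB, "total_de_pct")))
}

#' Impaction parameter
#'
#' `IP = d^2 Q` in the conventional mixed units (micrometre^2 L/min): the
#' classical correlating variable of nasal inertial deposition.
#' @param d_um particle aerodynamic diameter (micrometres).
#' @param Q_lpm volumetric flow (L/min).
#' @export
impaction_parameter <- function(d_um, Q_lpm) {
  stopifnot(all(d_um > 0), all(Q_lpm > 0))
  d_um^2 * Q_lpm
}

#' Deposition-efficiency curve over particle diameters
#'
#' Runs one transport simulation per diameter at a fixed flow rate and seed
#' and tabulates DE against the impaction parameter. On impaction-dominated
#' geometries (bends, the nasal surrogate) DE increases with `IP = d^2 Q`.
#'
#' @param mesh,grid geometry and its voxelized grid with `u` set for the
#'   requested flow.
#' @param diameters_um ascending particle diameters (micrometres).
#' @param Q_lpm flow rate (L/min); must match the field on `grid`.
#' @param seed integer seed reused for every diameter.
#' @param spec base [injection_spec()]; its diameter is overridden.
#' @param t_end simulation end time (s).
#' @param ... further arguments to [run_transport()].
#' @return data.frame with `d_um`, `ip`, `de_pct`.
#' @export
de_curve <- function(mesh, grid, diameters_um, Q_lpm, seed,
                     spec = injection_spec(), t_end, ...) {
  if (is.unsorted(diameters_um)) stop("diameters must be sorted ascending")
  w <- waveform("steady", lpm_to_m3s(Q_lpm), pi * prod(mesh$sweep$inlet_ab))
  rows <- lapply(diameters_um, function(dum) {
    sp <- spec
    sp$diameter_um <- dum
    res <- run_transport(mesh, grid, w, sp, t_end = t_end, seed = seed, ...)
    data.frame(d_um = dum, ip = impaction_parameter(dum, Q_lpm),
               de_pct = total_de(res))
  })
  do.call(rbind, rows)
}

#' Mass-balance residual of a run
#'
#' `|injected - deposited - escaped - airborne| / injected`; 0 for an empty
#' run. Every parcel keeps its mass through its fate, so the residual is a
#' pure bookkeeping audit that must sit at rounding level.
#'
#' @param result a `simulation_result`.
#' @return non-negative residual fraction.
#' @export
mass_balance <- function(result) {
  p <- result$parcels
  inj <- result$injected_mass_kg
  if (nrow(p) == 0L || inj == 0) return(0)
  acc <- sum(p$mass_kg[p$status == "deposited"]) +
    sum(p$mass_kg[p$status == "escaped"]) +
    sum(p$mass_kg[p$status == "airborne"])
  abs(inj - acc) / inj
}

#' @export
print.deposition_report <- function(x, ...) {
  cat(sprintf("deposition_report: injected %.3f mg, total DE %.3f %%\n",
              attr(x, "injected_mg"), attr(x, "total_de_pct")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("  escaped %.3f mg, airborne %.3f mg\n",
              attr(x, "escaped_mg"), attr(x, "airborne_mg")))
  invisible(x)
}
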