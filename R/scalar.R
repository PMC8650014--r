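# Passive-scalar ventilation tracer. C is the drug-laden-air fraction:
# 0 = resident air, 1 = inhaled air. It is advected by the resolved velocity
# and diffused with total diffusivity nu/Sc + nu_sgs/Sc_sgs; the inlet holds
# C = 1 (Dirichlet).

#' Mark the fluid cells adjacent to the inlet cap
#'
#' These cells carry the `C = 1` Dirichlet condition of the ventilation
#' tracer.
#' @param grid a `flow_grid`.
#' @param mesh the swept `surface_mesh`.
#' @param depth thickness of the inlet layer in cells.
#' @return logical array.
#' @export
inlet_cell_mask <- function(grid, mesh, depth = 1.5) {
  sw <- mesh$sweep
  P <- cell_centers(grid)
  rel <- sweep(P, 2, sw$inlet_center)
  along <- as.vector(rel %*% sw$inlet_tangent)
  array(as.vector(grid$inside) & along >= 0 & along <= depth * grid$dx,
        grid$dims)
}

#' Advance the passive ventilation scalar
#'
#' One explicit step of the scalar conservation law with first-order upwind
#' (donor-cell) advection and conservative central diffusion with spatially
#' varying total diffusivity `nu/Sc + nu_sgs/Sc_sgs`. Faces adjoining
#' non-fluid cells carry zero flux (impermeable walls). After the update the
#' inlet cells are reset to 1 and the field is clamped to `[0, 1]`.
#'
#' @param grid a `flow_grid` with `u` and `C` set.
#' @param dt time step (s); checked against the advective and diffusive
#'   stability bounds.
#' @param inlet_cells logical array from [inlet_cell_mask()].
#' @param Sc molecular Schmidt number (default 0.7, air-like tracer).
#' @param Sc_sgs subgrid Schmidt number (default 0.7).
#' @param nu gas kinematic viscosity (m^2/s).
#' @param nusgs SGS viscosity field or scalar (m^2/s), 0 when disabled.
#' @param scale quasi-steady waveform factor applied to the stored velocity.
#' @return the grid with `C` advanced by `dt`.
#' @export
advance_scalar <- function(grid, dt, inlet_cells, Sc = 0.7, Sc_sgs = 0.7,
                           nu = 1.5e-5, nusgs = 0, scale = 1) {
  stopifnot(!is.null(grid$u), !is.null(grid$C))
  d <- grid$dims
  dx <- grid$dx
  C <- grid$C
  ins <- grid$inside + 0

  D <- nu / Sc + nusgs / Sc_sgs
  if (is.null(dim(D))) D <- array(D, d)

  umax <- max(abs(grid$u)) * abs(scale)
  if (umax > 0 && dt > dx / umax)
    stop("stability error: dt exceeds the advective bound dx/max|u|")
  Dmax <- max(D)
  if (Dmax > 0 && dt > dx^2 / (6 * Dmax))
    stop("stability error: dt exceeds the diffusive bound dx^2/(6 D)")

  dC <- array(0, d)
  for (ax in 1:3) {
    sh_m <- replace(c(0, 0, 0), ax, 1)    # neighbour at i-1
    sh_p <- replace(c(0, 0, 0), ax, -1)   # neighbour at i+1
    uax <- array(grid$u[, , , ax], d) * scale
    u_m <- shift_array(uax, sh_m)
    C_m <- shift_array(C, sh_m)
    D_m <- shift_array(D, sh_m)
    ins_m <- shift_array(ins, sh_m)
    # face between cell i-1 and i (the "low" face of cell i)
    uf <- 0.5 * (uax + u_m)
    open <- ins * ins_m                   # both cells fluid
    adv_lo <- ifelse(uf > 0, uf * C_m, uf * C) * open
    dif_lo <- 0.5 * (D + D_m) * (C - C_m) / dx * open
    # the "high" face of cell i is the low face of cell i+1
    adv_hi <- shift_array(adv_lo, sh_p)
    dif_hi <- shift_array(dif_lo, sh_p)
    dC <- dC + (adv_lo - adv_hi) / dx + (dif_hi - dif_lo) / dx
  }
  C <- C + dt * dC
  C[inlet_cells] <- 1
  C <- pmin(pmax(C, 0), 1)
  C[!grid$inside] <- 0
  grid$C <- C
  grid
}

#' Volume-weighted mean scalar over a region
#'
#' `sum(C V_cell) / sum(V_cell)` over the fluid cells of the region.
#' @param grid a `flow_grid` with `C` set.
#' @param region logical array selecting the region's cells.
#' @return dimensionless fraction in `[0, 1]`.
#' @export
region_mean_C <- function(grid, region) {
  sel <- region & grid$inside
  if (!any(sel)) stop("domain error: empty region")
  mean(grid$C[sel])
}

#' Fraction of a region's volume above a scalar threshold
#'
#' The iso-volume diagnostic: the volume fraction of the region where
#' `C > threshold` (e.g. 0.99 = essentially fully filled by inhaled air).
#' @param grid a `flow_grid` with `C` set.
#' @param region logical array selecting the region.
#' @param threshold scalar threshold in (0, 1).
#' @export
iso_volume_fraction <- function(grid, region, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  sel <- region & grid$inside
  if (!any(sel)) stop("domain error: empty region")
  mean(grid$C[sel] > threshold)
}

#' Fraction of the inlet flow crossing a grid-plane section
#'
#' Integrates the normal velocity over an axis-aligned cross-section
#' (optionally restricted by a mask) and reports it as a percentage of the
#' inlet volumetric flow.
#'
#' @param grid a `flow_grid` with `u` set.
#' @param section list with `axis` (1, 2 or 3), `index` (plane cell index)
#'   and optionally `mask` (logical array of grid dims restricting the
#'   section).
#' @param Q_in inlet volumetric flow (m^3/s), > 0.
#' @return percentage of the inlet flow.
#' @export
region_flow_fraction <- function(grid, section, Q_in) {
  if (Q_in <= 0) stop("domain error: zero inlet flow")
  d <- grid$dims
  ax <- section$axis
  sel <- switch(ax,
                slice.index(grid$inside, 1) == section$index,
                slice.index(grid$inside, 2) == section$index,
                slice.index(grid$inside, 3) == section$index)
  sel <- sel & grid$inside
  if (!is.null(section$mask)) sel <- sel & section$mask
  uax <- array(grid$u[, , , ax], d)
  flux <- sum(uax[sel]) * grid$dx^2
  100 * flux / Q_in
}

#' Regional ventilation report
#'
#' Volume-weighted mean tracer, iso-volume fractions at the 0.5 and 0.99
#' thresholds, and (when sections are supplied) regional flow fractions.
#'
#' @param grid a `flow_grid` with `C` set.
#' @param regions named list of logical region masks.
#' @param time evaluation time (s), recorded in the report.
#' @param sections optional named list of section specs for
#'   [region_flow_fraction()].
#' @param Q_in inlet flow (m^3/s), required with `sections`.
#' @return data.frame of class `ventilation_report`.
#' @export
ventilation_report <- function(grid, regions, time = NA_real_,
                               sections = NULL, Q_in = NULL) {
  rows <- lapply(names(regions), function(nm) {
    data.frame(region = nm,
               mean_C = region_mean_C(grid, regions[[nm]]),
               iso_frac_0p5 = iso_volume_fraction(grid, regions[[nm]], 0.5),
               iso_frac_0p99 = iso_volume_fraction(grid, regions[[nm]], 0.99),
               flow_fraction_pct = if (!is.null(sections) && nm %in% names(sections))
                 region_flow_fraction(grid, sections[[nm]], Q_in) else NA_real_,
               time_s = time,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ventilation_report", "data.frame")
  out
}

#' Volumetric region masks for a swept geometry
#'
#' Assigns each fluid cell to the region of its nearest centerline station;
#' the olfactory regions are the dorsal sub-volumes (normalized dorsal
#' coordinate above `dorsal_frac`) of the olfactory streamwise windows.
#'
#' @param grid a `flow_grid` from [voxelize()].
#' @param mesh the swept `surface_mesh`.
#' @param dorsal_frac dorsal cutoff for the olfactory sub-volume.
#' @return named list of logical arrays.
#' @export
region_cell_masks <- function(grid, mesh, dorsal_frac = 0.6) {
  st <- mesh$sweep$stations
  C <- as.matrix(st[, c("cx", "cy", "cz")])
  ins <- which(grid$inside)
  P <- cell_centers(grid, grid$inside)
  idx <- cpp_nearest_station(P, C)
  reg <- st$region[idx]

  sw <- mesh$sweep
  if (!is.null(sw$olf_window_R)) {
    n2 <- as.matrix(st[, c("n2x", "n2y", "n2z")])
    rel <- P - C[idx, , drop = FALSE]
    zhat <- rowSums(rel * n2[idx, , drop = FALSE]) / st$a[idx]
    s_here <- st$s[idx]
    olfR <- s_here >= sw$olf_window_R[1] & s_here < sw$olf_window_R[2] &
      zhat > dorsal_frac
    olfL <- s_here >= sw$olf_window_L[1] & s_here < sw$olf_window_L[2] &
      zhat > dorsal_frac
    reg[olfR] <- "olfactory_R"
    reg[olfL] <- "olfactory_L"
  }

  out <- lapply(unique(reg), function(nm) {
    m <- array(FALSE, grid$dims)
    m[ins[reg == nm]] <- TRUE
    m
  })
  names(out) <- unique(reg)
  out
}
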