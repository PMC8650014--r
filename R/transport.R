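# Parcel transport: wall-hit detection against the triangulated boundary,
# the two-way-coupling momentum source, and the main time loop.

#' Build a triangle spatial index for wall-hit queries
#'
#' Bins triangles into a uniform voxel grid by their bounding boxes; segment
#' queries then test only local triangles.
#' @param mesh a `surface_mesh`.
#' @param cell_size index cell size (m); defaults to about twice the median
#'   triangle edge scale.
#' @return list used by [detect_wall_hits()].
#' @export
build_tri_index <- function(mesh, cell_size = NULL) {
  if (is.null(cell_size)) {
    cell_size <- 2 * sqrt(4 * stats::median(tri_areas(mesh)) / sqrt(3))
  }
  V <- mesh$vertices
  lo <- apply(V, 2, min) - cell_size
  hi <- apply(V, 2, max) + cell_size
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / cell_size)))
  idx <- cpp_build_cell_tris(V, mesh$triangles, lo, cell_size, dims)
  list(origin = lo, dx = cell_size, dims = dims,
       offsets = idx$offsets, items = idx$items)
}

#' Earliest wall hits for a batch of sub-step segments
#'
#' For each segment `x0 -> x1`, finds the earliest segment-triangle
#' intersection (smallest parametric fraction, ties broken by triangle
#' index) and reports the owning patch.
#'
#' @param P0,P1 n x 3 matrices of segment endpoints (m).
#' @param mesh a `surface_mesh`.
#' @param index optional index from [build_tri_index()] (built on the fly if
#'   missing).
#' @return list with `tri` (triangle id or NA), `frac` (fraction along the
#'   segment), `patch` (patch label or NA).
#' @export
detect_wall_hits <- function(P0, P1, mesh, index = NULL) {
  if (is.null(index)) index <- build_tri_index(mesh)
  res <- cpp_segment_hits(P0, P1, mesh$vertices, mesh$triangles,
                          index$offsets, index$items,
                          index$origin, index$dx, index$dims)
  patch <- rep(NA_character_, nrow(P0))
  hit <- !is.na(res$tri)
  patch[hit] <- mesh$patch[res$tri[hit]]
  list(tri = res$tri, frac = res$frac, patch = patch)
}

#' Wall-hit test for a single sub-step segment
#'
#' @param x0,x1 segment endpoints (length-3, m).
#' @param mesh a `surface_mesh`.
#' @param index optional triangle index.
#' @return `NULL` when the segment stays inside, else a list with `patch`,
#'   `point` (hit coordinates), `fraction` and `triangle`.
#' @export
detect_wall_hit <- function(x0, x1, mesh, index = NULL) {
  h <- detect_wall_hits(matrix(x0, 1), matrix(x1, 1), mesh, index)
  if (is.na(h$tri[1])) return(NULL)
  list(patch = h$patch[1],
       point = x0 + h$frac[1] * (x1 - x0),
       fraction = h$frac[1],
       triangle = h$tri[1])
}

#' Two-way-coupling momentum source field
#'
#' Distributes the reaction to the drag on each parcel,
#' `F_D = m_p (u_s - u_p)/tau_p`, to the 8 surrounding cells with trilinear
#' (linear kernel) weights, as a force density (kg m^-2 s^-2). By
#' construction `sum_cells S * V_cell = - sum_p w_p F_D` (Newton's third
#' law).
#'
#' @param x n x 3 active parcel positions.
#' @param u_p n x 3 parcel velocities.
#' @param u_s n x 3 gas velocities at the parcels.
#' @param d_p,rho_p,weight parcel diameter, density, statistical weight.
#' @param grid a `flow_grid`.
#' @param air gas properties.
#' @return list of class `coupling_source`: `S` (`[dims, 3]` force-density
#'   array), `total_drag` (length-3, N, = `sum_p w_p F_D`), `n_excluded`
#'   (parcels outside the grid box, excluded with a warning counter).
#' @export
coupling_source <- function(x, u_p, u_s, d_p, rho_p, weight, grid,
                            air = air_properties()) {
  d <- grid$dims
  ncell <- prod(d)
  S <- array(0, c(d, 3L))
  inbox <- in_domain_box(grid, x)
  n_excl <- sum(!inbox)
  if (any(inbox)) {
    x <- x[inbox, , drop = FALSE]
    u_p <- u_p[inbox, , drop = FALSE]
    u_s <- u_s[inbox, , drop = FALSE]
    d_p <- rep(d_p, length.out = length(inbox))[inbox]
    rho_p <- rep(rho_p, length.out = length(inbox))[inbox]
    weight <- rep(weight, length.out = length(inbox))[inbox]

    tau_st <- stokes_relaxation_time(d_p, rho_p, air$mu)
    Re <- particle_reynolds(u_s, u_p, d_p, air$nu)
    tau <- tau_st / drag_factor(Re)
    m_p <- particle_mass(d_p, rho_p)
    FD <- (u_s - u_p) * (m_p / tau)          # drag on each particle (N)

    g <- sweep(x, 2, grid$origin) / grid$dx - 0.5
    i0 <- floor(g)
    f <- g - i0
    for (ax in 1:3) {
      lo <- i0[, ax] < 0; hi <- i0[, ax] > d[ax] - 2
      f[lo, ax] <- 0; i0[lo, ax] <- 0
      f[hi, ax] <- 1; i0[hi, ax] <- d[ax] - 2
    }
    base <- 1 + i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3])
    Vc <- cell_volume(grid)
    for (c3 in 1:3) {
      comp <- numeric(ncell)
      val <- -weight * FD[, c3] / Vc         # reaction force density
      for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
        wgt <- (if (di) f[, 1] else 1 - f[, 1]) *
          (if (dj) f[, 2] else 1 - f[, 2]) *
          (if (dk) f[, 3] else 1 - f[, 3])
        idx <- base + di + d[1] * (dj + d[2] * dk)
        acc <- tapply(val * wgt, idx, sum)
        comp[as.integer(names(acc))] <- comp[as.integer(names(acc))] + acc
      }
      S[, , , c3] <- array(comp, d)
    }
    total_drag <- colSums(weight * FD)
  } else {
    total_drag <- c(0, 0, 0)
  }
  structure(list(S = S, total_drag = total_drag, n_excluded = n_excl),
            class = "coupling_source")
}

#' Run the Lagrangian transport simulation
#'
#' Time-marches the parcel ensemble through the prescribed (optionally
#' quasi-steadily pulsating) velocity field: injection, gas-velocity
#' sampling, exact drag+gravity sub-steps, stick-on-touch wall deposition,
#' outlet escape, and optional two-way-coupling source accounting, until
#' `t_end` or until no parcels remain airborne.
#'
#' @param mesh a swept `surface_mesh`.
#' @param grid its voxelized `flow_grid` with the base velocity field set
#'   (corresponding to the waveform's mean flow).
#' @param w a [waveform()].
#' @param spec an [injection_spec()].
#' @param t_end simulation end time (s), >= injection duration.
#' @param seed integer seed (injection stream).
#' @param two_way compute the coupling source each step. Engaged as
#'   configured; a message is emitted when the injected particle volume
#'   fraction is below the 1e-6 dilute-flow threshold.
#' @param apply_feedback with `two_way`, also perturb the frozen gas field by
#'   `S dt / rho` each step (one-directional coupling; no momentum solver).
#' @param courant_max Courant limit for the time step.
#' @param gravity gravity vector (m/s^2); default -z (dorsal pockets at +z).
#' @param air gas properties.
#' @param dt_max upper bound on the time step (s).
#' @return object of class `simulation_result`: parcel fate table, injected
#'   mass, coupling-source audit, and run metadata.
#' @export
run_transport <- function(mesh, grid, w, spec, t_end, seed = 1L,
                          two_way = FALSE, apply_feedback = FALSE,
                          courant_max = 0.9, gravity = c(0, 0, -9.81),
                          air = air_properties(), dt_max = 1e-3) {
  stopifnot(t_end >= spec$duration_s || spec$n_parcels == 0L)
  index <- build_tri_index(mesh)

  stream <- if (spec$n_parcels > 0L) inject_parcels(mesh, spec, seed) else NULL
  n <- if (is.null(stream)) 0L else spec$n_parcels

  # particle volume fraction during injection (threshold 1e-6 for two-way)
  vol_frac <- if (n > 0)
    (spec$mass_mg * 1e-6 / spec$density_kg_m3) / (w$Q0 * spec$duration_s)
  else 0
  if (two_way && vol_frac <= 1e-6)
    message(sprintf(
      "particle volume fraction %.2e is below the 1e-6 two-way threshold; proceeding as configured",
      vol_frac))

  PENDING <- 0L; ACTIVE <- 1L; DEPOSITED <- 2L; ESCAPED <- 3L
  status <- rep(PENDING, n)
  X <- if (n) stream$x else matrix(0, 0, 3)
  U <- matrix(0, n, 3)
  patch <- rep(NA_character_, n)
  dep_time <- rep(NA_real_, n)

  umax_base <- if (is.null(grid$u)) 0 else max(sqrt(
    grid$u[, , , 1]^2 + grid$u[, , , 2]^2 + grid$u[, , , 3]^2))
  peak <- if (w$mode == "sinusoidal") 2 else 1
  dt <- if (umax_base > 0) min(courant_max * grid$dx / (umax_base * peak), dt_max)
        else dt_max
  if (w$mode == "sinusoidal") dt <- min(dt, waveform_period(w) / 40)

  roles <- mesh$patch_table$role[match(mesh$patch, mesh$patch_table$patch)]
  t <- 0
  drag_impulse <- c(0, 0, 0)
  last_source <- NULL
  nsteps <- 0L

  while (t < t_end) {
    step <- min(dt, t_end - t)
    # activate newborns with the instantaneous gas velocity
    born <- status == PENDING & stream$birth_time <= t
    if (any(born)) {
      U[born, ] <- sample_velocity(grid, X[born, , drop = FALSE], w = w, t = t)
      status[born] <- ACTIVE
    }
    act <- which(status == ACTIVE)
    if (length(act) == 0L) {
      if (!any(status == PENDING)) break
      t <- t + step
      nsteps <- nsteps + 1L
      next
    }

    us <- sample_velocity(grid, X[act, , drop = FALSE], w = w, t = t)
    if (two_way) {
      src <- coupling_source(X[act, , drop = FALSE], U[act, , drop = FALSE],
                             us, stream$d_p[act], stream$rho_p[act],
                             stream$weight[act], grid, air)
      drag_impulse <- drag_impulse + src$total_drag * step
      last_source <- src
      if (apply_feedback) grid$u <- grid$u + src$S * (step / air$rho)
    }

    sub <- parcel_substep(X[act, , drop = FALSE], U[act, , drop = FALSE],
                          stream$d_p[act], stream$rho_p[act], us, gravity,
                          step, air)
    if (any(!is.finite(sub$x)) || any(!is.finite(sub$u))) {
      bad <- act[which(!is.finite(rowSums(sub$x)) | !is.finite(rowSums(sub$u)))]
      stop("parcel NaN state at t = ", t, "; parcel ids: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }

    hits <- detect_wall_hits(X[act, , drop = FALSE], sub$x, mesh, index)
    hit <- !is.na(hits$tri)
    if (any(hit)) {
      ids <- act[hit]
      hrole <- roles[hits$tri[hit]]
      hpt <- X[ids, , drop = FALSE] +
        hits$frac[hit] * (sub$x[hit, , drop = FALSE] - X[ids, , drop = FALSE])
      X[ids, ] <- hpt
      dep <- hrole == "wall"
      status[ids[dep]] <- DEPOSITED
      patch[ids[dep]] <- hits$patch[hit][dep]
      dep_time[ids[dep]] <- t + hits$frac[hit][dep] * step
      status[ids[!dep]] <- ESCAPED
      dep_time[ids[!dep]] <- t + hits$frac[hit][!dep] * step
    }
    ok <- !hit
    if (any(ok)) {
      ids <- act[ok]
      X[ids, ] <- sub$x[ok, , drop = FALSE]
      U[ids, ] <- sub$u[ok, , drop = FALSE]
      oob <- !in_domain_box(grid, X[ids, , drop = FALSE])
      if (any(oob)) {
        status[ids[oob]] <- ESCAPED
        dep_time[ids[oob]] <- t + step
      }
    }

    t <- t + step
    nsteps <- nsteps + 1L
    if (!any(status %in% c(PENDING, ACTIVE))) break
  }

  mass <- if (n) stream$weight * particle_mass(stream$d_p, stream$rho_p)
          else numeric(0)
  fate <- c("airborne", "airborne", "deposited", "escaped")[status + 1L]
  parcels <- data.frame(
    x = X[, 1], y = X[, 2], z = X[, 3],
    d_um = if (n) stream$d_p * 1e6 else numeric(0),
    weight = if (n) stream$weight else numeric(0),
    mass_kg = mass,
    birth_time = if (n) stream$birth_time else numeric(0),
    status = fate,
    patch = patch,
    deposit_time = dep_time,
    stringsAsFactors = FALSE)

  structure(list(
    parcels = parcels,
    injected_mass_kg = sum(mass),
    t_final = t,
    n_steps = nsteps,
    dt = dt,
    seed = seed,
    spec = spec,
    waveform = w[c("mode", "Q0", "U0", "omega")],
    volume_fraction = vol_frac,
    two_way = two_way,
    drag_impulse = drag_impulse,
    source = last_source,
    mesh_patches = mesh$patch_table),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  st <- table(factor(x$parcels$status,
                     levels = c("deposited", "escaped", "airborne")))
  cat(sprintf("simulation_result: %d parcels, %d steps to t = %.3f s (dt = %.2e s)\n",
              nrow(x$parcels), x$n_steps, x$t_final, x$dt))
  cat(sprintf("  injected %.3f mg | deposited %d, escaped %d, airborne %d parcels\n",
              x$injected_mass_kg * 1e6, st[1], st[2], st[3]))
  cat(sprintf("  mass balance residual %.2e\n", mass_balance(x)))
  invisible(x)
}
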