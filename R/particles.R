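# Parcel kinematics: Stokes relaxation time, Schiller-Naumann drag factor,
# and the exact (analytic) sub-step integrator for
#   du/dt = (u_s - u)/tau + g,   dx/dt = u
# with u_s frozen over the sub-step.

#' Stokes relaxation time
#'
#' `tau_St = rho_p d_p^2 / (18 mu)`: the e-folding time of a small sphere's
#' velocity toward the gas velocity in the Stokes-drag regime.
#' @param d_p particle diameter (m).
#' @param rho_p particle density (kg/m^3).
#' @param mu gas dynamic viscosity (Pa s).
#' @return relaxation time (s); vectorized.
#' @export
stokes_relaxation_time <- function(d_p, rho_p, mu) {
  stopifnot(all(d_p > 0), all(rho_p > 0), mu > 0)
  rho_p * d_p^2 / (18 * mu)
}

#' Schiller-Naumann drag factor
#'
#' Ratio of the actual drag to Stokes drag:
#' `f_d = 1` for `Re <= 1`, `1 + 0.15 Re^0.678` for `1 < Re <= 1000`,
#' `0.44 Re / 24` beyond (Newton regime). Monotone non-decreasing and equal
#' to 1 in the Stokes limit, so `tau_p = tau_St / f_d` recovers Stokes drag
#' for small particles.
#' @param Re_p particle Reynolds number, >= 0; vectorized.
#' @return drag factor (dimensionless).
#' @export
drag_factor <- function(Re_p) {
  if (any(Re_p < 0)) stop("domain error: negative particle Reynolds number")
  ifelse(Re_p <= 1, 1,
         ifelse(Re_p <= 1000, 1 + 0.15 * Re_p^0.678, 0.44 * Re_p / 24))
}

#' Particle Reynolds number
#'
#' `Re_p = |u_s - u_p| d_p / nu` on the slip velocity.
#' @param u_s gas velocity at the particle (n x 3 matrix or length-3).
#' @param u_p particle velocity (same shape).
#' @param d_p particle diameter (m).
#' @param nu gas kinematic viscosity (m^2/s).
#' @export
particle_reynolds <- function(u_s, u_p, d_p, nu) {
  stopifnot(nu > 0)
  if (is.null(dim(u_s))) u_s <- matrix(u_s, ncol = 3)
  if (is.null(dim(u_p))) u_p <- matrix(u_p, ncol = 3)
  slip <- sqrt(rowSums((u_s - u_p)^2))
  slip * d_p / nu
}

#' Mass of a single physical particle
#' @param d_p diameter (m).
#' @param rho_p density (kg/m^3).
#' @return mass (kg).
#' @export
particle_mass <- function(d_p, rho_p) rho_p * pi / 6 * d_p^3

# Vectorized analytic sub-step. x, u: n x 3; d_p, rho_p: length n (or 1);
# us: n x 3 frozen gas velocity; g: length-3. Returns list(x, u, tau).
parcel_substep <- function(x, u, d_p, rho_p, us, g, dt, air = air_properties()) {
  tau_st <- stokes_relaxation_time(d_p, rho_p, air$mu)
  Re <- particle_reynolds(us, u, d_p, air$nu)
  tau <- tau_st / drag_factor(Re)
  gmat <- matrix(g, nrow(x), 3, byrow = TRUE)
  ustar <- us + tau * gmat
  e <- exp(-dt / tau)
  unew <- ustar + (u - ustar) * e
  xnew <- x + ustar * dt + tau * (u - ustar) * (1 - e)
  list(x = xnew, u = unew, tau = tau)
}

#' Advance one parcel by the exact sub-step solution
#'
#' With `u_s` frozen over the sub-step, the drag+gravity equation has the
#' closed-form solution
#' `u(dt) = u* + (u_p - u*) exp(-dt/tau)`, `u* = u_s + tau g`,
#' `x(dt) = x_p + u* dt + tau (u_p - u*)(1 - exp(-dt/tau))`,
#' with `tau = tau_St / f_d` evaluated at sub-step start. The update is exact
#' for any `dt`, including `dt >> tau` (tracer limit) and `dt << tau`
#' (ballistic limit).
#'
#' @param p parcel list with fields `x`, `u` (length-3), `d_p`, `rho_p`.
#' @param u_s frozen gas velocity seen by the parcel (length-3, m/s).
#' @param g gravitational acceleration vector (m/s^2).
#' @param dt sub-step (s), > 0.
#' @param air gas properties from [air_properties()].
#' @return the parcel with `x` and `u` advanced.
#' @export
advance_parcel <- function(p, u_s, g, dt, air = air_properties()) {
  stopifnot(dt > 0)
  res <- parcel_substep(matrix(p$x, 1), matrix(p$u, 1), p$d_p, p$rho_p,
                        matrix(u_s, 1), g, dt, air)
  p$x <- drop(res$x)
  p$u <- drop(res$u)
  p
}

#' Courant-limited adaptive time step
#'
#' `dt = courant_max * dx / max|u|`, additionally capped at a fifth of the
#' smallest active parcel relaxation time when `tau_min` is supplied. With a
#' quiescent field the configured `dt_max` is returned.
#'
#' @param grid a `flow_grid` with `u` set.
#' @param courant_max maximum cell Courant number, in (0, 1].
#' @param tau_min smallest active parcel relaxation time (s) or `NULL`.
#' @param tau_cap_factor divisor of the tau cap (default 5).
#' @param dt_max fallback/upper bound (s).
#' @return time step (s).
#' @export
adaptive_dt <- function(grid, courant_max, tau_min = NULL,
                        tau_cap_factor = 5, dt_max = 1e-3) {
  stopifnot(courant_max > 0, courant_max <= 1)
  umax <- max(abs(grid$u))
  dt <- if (umax == 0) dt_max else min(courant_max * grid$dx / umax, dt_max)
  if (!is.null(tau_min)) dt <- min(dt, tau_min / tau_cap_factor)
  dt
}

#' Injection specification
#' @param n_parcels number of computational parcels.
#' @param mass_mg total injected physical mass (mg).
#' @param duration_s injection duration (s).
#' @param diameter_um particle diameter (micrometres).
#' @param density_kg_m3 particle density (kg/m^3); aqueous-drug default.
#' @return list of class `injection_spec`.
#' @export
injection_spec <- function(n_parcels = 2000L, mass_mg = 2.5, duration_s = 0.5,
                           diameter_um = 1, density_kg_m3 = 1000) {
  stopifnot(n_parcels >= 0L, duration_s > 0, mass_mg > 0,
            diameter_um > 0, density_kg_m3 > 0)
  structure(list(n_parcels = as.integer(n_parcels), mass_mg = mass_mg,
                 duration_s = duration_s, diameter_um = diameter_um,
                 density_kg_m3 = density_kg_m3),
            class = "injection_spec")
}

#' Draw the parcel injection stream
#'
#' Parcels enter uniformly and randomly over the inlet disc, with birth times
#' uniform over the injection duration. Statistical weights are set so the
#' parcel masses sum exactly to the requested injected mass. Initial parcel
#' velocities equal the instantaneous local gas velocity and are assigned at
#' activation time by the transport loop (or here, if a grid is supplied).
#'
#' @param mesh a swept `surface_mesh` (supplies the inlet disc geometry).
#' @param spec an [injection_spec()].
#' @param seed integer RNG seed; identical seeds give identical streams.
#' @param grid optional `flow_grid` with `u`; fills initial velocities.
#' @param w optional [waveform()] for the time scaling of initial velocities.
#' @return list of class `parcel_stream`: `x` (n x 3), `u`, `d_p`, `rho_p`,
#'   `weight`, `birth_time` (sorted ascending).
#' @export
inject_parcels <- function(mesh, spec, seed, grid = NULL, w = NULL) {
  sw <- mesh$sweep
  if (is.null(sw)) stop("geometry error: mesh has no sweep metadata")
  ab <- sw$inlet_ab
  if (any(ab <= 0)) stop("geometry error: zero inlet area")
  n <- spec$n_parcels
  d_p <- spec$diameter_um * 1e-6
  rho_p <- spec$density_kg_m3

  draws <- with_seed(seed, {
    list(r = sqrt(runif(n)), phi = runif(n, 0, 2 * pi),
         tb = sort(runif(n, 0, spec$duration_s)))
  })
  # uniform over the (elliptic) inlet disc, nudged inward off the cap
  xi <- draws$r * cos(draws$phi)
  ze <- draws$r * sin(draws$phi)
  ctr <- sw$inlet_center
  n1 <- sw$inlet_frame$n1
  n2 <- sw$inlet_frame$n2
  tg <- sw$inlet_tangent
  shrink <- 0.995  # keep samples off the rim
  pos <- cbind(ctr[1] + shrink * (ab[2] * xi * n1[1] + ab[1] * ze * n2[1]),
               ctr[2] + shrink * (ab[2] * xi * n1[2] + ab[1] * ze * n2[2]),
               ctr[3] + shrink * (ab[2] * xi * n1[3] + ab[1] * ze * n2[3]))
  pos <- pos + matrix(tg, n, 3, byrow = TRUE) * (1e-6)

  m1 <- particle_mass(d_p, rho_p)
  wgt <- rep((spec$mass_mg * 1e-6) / (n * m1), n)

  u <- matrix(NA_real_, n, 3)
  if (!is.null(grid)) {
    u <- sample_velocity(grid, pos)
    if (!is.null(w)) u <- u * (inlet_velocity(w, draws$tb) / w$U0)
  }

  structure(list(x = pos, u = u, d_p = rep(d_p, n), rho_p = rep(rho_p, n),
                 weight = wgt, birth_time = draws$tb, spec = spec,
                 seed = seed),
            class = "parcel_stream")
}
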