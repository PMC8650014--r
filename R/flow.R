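#' Air properties
#'
#' Room-temperature air defaults: density 1.2 kg/m^3, dynamic viscosity
#' 1.8e-5 Pa s (kinematic viscosity 1.5e-5 m^2/s).
#' @param rho gas density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @return list with `rho`, `mu`, `nu`.
#' @export
air_properties <- function(rho = 1.2, mu = 1.8e-5) {
  list(rho = rho, mu = mu, nu = mu / rho)
}

#' Convert L/min to m^3/s
#' @param q flow rate in litres per minute.
#' @export
lpm_to_m3s <- function(q) q / 6e4

#' Inlet volumetric-flow waveform
#'
#' Steady flow, or the sinusoidal pulsatile law
#' `U(t) = U0 * (1 + sin(2 pi omega t))` whose time average over any whole
#' number of periods equals the mean inlet speed `U0 = Q0 / inlet area`.
#'
#' @param mode `"steady"` or `"sinusoidal"`.
#' @param Q0 mean volumetric flow (m^3/s).
#' @param inlet_area inlet cross-sectional area (m^2).
#' @param frequency pulsation frequency (Hz); required (> 0) in sinusoidal
#'   mode. The default 45 Hz is the operating frequency of pulsatile nasal
#'   nebulizers.
#' @return object of class `waveform` with fields `mode`, `Q0`, `U0`,
#'   `omega`.
#' @export
waveform <- function(mode = c("steady", "sinusoidal"), Q0, inlet_area,
                     frequency = 45) {
  mode <- match.arg(mode)
  stopifnot(Q0 > 0, inlet_area > 0)
  if (mode == "sinusoidal" && !(frequency > 0))
    stop("pulsation frequency must be > 0 in sinusoidal mode")
  structure(list(mode = mode, Q0 = Q0, area = inlet_area,
                 U0 = Q0 / inlet_area,
                 omega = if (mode == "sinusoidal") frequency else NA_real_),
            class = "waveform")
}

#' Instantaneous inlet speed
#'
#' @param w a [waveform()].
#' @param t time (s), >= 0; vectorized.
#' @return inlet speed (m/s); in `[0, 2 U0]` for the sinusoidal mode.
#' @export
inlet_velocity <- function(w, t) {
  stopifnot(all(t >= 0))
  if (w$mode == "steady") rep(w$U0, length(t))
  else w$U0 * (1 + sin(2 * pi * w$omega * t))
}

#' Pulsation period (s)
#' @param w a [waveform()].
#' @export
waveform_period <- function(w) {
  if (w$mode != "sinusoidal") return(Inf)
  1 / w$omega
}

# ---------------------------------------------------------------------------
# Prescribed velocity fields
# ---------------------------------------------------------------------------

# Fill field values outside the fluid mask with nearest-inside values
# (iterative face-neighbour dilation, `layers` cells deep). Avoids spurious
# deceleration of near-wall parcels before the geometric wall test.
fill_outside <- function(A, inside, layers = 3L) {
  d <- dim(inside)
  filled <- inside
  for (lay in seq_len(layers)) {
    target <- !filled
    if (!any(target)) break
    acc <- array(0, d)
    cnt <- array(0, d)
    shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
    for (sh in shifts) {
      Av <- shift_array(A * filled, sh)
      Fv <- shift_array(filled + 0, sh)
      acc <- acc + Av
      cnt <- cnt + Fv
    }
    new <- target & (cnt > 0)
    A[new] <- acc[new] / cnt[new]
    filled <- filled | new
  }
  A
}

# Shift an array by an integer offset, replicating the edge (zero-gradient
# extension); used by upwind derivatives at domain faces.
shift_array_rep <- function(A, sh) {
  d <- dim(A)
  idx <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]; o <- sh[ax]
    idx[[ax]] <- pmin(pmax(seq_len(n) - o, 1L), n)
  }
  A[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Shift an array by an integer offset, zero-padding the exposed edge.
shift_array <- function(A, sh) {
  d <- dim(A)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]; o <- sh[ax]
    if (o >= 0) { src[[ax]] <- seq_len(n - o); dst[[ax]] <- seq_len(n - o) + o }
    else { src[[ax]] <- seq_len(n + o) - o; dst[[ax]] <- seq_len(n + o) }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

#' Analytic Poiseuille field on a voxelized circular duct
#'
#' Sets the grid velocity to the laminar profile
#' `u(r) = 2 (Q / pi R^2) (1 - (r/R)^2)` along the duct axis; points outside
#' the duct radius get zero before the nearest-inside extension is applied.
#'
#' @param grid a `flow_grid` voxelizing a circular duct.
#' @param axis_point a point on the duct axis (m).
#' @param axis_dir unit axis direction.
#' @param radius duct radius (m).
#' @param Q volumetric flow (m^3/s).
#' @return the grid with `u` set (4-d array, last dim = component).
#' @export
poiseuille_field <- function(grid, axis_point, axis_dir, radius, Q) {
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  P <- cell_centers(grid)
  rel <- sweep(P, 2, axis_point)
  along <- rel %*% axis_dir
  perp <- rel - along %*% t(axis_dir)
  r2 <- rowSums(perp^2) / radius^2
  umag <- 2 * (Q / (pi * radius^2)) * pmax(0, 1 - r2)
  u <- array(0, c(grid$dims, 3L))
  for (c3 in 1:3) {
    comp <- array(umag * axis_dir[c3], grid$dims)
    comp[!grid$inside] <- 0
    u[, , , c3] <- fill_outside(comp, grid$inside)
  }
  grid$u <- u
  grid
}

#' Quasi-one-dimensional duct flow for swept geometries
#'
#' Prescribes a mass-conserving laminar-style field along the sweep
#' centerline of a generated geometry: at each fluid cell the speed follows
#' the elliptic-duct parabolic profile `2 (Q/A(s)) (1 - rho^2)` (or a plug
#' profile), and the direction follows the local stream-tube of the varying
#' cross-section, so converging/diverging sections carry the corresponding
#' wall-parallel radial velocity.
#'
#' @param grid a `flow_grid` from [voxelize()].
#' @param mesh the swept `surface_mesh` the grid voxelizes.
#' @param Q volumetric flow (m^3/s).
#' @param profile `"parabolic"` or `"plug"`.
#' @return the grid with `u` set.
#' @export
sweep_velocity_field <- function(grid, mesh, Q, profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  st <- mesh$sweep$stations
  C <- as.matrix(st[, c("cx", "cy", "cz")])
  P <- cell_centers(grid, grid$inside)
  idx <- cpp_nearest_station(P, C)

  n1 <- as.matrix(st[, c("n1x", "n1y", "n1z")])
  n2 <- as.matrix(st[, c("n2x", "n2y", "n2z")])
  Tm <- as.matrix(st[, c("tx", "ty", "tz")])
  # streamwise derivatives of the section semi-axes
  dads <- c(0, diff(st$a)) / c(1, diff(st$s))
  dbds <- c(0, diff(st$b)) / c(1, diff(st$s))
  ns <- nrow(st)
  dads <- (c(diff(st$a), 0) + c(0, diff(st$a))) /
    (c(diff(st$s), Inf) + c(Inf, diff(st$s)))
  dbds <- (c(diff(st$b), 0) + c(0, diff(st$b))) /
    (c(diff(st$s), Inf) + c(Inf, diff(st$s)))
  dads <- pmax(pmin(dads, 5), -5)
  dbds <- pmax(pmin(dbds, 5), -5)

  rel <- P - C[idx, , drop = FALSE]
  xi <- rowSums(rel * n1[idx, , drop = FALSE]) / st$b[idx]
  ze <- rowSums(rel * n2[idx, , drop = FALSE]) / st$a[idx]
  rho2 <- xi^2 + ze^2
  A <- pi * st$a[idx] * st$b[idx]
  fac <- if (profile == "parabolic") 2 * pmax(0, 1 - rho2) else as.numeric(rho2 <= 1)
  speed <- (Q / A) * fac
  D <- Tm[idx, , drop = FALSE] +
    xi * dbds[idx] * n1[idx, , drop = FALSE] +
    ze * dads[idx] * n2[idx, , drop = FALSE]

  u <- array(0, c(grid$dims, 3L))
  ins <- which(grid$inside)
  ncell <- prod(grid$dims)
  for (c3 in 1:3) {
    comp <- array(0, grid$dims)
    comp[ins] <- speed * D[, c3]
    u[, , , c3] <- fill_outside(comp, grid$inside)
  }
  grid$u <- u
  grid
}

#' Scale a base field quasi-steadily by the waveform
#'
#' Returns a copy of the grid whose velocity is the base field multiplied by
#' `inlet_velocity(w, t) / U0`. A divergence-free base stays divergence-free;
#' at any time the scaled field is a scalar multiple of the base.
#'
#' @param grid a `flow_grid` with `u` set (base field for mean flow `Q0`).
#' @param w a [waveform()].
#' @param t time (s).
#' @export
quasi_steady_scale <- function(grid, w, t) {
  stopifnot(!is.null(grid$u))
  grid$u <- grid$u * (inlet_velocity(w, t) / w$U0)
  grid
}

#' Sample the gridded velocity at arbitrary points
#'
#' Trilinear interpolation of the cell-centered velocity; coordinates are
#' clamped to the cell-center lattice so queries marginally outside the box
#' return the nearest face value. Outside-fluid values were extended from the
#' nearest fluid cells when the field was built.
#'
#' @param grid a `flow_grid` with `u` set.
#' @param x numeric length-3 position or n x 3 matrix (m).
#' @param w optional [waveform()] for quasi-steady time scaling.
#' @param t time (s), used with `w`.
#' @return n x 3 matrix of velocities (m/s).
#' @export
sample_velocity <- function(grid, x, w = NULL, t = 0) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  u <- sample_field(grid, grid$u, x)
  if (!is.null(w)) u <- u * (inlet_velocity(w, t) / w$U0)
  u
}

# Trilinear sampling of a (dims) or (dims,3) array at points x.
sample_field <- function(grid, A, x) {
  d <- grid$dims
  ncomp <- if (length(dim(A)) == 4L) dim(A)[4] else 1L
  g <- sweep(x, 2, grid$origin) / grid$dx - 0.5
  out <- matrix(0, nrow(x), ncomp)
  i0 <- floor(g)
  f <- g - i0
  # clamp to valid cell-center lattice
  for (ax in 1:3) {
    lo <- i0[, ax] < 0
    hi <- i0[, ax] > d[ax] - 2
    f[lo, ax] <- 0; i0[lo, ax] <- 0
    f[hi, ax] <- 1; i0[hi, ax] <- d[ax] - 2
    if (d[ax] == 1L) { i0[, ax] <- 0; f[, ax] <- 0 }
  }
  ncell <- prod(d)
  base <- 1 + i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3])
  for (c3 in seq_len(ncomp)) {
    off <- (c3 - 1L) * ncell
    acc <- 0
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      wgt <- (if (di) f[, 1] else 1 - f[, 1]) *
        (if (dj) f[, 2] else 1 - f[, 2]) *
        (if (dk) f[, 3] else 1 - f[, 3])
      idx <- base + di + d[1] * (dj + d[2] * dk)
      acc <- acc + wgt * A[off + idx]
    }
    out[, c3] <- acc
  }
  out
}

#' Is a point inside the grid bounding box?
#' @param grid a `flow_grid`.
#' @param x n x 3 matrix of positions.
#' @return logical vector.
#' @export
in_domain_box <- function(grid, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  hi <- grid$origin + grid$dims * grid$dx
  x[, 1] >= grid$origin[1] & x[, 1] <= hi[1] &
    x[, 2] >= grid$origin[2] & x[, 2] <= hi[2] &
    x[, 3] >= grid$origin[3] & x[, 3] <= hi[3]
}

# Central-difference partial derivative along an axis, one-sided at the box
# faces.
array_deriv <- function(A, dx, axis) {
  d <- dim(A)
  n <- d[axis]
  fwd <- shift_array(A, replace(c(0, 0, 0), axis, -1))  # A[i+1]
  bwd <- shift_array(A, replace(c(0, 0, 0), axis, 1))   # A[i-1]
  out <- (fwd - bwd) / (2 * dx)
  # one-sided at faces
  sel_lo <- sel_hi <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx <- function(i) {
    a <- list(TRUE, TRUE, TRUE); a[[axis]] <- i; a
  }
  lo <- idx(1L); hi <- idx(n)
  lo2 <- idx(2L); hi2 <- idx(n - 1L)
  out[lo[[1]], lo[[2]], lo[[3]]] <-
    (A[lo2[[1]], lo2[[2]], lo2[[3]]] - A[lo[[1]], lo[[2]], lo[[3]]]) / dx
  out[hi[[1]], hi[[2]], hi[[3]]] <-
    (A[hi[[1]], hi[[2]], hi[[3]]] - A[hi2[[1]], hi2[[2]], hi2[[3]]]) / dx
  out
}

#' Discrete divergence of the velocity field
#'
#' Central differences on the box (one-sided at the domain faces); the
#' incompressibility diagnostic for prescribed or externally supplied fields.
#'
#' @param grid a `flow_grid` with `u` set.
#' @return array of `du_i/dx_i` (1/s).
#' @export
divergence <- function(grid) {
  stopifnot(!is.null(grid$u))
  array_deriv(grid$u[, , , 1], grid$dx, 1L) +
    array_deriv(grid$u[, , , 2], grid$dx, 2L) +
    array_deriv(grid$u[, , , 3], grid$dx, 3L)
}
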