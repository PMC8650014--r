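# Localized dynamic k-equation subgrid-scale (SGS) diagnostics.
#
# The eddy viscosity is nu_sgs = Ck * filter_width * sqrt(k_sgs), with k_sgs
# carried by its own transport equation (production by resolved strain,
# dissipation Ce * k^{3/2} / filter_width, advection, and nu_sgs-diffusion).
# Ck and Ce are localized dynamic coefficients obtained from the Germano
# identity with a test filter of width twice the grid filter; the test-filter
# "volume average" is realized as the 3^3 box-stencil average, one-sided
# truncated at the domain boundary.

#' Filtered strain-rate tensor
#'
#' `S_ij = (du_i/dx_j + du_j/dx_i) / 2` by central differences (one-sided at
#' the box faces). Returned as a 5-d array `[dims, 3, 3]`, symmetric by
#' construction.
#' @param grid a `flow_grid` with `u` set.
#' @return strain-rate tensor field (1/s).
#' @export
strain_rate <- function(grid) {
  stopifnot(!is.null(grid$u))
  d <- grid$dims
  S <- array(0, c(d, 3L, 3L))
  gradu <- vector("list", 3)
  for (i in 1:3) {
    gradu[[i]] <- lapply(1:3, function(j)
      array_deriv(grid$u[, , , i], grid$dx, j))
  }
  for (i in 1:3) for (j in 1:3)
    S[, , , i, j] <- 0.5 * (gradu[[i]][[j]] + gradu[[j]][[i]])
  S
}

#' Strain-rate magnitude |S| = sqrt(2 S_ij S_ij)
#' @param S a strain tensor field from [strain_rate()].
#' @return scalar field (1/s).
#' @export
strain_magnitude <- function(S) {
  d <- dim(S)[1:3]
  acc <- array(0, d)
  for (i in 1:3) for (j in 1:3) acc <- acc + S[, , , i, j]^2
  sqrt(2 * acc)
}

#' Test filter (3^3 box average)
#'
#' Top-hat average over the 3x3x3 neighbourhood, truncated one-sidedly at the
#' box boundary (the average runs over the cells that exist). The associated
#' test-filter width is twice the grid filter width. The operator is linear
#' and preserves constants.
#'
#' @param A scalar array (grid dims) or higher-d array whose first 3 dims are
#'   the grid.
#' @return filtered array of the same shape.
#' @export
test_filter <- function(A) {
  d <- dim(A)
  if (length(d) == 3L) return(box_filter3(A))
  out <- A
  extra <- prod(d[-(1:3)])
  Af <- A
  dim(Af) <- c(d[1:3], extra)
  for (q in seq_len(extra)) {
    slice <- array(Af[, , , q], d[1:3])
    Af[, , , q] <- box_filter3(slice)
  }
  dim(Af) <- d
  Af
}

box_filter3 <- function(A) {
  d <- dim(A)
  acc <- array(0, d)
  cnt <- array(0, d)
  one <- array(1, d)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    sh <- c(di, dj, dk)
    acc <- acc + shift_array(A, sh)
    cnt <- cnt + shift_array(one, sh)
  }
  acc / cnt
}

#' Test-filter width
#' @param grid a `flow_grid`.
#' @return `2 * filter_width(grid)` (m), exactly.
#' @export
test_filter_width <- function(grid) 2 * filter_width(grid)

#' Germano-identity resolved stress L_ij
#'
#' `L_ij = testfilter(u_i u_j) - testfilter(u_i) testfilter(u_j)`; the
#' resolved part of the subtest-scale stress, symmetric by construction.
#' @param grid a `flow_grid` with `u` set.
#' @return tensor field `[dims, 3, 3]` (m^2/s^2).
#' @export
germano_L <- function(grid) {
  stopifnot(!is.null(grid$u))
  d <- grid$dims
  uf <- lapply(1:3, function(i) box_filter3(array(grid$u[, , , i], d)))
  L <- array(0, c(d, 3L, 3L))
  for (i in 1:3) for (j in i:3) {
    lij <- box_filter3(array(grid$u[, , , i] * grid$u[, , , j], d)) -
      uf[[i]] * uf[[j]]
    L[, , , i, j] <- lij
    L[, , , j, i] <- lij
  }
  L
}

#' Two-filter-level scalar of the dynamic procedure
#'
#' Evaluates, literally, the two-term expression
#' `M = testfilter(filter_width * k^(1/2) * |S|) -
#'      2 * test_filter_width * ktest^(1/2) * |Stest|`
#' where `ktest` and `Stest` are the test-filtered kinetic energy and strain.
#' The printed form of this quantity carries no free tensor structure, so it
#' is returned as a scalar field; [dynamic_coeffs()] offers both contraction
#' conventions against `L_ij` (see its `contraction` argument).
#'
#' @param grid a `flow_grid` with `u` set.
#' @param ksgs SGS kinetic-energy field (m^2/s^2), >= 0.
#' @return scalar field (m^2/s^2).
#' @export
m_tensor <- function(grid, ksgs) {
  if (any(ksgs < 0)) stop("domain error: negative k_sgs")
  dlt <- filter_width(grid)
  S <- strain_rate(grid)
  Smag <- strain_magnitude(S)
  term1 <- box_filter3(dlt * sqrt(ksgs) * Smag)
  khat <- box_filter3(ksgs)
  Shat_mag <- strain_magnitude(test_filter(S))
  term1 - 2 * test_filter_width(grid) * sqrt(pmax(khat, 0)) * Shat_mag
}

# 3^3-stencil volume average used for the <.> brackets of the dynamic
# procedure (same stencil as the test filter).
stencil_avg <- box_filter3

#' Localized dynamic coefficients Ck and Ce
#'
#' Ck from the Germano identity, `Ck = <L : M> / <M : M>`, and Ce from
#' `Ce = <xi m> / <m m>` with `xi = L_ii` (trace) and
#' `m = ktest^{3/2}/test_width - testfilter(k^{3/2}/width)`. The brackets are
#' 3^3-stencil volume averages. Coefficients are clipped to stabilizing
#' ranges and fall back to the standard one-equation constants
#' (Ck = 0.094, Ce = 1.048) where the contractions degenerate numerically
#' (vanishing numerator or denominator, e.g. strain-free uniform flow).
#'
#' @param grid a `flow_grid` with `u` set.
#' @param ksgs SGS kinetic-energy field, >= 0.
#' @param contraction `"strain"` contracts the scalar `M` through the unit
#'   strain direction tensor against `L_ij`; `"scalar"` contracts against the
#'   trace `L_ii`.
#' @param clip logical; apply the stabilizing clips `Ck in [0, 0.5]`,
#'   `Ce in [0.5, 5]`.
#' @param fallback constants used where denominators vanish.
#' @return list with fields `Ck` and `Ce` (arrays).
#' @export
dynamic_coeffs <- function(grid, ksgs, contraction = c("strain", "scalar"),
                           clip = TRUE, fallback = c(Ck = 0.094, Ce = 1.048)) {
  contraction <- match.arg(contraction)
  if (any(ksgs < 0)) stop("domain error: negative k_sgs")
  d <- grid$dims
  L <- germano_L(grid)
  M <- m_tensor(grid, ksgs)
  tiny <- 1e-30

  if (contraction == "strain") {
    S <- strain_rate(grid)
    Smag <- strain_magnitude(S)
    LS <- array(0, d)
    for (i in 1:3) for (j in 1:3) LS <- LS + L[, , , i, j] * S[, , , i, j]
    safe <- pmax(Smag, tiny)
    num <- stencil_avg(LS * M / safe)
    den <- stencil_avg((M / safe)^2 * Smag^2 / 2)
  } else {
    xi_tr <- L[, , , 1, 1] + L[, , , 2, 2] + L[, , , 3, 3]
    num <- stencil_avg(xi_tr * M)
    den <- stencil_avg(M * M)
  }
  Ck <- ifelse(abs(den) > tiny & abs(num) > tiny, num / den, fallback[["Ck"]])

  dlt <- filter_width(grid)
  khat <- pmax(box_filter3(ksgs), 0)
  m <- khat^1.5 / test_filter_width(grid) - box_filter3(ksgs^1.5 / dlt)
  xi <- L[, , , 1, 1] + L[, , , 2, 2] + L[, , , 3, 3]
  num_e <- stencil_avg(xi * m)
  den_e <- stencil_avg(m * m)
  Ce <- ifelse(abs(den_e) > tiny & abs(num_e) > tiny, num_e / den_e,
               fallback[["Ce"]])

  if (clip) {
    Ck <- pmin(pmax(Ck, 0), 0.5)
    Ce <- pmin(pmax(Ce, 0.5), 5)
  }
  list(Ck = array(Ck, d), Ce = array(Ce, d))
}

#' SGS eddy viscosity
#'
#' `nu_sgs = Ck * filter_width * sqrt(k_sgs)`, pointwise and non-negative.
#' @param ksgs SGS kinetic energy (array or scalar), >= 0.
#' @param delta filter width (m).
#' @param Ck coefficient (array or scalar).
#' @return eddy viscosity (m^2/s).
#' @export
nu_sgs <- function(ksgs, delta, Ck = 0.094) {
  if (any(ksgs < 0)) stop("domain error: negative k_sgs")
  Ck * delta * sqrt(ksgs)
}

#' Advance the SGS kinetic-energy transport equation
#'
#' Explicit update of
#' `dk/dt + u . grad k = nu_sgs (2 S:S) - Ce k^{3/2}/width + div(nu_sgs grad k)`
#' with first-order upwind advection, central diffusion, pointwise production
#' and dissipation; the result is clipped at zero.
#'
#' @param grid a `flow_grid` with `u` and `ksgs` set.
#' @param dt time step (s); checked against the advective and diffusive
#'   stability bounds.
#' @param Ck,Ce coefficients; `NULL` computes them dynamically via
#'   [dynamic_coeffs()].
#' @return the grid with `ksgs` advanced by `dt`.
#' @export
advance_ksgs <- function(grid, dt, Ck = NULL, Ce = NULL) {
  stopifnot(!is.null(grid$u), !is.null(grid$ksgs))
  k <- grid$ksgs
  if (any(k < 0)) stop("domain error: negative k_sgs")
  d <- grid$dims
  dx <- grid$dx
  dlt <- filter_width(grid)
  if (is.null(Ck) || is.null(Ce)) {
    co <- dynamic_coeffs(grid, k)
    if (is.null(Ck)) Ck <- co$Ck
    if (is.null(Ce)) Ce <- co$Ce
  }
  nus <- nu_sgs(k, dlt, Ck)

  umax <- max(abs(grid$u))
  numax <- max(nus)
  if (umax > 0 && dt > dx / umax)
    stop("stability error: dt exceeds the advective bound dx/max|u|")
  if (numax > 0 && dt > dx^2 / (6 * numax))
    stop("stability error: dt exceeds the diffusive bound dx^2/(6 nu_sgs)")

  S <- strain_rate(grid)
  prod_t <- nus * strain_magnitude(S)^2     # nu_sgs * 2 S:S
  diss <- Ce * k^1.5 / dlt

  adv <- array(0, d)
  for (ax in 1:3) {
    uax <- array(grid$u[, , , ax], d)
    # upwind one-sided differences; zero-gradient extension at box faces
    fwd <- (shift_array_rep(k, replace(c(0, 0, 0), ax, -1)) - k) / dx
    bwd <- (k - shift_array_rep(k, replace(c(0, 0, 0), ax, 1))) / dx
    adv <- adv + ifelse(uax > 0, uax * bwd, uax * fwd)
  }

  diff_t <- array(0, d)
  for (ax in 1:3) {
    kp <- shift_array(k, replace(c(0, 0, 0), ax, -1))
    km <- shift_array(k, replace(c(0, 0, 0), ax, 1))
    np <- shift_array(nus, replace(c(0, 0, 0), ax, -1))
    nm <- shift_array(nus, replace(c(0, 0, 0), ax, 1))
    has_p <- shift_array(array(1, d), replace(c(0, 0, 0), ax, -1))
    has_m <- shift_array(array(1, d), replace(c(0, 0, 0), ax, 1))
    fp <- 0.5 * (nus + np) * (kp - k) / dx * has_p
    fm <- 0.5 * (nus + nm) * (k - km) / dx * has_m
    diff_t <- diff_t + (fp - fm) / dx
  }

  knew <- k + dt * (-adv + prod_t - diss + diff_t)
  grid$ksgs <- pmax(knew, 0)
  grid
}

#' LES index of resolution quality
#'
#' `M = k_res / (k_res + k_sgs)`: the fraction of turbulent kinetic energy
#' resolved on the grid. `M` is in `[0, 1]`; quiescent cells (both zero) are
#' defined as fully resolved (`M = 1`). Grids with `M > 0.8` are commonly
#' considered adequately resolved (recommended band 0.77-0.85).
#'
#' @param k_res resolved turbulent kinetic energy (array or scalar), >= 0.
#' @param ksgs SGS kinetic energy, >= 0.
#' @return `M` field in `[0, 1]`.
#' @export
les_iq <- function(k_res, ksgs) {
  if (any(k_res < 0) || any(ksgs < 0)) stop("domain error: negative TKE")
  tot <- k_res + ksgs
  out <- ifelse(tot > 0, k_res / tot, 1)
  if (!is.null(dim(k_res))) dim(out) <- dim(k_res)
  out
}

#' Resolved turbulent kinetic energy from velocity snapshots
#'
#' `k_res = 0.5 <(u - <u>_t) . (u - <u>_t)>_t` over the supplied time window
#' of velocity fields.
#' @param snapshots list of velocity arrays `[dims, 3]` at successive times.
#' @return `k_res` array (m^2/s^2).
#' @export
resolved_tke <- function(snapshots) {
  stopifnot(length(snapshots) >= 2L)
  d <- dim(snapshots[[1]])
  mean_u <- Reduce(`+`, snapshots) / length(snapshots)
  acc <- array(0, d[1:3])
  for (s in snapshots) {
    fl <- s - mean_u
    acc <- acc + fl[, , , 1]^2 + fl[, , , 2]^2 + fl[, , , 3]^2
  }
  0.5 * acc / length(snapshots)
}

#' Resolution-quality summary
#'
#' Fractions of fluid cells whose LES quality index exceeds the standard
#' thresholds.
#' @param M quality-index field from [les_iq()].
#' @param inside optional logical mask restricting the census.
#' @return list with fractions above 0.8 and 0.99 and below 0.77.
#' @export
les_iq_summary <- function(M, inside = NULL) {
  v <- if (is.null(inside)) as.vector(M) else M[inside]
  list(frac_ge_0p8 = mean(v >= 0.8),
       frac_ge_0p99 = mean(v >= 0.99),
       frac_below_band = mean(v < 0.77))
}
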