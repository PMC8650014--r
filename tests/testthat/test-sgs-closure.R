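# Dynamic k-equation SGS operators, checked against explicit-loop oracles on
# random smooth 8^3 fields.

test_that("strain-rate tensor handles shear, rotation and uniform flow", {
  g <- flow_grid_box(c(8, 8, 8), 0.01)
  cc <- cell_centers(g)
  gamma <- 3.2
  u <- array(0, c(g$dims, 3))
  u[, , , 1] <- array(gamma * cc[, 2], g$dims)
  g$u <- u
  S <- strain_rate(g)
  expect_equal(max(abs(S[, , , 1, 2] - gamma / 2)), 0, tolerance = 1e-12)
  expect_equal(S[, , , 1, 2], S[, , , 2, 1])
  expect_lt(max(abs(S[, , , 1, 1])) + max(abs(S[, , , 3, 3])), 1e-12)
  # solid-body rotation is strain-free
  u[, , , 1] <- array(-2 * cc[, 2], g$dims)
  u[, , , 2] <- array(2 * cc[, 1], g$dims)
  g$u <- u
  expect_lt(max(abs(strain_rate(g))), 1e-12)
  g$u <- array(1.5, c(g$dims, 3))
  expect_equal(max(abs(strain_rate(g))), 0)
})

test_that("test filter is a linear constant-preserving box average", {
  d <- c(8, 8, 8)
  expect_equal(test_filter(array(3.3, d)), array(3.3, d), tolerance = 1e-14)
  sp <- array(0, d); sp[4, 5, 4] <- 27
  expect_equal(test_filter(sp)[4, 5, 4], 1)
  set.seed(11)
  A <- array(rnorm(prod(d)), d); B <- array(rnorm(prod(d)), d)
  expect_lt(max(abs(test_filter(2.5 * A + B) -
                      (2.5 * test_filter(A) + test_filter(B)))), 1e-12)
  # averaging operator: sup-norm non-expansive, idempotence bound
  expect_lte(max(abs(test_filter(test_filter(A)))), max(abs(A)))
  g <- flow_grid_box(d, 0.004)
  expect_identical(test_filter_width(g), 2 * g$dx)
})

test_that("Germano L matches an explicit-loop oracle and is symmetric", {
  g <- random_sgs_grid(3)
  L <- germano_L(g)
  for (i in 1:3) for (j in 1:3)
    expect_equal(L[, , , i, j], L[, , , j, i])
  uf <- lapply(1:3, function(i) loop_box_filter(array(g$u[, , , i], g$dims)))
  for (i in 1:3) for (j in 1:3) {
    oracle <- loop_box_filter(array(g$u[, , , i] * g$u[, , , j], g$dims)) -
      uf[[i]] * uf[[j]]
    expect_lt(max(abs(L[, , , i, j] - oracle)), 1e-12)
  }
  gu <- flow_grid_box(c(6, 6, 6), 0.01)
  gu$u <- array(2, c(gu$dims, 3))
  expect_lt(max(abs(germano_L(gu))), 1e-14)
})

test_that("two-level scalar M matches its loop oracle and degenerates to 0", {
  g <- random_sgs_grid(5)
  M <- m_tensor(g, g$ksgs)
  dlt <- filter_width(g)
  S <- strain_rate(g)
  Smag <- strain_magnitude(S)
  oracle <- loop_box_filter(dlt * sqrt(g$ksgs) * Smag) -
    2 * (2 * dlt) * sqrt(loop_box_filter(g$ksgs)) *
      strain_magnitude(test_filter(S))
  expect_lt(max(abs(M - oracle)), 1e-12)
  expect_equal(max(abs(m_tensor(g, array(0, g$dims)))), 0)
  gu <- flow_grid_box(c(6, 6, 6), 0.01)
  gu$u <- array(1, c(gu$dims, 3))
  expect_lt(max(abs(m_tensor(gu, array(0.2, gu$dims)))), 1e-14)
  expect_error(m_tensor(g, -g$ksgs), "domain")
})

test_that("dynamic coefficients match the loop oracle and fall back when degenerate", {
  g <- random_sgs_grid(7)
  co <- dynamic_coeffs(g, g$ksgs, contraction = "scalar", clip = FALSE)
  # independent loop-based evaluation
  L <- germano_L(g)
  M <- m_tensor(g, g$ksgs)
  xi <- L[, , , 1, 1] + L[, , , 2, 2] + L[, , , 3, 3]
  Ck_o <- loop_box_filter(xi * M) / loop_box_filter(M * M)
  expect_lt(max(abs(co$Ck - Ck_o)), 1e-10)
  dlt <- filter_width(g)
  khat <- loop_box_filter(g$ksgs)
  m <- khat^1.5 / (2 * dlt) - loop_box_filter(g$ksgs^1.5 / dlt)
  Ce_o <- loop_box_filter(xi * m) / loop_box_filter(m * m)
  expect_lt(max(abs(co$Ce - Ce_o)), 1e-10)
  # strain-free uniform state falls back to the standard constants
  gu <- flow_grid_box(c(6, 6, 6), 0.01)
  gu$u <- array(1, c(gu$dims, 3))
  cou <- dynamic_coeffs(gu, array(0.2, gu$dims))
  expect_equal(unique(as.vector(cou$Ck)), 0.094)
  expect_equal(unique(as.vector(cou$Ce)), 1.048)
})

test_that("Ck is invariant under u -> lambda u, k -> lambda^2 k", {
  g <- random_sgs_grid(13)
  co1 <- dynamic_coeffs(g, g$ksgs, clip = FALSE)
  lam <- 3.7
  g2 <- g
  g2$u <- g$u * lam
  co2 <- dynamic_coeffs(g2, g$ksgs * lam^2, clip = FALSE)
  expect_equal(co2$Ck, co1$Ck, tolerance = 1e-10)
})

test_that("nu_sgs is the pointwise product Ck width sqrt(k)", {
  expect_equal(nu_sgs(1e-2, 1e-3, 0.094), 9.4e-6)
  expect_equal(nu_sgs(0, 1e-3), 0)
  expect_equal(nu_sgs(1e-2, 2e-3, 0.094), 2 * nu_sgs(1e-2, 1e-3, 0.094))
  expect_error(nu_sgs(-1, 1e-3), "domain")
})

test_that("k_sgs decay follows the closed-form ODE solution", {
  g <- flow_grid_box(c(4, 4, 4), 1)   # filter width 1
  g$u <- array(0, c(g$dims, 3))
  g$ksgs <- array(1, g$dims)
  dt <- 1e-3
  for (i in seq_len(2000)) g <- advance_ksgs(g, dt, Ck = 0, Ce = 1)
  k_exact <- 1 / (1 + 0.5 * sqrt(1) * 2)^2      # k0/(1 + sqrt(k0) t / 2)^2
  expect_lt(abs(g$ksgs[1, 1, 1] - k_exact) / k_exact, 0.01)
  expect_lt(diff(range(g$ksgs)), 1e-14)
  # zero strain, zero k stays zero
  g0 <- flow_grid_box(c(4, 4, 4), 1)
  g0$u <- array(0, c(g0$dims, 3)); g0$ksgs <- array(0, g0$dims)
  g0 <- advance_ksgs(g0, 1e-3, Ck = 0.094, Ce = 1.048)
  expect_equal(max(g0$ksgs), 0)
})

test_that("k_sgs grows at the production rate under frozen uniform shear", {
  g <- flow_grid_box(c(8, 8, 8), 0.01)
  cc <- cell_centers(g)
  gamma <- 5
  u <- array(0, c(g$dims, 3))
  u[, , , 1] <- array(gamma * cc[, 2], g$dims)
  g$u <- u
  k0 <- 1e-4
  g$ksgs <- array(k0, g$dims)
  Ck <- 0.094
  dt <- 2e-4
  nsteps <- 50L
  for (i in seq_len(nsteps)) g <- advance_ksgs(g, dt, Ck = Ck, Ce = 0)
  rate0 <- nu_sgs(k0, g$dx, Ck) * gamma^2   # nu_sgs * 2 S:S at t = 0
  kc <- g$ksgs[4, 4, 4]                     # interior cell
  expect_lt(abs((kc - k0) - rate0 * nsteps * dt) / (rate0 * nsteps * dt), 0.01)
  expect_true(all(g$ksgs >= 0))
})

test_that("advance_ksgs enforces stability bounds and non-negativity", {
  g <- flow_grid_box(c(6, 6, 6), 0.01)
  g$u <- array(2, c(g$dims, 3))
  g$ksgs <- array(0.1, g$dims)
  expect_error(advance_ksgs(g, 1, Ck = 0.094, Ce = 1.048), "stability")
  set.seed(21)
  g$u <- array(rnorm(prod(g$dims) * 3, sd = 0.5), c(g$dims, 3))
  g$ksgs <- array(runif(prod(g$dims), 0, 1e-3), g$dims)
  for (i in 1:20) g <- advance_ksgs(g, 5e-4, Ck = 0.094, Ce = 1.048)
  expect_true(all(g$ksgs >= 0))
})

test_that("LES quality index is bounded, monotone, and flags the band", {
  expect_equal(les_iq(4, 1), 0.8)
  expect_equal(les_iq(0, 0), 1)
  expect_equal(les_iq(1, 0), 1)
  ks <- seq(0, 5, by = 0.5)
  M <- les_iq(rep(2, length(ks)), ks)
  expect_true(all(diff(M) < 0))
  expect_true(all(M >= 0 & M <= 1))
  expect_error(les_iq(-1, 0), "domain")
  s <- les_iq_summary(array(c(0.5, 0.79, 0.85, 1), c(4, 1, 1)))
  expect_equal(s$frac_ge_0p8, 0.5)
  expect_equal(s$frac_below_band, 0.25)
})

test_that("resolved TKE recovers the fluctuation energy of snapshots", {
  d <- c(4, 4, 4)
  base <- array(1, c(d, 3))
  amp <- 0.3
  snaps <- lapply(c(-1, 1), function(s) base + s * amp)
  kres <- resolved_tke(snaps)
  expect_equal(kres[1, 1, 1], 0.5 * 3 * amp^2, tolerance = 1e-12)
})
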