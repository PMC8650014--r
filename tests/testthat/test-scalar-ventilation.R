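# Passive ventilation tracer and its regional metrics.

test_that("uniform C = 1 is a fixed point of the scalar update", {
  d <- c(20, 6, 6)
  g <- flow_grid_box(d, 0.001)
  g$u <- array(0, c(d, 3)); g$u[, , , 1] <- 0.3
  g$C <- array(1, d)
  inlet <- array(FALSE, d); inlet[1, , ] <- TRUE
  for (i in 1:20) g <- advance_scalar(g, 8e-4, inlet)
  expect_equal(max(abs(g$C - 1)), 0)
})

test_that("plug-flow advection moves the front at u t within one cell", {
  d <- c(40, 6, 6)
  g <- flow_grid_box(d, 0.001)
  g$u <- array(0, c(d, 3)); g$u[, , , 1] <- 0.5
  g$C <- array(0, d)
  inlet <- array(FALSE, d); inlet[1, , ] <- TRUE
  dt <- 8e-4
  for (i in 1:50) g <- advance_scalar(g, dt, inlet, nu = 0)
  prof <- apply(g$C, 1, mean)
  front <- which.min(abs(prof - 0.5))
  expect_lt(abs(front * g$dx - 0.5 * 50 * dt), 1.5 * g$dx)
  expect_true(all(g$C >= 0 & g$C <= 1))
})

test_that("pure diffusion fills a closed pocket to the inlet value", {
  d <- c(12, 4, 4)
  g <- flow_grid_box(d, 0.001)
  g$u <- array(0, c(d, 3))
  g$C <- array(0, d)
  inlet <- array(FALSE, d); inlet[1, , ] <- TRUE
  dt <- 0.9 * g$dx^2 / (6 * (1.5e-5 / 0.7))
  for (i in 1:4000) g <- advance_scalar(g, dt, inlet)
  expect_gt(min(g$C), 0.999)   # Laplace steady state C -> 1 everywhere
})

test_that("regional means and iso-volume fractions match hand counts", {
  d <- c(10, 4, 4)
  g <- flow_grid_box(d, 0.001)
  g$C <- array(0, d)
  g$C[1:5, , ] <- 1
  whole <- array(TRUE, d)
  expect_equal(region_mean_C(g, whole), 0.5)
  expect_equal(iso_volume_fraction(g, whole, 0.99), 0.5)
  g$C <- array(0.98, d)
  expect_equal(iso_volume_fraction(g, whole, 0.99), 0)
  g$C <- array(1, d)
  expect_equal(region_mean_C(g, whole), 1)
  # explicit-loop oracle on a random field
  set.seed(8)
  g$C <- array(runif(prod(d)), d)
  mask <- array(runif(prod(d)) > 0.5, d)
  acc <- 0; vol <- 0; cnt <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (mask[i, j, k]) {
      acc <- acc + g$C[i, j, k] * cell_volume(g)
      vol <- vol + cell_volume(g)
      cnt <- cnt + (g$C[i, j, k] > 0.3)
    }
  }
  expect_lt(abs(region_mean_C(g, mask) - acc / vol), 1e-12)
  expect_equal(iso_volume_fraction(g, mask, 0.3),
               cnt / (vol / cell_volume(g)))
  expect_error(region_mean_C(g, array(FALSE, d)), "empty")
})

test_that("flow fractions recover continuity, halves and the annulus integral", {
  d <- c(8, 10, 10)
  g <- flow_grid_box(d, 0.001)
  g$u <- array(0, c(d, 3)); g$u[, , , 1] <- 0.25
  Q <- 0.25 * (10 * 0.001)^2
  expect_equal(region_flow_fraction(g, list(axis = 1, index = 4L), Q), 100)
  mask <- array(FALSE, d); mask[, 1:5, ] <- TRUE
  expect_equal(region_flow_fraction(g, list(axis = 1, index = 4L,
                                            mask = mask), Q), 50)
  expect_error(region_flow_fraction(g, list(axis = 1, index = 4L), 0),
               "domain")
  # Poiseuille annulus r > R/sqrt(2) carries 25% of the flow
  m <- build_duct(0.005, 0.01, 64L, 5L)
  gp <- voxelize(m, 0.005 / 16)
  Qp <- lpm_to_m3s(4)
  gp <- poiseuille_field(gp, c(0, 0, 0), c(1, 0, 0), 0.005, Qp)
  cc <- cell_centers(gp)
  r <- sqrt(cc[, 2]^2 + cc[, 3]^2)
  maskA <- array(r > 0.005 / sqrt(2), gp$dims)
  ix <- as.integer(round((0.005 - gp$origin[1]) / gp$dx))
  ffA <- region_flow_fraction(gp, list(axis = 1, index = ix, mask = maskA), Qp)
  expect_lt(abs(ffA - 25), 2.5)
})

test_that("scalar stays bounded and fills monotonically under random flow", {
  set.seed(31)
  d <- c(12, 8, 8)
  g <- flow_grid_box(d, 0.001)
  u <- array(rnorm(prod(d) * 3, sd = 0.2), c(d, 3))
  g$u <- u
  g$C <- array(0, d)
  inlet <- array(FALSE, d); inlet[1, , ] <- TRUE
  means <- numeric(40)
  whole <- array(TRUE, d)
  for (i in 1:40) {
    g <- advance_scalar(g, 5e-4, inlet)
    expect_gte(min(g$C), 0)
    expect_lte(max(g$C), 1)
    means[i] <- region_mean_C(g, whole)
  }
  expect_true(all(diff(means) >= -1e-12))
})

test_that("scalar update enforces its stability bounds", {
  d <- c(8, 4, 4)
  g <- flow_grid_box(d, 0.001)
  g$u <- array(0, c(d, 3)); g$u[, , , 1] <- 2
  g$C <- array(0, d)
  inlet <- array(FALSE, d); inlet[1, , ] <- TRUE
  expect_error(advance_scalar(g, 0.1, inlet), "stability")
  g$u[, , , 1] <- 0
  expect_error(advance_scalar(g, 10, inlet, nu = 1e-3), "stability")
})

test_that("ventilation report aggregates regions with bounded fractions", {
  d <- c(10, 4, 4)
  g <- flow_grid_box(d, 0.001)
  g$u <- array(0, c(d, 3))
  g$C <- array(seq(0, 1, length.out = prod(d)), d)
  regions <- list(front = array(slice.index(g$C, 1) <= 5, d),
                  back = array(slice.index(g$C, 1) > 5, d))
  rep <- ventilation_report(g, regions, time = 1.98)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$mean_C >= 0 & rep$mean_C <= 1))
  expect_true(all(rep$iso_frac_0p99 >= 0 & rep$iso_frac_0p99 <= 1))
  expect_gt(rep$mean_C[rep$region == "back"],
            rep$mean_C[rep$region == "front"])
})
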