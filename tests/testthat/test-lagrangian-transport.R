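# Parcel kinematics, wall deposition, injection, coupling and the transport
# loop.

test_that("Stokes relaxation time follows rho d^2 / 18 mu", {
  mu <- 1.8e-5
  expect_equal(stokes_relaxation_time(1e-6, 1000, mu), 3.0864e-6,
               tolerance = 1e-4)
  expect_equal(stokes_relaxation_time(2e-6, 1000, mu),
               4 * stokes_relaxation_time(1e-6, 1000, mu))
  expect_equal(stokes_relaxation_time(3e-6, 1000, mu), 2.78e-5,
               tolerance = 1e-3)
})

test_that("Schiller-Naumann drag factor has the three-regime form", {
  expect_equal(drag_factor(0.5), 1)
  expect_equal(drag_factor(1), 1)
  expect_equal(drag_factor(10), 1 + 0.15 * 10^0.678)
  expect_equal(drag_factor(10), 1.7146, tolerance = 1e-4)
  expect_equal(drag_factor(2000), 0.44 * 2000 / 24)
  expect_equal(drag_factor(2000), 36.67, tolerance = 1e-3)
  Re <- seq(1, 5000, length.out = 400)
  expect_true(all(diff(drag_factor(Re)) >= 0))
  expect_true(all(drag_factor(Re) >= 1))
  expect_error(drag_factor(-1), "domain")
})

test_that("particle Reynolds number uses the slip speed", {
  expect_equal(particle_reynolds(c(0, 0, 0), c(0, 0, 0), 1e-6, 1.5e-5), 0)
  expect_equal(particle_reynolds(c(1, 0, 0), c(0, 0, 0), 1e-6, 1.5e-5),
               1e-6 / 1.5e-5)
  expect_equal(particle_reynolds(c(30, 0, 0), c(0, 0, 0), 1e-5, 1.5e-5), 20)
})

test_that("analytic sub-step is exact for decay, terminal and tracer limits", {
  air <- air_properties()
  p <- list(x = c(0, 0, 0), u = c(0.01, 0, 0), d_p = 1e-6, rho_p = 1000)
  tau <- stokes_relaxation_time(1e-6, 1000, air$mu)
  dt <- 2 * tau
  p2 <- advance_parcel(p, c(0, 0, 0), c(0, 0, 0), dt)
  expect_equal(p2$u[1], 0.01 * exp(-2), tolerance = 1e-12)
  # terminal velocity in quiescent air with gravity
  g <- c(0, 0, -9.81)
  p3 <- advance_parcel(list(x = c(0, 0, 0), u = c(0, 0, 0), d_p = 1e-6,
                            rho_p = 1000), c(0, 0, 0), g, 10 * tau)
  expect_equal(-p3$u[3], tau * 9.81, tolerance = 1e-3)
  expect_equal(tau * 9.81, 3.03e-5, tolerance = 1e-2)
  expect_lt(abs(-p3$u[3] - tau * 9.81) / (tau * 9.81), 0.001)
  # tracer limit dt/tau = 50 relaxes onto u*
  p4 <- advance_parcel(list(x = c(0, 0, 0), u = c(5, 0, 0), d_p = 1e-6,
                            rho_p = 1000), c(0.3, 0.1, 0), c(0, 0, 0),
                       50 * tau)
  expect_lt(max(abs(p4$u - c(0.3, 0.1, 0))), 5 * exp(-50) + 1e-15)
})

test_that("wall-hit detection finds the earliest intersection and owner patch", {
  m <- build_duct(0.005, 0.05, 48L, 17L)
  idx <- build_tri_index(m)
  # radial segment through the wall
  h <- detect_wall_hit(c(0.025, 0, 0), c(0.025, 0.01, 0), m, idx)
  expect_identical(h$patch, "wall")
  expect_equal(h$fraction, 0.5, tolerance = 0.02)  # polygonal radius < r
  # fully interior segment
  expect_null(detect_wall_hit(c(0.01, 0, 0), c(0.02, 0.001, 0), m, idx))
  # wall before cap: earlier fraction wins
  h2 <- detect_wall_hit(c(0.047, 0.0048, 0), c(0.051, 0.0052, 0), m, idx)
  expect_identical(h2$patch, "wall")
  # cap before wall
  h3 <- detect_wall_hit(c(0.049, 0, 0), c(0.053, 0.008, 0), m, idx)
  expect_identical(h3$patch, "outlet")
  expect_equal(h3$fraction, 0.25, tolerance = 0.01)
})

test_that("injection conserves mass exactly and is reproducible", {
  fx <- mini_surrogate_fixture()
  spec <- injection_spec(n_parcels = 500L, mass_mg = 2.5, duration_s = 0.5,
                         diameter_um = 1)
  s1 <- inject_parcels(fx$mesh, spec, seed = 3L)
  s2 <- inject_parcels(fx$mesh, spec, seed = 3L)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$birth_time, s2$birth_time)
  total <- sum(s1$weight * particle_mass(s1$d_p, s1$rho_p))
  expect_lt(abs(total - 2.5e-6) / 2.5e-6, 1e-12)
  # uniform birth times: mean within 3 sigma of duration/2
  sigma <- 0.5 / sqrt(12 * spec$n_parcels)
  expect_lt(abs(mean(s1$birth_time) - 0.25), 3 * sigma)
  # all samples start inside the mesh (no immediate wall hit)
  hits <- detect_wall_hits(s1$x, s1$x + 1e-9, fx$mesh)
  expect_true(all(is.na(hits$tri)))
})

test_that("coupling source obeys Newton's third law and the linear kernel", {
  g <- flow_grid_box(c(6, 6, 6), 0.01)
  g$u <- array(0, c(g$dims, 3))
  # single parcel exactly at a cell center
  xc <- cell_centers(g)[100, , drop = FALSE]
  src <- coupling_source(xc, matrix(c(1, 0, 0), 1), matrix(0, 1, 3),
                         1e-6, 1000, 2e9, g)
  comp <- abs(src$S[, , , 1])
  expect_gt(comp[100] / sum(comp), 1 - 1e-9)
  # conservation: sum S V = - sum w FD
  set.seed(5)
  n <- 200
  x <- cbind(runif(n, 0.005, 0.055), runif(n, 0.005, 0.055),
             runif(n, 0.005, 0.055))
  up <- matrix(rnorm(3 * n), n, 3)
  us <- matrix(rnorm(3 * n), n, 3)
  src2 <- coupling_source(x, up, us, rep(2e-6, n), rep(1000, n),
                          rep(1e8, n), g)
  lhs <- c(sum(src2$S[, , , 1]), sum(src2$S[, , , 2]),
           sum(src2$S[, , , 3])) * cell_volume(g)
  expect_lt(max(abs(lhs + src2$total_drag)) /
              max(abs(src2$total_drag)), 1e-12)
  # zero slip produces no source
  src3 <- coupling_source(x, up, up, rep(2e-6, n), rep(1000, n),
                          rep(1e8, n), g)
  expect_equal(max(abs(src3$S)), 0)
})

test_that("adaptive time step combines Courant and relaxation caps", {
  g <- flow_grid_box(c(4, 4, 4), 1e-3)
  g$u <- array(0, c(g$dims, 3))
  g$u[, , , 1] <- 2
  expect_equal(adaptive_dt(g, 0.9), 0.9 * 1e-3 / 2)
  tau1 <- stokes_relaxation_time(1e-6, 1000, 1.8e-5)
  expect_equal(adaptive_dt(g, 0.9, tau_min = tau1), tau1 / 5)
  expect_lt(adaptive_dt(g, 0.9, tau_min = tau1), 6.2e-7)
  g2 <- flow_grid_box(c(4, 4, 4), 2e-3)
  g2$u <- g$u
  expect_equal(adaptive_dt(g2, 0.9), 2 * adaptive_dt(g, 0.9))
  g$u <- array(0, c(g$dims, 3))
  expect_equal(adaptive_dt(g, 0.9, dt_max = 1e-3), 1e-3)
})

test_that("empty injection yields an empty, balanced result", {
  fx <- duct_fixture()
  w <- waveform("steady", fx$Q, pi * fx$radius^2)
  spec <- injection_spec(n_parcels = 1L, mass_mg = 1, duration_s = 0.01)
  spec$n_parcels <- 0L
  res <- run_transport(fx$mesh, fx$grid, w, spec, t_end = 0.01, seed = 1)
  expect_identical(nrow(res$parcels), 0L)
  expect_equal(mass_balance(res), 0)
})

test_that("tracer parcels follow streamlines out of a straight duct", {
  mesh <- build_duct(0.005, 0.05, 48L, 17L)
  grid <- voxelize(mesh, 0.001)
  Q <- lpm_to_m3s(15)
  grid <- poiseuille_field(grid, c(0, 0, 0), c(1, 0, 0), 0.005, Q)
  w <- waveform("steady", Q, pi * 0.005^2)
  spec <- injection_spec(n_parcels = 400L, mass_mg = 1, duration_s = 0.02,
                         diameter_um = 1)
  res <- run_transport(mesh, grid, w, spec, t_end = 0.9, seed = 2,
                       gravity = c(0, 0, 0))
  tab <- table(res$parcels$status)
  expect_gte(tab[["escaped"]] / 400, 0.99)
  expect_lt(total_de(res), 1)
  expect_lt(mass_balance(res), 1e-12)
})

test_that("transport is deterministic under a fixed seed", {
  fx <- bend_fixture()
  w <- waveform("steady", fx$Q, pi * prod(fx$mesh$sweep$inlet_ab))
  spec <- injection_spec(n_parcels = 300L, mass_mg = 2.5, duration_s = 0.005,
                         diameter_um = 5)
  r1 <- run_transport(fx$mesh, fx$grid, w, spec, t_end = 0.05, seed = 9)
  r2 <- run_transport(fx$mesh, fx$grid, w, spec, t_end = 0.05, seed = 9)
  expect_identical(r1$parcels, r2$parcels)
  expect_lt(mass_balance(r1), 1e-12)
})

test_that("two-way coupled run accounts the drag impulse", {
  fx <- bend_fixture()
  w <- waveform("steady", fx$Q, pi * prod(fx$mesh$sweep$inlet_ab))
  # dilute short burst: volume fraction below the 1e-6 threshold -> warning
  spec <- injection_spec(n_parcels = 150L, mass_mg = 1e-4, duration_s = 0.005,
                         diameter_um = 10)
  expect_message(
    res <- run_transport(fx$mesh, fx$grid, w, spec, t_end = 0.02, seed = 4,
                         two_way = TRUE),
    "volume fraction")
  expect_true(any(res$drag_impulse != 0))
  expect_s3_class(res$source, "coupling_source")
  expect_lt(mass_balance(res), 1e-12)
})
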