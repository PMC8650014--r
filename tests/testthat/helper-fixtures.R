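# Shared fixtures. Heavy objects are built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# small straight duct + poiseuille grid (r = 5 mm, L = 5 cm)
duct_fixture <- function() {
  fixture("duct", function() {
    mesh <- build_duct(0.005, 0.05, 48L, 17L)
    grid <- voxelize(mesh, 0.000625)
    Q <- lpm_to_m3s(4)
    grid <- poiseuille_field(grid, c(0, 0, 0), c(1, 0, 0), 0.005, Q)
    list(mesh = mesh, grid = grid, Q = Q, radius = 0.005, length = 0.05)
  })
}

# 90-degree bend for impaction checks (r = 2.5 mm, bend radius 12.5 mm)
bend_fixture <- function() {
  fixture("bend", function() {
    mesh <- build_bend(0.0025, 0.0125, pi / 2, n_theta = 40L)
    grid <- voxelize(mesh, 0.0004)
    Q <- lpm_to_m3s(15)
    grid <- sweep_velocity_field(grid, mesh, Q)
    list(mesh = mesh, grid = grid, Q = Q)
  })
}

# reduced nasal surrogate: same topology, desk-test scale
mini_nasal_params <- function(...) {
  nasal_params(channel_half_height = 0.010, channel_half_width = 0.0024,
               channel_length = 0.035, ubend_radius = 0.010,
               nosepiece_radius = 0.003, nosepiece_length = 0.010,
               fillet_radius = 0.006, vestibule_length = 0.008,
               valve_offset = 0.004, valve_length = 0.006,
               olf_len_R = 0.008, olf_len_L = 0.008, olf_end_offset = 0.003,
               n_theta = 40L, ds_channel = 0.0015, ds_arc = 0.002, ...)
}

mini_surrogate_fixture <- function() {
  fixture("mini_surrogate", function() {
    mesh <- build_nasal_surrogate(mini_nasal_params(), seed = 1L)
    grid <- voxelize(mesh, 0.00055)
    Q <- lpm_to_m3s(4)
    grid <- sweep_velocity_field(grid, mesh, Q)
    list(mesh = mesh, grid = grid, Q = Q,
         area = pi * prod(mesh$sweep$inlet_ab))
  })
}

# random smooth periodic-mode velocity + k fields on an 8^3 box
random_sgs_grid <- function(seed = 1, n = 8L, dx = 0.01) {
  set.seed(seed)
  g <- flow_grid_box(rep(n, 3L), dx)
  cc <- cell_centers(g)
  u <- array(0, c(g$dims, 3L))
  for (c3 in 1:3) {
    f <- array(0, g$dims)
    for (m in 1:3) {
      kv <- sample(1:2, 3, replace = TRUE)
      ph <- runif(3, 0, 2 * pi)
      f <- f + array(runif(1, -1, 1) *
                       sin(2 * pi * kv[1] * cc[, 1] / (n * dx) + ph[1]) *
                       sin(2 * pi * kv[2] * cc[, 2] / (n * dx) + ph[2]) *
                       sin(2 * pi * kv[3] * cc[, 3] / (n * dx) + ph[3]),
                     g$dims)
    }
    u[, , , c3] <- f
  }
  g$u <- u
  g$ksgs <- array(runif(prod(g$dims), 0, 0.5), g$dims)
  g
}

# explicit-loop 3^3 box filter (independent of the vectorized operator)
loop_box_filter <- function(A) {
  d <- dim(A)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    out[i, j, k] <- mean(A[ii, jj, kk])
  }
  out
}
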