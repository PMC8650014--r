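# Deposition endpoints: DE tables, dose per area, ratio arithmetic, the
# impaction parameter and the mass-balance audit.

# construct a minimal simulation_result by hand
fake_result <- function(masses, status, patch, patches = c("wall_a", "wall_b")) {
  n <- length(masses)
  parcels <- data.frame(
    x = rep(0, n), y = rep(0, n), z = rep(0, n), d_um = rep(1, n),
    weight = rep(1, n), mass_kg = masses, birth_time = rep(0, n),
    status = as.character(status), patch = as.character(patch),
    deposit_time = ifelse(status == "deposited", 0.1, NA),
    stringsAsFactors = FALSE)
  pt <- data.frame(patch = c(patches, "inlet", "outlet"),
                   role = c(rep("wall", length(patches)), "inlet", "outlet"),
                   region = c(patches, "inlet", "outlet"),
                   side = c(rep(c("R", "L"), length.out = length(patches)),
                            "R", "L"),
                   stringsAsFactors = FALSE)
  structure(list(parcels = parcels, injected_mass_kg = sum(masses),
                 mesh_patches = pt),
            class = "simulation_result")
}

test_that("deposition efficiency splits the injected mass over regions", {
  res <- fake_result(masses = rep(1e-9, 4),
                     status = c("deposited", "deposited", "escaped",
                                "airborne"),
                     patch = c("wall_a", "wall_a", NA, NA))
  rep <- deposition_efficiency(res)
  expect_equal(rep$de_pct[rep$region == "wall_a"], 50)
  expect_equal(rep$de_pct[rep$region == "wall_b"], 0)
  expect_equal(attr(rep, "total_de_pct"), 50)
  expect_equal(total_de(res), 50)
  # all escape
  res2 <- fake_result(rep(1e-9, 3), rep("escaped", 3), rep(NA, 3))
  rep2 <- deposition_efficiency(res2)
  expect_true(all(rep2$de_pct == 0))
  expect_equal(attr(rep2, "escaped_mg"), 3e-3)
})

test_that("random-fate DE table matches an explicit-loop oracle", {
  set.seed(12)
  n <- 300
  status <- sample(c("deposited", "escaped", "airborne"), n, replace = TRUE)
  patch <- ifelse(status == "deposited",
                  sample(c("wall_a", "wall_b"), n, replace = TRUE), NA)
  masses <- runif(n, 1e-10, 1e-9)
  res <- fake_result(masses, status, patch)
  rep <- deposition_efficiency(res)
  for (rg in c("wall_a", "wall_b")) {
    acc <- 0
    for (i in seq_len(n))
      if (status[i] == "deposited" && !is.na(patch[i]) && patch[i] == rg)
        acc <- acc + masses[i]
    expect_lt(abs(rep$de_pct[rep$region == rg] - 100 * acc / sum(masses)),
              1e-12)
  }
  # partition additivity: regional DEs sum to whole-domain DE
  expect_lt(abs(sum(rep$de_pct) - total_de(res)), 1e-12)
})

test_that("dose per area divides nanogram mass by patch area", {
  expect_equal(dose_from_mass(11.98e-9, 330), 36.3, tolerance = 1e-3)
  expect_equal(dose_from_mass(0, 330), 0)
  expect_equal(dose_from_mass(1e-9, 200), 2 * dose_from_mass(1e-9, 400))
  expect_error(dose_from_mass(1e-9, 0), "domain")
  res <- fake_result(masses = c(2e-9, 2e-9), status = rep("deposited", 2),
                     patch = c("wall_a", "wall_b"))
  tab <- dose_per_area(res, c(wall_a = 100, wall_b = 400))
  expect_equal(tab$dose_ng_mm2[tab$patch == "wall_a"], 2000 / 100)
  expect_equal(tab$dose_ng_mm2[tab$patch == "wall_b"], 2000 / 400)
  # dose x area recovers the deposited mass exactly
  expect_equal(tab$dose_ng_mm2 * tab$area_mm2, tab$deposited_ng)
})

test_that("ratio metrics reproduce the printed fold-change arithmetic", {
  expect_equal(fold_change(50.9, 34.4), 1.48, tolerance = 1e-2)
  expect_equal(round(fold_change(50.9, 34.4), 2), 1.48)
  expect_equal(fold_change(0.48, 0.12), 4, tolerance = 0.01)
  expect_identical(fold_change(1, 0), Inf)
  expect_identical(fold_change(0, 0), 1)
  resA <- fake_result(masses = c(3e-9, 1e-9, 1e-9),
                      status = c("deposited", "deposited", "escaped"),
                      patch = c("wall_a", "wall_b", NA))
  repA <- deposition_efficiency(resA)
  rt <- ratio_metrics(repA, repA)
  expect_true(all(rt$fold_change == 1))
  expect_equal(rt$total_fold_change, 1)
  expect_equal(rt$right_left_A, 3)   # wall_a side R vs wall_b side L
  # zero left DE -> Inf marker, never an error
  resB <- fake_result(masses = c(3e-9, 1e-9), status = c("deposited",
                                                         "escaped"),
                      patch = c("wall_a", NA))
  rtB <- ratio_metrics(deposition_efficiency(resB),
                       deposition_efficiency(resB))
  expect_identical(rtB$right_left_A, Inf)
})

test_that("impaction parameter is d^2 Q in conventional units", {
  expect_equal(impaction_parameter(1, 4), 4)
  expect_equal(impaction_parameter(10, 30), 3000)
  expect_equal(impaction_parameter(3, 15), 135)
  expect_error(impaction_parameter(-1, 4))
})

test_that("mass balance audits bookkeeping and flags corruption", {
  res <- fake_result(masses = rep(1e-9, 4),
                     status = c("deposited", "escaped", "airborne",
                                "escaped"),
                     patch = c("wall_a", NA, NA, NA))
  expect_lt(mass_balance(res), 1e-12)
  res$injected_mass_kg <- res$injected_mass_kg * 1.05
  expect_gt(mass_balance(res), 0.01)
  empty <- fake_result(numeric(0), character(0), character(0))
  expect_equal(mass_balance(empty), 0)
})

test_that("DE curve is reproducible under a fixed seed", {
  fx <- bend_fixture()
  spec <- injection_spec(n_parcels = 200L, mass_mg = 2.5,
                         duration_s = 0.005, diameter_um = 1)
  t1 <- de_curve(fx$mesh, fx$grid, c(5, 10), 15, seed = 2, spec = spec,
                 t_end = 0.04)
  t2 <- de_curve(fx$mesh, fx$grid, c(5, 10), 15, seed = 2, spec = spec,
                 t_end = 0.04)
  expect_identical(t1, t2)
  expect_equal(t1$ip, c(375, 1500))
  expect_error(de_curve(fx$mesh, fx$grid, c(10, 5), 15, seed = 2,
                        spec = spec, t_end = 0.04), "sorted")
})
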