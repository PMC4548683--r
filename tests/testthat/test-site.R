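# Steady flow solver and plume forecasting on reduced grids.

small_site <- function(...) {
  site_model(nx = 20, ny = 10, nlayers = 2, head_west = 10.5,
             head_east = 10.0, ...)
}

test_that("a homogeneous site with two fixed faces gives an exactly linear head field", {
  fl <- solve_steady_flow(small_site())
  h_exp <- 10.5 + (seq_len(20) - 1) / 19 * (10.0 - 10.5)
  for (k in 1:2)
    expect_lt(max(abs(sweep(fl$heads[, , k], 2, h_exp))), 1e-10)
  expect_lt(fl$divergence_max, 1e-10)
})

test_that("doubling the conductivity leaves heads unchanged and doubles fluxes", {
  f1 <- solve_steady_flow(small_site())
  f2 <- solve_steady_flow(small_site(hk = 2 * 2.25e-7 * 86400 * 10))
  expect_equal(f1$heads, f2$heads, tolerance = 1e-10)
  expect_equal(2 * f1$qx, f2$qx, tolerance = 1e-10)
})

test_that("heterogeneous conductivity still yields a divergence-free interior", {
  set.seed(42)
  K <- array(exp(rnorm(10 * 20 * 2, log(0.19), 1)), c(10, 20, 2))
  fl <- solve_steady_flow(small_site(hk = K))
  flux_scale <- max(abs(fl$qx)) * 1 * 2  # max face flux in m^3/d
  expect_lt(fl$divergence_max / flux_scale, 1e-8)
})

test_that("a site without constant-head cells is rejected", {
  expect_error(site_model(nx = 5, ny = 5, nlayers = 1, head_west = NULL,
                          head_east = NULL), "constant-head")
})

test_that("zero velocity and zero decay leave the plume unchanged", {
  site <- site_model(nx = 20, ny = 10, nlayers = 2, head_west = 10,
                     head_east = 10)
  fl <- solve_steady_flow(site)
  init <- array(0, c(10, 20, 2))
  init[5, 10, 1] <- 50
  fc <- simulate_plume(fl, init, retardation = 1.425, decay = 0,
                       dispersivities = c(0, 0), times = c(10, 100))
  for (s in fc$states) expect_equal(s$conc, init, tolerance = 1e-12)
})

test_that("total mass follows M0 exp(-k t / R) under aqueous decay with sorption", {
  site <- site_model(nx = 20, ny = 10, nlayers = 2, head_west = 10,
                     head_east = 10)
  fl <- solve_steady_flow(site)
  init <- array(0, c(10, 20, 2))
  init[4:6, 8:12, 1] <- 20
  R <- 1.425
  k <- 0.0045
  fc <- simulate_plume(fl, init, retardation = R, decay = k,
                       times = c(183, 365, 1825))
  m0 <- sum(init * site$porosity[1] * 2) * R
  expected <- m0 * exp(-k * fc$mass$time_d / R)
  expect_true(all(abs(fc$mass$mass_g / expected - 1) < 0.005))
})

test_that("a point mass advects by v t / R within one cell", {
  site <- site_model(nx = 40, ny = 5, nlayers = 1, hk = 10,
                     head_west = 11, head_east = 10, porosity = 0.296)
  fl <- solve_steady_flow(site)
  v <- fl$vx[3, 20, 1]
  init <- array(0, c(5, 40, 1))
  init[3, 5, 1] <- 100
  R <- 2
  t_end <- 10
  fc <- simulate_plume(fl, init, retardation = R, decay = 0,
                       dispersivities = c(0.05, 0.005), times = t_end)
  pm <- plume_metrics(fc$states[[1]], site)
  x0 <- (5 - 0.5) * site$dx
  expect_lt(abs(pm$centroid["x"] - (x0 + v * t_end / R)), site$dx)
  expect_lt(abs(pm$centroid["y"] - 2.5), 0.2)
})

test_that("conservative transport conserves mass away from the boundaries", {
  site <- site_model(nx = 30, ny = 20, nlayers = 2)
  fl <- solve_steady_flow(site)
  init <- array(0, c(20, 30, 2))
  init[8:12, 12:18, ] <- 10
  fc <- simulate_plume(fl, init, retardation = 1.425, decay = 0,
                       times = c(365, 1825))
  m0 <- sum(init * site$porosity[1] * 2) * 1.425
  expect_true(all(abs(fc$mass$mass_g / m0 - 1) < 1e-3))
})

test_that("plume metrics honour thresholds, inclusivity and monotonicity", {
  site <- site_model(nx = 10, ny = 10, nlayers = 1, head_west = 10,
                     head_east = 10)
  zero <- plume_state(array(0, c(10, 10, 1)))
  pm0 <- plume_metrics(zero, site, thresholds = c(25, 0.3))
  expect_equal(pm0$max_conc, 0)
  expect_equal(pm0$exceedance$area_m2, c(0, 0))

  conc <- array(0, c(10, 10, 1))
  conc[4, 7, 1] <- 25
  pm1 <- plume_metrics(plume_state(conc), site, thresholds = 25)
  expect_equal(pm1$exceedance$cells, 1L)   # >= is inclusive
  expect_equal(pm1$exceedance$area_m2, 1)

  g <- outer(seq_len(10), seq_len(10),
             function(i, j) 40 * exp(-((i - 5)^2 + (j - 5)^2) / 8))
  pmg <- plume_metrics(plume_state(array(g, c(10, 10, 1))), site,
                       thresholds = c(0.5, 5, 20, 39))
  expect_equal(pmg$max_conc, max(g))
  expect_true(all(diff(pmg$exceedance$area_m2) <= 0))
})

test_that("well comparison reproduces closed-form errors and checks the grid", {
  site <- site_model(nx = 20, ny = 10, nlayers = 2, head_west = 10,
                     head_east = 10)
  fl <- solve_steady_flow(site)
  init <- array(0, c(10, 20, 2))
  init[5, 10, 1] <- 40
  fc <- simulate_plume(fl, init, retardation = 1, decay = 0.002,
                       times = c(10, 50, 100, 200))
  wells <- data.frame(well_id = "W1", row = 5, col = 10, layer = 1)
  times <- c(10, 50, 100, 200)
  obs0 <- generate_well_observations(fc, wells, times, noise_sd = 0)
  expect_equal(compare_wells(obs0, fc)$mse, 0)

  obs_off <- obs0
  obs_off$conc_mg_per_L <- obs_off$conc_mg_per_L + 0.7
  expect_equal(compare_wells(obs_off, fc)$mse, 0.49, tolerance = 1e-10)

  out <- obs0
  out$col <- 99
  expect_error(compare_wells(out, fc), "outside")
})

test_that("a noisy synthetic twin gives MSE near the noise variance", {
  site <- site_model(nx = 20, ny = 10, nlayers = 1, head_west = 10,
                     head_east = 10)
  fl <- solve_steady_flow(site)
  init <- array(0, c(10, 20, 1))
  init[5, 10, 1] <- 40
  times_out <- seq(5, 300, by = 5)
  fc <- simulate_plume(fl, init, retardation = 1, decay = 0.002,
                       times = times_out)
  wells <- data.frame(well_id = "W1", row = 5, col = 10, layer = 1)
  obs <- generate_well_observations(fc, wells, times_out, noise_sd = 0.5,
                                    seed = 3)
  mse <- compare_wells(obs, fc)$mse
  expect_lt(abs(mse / 0.25 - 1), 0.35)
  # determinism of the generator
  obs2 <- generate_well_observations(fc, wells, times_out, noise_sd = 0.5,
                                     seed = 3)
  expect_identical(obs, obs2)
})
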