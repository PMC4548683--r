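# Column transport solver: limits, oracle equivalence, conservation,
# monotonicity and grid convergence.

test_that("a conservative tracer reaches the influent plateau", {
  pars <- column_transport_params(col1, sorption_coeff = 0, decay = 0)
  sim <- simulate_column(col1, pars, constant_inlet(31.36, 25),
                         sample_times = seq(1, 25, 2))
  expect_rel_error(tail(sim$btc$conc_mg_per_L, 1), 31.36, 1e-6)
  mb <- mass_balance(sim)
  expect_equal(mb$degraded, 0)
  expect_lt(mb$closure_error, 1e-10)
})

test_that("the decaying plateau matches the plug-flow steady-state ratio", {
  pars <- column_transport_params(col1, sorption_coeff = 0, decay = 0.0045)
  sim <- simulate_column(col1, pars, constant_inlet(31.36, 60),
                         sample_times = c(60))
  expect_rel_error(sim$btc$conc_mg_per_L / 31.36,
                   steady_state_ratio(0.0045, residence_time(col1)), 1e-4)
})

test_that("equilibrium-sorption simulation agrees with the closed form to <1% L2", {
  # remote-outlet comparison: the closed form is for a semi-infinite domain,
  # so the simulated domain extends well past the observation point
  long <- col1
  long$length <- 0.6
  pars <- column_transport_params(col1, sorption_coeff = 6.8e-5,
                                  sorption_rate = Inf, decay = 0.0045)
  t_obs <- seq(0.5, 25, 0.5)
  sim <- simulate_column(long, pars, constant_inlet(31.36, 25), nx = 800,
                         inlet_bc = "first", state_times = t_obs)
  num <- vapply(sim$states, function(s) approx(s$x, s$c, xout = 0.3)$y,
                numeric(1))
  ana <- analytic_ade(0.3, t_obs, pars, 31.36)
  expect_lt(sqrt(sum((num - ana)^2) / sum(ana^2)), 0.01)
})

test_that("halving the grid and time step changes the BTC by <0.5%", {
  ts <- seq(0.5, 25, 0.5)
  cases <- list(
    column_transport_params(col1, sorption_coeff = 0.068,
                            sorption_rate = 1e-4, decay = 0.0045),
    column_transport_params(col1, sorption_coeff = 0, decay = 0))
  for (pars in cases) {
    s1 <- simulate_column(col1, pars, constant_inlet(31.36, 25), nx = 200,
                          courant = 0.5, sample_times = ts)
    s2 <- simulate_column(col1, pars, constant_inlet(31.36, 25), nx = 400,
                          courant = 0.25, sample_times = ts)
    expect_lt(max(abs(s1$btc$conc_mg_per_L - s2$btc$conc_mg_per_L)) / 31.36,
              0.005)
  }
})

test_that("concentrations stay non-negative within tolerance across regimes", {
  params_sets <- list(
    column_transport_params(col1, sorption_coeff = 0, decay = 0),
    column_transport_params(col1, sorption_coeff = 0.068,
                            sorption_rate = 1e-4, decay = 0.0045),
    column_transport_params(col1, sorption_coeff = 6.8e-5,
                            sorption_rate = Inf, decay = 0),
    column_transport_params(col1, dispersivity = 0.001,
                            sorption_coeff = 0, decay = 0.01))
  for (pars in params_sets) {
    sim <- simulate_column(col1, pars, constant_inlet(31.36, 25))
    expect_gte(sim$numerics$min_c, -1e-9 * 31.36)
  }
})

test_that("the BTC is pointwise non-increasing in the decay rate", {
  ts <- seq(1, 25, 2)
  prev <- NULL
  for (k in c(0, 0.002, 0.0045, 0.01)) {
    pars <- column_transport_params(col1, sorption_coeff = 0.068,
                                    sorption_rate = 1e-4, decay = k)
    cc <- simulate_column(col1, pars, constant_inlet(31.36, 25),
                          sample_times = ts)$btc$conc_mg_per_L
    if (!is.null(prev)) expect_true(all(cc <= prev + 1e-9))
    prev <- cc
  }
})

test_that("the first temporal moment of the BTC is non-decreasing in Kd", {
  ts <- seq(0.1, 25, 0.1)
  inlet <- constant_inlet(31.36, 25)
  m1 <- sapply(c(0, 3.4e-5, 6.8e-5, 1.2e-4), function(Kd) {
    pars <- column_transport_params(col1, sorption_coeff = Kd,
                                    sorption_rate = Inf, decay = 0)
    btc <- simulate_column(col1, pars, inlet, sample_times = ts)$btc
    suppressWarnings(temporal_moments(btc, inlet))$mean_arrival
  })
  expect_true(all(diff(m1) > 0))
})

test_that("mass balance closes below 0.1% for kinetic, equilibrium and pulse runs", {
  pulse <- inlet_schedule(c(0, 10), c(10, 25), c(31.36, 0))
  runs <- list(
    list(p = column_transport_params(col1, sorption_coeff = 0.068,
                                     sorption_rate = 1e-4, decay = 0.0045),
         inl = constant_inlet(31.36, 25)),
    list(p = column_transport_params(col1, sorption_coeff = 6.8e-5,
                                     sorption_rate = Inf, decay = 0.0045),
         inl = constant_inlet(31.36, 25)),
    list(p = column_transport_params(col1, sorption_coeff = 0.068,
                                     sorption_rate = 1e-4, decay = 0),
         inl = pulse))
  for (r in runs) {
    sim <- simulate_column(col1, r$p, r$inl)
    expect_lt(mass_balance(sim)$closure_error, 1e-3)
    expect_lt(mass_balance(sim)$closure_error, 1e-8)  # scheme-consistent
  }
})

test_that("a zero-inlet, zero-initial run stays identically zero", {
  pars <- column_transport_params(col1, sorption_coeff = 0.068,
                                  sorption_rate = 1e-4, decay = 0.0045)
  sim <- simulate_column(col1, pars, constant_inlet(0, 10))
  mb <- mass_balance(sim)
  expect_equal(mb$inflow, 0)
  expect_equal(mb$outflow, 0)
  expect_equal(mb$degraded, 0)
  expect_equal(max(abs(sim$effluent$conc_mg_per_L)), 0)
})

test_that("invalid numerics and sampling are rejected", {
  pars <- column_transport_params(col1)
  expect_error(simulate_column(col1, pars, constant_inlet(1, 10),
                               courant = 0), "courant")
  expect_error(simulate_column(col1, pars, constant_inlet(1, 10),
                               sample_times = c(5, 20)), "beyond")
})
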