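# Synthetic data generators: determinism, noiseless equivalence to the
# forward model, and the study-design sampling layout.

test_that("a noiseless sterile generation equals the forward model exactly", {
  scen <- noiseless_scenario()
  btc <- generate_column_btc(scen, sterile = TRUE, seed = 5)
  pars <- column_transport_params(scen$spec_control,
                                  dispersivity = scen$dispersivity,
                                  sorption_coeff = scen$sorption_coeff,
                                  sorption_rate = scen$sorption_rate,
                                  decay = 0)
  ref <- simulate_column(scen$spec_control, pars,
                         constant_inlet(scen$c0_mean, scen$duration),
                         sample_times = btc$time_d)
  expect_equal(btc$conc_mg_per_L, ref$btc$conc_mg_per_L, tolerance = 1e-12)
  expect_equal(attr(btc, "truth")$decay, 0)
})

test_that("the default sampling layout ends at 5.16 pore volumes", {
  scen <- noiseless_scenario()
  btc <- generate_column_btc(scen, sterile = FALSE, seed = 1)
  expect_equal(nrow(btc), 13)
  expect_equal(diff(btc$time_d), rep(2, 12))
  expect_equal(round(max(btc$pore_volumes), 2), 5.16)
})

test_that("generators are reproducible under a fixed seed and vary across seeds", {
  scen <- noisy_scenario()
  a <- generate_column_btc(scen, sterile = FALSE, seed = 3)
  b <- generate_column_btc(scen, sterile = FALSE, seed = 3)
  c <- generate_column_btc(scen, sterile = FALSE, seed = 4)
  expect_identical(a$conc_mg_per_L, b$conc_mg_per_L)
  expect_false(identical(a$conc_mg_per_L, c$conc_mg_per_L))
  # generation does not disturb the caller's RNG stream
  set.seed(99)
  ref <- rnorm(3)
  set.seed(99)
  invisible(generate_column_btc(scen, sterile = FALSE, seed = 3))
  expect_identical(rnorm(3), ref)
})

test_that("the influent reservoir draw is recorded in the truth record", {
  scen <- synthetic_scenario(noise_sd = 0)  # reservoir variability only
  btc <- generate_column_btc(scen, sterile = FALSE, seed = 2)
  truth <- attr(btc, "truth")
  expect_false(truth$influent == scen$c0_mean)
  expect_lt(abs(truth$influent - scen$c0_mean), 5 * scen$c0_sd)
})

test_that("the noiseless tracer plateaus at the feed concentration with 1 PV arrival", {
  tr <- generate_tracer_btc(col1, dispersivity = 0.005, noise_sd = 0)
  expect_rel_error(tail(tr$conc_mg_per_L, 1), 3, 1e-4)
  mom <- temporal_moments(tr, constant_inlet(3, max(tr$time_d)))
  expect_rel_error(mom$mean_arrival / residence_time(col1), 1, 0.02)
})

test_that("the synthetic site reproduces its anchors exactly", {
  syn <- generate_site()
  wells <- syn$anchors
  for (r in seq_len(nrow(wells)))
    expect_equal(syn$initial$conc[wells$row[r], wells$col[r],
                                  wells$layer[r]],
                 wells$conc_mg_per_L[r], tolerance = 1e-9)
  # a single anchor peaks at its own cell
  one <- generate_site(anchors = data.frame(
    well_id = "A", row = 10, col = 12, layer = 1, conc_mg_per_L = 7))
  expect_equal(max(one$initial$conc), 7, tolerance = 1e-9)
  expect_equal(which.max(one$initial$conc[, , 1]),
               which(matrix(seq_len(100 * 100), 100) ==
                       (12 - 1) * 100 + 10))
})

test_that("a vanishing kernel scale localises the plume to the anchor cells", {
  syn <- generate_site(length_scale = 0.2, vertical_scale = 0.2)
  conc <- syn$initial$conc
  for (r in seq_len(nrow(syn$anchors)))
    conc[syn$anchors$row[r], syn$anchors$col[r], syn$anchors$layer[r]] <- 0
  expect_lt(max(conc), 1e-4 * max(syn$anchors$conc_mg_per_L))
})

test_that("anchors outside the grid are rejected", {
  bad <- data.frame(well_id = "X", row = 500, col = 1, layer = 1,
                    conc_mg_per_L = 1)
  expect_error(generate_site(anchors = bad), "outside")
})
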