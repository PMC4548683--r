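# Shared fixtures: the two published column specifications and canonical
# synthetic scenarios. Fast-numerics settings (coarser grid, Courant 1) are
# used by simulation-heavy tests; the cell-Peclet guard still refines them
# to a stable resolution.

col1 <- tca_column_spec(1)
col2 <- tca_column_spec(2)

noiseless_scenario <- function(...) {
  synthetic_scenario(c0_sd = 0, noise_sd = 0, ...)
}

noisy_scenario <- function(...) {
  # measurement noise only (5% of influent), shared reservoir at the mean
  synthetic_scenario(c0_sd = 0, ...)
}

fast_nx <- 60
fast_courant <- 1

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
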