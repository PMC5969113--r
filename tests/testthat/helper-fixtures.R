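# Shared, lazily built fixtures. Monte Carlo runs and look-up tables are
# expensive, so each is built once per test session and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

small_extent <- function() list(x = c(-25, 25), y = c(-30, 40), z = c(0, 180))

water_small <- function() {
  fixture("water_small", build_homogeneous("water", extent = small_extent()))
}

# single-energy water look-up tables on the full ROI grid
mini_lut_15T <- function() {
  fixture("mini_lut_15T", build_luts(150, 1.5, mc_config(3e4, seed = 101)))
}

mini_lut_0T <- function() {
  fixture("mini_lut_0T", build_luts(150, 0, mc_config(3e4, seed = 103)))
}

# the full acceptance battery (built on first use by test-acceptance.R)
acceptance_battery <- function() {
  fixture("battery", benchmark_battery(seed = 1, n_histories = 2e5,
                                       verbose = FALSE))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
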