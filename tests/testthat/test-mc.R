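test_that("with only mean energy loss the scored peak sits at the CSDA range", {
  ph <- water_small()
  cfg <- mc_config(2000, seed = 5, straggling = FALSE, nuclear = FALSE,
                   mcs = FALSE)
  dg <- simulate_beam(beam_spec(150), ph, 0, cfg)
  curve <- idd(dg)
  expect_lt(abs(curve$z[which.max(curve$e)] - csda_range(150, material("water"))),
            1)
})

test_that("identical configurations reproduce bit-identical dose grids", {
  ph <- water_small()
  a <- simulate_beam(beam_spec(100), ph, 1.5, mc_config(5000, seed = 77))
  b <- simulate_beam(beam_spec(100), ph, 1.5, mc_config(5000, seed = 77))
  expect_identical(a$values, b$values)
  c <- simulate_beam(beam_spec(100), ph, 1.5, mc_config(5000, seed = 78))
  expect_false(identical(a$values, c$values))
})

test_that("energy is conserved across scoring, escape and nuclear removal", {
  ph <- water_small()
  dg <- simulate_beam(beam_spec(150), ph, 1.5, mc_config(2e4, seed = 9))
  t <- dg$totals
  resid <- t$E_in - t$E_scored - t$E_escaped - t$E_nuclear_lost
  expect_lt(abs(resid) / t$E_in, 1e-3)
  expect_equal(sum(dg$values), t$E_scored, tolerance = 1e-9)
})

test_that("the dose is y-symmetric without a field and asymmetric with one", {
  ph <- water_small()
  centroid_y <- function(B, seed) {
    dg <- simulate_beam(beam_spec(100), ph, B, mc_config(2e4, seed = seed))
    yz <- project_grid(dg, "yz")
    prof <- rowSums(yz)
    sum(attr(yz, "lat") * prof) / sum(prof)
  }
  expect_lt(abs(centroid_y(0, 13)), 0.3)
  expect_gt(centroid_y(3, 14), 2)   # bends clearly toward +y
})

test_that("multiple-scattering growth matches the Fermi-Eyges variance integral", {
  ph <- water_small()
  cfg <- mc_config(3e4, seed = 21, straggling = FALSE, nuclear = FALSE,
                   mcs = TRUE)
  dg <- simulate_beam(beam_spec(150), ph, 0, cfg)
  yz <- project_grid(dg, "yz")
  zq <- 120
  prof <- yz[, which(attr(yz, "z") == zq - 0.5)]
  lat <- attr(yz, "lat")
  mu <- sum(lat * prof) / sum(prof)
  var_mc <- sum((lat - mu)^2 * prof) / sum(prof) - 1 / 12  # de-bin
  # oracle: independent analytic propagation of the same per-step Highland
  # angles, var(z) = sum theta0^2(s) (z - s)^2, plus the entrance spot
  w <- material("water")
  s <- seq(0.5, zq - 0.5, by = 1)
  Es <- residual_energy(150, s, w, step = 0.1)
  p <- proton_momentum(Es)
  betap <- p^2 / (Es + 938.27208816)
  t <- (w$rho / 10) / w$X0            # per mm
  th0 <- 13.6 / betap * sqrt(t) * pmax(1 + 0.038 * log(t), 0.1)
  var_fe <- 9 + sum(th0^2 * (zq - s)^2)
  expect_rel_equal(var_mc, var_fe, 0.05)
})

test_that("magnetic displacement of the Bragg peak matches the trajectory module", {
  ph <- build_homogeneous("water")
  dg <- simulate_beam(beam_spec(240), ph, 1.5, mc_config(2e4, seed = 3))
  yz <- project_grid(dg, "yz")
  pk <- which(yz == max(yz), arr.ind = TRUE)
  y_mc <- attr(yz, "lat")[pk[1]]; z_mc <- attr(yz, "z")[pk[2]]
  tr <- integrate_trajectory(240, 1.5, "water")
  expect_lt(abs(y_mc - trajectory_at(tr, z_mc)$y), 1)
})

test_that("batch statistics follow the 1/sqrt(N) Monte Carlo law", {
  ph <- water_small()
  med_err <- function(n, seed) {
    dg <- simulate_beam(beam_spec(100), ph, 0,
                        mc_config(n, seed = seed, n_batches = 10))
    rel <- score_statistics(dg, threshold_frac = 0.1)
    median(rel, na.rm = TRUE)
  }
  e1 <- med_err(1e4, 41)
  e4 <- med_err(4e4, 42)
  expect_rel_equal(e1 / e4, 2, 0.2)
  expect_lt(e4, 0.07)   # a few percent in the high-dose region
})

test_that("score_statistics reports zero spread for identical batches", {
  ph <- water_small()
  d <- dim(ph$labels)
  vals <- array(runif(prod(d)), d)
  g <- dose_grid(vals, ph, n_histories = 100)
  g$n_batches <- 10L
  g$batch_sumsq <- vals^2 / 10     # ten identical batches of vals/10 each
  rel <- score_statistics(g, threshold_frac = 0)
  expect_lt(max(rel, na.rm = TRUE), 1e-7)
  expect_error(score_statistics(dose_grid(vals, ph)), "batches")
})

test_that("a beam missing the phantom yields a zero grid with a warning", {
  ph <- water_small()
  expect_warning(dg <- simulate_beam(beam_spec(100, position = c(500, 0)),
                                     ph, 0, mc_config(100, seed = 1)),
                 "misses")
  expect_equal(sum(dg$values), 0)
})
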