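test_that("integrated depth dose conserves and localizes energy", {
  ph <- water_small()
  d <- dim(ph$labels)
  vals <- array(0, d); vals[20, 30, 77] <- 3
  g <- dose_grid(vals, ph)
  curve <- idd(g)
  expect_equal(sum(curve$e), 3)
  expect_equal(curve$e[77], 3)         # delta-like deposit stays in its slab
  expect_true(all(curve$e[-77] == 0))
})

test_that("r80 matches the closed form on a triangular peak", {
  z <- 0:10
  e <- c(0, 1, 2, 3, 4, 5, 3.75, 2.5, 1.25, 0, 0)  # peak 5 at z=5, down to 0 at z=9
  curve <- data.frame(z = z, e = e)
  expect_equal(r80(curve), 5.8)                     # 5 + 0.2 * 4 analytically
  expect_equal(r80(data.frame(z = z, e = 17 * e)), 5.8)  # scale invariant
  expect_error(r80(data.frame(z = z, e = z)), "distal")
})

test_that("mean dose difference reports exact uniform offsets", {
  z <- seq(0.5, 99.5, 1)
  ref <- data.frame(z = z, e = dnorm(z, 70, 12) + 0.01)
  expect_equal(mean_dose_difference(ref, ref), 0)
  up <- ref; up$e <- 1.01 * up$e
  expect_equal(mean_dose_difference(ref, up), 1)
  expect_error(mean_dose_difference(ref, up, threshold_frac = 2), "disjoint")
})

test_that("profile metrics vanish for a grid compared with itself", {
  lut <- mini_lut_15T()
  out <- compute_dose(beam_spec(150), build_homogeneous("water"), 1.5, lut,
                      output = "yz")
  a <- profile_metrics(out, c(30, 80))
  b <- profile_metrics(out, c(30, 80))
  expect_equal(a$center, b$center)
  expect_equal(a$fwhm, b$fwhm)
  expect_true(all(a$converged))
})

test_that("spot size grows monotonically with depth at zero field", {
  lut <- mini_lut_0T()
  ent <- lut$tables[["0"]][["150"]]
  rng <- r80(data.frame(z = lut$z, e = ent$e_dep))
  pm <- data.frame(z = lut$z, fwhm = 2 * sqrt(2 * log(2)) * ent$params_y[, "sigma"])
  sel <- pm$z > 10 & pm$z < 0.9 * rng
  fw <- pm$fwhm[sel]
  expect_gt(tail(fw, 1), fw[1])
  expect_true(all(diff(stats::filter(fw, rep(1 / 7, 7))[4:(sum(sel) - 4)]) > -0.05))
})

test_that("gamma of a distribution against itself is identically zero", {
  set.seed(8)
  a <- array(exp(-((1:20 - 10)^2) %o% rep(1, 20) / 30) %o% rep(1, 20), c(20, 20, 20))
  g <- gamma_index(a, a, spacing = 1)
  expect_true(all(g$gamma[!is.na(g$gamma)] == 0))
  expect_equal(g$pass_rate, 100)
  expect_equal(g$gamma_mean, 0)
})

test_that("a rigid 2-mm shift yields gamma at most one", {
  x <- seq(0.5, 39.5, 1)
  f <- function(x0) outer(dnorm(x, x0, 4), dnorm(x, 20, 6)) * 1e3
  ref <- f(20); ev <- f(22)    # exact 2-mm rigid shift along the first axis
  g <- gamma_index(ref, ev, spacing = c(1, 1))
  gv <- g$gamma[!is.na(g$gamma)]
  expect_lt(max(gv), 1 + 1e-6)
  expect_gt(max(gv), 0.8)      # steep-gradient voxels approach the criterion
})

test_that("the fast gamma kernel equals the brute-force oracle", {
  set.seed(99)
  n <- 20
  x <- seq_len(n)
  base <- exp(-outer(outer((x - 10)^2, (x - 11)^2, "+"), (x - 9)^2, "+") / 150)
  ref <- base
  ev <- base * (1 + 0.03 * array(sin(seq_len(n^3)), dim(base)))
  fast <- gamma_index(ref, ev, spacing = 1, threshold = 5,
                      sample_step = 0.5, search_factor = 2)
  brute <- gamma_index_brute(ref, ev, spacing = 1, threshold = 5,
                             sample_step = 0.5, search_factor = 2)
  expect_lt(max(abs(fast$gamma - brute$gamma), na.rm = TRUE), 1e-6)
  expect_equal(fast$pass_rate, brute$pass_rate)
  expect_equal(fast$gamma_mean, brute$gamma_mean, tolerance = 1e-9)
})

test_that("gamma is invariant under a common scale and monotone in the criteria", {
  set.seed(12)
  x <- seq_len(30)
  ref <- outer(dnorm(x, 15, 5), dnorm(x, 15, 7)) * 1e3
  ev <- ref * (1 + 0.04 * matrix(sin(1:900), 30))
  g1 <- gamma_index(ref, ev, spacing = 1)
  g2 <- gamma_index(5 * ref, 5 * ev, spacing = 1)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-12)
  tight <- gamma_index(ref, ev, dose_crit = 1, dist_crit = 1, spacing = 1)
  loose <- gamma_index(ref, ev, dose_crit = 3, dist_crit = 3, spacing = 1)
  expect_lte(tight$pass_rate, g1$pass_rate)
  expect_lte(g1$pass_rate, loose$pass_rate)
  expect_error(gamma_index(ref, ev[1:10, 1:10], spacing = 1), "geometry")
})
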