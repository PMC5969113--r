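test_that("beam splitting spans +-3 sigma with normalized weights", {
  beam <- beam_spec(150)
  s1 <- split_beam(beam, 1)
  expect_equal(s1$offsets$oy, 0)
  expect_equal(s1$weights, 1)
  s9 <- split_beam(beam, 9)
  expect_equal(range(s9$offsets$oy), c(-9, 9))        # 3 sigma at 3 mm
  expect_equal(diff(s9$offsets$oy), rep(2.25, 8))     # equidistant
  expect_equal(sum(s9$weights), 1)
  expect_error(split_beam(beam, 4), "odd")
  # 2-D grid splitting for the square of an odd count
  s81 <- split_beam(beam, 81)
  expect_equal(nrow(s81$offsets), 81)
  expect_equal(length(unique(s81$offsets$ox)), 9)
  s15 <- split_beam(beam, 15)
  expect_equal(nrow(s15$offsets), 15)
})

test_that("superposed subbeam fluence reproduces the parent Gaussian", {
  beam <- beam_spec(150)
  for (k in c(9, 15, 81)) {
    expect_lt(entrance_fluence_error(split_beam(beam, k)), 0.01)
  }
})

test_that("center shifting follows each subbeam through its own materials", {
  beam <- beam_spec(150)
  # B = 0, homogeneous: no deflection for any subbeam
  subs <- shift_centers(split_beam(beam, 9), water_small(), 0)
  expect_true(all(vapply(subs$trajectories,
                         function(t) max(abs(t$y_defl)), 1) == 0))
  # homogeneous water with field: all subbeams share the water curve
  ph <- build_homogeneous("water")
  subs <- shift_centers(split_beam(beam, 9), ph, 1.5)
  y0 <- subs$trajectories[[5]]$y_defl
  for (j in c(1, 9)) expect_equal(subs$trajectories[[j]]$y_defl, y0)
  # opposing-slab phantom: bone-side and air-side subbeams diverge
  phl <- build_lateral_opposing()
  subs <- shift_centers(split_beam(beam, 9), phl, 1.5)
  at60 <- function(j) approx(subs$wepl[[j]]$z, subs$wepl[[j]]$z_eq, 60)$y
  # at 60 mm depth the bone-side subbeam has consumed ~34 mm more water
  # equivalence than the air-side one (20 mm bone vs 20 mm air)
  expect_gt(at60(9) - at60(1), 25)
  # and the bone-side subbeam ranges out earlier in geometric depth
  expect_lt(max(subs$wepl[[9]]$z), max(subs$wepl[[1]]$z) - 20)
})

test_that("in water the engine reduces to an exact replay of the tables", {
  lut <- mini_lut_15T()
  ph <- build_homogeneous("water")
  expect_equal(equivalent_depth(c(25, 100, 140), "water", 150, 1.5),
               c(25, 100, 140))
  out <- compute_dose(beam_spec(150), ph, 1.5, lut, k = 1,
                      output = c("yz", "idd"))
  ent <- lut$tables[["1.5"]][["150"]]
  sel <- ent$e_dep > 1e-3 * max(ent$e_dep)
  expect_lt(max(abs(out$idd$e[sel] - ent$e_dep[sel]) / ent$e_dep[sel]), 2e-3)
  # the replayed lateral profile refits to the calibrated parameters
  zi <- 100
  refit <- fit_lateral(attr(out$yz, "lat"), out$yz[, zi])
  expect_equal(coef(refit)[["x_m"]], unname(ent$params_y[zi, "x_m"]),
               tolerance = 1e-4)
  expect_equal(coef(refit)[["sigma"]], unname(ent$params_y[zi, "sigma"]),
               tolerance = 1e-4)
})

test_that("dose superposition is linear over subbeams", {
  lut <- mini_lut_15T()
  ph <- build_homogeneous("water")
  beam <- beam_spec(150)
  subs <- shift_centers(split_beam(beam, 9), ph, 1.5)
  full <- compute_dose(beam, ph, 1.5, lut, output = "yz", subs = subs)
  acc <- 0
  for (j in 1:9) {
    sj <- subs
    sj$offsets <- subs$offsets[j, , drop = FALSE]
    sj$weights <- subs$weights[j]
    sj$trajectories <- subs$trajectories[j]
    sj$wepl <- subs$wepl[j]
    acc <- acc + compute_dose(beam, ph, 1.5, lut, output = "yz", subs = sj)
  }
  expect_lt(max(abs(acc - full)) / max(full), 1e-12)
})

test_that("transverse slab sums recover the tabulated depth dose", {
  lut <- mini_lut_15T()
  ph <- build_homogeneous("water")
  g <- compute_dose(beam_spec(150), ph, 1.5, lut, k = 1, output = "grid")
  ent <- lut$tables[["1.5"]][["150"]]
  for (zi in c(40, 100, 140)) {
    slab_sum <- sum(g$values[, , zi])
    # equality up to the lateral window truncation by the grid
    expect_lt(abs(slab_sum / ent$e_dep[zi] - 1), 5e-3)
  }
})

test_that("splitting with center shifting improves the lateral-phantom depth dose", {
  lut <- mini_lut_15T()
  ph <- build_lateral_opposing()
  mc <- fixture("lateral_mc_150_15",
                simulate_beam(beam_spec(150), ph, 1.5, mc_config(4e4, seed = 301)))
  ref <- idd(mc)
  err <- function(k) {
    out <- compute_dose(beam_spec(150), ph, 1.5, lut, k = k, output = "idd")
    sel <- ref$e > 0.01 * max(ref$e)
    sqrt(mean((out$e[sel] - ref$e[sel])^2)) / max(ref$e)
  }
  e1 <- err(1); e9 <- err(9); e15 <- err(15)
  expect_lt(e9, e1)
  expect_lte(e15, e9 * 1.02)
  expect_gt(e1, 2 * e9)   # the unsplit beam misses the double structure
})

test_that("requesting an uncalibrated field is an error", {
  lut <- mini_lut_15T()
  expect_error(compute_dose(beam_spec(150), water_small(), 3, lut), "not calibrated")
})
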