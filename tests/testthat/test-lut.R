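test_that("the calibrated depth dose accounts for all scored energy", {
  lut <- mini_lut_15T()
  ent <- lut$tables[["1.5"]][["150"]]
  # the IDD integral (1-mm slabs) must equal the total scored energy per
  # proton: a pure bookkeeping identity of the extraction
  expect_true(all(ent$e_dep >= 0))
  expect_gt(sum(ent$e_dep), 100)     # most of 150 MeV ends up in the grid
  # single global maximum region (Bragg peak)
  pk <- which.max(ent$e_dep)
  expect_gt(ent$e_dep[pk] / ent$e_dep[5], 2.5)
})

test_that("the zero-field Bragg peak depth matches the CSDA range", {
  lut <- mini_lut_0T()
  ent <- lut$tables[["0"]][["150"]]
  pk <- lut$z[which.max(ent$e_dep)]
  expect_lt(abs(pk - csda_range(150, material("water"))), 3)
})

test_that("the fitted y-plane center tracks the trajectory deflection", {
  lut <- mini_lut_15T()
  ent <- lut$tables[["1.5"]][["150"]]
  tr <- integrate_trajectory(150, 1.5, "water")
  rng <- r80(data.frame(z = lut$z, e = ent$e_dep))
  sel <- which(lut$z > 5 & lut$z < 0.8 * rng)
  dev <- ent$params_y[sel, "x_m"] - trajectory_at(tr, lut$z[sel])$y
  expect_lt(max(abs(dev)), 1)
  # x-plane profiles stay centered and near-symmetric at all depths
  expect_lt(max(abs(ent$params_x[sel, "x_m"])), 1)
  expect_lt(median(abs(ent$params_x[sel, "f_L"] - ent$params_x[sel, "f_R"])), 0.1)
})

test_that("interpolation is exact at grid nodes and bounded between them", {
  lut <- fixture("lut_pair",
                 build_luts(c(150, 160), 1.5, mc_config(2e4, seed = 107)))
  zq <- seq(10, 120, by = 10)
  at150 <- lut_interpolate(lut, 150, 1.5, zq)
  ent <- lut$tables[["1.5"]][["150"]]
  expect_equal(at150$e_dep, approx(lut$z, ent$e_dep, zq)$y)
  expect_equal(at150$params_y[, "sigma"],
               approx(lut$z, ent$params_y[, "sigma"], zq)$y)
  # between nodes, the plateau depth dose lies between the two curves
  at155 <- lut_interpolate(lut, 155, 1.5, zq)
  lo <- pmin(at150$e_dep, lut_interpolate(lut, 160, 1.5, zq)$e_dep)
  hi <- pmax(at150$e_dep, lut_interpolate(lut, 160, 1.5, zq)$e_dep)
  expect_true(all(at155$e_dep >= lo - 1e-12 & at155$e_dep <= hi + 1e-12))
  # interpolated parameters keep the model invariants
  pp <- at155$params_y
  expect_true(all(pp[, "sigma"] > 0 & pp[, "gamma_L"] > 0 & pp[, "gamma_R"] > 0))
  expect_true(all(pp[, "f_L"] >= 0 & pp[, "f_R"] >= 0 &
                  pp[, "f_L"] + pp[, "f_R"] < 1))
})

test_that("uncalibrated fields and out-of-grid energies are errors", {
  lut <- mini_lut_15T()
  expect_error(lut_interpolate(lut, 150, 2.5, 10), "not calibrated")
  expect_error(lut_interpolate(lut, 90, 1.5, 10), "energy grid")
})

test_that("look-up tables round trip exactly through both formats", {
  lut <- mini_lut_15T()
  rds <- tempfile(fileext = ".rds")
  write_lut(lut, rds)
  expect_identical(read_lut(rds), lut)
  tsv <- tempfile(fileext = ".tsv")
  write_lut(lut, tsv)
  back <- read_lut(tsv)
  ent <- lut$tables[["1.5"]][["150"]]
  bent <- back$tables[["1.5"]][["150"]]
  expect_identical(bent$e_dep, ent$e_dep)
  expect_identical(unname(bent$params_y), unname(ent$params_y))
  expect_identical(back$z, lut$z)
  unlink(c(rds, tsv))
})

test_that("rebuilding with the same seed reproduces the tables", {
  a <- build_luts(80, 0.5, mc_config(5e3, seed = 201),
                  phantom = build_homogeneous("water",
                    extent = list(x = c(-25, 25), y = c(-30, 40), z = c(0, 70))))
  b <- build_luts(80, 0.5, mc_config(5e3, seed = 201),
                  phantom = build_homogeneous("water",
                    extent = list(x = c(-25, 25), y = c(-30, 40), z = c(0, 70))))
  expect_identical(a$tables, b$tables)
})
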