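test_that("the profile reduces to a pure Gaussian when tails vanish", {
  p <- lateral_params(A = 2.5, f_L = 0, f_R = 0, x_m = 1, sigma = 3,
                      gamma_L = 2, gamma_R = 2)
  expect_equal(eval_profile(1, p), 2.5 / (3 * sqrt(2 * pi)))
  xx <- seq(-14, 16, 0.5)
  expect_equal(eval_profile(xx, p), 2.5 * dnorm((xx - 1) / 3) / 3)
})

test_that("equal tails give a profile symmetric about the center", {
  p <- lateral_params(A = 1, f_L = 0.2, f_R = 0.2, x_m = -2, sigma = 2.5,
                      gamma_L = 4, gamma_R = 4)
  u <- seq(0.1, 30, length.out = 50)
  expect_equal(eval_profile(-2 + u, p), eval_profile(-2 - u, p),
               tolerance = 1e-10)
})

test_that("every component has unit area for random valid parameters", {
  set.seed(42)
  du <- 0.02
  u <- seq(-320, 320, by = du)   # > 12 decay lengths for the slowest tails
  for (i in 1:1000) {
    g <- exp(runif(1, log(1.5), log(25)))
    side <- if (i %% 2 == 0) protonPBA:::.ltail_u(u, g)
            else protonPBA:::.rtail_u(u, g)
    expect_lt(abs(sum(side) * du - 1), 1e-4)
  }
  # and therefore the full profile integrates to A
  p <- lateral_params(A = 7.3, f_L = 0.15, f_R = 0.3, x_m = 0, sigma = 2,
                      gamma_L = 3, gamma_R = 8)
  expect_lt(abs(sum(eval_profile(u * 2, p)) * du * 2 - 7.3) / 7.3, 1e-4)
})

test_that("the profile is finite and continuous out to 40 sigma", {
  p <- lateral_params(A = 1, f_L = 0.1, f_R = 0.1, x_m = 0, sigma = 3,
                      gamma_L = 1.5, gamma_R = 28)
  x <- seq(-40 * 3, 40 * 3, by = 0.1)
  v <- eval_profile(x, p)
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0))
  expect_lt(max(abs(diff(v))) , max(v))  # no jumps at branch switches
})

test_that("parameter invariants are enforced", {
  expect_error(lateral_params(1, 0.6, 0.5, 0, 3, 2, 2), "invariant")
  expect_error(lateral_params(1, -0.1, 0, 0, 3, 2, 2), "invariant")
  expect_error(lateral_params(1, 0, 0, 0, -3, 2, 2), "invariant")
  expect_error(lateral_params(0, 0, 0, 0, 3, 2, 2), "invariant")
})

test_that("fitting noiseless samples recovers the parameters (round trip)", {
  p <- lateral_params(A = 10, f_L = 0.08, f_R = 0.18, x_m = 1.2, sigma = 3,
                      gamma_L = 4, gamma_R = 6)
  x <- seq(-60, 80, by = 1)
  fit <- fit_lateral(x, eval_profile(x, p))
  got <- coef(fit)
  for (nm in c("A", "f_L", "f_R", "sigma", "gamma_L", "gamma_R")) {
    expect_lt(abs(got[[nm]] / p[[nm]] - 1), 0.01)
  }
  expect_lt(abs(got[["x_m"]] - p[["x_m"]]), 0.01 * p[["sigma"]])
  expect_true(fit$converged)
  expect_false(fit$fallback_gaussian)
})

test_that("fitting a pure Gaussian yields negligible tail fractions", {
  x <- seq(-40, 40, by = 1)
  fit <- fit_lateral(x, 5 * dnorm(x, 2, 3.2))
  expect_lte(coef(fit)[["f_L"]], 0.02)
  expect_lte(coef(fit)[["f_R"]], 0.02)
  expect_rel_equal(coef(fit)[["sigma"]], 3.2, 0.01)
})

test_that("gaussian component metrics follow the closed form", {
  p <- lateral_params(1, 0.1, 0.2, 5, 3, 2, 9)
  m <- gaussian_component_metrics(p)
  expect_equal(m$center, 5)
  expect_equal(m$fwhm, 2 * sqrt(2 * log(2)) * 3)
  # center and FWHM do not depend on the tail parameters
  p2 <- lateral_params(4, 0.3, 0.05, 5, 3, 7, 1.6)
  expect_equal(gaussian_component_metrics(p2)[c("center", "fwhm")],
               m[c("center", "fwhm")])
})

test_that("lateral_fit methods are coherent", {
  p <- lateral_params(3, 0.1, 0.1, 0, 3, 3, 3)
  x <- seq(-50, 50, by = 1)
  y <- eval_profile(x, p)
  fit <- fit_lateral(x, y)
  expect_s3_class(fit, "lateral_fit")
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), y - fitted(fit))
  expect_lt(max(abs(residuals(fit))) / max(y), 1e-6)
  expect_output(print(fit), "Tailed-Gaussian")
})

test_that("degenerate inputs are rejected or flagged", {
  x <- seq(-20, 20, by = 1)
  expect_error(fit_lateral(x, rep(0, length(x))), "all-zero")
  expect_error(fit_lateral(x, c(rep(1, 40), -1)), "negative")
  expect_error(fit_lateral(1:10, 1:10), "length")
})
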