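#' Parameters of the asymmetric lateral profile model
#'
#' The lateral dose profile of a proton pencil beam in a transverse magnetic
#' field is described by a Gaussian core plus independent left and right
#' exponential tails (each an exponentially-modified-Gaussian density built
#' from exp x erfc), seven free parameters in total:
#'
#' f(x) = A * \[(1 - f_L - f_R) G(x) + f_L LTail(x) + f_R RTail(x)]
#'
#' where G is the unit Gaussian density at (x_m, sigma) and LTail/RTail are
#' unit-area densities with exponential decay lengths gamma_L * sigma (to
#' the left) and gamma_R * sigma (to the right). Each component integrates
#' to 1 over the real line, so the profile integrates to A.
#'
#' @param A total peak area (> 0).
#' @param f_L,f_R tail area fractions (>= 0, f_L + f_R < 1).
#' @param x_m core center (mm).
#' @param sigma core standard deviation (mm, > 0).
#' @param gamma_L,gamma_R tail decay rates relative to sigma (> 0).
#' @return a named numeric vector of class `lateral_params`.
#' @export
lateral_params <- function(A, f_L, f_R, x_m, sigma, gamma_L, gamma_R) {
  p <- c(A = A, f_L = f_L, f_R = f_R, x_m = x_m, sigma = sigma,
         gamma_L = gamma_L, gamma_R = gamma_R)
  validate_lateral_params(p)
  class(p) <- "lateral_params"
  p
}

validate_lateral_params <- function(p) {
  if (!all(c("A", "f_L", "f_R", "x_m", "sigma", "gamma_L", "gamma_R") %in%
           names(p))) {
    stop("lateral_params: missing parameter names", call. = FALSE)
  }
  if (p[["sigma"]] <= 0 || p[["gamma_L"]] <= 0 || p[["gamma_R"]] <= 0 ||
      p[["f_L"]] < 0 || p[["f_R"]] < 0 ||
      p[["f_L"]] + p[["f_R"]] >= 1 || p[["A"]] <= 0) {
    stop("lateral_params: invariant violation (sigma, gamma > 0; ",
         "f_L, f_R >= 0 with f_L + f_R < 1; A > 0)", call. = FALSE)
  }
  invisible(p)
}

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x).
# Direct product below x = 12 (both factors representable), 7-term
# asymptotic series above (relative truncation error < 1e-12 at x = 12);
# the naive product overflows beyond x ~ 26.6.
.erfcx <- function(x) {
  out <- numeric(length(x))
  lo <- x < 12
  out[lo] <- exp(x[lo]^2) * 2 * pnorm(-x[lo] * sqrt(2))
  if (any(!lo)) {
    t <- 1 / (2 * x[!lo]^2)
    s <- 1 - t * (1 - 3 * t * (1 - 5 * t * (1 - 7 * t *
           (1 - 9 * t * (1 - 11 * t)))))
    out[!lo] <- s / (x[!lo] * sqrt(pi))
  }
  out
}

# Unit-area components. u = (x - x_m)/sigma. The exp x erfc product is
# evaluated through the scaled complementary error function:
# exp(1/(2 g^2)) exp(+-u/g) erfc(+-u/sqrt2 + 1/(sqrt2 g))
#   = erfcx(+-u/sqrt2 + 1/(sqrt2 g)) * exp(-u^2/2),
# finite for any |u| (no overflow out to 40 sigma and beyond).
.ltail_u <- function(u, g) {
  b <- u / sqrt(2) + 1 / (sqrt(2) * g)
  # erfcx overflows for b << 0; there erfcx(b) ~ 2 exp(b^2), and
  # b^2 - u^2/2 = u/g + 1/(2 g^2) exactly, giving the pure exponential tail
  safe <- b > -15
  out <- numeric(length(u))
  out[safe] <- .erfcx(b[safe]) * exp(-u[safe]^2 / 2) / (2 * g)
  out[!safe] <- exp(u[!safe] / g + 1 / (2 * g^2)) / g
  out
}
.rtail_u <- function(u, g) .ltail_u(-u, g)

#' Evaluate the lateral profile model
#'
#' @param x positions (mm), vectorized.
#' @param p a [lateral_params()] vector (or named numeric with the same
#'   elements).
#' @param component `"all"` (default) for the full profile, or one of
#'   `"gauss"`, `"ltail"`, `"rtail"` for a single unit-area component
#'   (without A or the fractions).
#' @return intensity values (>= 0, finite for |x - x_m| up to 40 sigma and
#'   beyond).
#' @examples
#' p <- lateral_params(1, 0.1, 0.2, 0, 3, 4, 4)
#' eval_profile(0, p)
#' @export
eval_profile <- function(x, p, component = c("all", "gauss", "ltail", "rtail")) {
  component <- match.arg(component)
  validate_lateral_params(p)
  u <- (x - p[["x_m"]]) / p[["sigma"]]
  s <- p[["sigma"]]
  switch(component,
    gauss = dnorm(u) / s,
    ltail = .ltail_u(u, p[["gamma_L"]]) / s,
    rtail = .rtail_u(u, p[["gamma_R"]]) / s,
    all = {
      fL <- p[["f_L"]]; fR <- p[["f_R"]]
      p[["A"]] * ((1 - fL - fR) * dnorm(u) / s +
                  fL * .ltail_u(u, p[["gamma_L"]]) / s +
                  fR * .rtail_u(u, p[["gamma_R"]]) / s)
    })
}

#' Center and FWHM of the Gaussian component
#'
#' The lateral bending coordinate and beam spot size used throughout the
#' evaluation battery: the center is x_m and the full width at half maximum
#' is 2 sqrt(2 ln 2) sigma of the Gaussian core, independent of the tail
#' parameters.
#'
#' @param p a [lateral_params()] vector.
#' @return list with `center` (mm) and `fwhm` (mm).
#' @export
gaussian_component_metrics <- function(p) {
  validate_lateral_params(p)
  list(center = unname(p[["x_m"]]),
       fwhm = 2 * sqrt(2 * log(2)) * unname(p[["sigma"]]))
}

#' Fit the asymmetric lateral profile model to a sampled profile
#'
#' Bounded weighted least squares (Levenberg-Marquardt) fit of the
#' seven-parameter tailed-Gaussian model to a sampled lateral dose profile.
#' Initialization is moment-based: center from the centroid of the samples
#' above half maximum, sigma from the interpolated FWHM, area from the
#' trapezoidal integral, small symmetric starting tails. Weights default to
#' Poisson-like 1/sqrt(intensity) with a floor at 1e-3 of the peak, since
#' Monte Carlo profiles are count-derived. On non-convergence the fit falls
#' back to a pure Gaussian (f_L = f_R = 0) with a warning and a flag.
#'
#' @param x sample positions (mm), at least 30, spanning core and tails.
#' @param y sampled intensities (nonnegative).
#' @param weights optional fit weights (same length as x).
#' @param start optional named start values overriding the moment-based
#'   initialization.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return an object of class `lateral_fit` with components `params`
#'   (a [lateral_params()] vector), `converged`, `fallback_gaussian`,
#'   `rms_residual` (RMS residual relative to the profile maximum), `data`,
#'   and `weights`. Methods: `coef`, `print`, `summary`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' p <- lateral_params(10, 0.08, 0.15, 1, 3, 5, 5)
#' x <- seq(-40, 40, by = 1)
#' fit <- fit_lateral(x, eval_profile(x, p))
#' coef(fit)
#' @export
fit_lateral <- function(x, y, weights = NULL, start = NULL, maxiter = 100) {
  stopifnot(length(x) == length(y), length(x) >= 30)
  if (any(y < 0)) stop("fit_lateral: negative intensities", call. = FALSE)
  ymax <- max(y)
  if (ymax <= 0) stop("fit_lateral: all-zero profile", call. = FALSE)
  if (is.null(weights)) {
    weights <- 1 / sqrt(pmax(y, 1e-3 * ymax))
  }

  init <- .lateral_init(x, y)
  if (!is.null(start)) {
    start <- start[is.finite(start)]
    init[names(start)] <- start
  }

  lower <- c(A = 1e-12, f_L = 0, f_R = 0, x_m = min(x) - 10,
             sigma = 0.2, gamma_L = 1.5, gamma_R = 1.5)
  upper <- c(A = Inf, f_L = 0.45, f_R = 0.45, x_m = max(x) + 10,
             sigma = diff(range(x)), gamma_L = 30, gamma_R = 30)
  init <- pmin(pmax(init, lower + 1e-9), ifelse(is.finite(upper), upper - 1e-9, init))

  resid_fn <- function(par) {
    pp <- par
    if (any(!is.finite(pp))) return(rep(1e6, length(x)))
    # keep the mixture valid inside the optimizer
    if (pp[["f_L"]] + pp[["f_R"]] >= 0.95) {
      sc <- 0.94 / (pp[["f_L"]] + pp[["f_R"]])
      pp[["f_L"]] <- pp[["f_L"]] * sc; pp[["f_R"]] <- pp[["f_R"]] * sc
    }
    (.eval_profile_raw(x, pp) - y) * weights
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ptol = 1e-10, ftol = 1e-10))
  par <- fit$par
  converged <- fit$info %in% c(1, 2, 3, 4) && all(is.finite(unlist(par)))
  fallback <- FALSE
  rms <- if (converged) sqrt(mean((.eval_profile_raw(x, par) - y)^2)) / ymax
         else Inf

  if (!converged || !is.finite(rms) || rms > 0.2) {
    # pure-Gaussian fallback
    fallback <- TRUE
    warning("fit_lateral: tailed fit did not converge; pure-Gaussian fallback",
            call. = FALSE)
    g_init <- init[c("A", "x_m", "sigma")]
    gfit <- minpack.lm::nls.lm(
      par = g_init, lower = lower[c("A", "x_m", "sigma")],
      upper = upper[c("A", "x_m", "sigma")],
      fn = function(par) {
        pp <- c(par["A"], f_L = 0, f_R = 0, par["x_m"], par["sigma"],
                gamma_L = 1, gamma_R = 1)
        names(pp) <- c("A", "f_L", "f_R", "x_m", "sigma", "gamma_L", "gamma_R")
        (.eval_profile_raw(x, pp) - y) * weights
      },
      control = minpack.lm::nls.lm.control(maxiter = maxiter))
    gp <- gfit$par
    if (any(!is.finite(unlist(gp)))) gp <- as.list(g_init)
    par <- c(gp[["A"]], f_L = 0 + 1e-12, f_R = 1e-12, gp[["x_m"]],
             gp[["sigma"]], gamma_L = 1, gamma_R = 1)
    names(par) <- c("A", "f_L", "f_R", "x_m", "sigma", "gamma_L", "gamma_R")
    converged <- gfit$info %in% c(1, 2, 3, 4)
    rms <- sqrt(mean((.eval_profile_raw(x, par) - y)^2)) / ymax
  }

  params <- lateral_params(par[["A"]], max(par[["f_L"]], 0), max(par[["f_R"]], 0),
                           par[["x_m"]], par[["sigma"]],
                           par[["gamma_L"]], par[["gamma_R"]])
  structure(list(params = params, converged = converged,
                 fallback_gaussian = fallback, rms_residual = rms,
                 niter = fit$niter, data = list(x = x, y = y),
                 weights = weights),
            class = "lateral_fit")
}

# evaluation without the class/validation overhead, for the optimizer
.eval_profile_raw <- function(x, p) {
  u <- (x - p[["x_m"]]) / p[["sigma"]]
  s <- p[["sigma"]]
  fL <- p[["f_L"]]; fR <- p[["f_R"]]
  p[["A"]] * ((1 - fL - fR) * dnorm(u) / s +
              (if (fL > 0) fL * .ltail_u(u, p[["gamma_L"]]) / s else 0) +
              (if (fR > 0) fR * .rtail_u(u, p[["gamma_R"]]) / s else 0))
}

.lateral_init <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  above <- y >= half
  x_m <- sum(x[above] * y[above]) / sum(y[above])
  # interpolated half-maximum crossings
  xl <- x[imax]; xr <- x[imax]
  il <- which(!above & x < x[imax]); ir <- which(!above & x > x[imax])
  cross <- function(x1, x2, y1, y2) {
    if (y2 == y1) return(x1)
    x1 + (half - y1) / (y2 - y1) * (x2 - x1)
  }
  if (length(il)) {
    i <- max(il)
    xl <- cross(x[i], x[i + 1], y[i], y[i + 1])
  }
  if (length(ir)) {
    i <- min(ir)
    xr <- cross(x[i - 1], x[i], y[i - 1], y[i])
  }
  fwhm <- max(xr - xl, diff(range(x)) / 50)
  if (!is.finite(fwhm) || !is.finite(x_m)) {
    x_m <- x[imax]; fwhm <- diff(range(x)) / 10
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  A <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  c(A = max(A, 1e-9), f_L = 0.02, f_R = 0.02, x_m = x_m,
    sigma = sigma, gamma_L = 3, gamma_R = 3)
}

#' @export
coef.lateral_fit <- function(object, ...) object$params

#' @export
print.lateral_fit <- function(x, ...) {
  p <- x$params
  cat("Tailed-Gaussian lateral profile fit\n")
  cat(sprintf("  center x_m = %.3f mm, sigma = %.3f mm (FWHM %.3f mm)\n",
              p[["x_m"]], p[["sigma"]], 2 * sqrt(2 * log(2)) * p[["sigma"]]))
  cat(sprintf("  tails: f_L = %.4f (gamma_L %.2f), f_R = %.4f (gamma_R %.2f), A = %.4g\n",
              p[["f_L"]], p[["gamma_L"]], p[["f_R"]], p[["gamma_R"]], p[["A"]]))
  cat(sprintf("  converged: %s%s, RMS residual %.3g of peak\n",
              x$converged, if (x$fallback_gaussian) " (gaussian fallback)" else "",
              x$rms_residual))
  invisible(x)
}

#' @export
summary.lateral_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
predict.lateral_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.list(newdata)) newdata$x else newdata
  eval_profile(x, object$params)
}

#' @export
fitted.lateral_fit <- function(object, ...) predict(object)

#' @export
residuals.lateral_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Overlay a fitted lateral profile on its data
#'
#' @param x a `lateral_fit`.
#' @param log use a logarithmic intensity axis (default TRUE; the tails span
#'   orders of magnitude).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lateral_fit <- function(x, log = TRUE, ...) {
  d <- x$data
  xx <- seq(min(d$x), max(d$x), length.out = 400)
  yy <- eval_profile(xx, x$params)
  floor_y <- max(d$y) * 1e-6
  graphics::plot(d$x, pmax(d$y, if (log) floor_y else 0),
                 log = if (log) "y" else "",
                 xlab = "lateral position (mm)", ylab = "intensity",
                 pch = 1, ...)
  graphics::lines(xx, pmax(yy, if (log) floor_y else 0), col = 2, lwd = 2)
  invisible(x)
}
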