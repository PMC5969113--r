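#' Integrated depth dose of a dose grid
#'
#' Transverse sum of deposited energy per depth slab, per history.
#'
#' @param grid a `dose_grid`, or a projected map from [project_grid()].
#' @return data.frame with `z` (mm) and `e` (MeV per slab per history).
#' @export
idd <- function(grid) {
  if (inherits(grid, "dose_grid")) {
    data.frame(z = voxel_centers(grid, 3),
               e = apply(grid$values, 3, sum) / grid$n_histories)
  } else if (is.matrix(grid)) {
    data.frame(z = attr(grid, "z"), e = colSums(grid))
  } else stop("idd: expected a dose_grid or projected map")
}

#' R80 beam range from a depth-dose curve
#'
#' Depth distal to the global maximum where the curve first crosses 80% of
#' the maximum, with linear interpolation between samples -- the
#' operational beam range.
#'
#' @param curve data.frame with `z` and `e` (an [idd()] result), or a
#'   numeric vector with depths as names/attribute `z`.
#' @param level fractional dose level (default 0.8).
#' @return depth (mm).
#' @export
r80 <- function(curve, level = 0.8) {
  z <- curve$z; e <- curve$e
  imax <- which.max(e)
  target <- level * e[imax]
  distal <- seq(imax, length(e))
  below <- distal[which(e[distal] < target)]
  if (!length(below)) {
    stop("r80: no distal crossing (beam may exit the grid)", call. = FALSE)
  }
  i <- below[1]
  approx(e[c(i - 1, i)], z[c(i - 1, i)], xout = target)$y
}

# FWHM of the depth-dose peak (for the proximal-region definition)
.idd_peak_fwhm <- function(curve) {
  z <- curve$z; e <- curve$e
  imax <- which.max(e)
  half <- e[imax] / 2
  il <- which(e[seq_len(imax)] < half)
  ir <- which(e[imax:length(e)] < half) + imax - 1L
  zl <- if (length(il)) approx(e[c(max(il), max(il) + 1)],
                               z[c(max(il), max(il) + 1)], xout = half)$y
        else z[1]
  zr <- if (length(ir)) approx(e[c(min(ir) - 1, min(ir))],
                               z[c(min(ir) - 1, min(ir))], xout = half)$y
        else z[length(z)]
  zr - zl
}

#' Proximal (pre-peak) region of a depth-dose curve
#'
#' Depth selector used for the sub-0.1% plateau comparison: depths before
#' R80 minus twice the peak FWHM.
#'
#' @param curve an [idd()] data.frame.
#' @return logical vector over the rows of `curve`.
#' @export
idd_proximal_region <- function(curve) {
  curve$z < r80(curve) - 2 * .idd_peak_fwhm(curve)
}

#' Mean local dose difference between two depth-dose curves
#'
#' Signed local relative differences (eval - ref)/ref at depths where the
#' reference exceeds a cutoff (default 1% of its maximum), averaged through
#' a count-weighted histogram (bins of 0.1 percentage points) to smooth the
#' influence of the falloff region.
#'
#' @param ref,eval [idd()] data.frames on a common depth grid.
#' @param threshold_frac inclusion cutoff as a fraction of the reference
#'   maximum.
#' @param region optional additional logical selector over depths (e.g.
#'   [idd_proximal_region()]).
#' @param bin_width histogram bin width in percentage points.
#' @return signed mean difference, %.
#' @export
mean_dose_difference <- function(ref, eval, threshold_frac = 0.01,
                                 region = NULL, bin_width = 0.1) {
  stopifnot(nrow(ref) == nrow(eval), all(abs(ref$z - eval$z) < 1e-9))
  sel <- ref$e > threshold_frac * max(ref$e)
  if (!is.null(region)) sel <- sel & region
  if (!any(sel)) stop("mean_dose_difference: disjoint supports", call. = FALSE)
  d <- 100 * (eval$e[sel] - ref$e[sel]) / ref$e[sel]
  # bins centered on multiples of bin_width, so a uniform difference is
  # reported exactly
  br <- seq((round(min(d) / bin_width) - 1) * bin_width - bin_width / 2,
            (round(max(d) / bin_width) + 1) * bin_width + bin_width / 2,
            by = bin_width)
  h <- graphics::hist(d, breaks = br, plot = FALSE)
  weighted.mean(h$mids, h$counts)
}

#' Lateral profile metrics at selected depths
#'
#' Fits the seven-parameter lateral model to the transverse profile of a
#' projected energy map at the requested depths and reports the Gaussian
#' component's center (lateral bending coordinate) and FWHM (beam spot
#' size).
#'
#' @param map a projected map from [project_grid()] or
#'   [compute_dose()] (`"yz"` or `"xz"`).
#' @param depths depths (mm) at which to fit; each snaps to the nearest
#'   depth bin.
#' @return data.frame with `z`, `center`, `fwhm`, `converged`.
#' @export
profile_metrics <- function(map, depths) {
  lat <- attr(map, "lat"); z <- attr(map, "z")
  out <- lapply(depths, function(d) {
    i <- which.min(abs(z - d))
    f <- .quiet_fit(lat, map[, i], NULL)
    gm <- gaussian_component_metrics(f$params)
    data.frame(z = z[i], center = gm$center, fwhm = gm$fwhm,
               converged = f$converged)
  })
  do.call(rbind, out)
}

#' Gamma-index comparison of two dose distributions
#'
#' Low-style gamma index with criteria relative to the global maximum of
#' the reference: for every reference voxel above the inclusion threshold,
#' the minimum over a sampled neighborhood of
#' sqrt((|dr|/dist_crit)^2 + (dD/dose_tol)^2), where the evaluated
#' distribution is interpolated trilinearly at sub-voxel sample points
#' (default 0.2 mm spacing) within a search radius of
#' `search_factor * dist_crit`. The early-exit search is exact: results
#' are identical to exhaustive search over the same sample lattice (see
#' [gamma_index_brute()]).
#'
#' @param ref,eval `dose_grid`s, projected maps, or plain arrays on the
#'   same geometry (reference first).
#' @param dose_crit dose criterion, % of the global reference maximum.
#' @param dist_crit distance-to-agreement criterion (mm).
#' @param threshold inclusion cutoff, % of the global reference maximum.
#' @param spacing voxel spacing (mm); taken from the grid when available.
#' @param sample_step sub-voxel search sampling step (mm).
#' @param search_factor search radius in units of `dist_crit`.
#' @return object of class `gamma_result`: `gamma` (array, NA outside the
#'   threshold), `pass_rate` (% of included voxels with gamma < 1),
#'   `gamma_mean`, `n_included`, and the criteria.
#' @export
gamma_index <- function(ref, eval, dose_crit = 2, dist_crit = 2,
                        threshold = 0.1, spacing = NULL, sample_step = 0.2,
                        search_factor = 3) {
  ra <- .as_eval_array(ref, spacing)
  ea <- .as_eval_array(eval, spacing)
  if (!all(ra$dims == ea$dims) || !all(abs(ra$spacing - ea$spacing) < 1e-9)) {
    stop("gamma_index: geometry mismatch between ref and eval", call. = FALSE)
  }
  dmax <- max(ra$values)
  res <- gamma_index_cpp(ra$values, ea$values, as.integer(ra$dims), ra$spacing,
                         dose_crit / 100 * dmax, dist_crit,
                         threshold / 100 * dmax, sample_step, search_factor)
  structure(list(gamma = array(res$gamma, ra$dims),
                 pass_rate = res$pass_rate, gamma_mean = res$gamma_mean,
                 n_included = res$n_included,
                 criteria = c(dose_crit = dose_crit, dist_crit = dist_crit),
                 threshold = threshold),
            class = "gamma_result")
}

.as_eval_array <- function(x, spacing) {
  if (inherits(x, "dose_grid")) {
    list(values = as.vector(x$values) / x$n_histories,
         dims = dim(x$values), spacing = x$spacing)
  } else if (is.matrix(x)) {
    list(values = as.vector(x), dims = c(dim(x), 1L),
         spacing = c(rep(spacing %||% 1, length.out = 2), 1))
  } else {
    d <- dim(x) %||% c(length(x), 1L, 1L)
    d <- c(d, rep(1L, 3 - length(d)))
    list(values = as.vector(x), dims = d,
         spacing = rep(spacing %||% 1, length.out = 3))
  }
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma-index %g%%/%g mm (global), %g%% Dmax threshold\n",
              x$criteria["dose_crit"], x$criteria["dist_crit"], x$threshold))
  cat(sprintf("  included voxels: %d, pass rate (gamma < 1): %.2f%%, mean gamma: %.4f\n",
              as.integer(x$n_included), x$pass_rate, x$gamma_mean))
  invisible(x)
}

#' Brute-force gamma index (reference oracle)
#'
#' Exhaustive-search implementation of the same gamma definition as
#' [gamma_index()] (identical sample lattice and trilinear interpolation,
#' no early exit), kept as the correctness anchor for the fast kernel.
#' Intended for small grids.
#'
#' @inheritParams gamma_index
#' @return a `gamma_result`.
#' @export
gamma_index_brute <- function(ref, eval, dose_crit = 2, dist_crit = 2,
                              threshold = 0.1, spacing = NULL,
                              sample_step = 0.2, search_factor = 3) {
  ra <- .as_eval_array(ref, spacing)
  ea <- .as_eval_array(eval, spacing)
  stopifnot(all(ra$dims == ea$dims))
  d <- ra$dims; sp <- ra$spacing
  refv <- array(ra$values, d); evv <- array(ea$values, d)
  dmax <- max(refv)
  tol <- dose_crit / 100 * dmax
  thr <- threshold / 100 * dmax
  R <- search_factor * dist_crit
  ks <- lapply(1:3, function(a) {
    if (d[a] > 1) seq(-floor(R / sample_step), floor(R / sample_step)) * sample_step
    else 0
  })
  offs <- expand.grid(ox = ks[[1]], oy = ks[[2]], oz = ks[[3]])
  offs$d2 <- offs$ox^2 + offs$oy^2 + offs$oz^2
  offs <- offs[offs$d2 <= R^2, ]

  inc <- which(refv >= thr)
  ijk <- arrayInd(inc, d)
  best <- ((refv[inc] - evv[inc]) / tol)^2
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (o$d2 == 0) next
    fx <- ijk[, 1] - 1 + o$ox / sp[1]
    fy <- ijk[, 2] - 1 + o$oy / sp[2]
    fz <- ijk[, 3] - 1 + o$oz / sp[3]
    okp <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
           fz >= 0 & fz <= d[3] - 1
    if (!any(okp)) next
    De <- .trilinear(evv, fx[okp], fy[okp], fz[okp])
    cand <- o$d2 / dist_crit^2 + ((refv[inc][okp] - De) / tol)^2
    best[okp] <- pmin(best[okp], cand)
  }
  g <- array(NA_real_, d)
  g[inc] <- sqrt(best)
  structure(list(gamma = g,
                 pass_rate = 100 * mean(sqrt(best) < 1),
                 gamma_mean = mean(sqrt(best)),
                 n_included = length(inc),
                 criteria = c(dose_crit = dose_crit, dist_crit = dist_crit),
                 threshold = threshold),
            class = "gamma_result")
}

# vectorized trilinear interpolation at fractional 0-based indices
.trilinear <- function(arr, fx, fy, fz) {
  d <- dim(arr)
  i0 <- pmin(floor(fx), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz), d[3] - 2); k0 <- pmax(k0, 0)
  if (d[1] == 1) i0 <- rep(0, length(fx))
  if (d[2] == 1) j0 <- rep(0, length(fy))
  if (d[3] == 1) k0 <- rep(0, length(fz))
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  i1 <- if (d[1] > 1) i0 + 1 else i0
  j1 <- if (d[2] > 1) j0 + 1 else j0
  k1 <- if (d[3] > 1) k0 + 1 else k0
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  c00 <- at(i0, j0, k0) * (1 - tx) + at(i1, j0, k0) * tx
  c10 <- at(i0, j1, k0) * (1 - tx) + at(i1, j1, k0) * tx
  c01 <- at(i0, j0, k1) * (1 - tx) + at(i1, j0, k1) * tx
  c11 <- at(i0, j1, k1) * (1 - tx) + at(i1, j1, k1) * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}
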