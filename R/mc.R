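#' Beam specification
#'
#' A parallel monoenergetic scanned proton pencil beam entering the phantom
#' along +z at `position` in the entrance plane, with a Gaussian spot of
#' entrance sigmas `sigma_x`, `sigma_y` (default 3 mm, a typical scanned
#' spot size).
#'
#' @param E0 kinetic energy (MeV), in \[40, 250].
#' @param sigma_x,sigma_y entrance spot sigmas (mm), positive.
#' @param position c(x, y) entry position in the entrance plane (mm).
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(E0, sigma_x = 3, sigma_y = 3, position = c(0, 0)) {
  stopifnot(E0 >= 40, E0 <= 250, sigma_x > 0, sigma_y > 0,
            length(position) == 2L)
  structure(list(E0 = E0, sigma_x = sigma_x, sigma_y = sigma_y,
                 position = as.numeric(position)),
            class = "beam_spec")
}

#' Monte Carlo transport configuration
#'
#' @param n_histories number of primary protons (>= 1).
#' @param step nominal step length (mm); refined automatically near the
#'   range end.
#' @param seed integer RNG seed; identical configurations reproduce
#'   bit-identical dose grids.
#' @param straggling,nuclear,mcs independently toggleable physics:
#'   Bohr Gaussian energy-loss straggling, first-order nuclear removal
#'   with secondary-proton halo emission, Highland multiple Coulomb
#'   scattering.
#' @param nuclear_local_frac fraction of a nuclear-removed primary's
#'   residual energy carried off (and mostly re-deposited in the phantom)
#'   by the representative secondary proton; the remainder is treated as
#'   escaping with neutral secondaries.
#' @param e_nuc_min energy floor (MeV) below which nuclear removal is off.
#' @param n_batches if > 0, score in this many batches to enable
#'   [score_statistics()] (>= 10 recommended).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(n_histories = 2e5, step = 1, seed = 1,
                      straggling = TRUE, nuclear = TRUE, mcs = TRUE,
                      nuclear_local_frac = 0.6, e_nuc_min = 20,
                      n_batches = 0) {
  stopifnot(n_histories >= 1, step > 0)
  structure(list(n_histories = as.integer(n_histories), step = step,
                 seed = as.integer(seed), straggling = straggling,
                 nuclear = nuclear, mcs = mcs,
                 nuclear_local_frac = nuclear_local_frac,
                 e_nuc_min = e_nuc_min, n_batches = as.integer(n_batches)),
            class = "mc_config")
}

#' Condensed-history Monte Carlo proton transport
#'
#' Transports `cfg$n_histories` protons through the phantom under a uniform
#' transverse magnetic field and scores deposited energy per voxel. Per
#' history, the entrance position is Gaussian-sampled from the beam spot;
#' per step, the mean Bethe-Bloch loss (with optional Bohr straggling) is
#' deposited at the step midpoint, the magnetic deflection is applied as an
#' exact arc of the local gyroradius, and Highland multiple-scattering
#' kicks are applied in both transverse planes. Nuclear interactions absorb
#' the primary with an energy-independent removal length; part of the
#' removed energy is carried off by a representative forward-peaked
#' secondary proton that is transported in straight (field-bent) line and
#' builds the low-dose lateral halo. Transport below 0.5 MeV deposits the
#' residual locally.
#'
#' @param beam a [beam_spec()].
#' @param phantom a `phantom_grid`.
#' @param B magnetic field (tesla, scalar along +x, or transverse 3-vector).
#' @param cfg an [mc_config()].
#' @return a [dose_grid()] with energy-accounting totals in `$totals`
#'   (`E_in`, `E_scored`, `E_escaped`, `E_nuclear_lost`) and, when
#'   `cfg$n_batches > 0`, batch sums-of-squares for uncertainty estimation.
#' @examples
#' \donttest{
#' ph <- build_homogeneous("water", extent = list(x = c(-20, 20),
#'   y = c(-20, 20), z = c(0, 80)))
#' dg <- simulate_beam(beam_spec(60), ph, B = 0, mc_config(2000, seed = 7))
#' }
#' @export
simulate_beam <- function(beam, phantom, B, cfg = mc_config()) {
  stopifnot(inherits(beam, "beam_spec"), inherits(phantom, "phantom_grid"),
            inherits(cfg, "mc_config"))
  Bx <- .check_field(B)
  d <- dim(phantom$labels)
  xr <- range(voxel_centers(phantom, 1)); yr <- range(voxel_centers(phantom, 2))
  if (beam$position[1] < xr[1] || beam$position[1] > xr[2] ||
      beam$position[2] < yr[1] || beam$position[2] > yr[2]) {
    warning("beam misses the phantom entrance face; returning zero grid")
    return(dose_grid(array(0, d), phantom, n_histories = cfg$n_histories))
  }
  props <- as.matrix(phantom$materials[, c("rho", "I", "ZA", "X0", "lambda_nuc")])
  res <- mc_simulate_cpp(
    beam$E0, beam$sigma_x, beam$sigma_y,
    beam$position[1], beam$position[2],
    as.integer(phantom$labels), as.integer(d),
    phantom$spacing, phantom$origin, props,
    Bx, cfg$n_histories, cfg$step, as.numeric(cfg$seed),
    cfg$straggling, cfg$nuclear, cfg$mcs,
    cfg$nuclear_local_frac, .const$E_CUT, cfg$e_nuc_min, cfg$n_batches)
  totals <- res[c("E_in", "E_scored", "E_escaped", "E_nuclear_lost")]
  g <- dose_grid(array(res$values, d), phantom,
                 n_histories = cfg$n_histories, totals = totals,
                 meta = list(beam = beam, B = Bx, cfg = cfg))
  if (cfg$n_batches > 0) {
    g$batch_sumsq <- array(res$batch_sumsq, d)
    g$n_batches <- res$n_batches
  }
  g
}

#' Batch-based statistical uncertainty of a Monte Carlo dose grid
#'
#' Relative standard error of the mean per voxel, estimated from batch
#' variance; reported only for voxels above a dose threshold (default 1% of
#' the maximum), NA elsewhere.
#'
#' @param grid a `dose_grid` simulated with `n_batches >= 10`.
#' @param threshold_frac report voxels with energy above this fraction of
#'   the maximum.
#' @return 3-D array of relative standard errors (fraction, not %).
#' @export
score_statistics <- function(grid, threshold_frac = 0.01) {
  if (is.null(grid$batch_sumsq)) {
    stop("grid was not scored in batches; set mc_config(n_batches >= 10)",
         call. = FALSE)
  }
  nb <- grid$n_batches
  if (nb < 10) stop("need at least 10 batches", call. = FALSE)
  mean_b <- grid$values / nb
  var_b <- pmax(grid$batch_sumsq / nb - mean_b^2, 0) * nb / (nb - 1)
  se <- sqrt(var_b / nb) * nb            # SE of the batch-sum total
  rel <- se / grid$values
  rel[grid$values < threshold_frac * max(grid$values)] <- NA_real_
  rel
}
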