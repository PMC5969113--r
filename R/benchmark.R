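#' Run the full calibrate-then-benchmark evaluation battery
#'
#' Reproduces the self-consistent evaluation design of the engine: look-up
#' tables are calibrated from the in-package Monte Carlo engine in water,
#' the pencil-beam algorithm computes dose with those tables, and the
#' result is benchmarked against independent Monte Carlo runs (fresh seeds)
#' of the same engine. Scenarios:
#' \describe{
#'   \item{water}{homogeneous water, 80/150/240 MeV: proximal mean local
#'     IDD difference, R80 shift, gamma-index on the bending-plane
#'     projected energy maps, lateral profile metrics at 20/50/80% of
#'     range for 240 MeV}
#'   \item{adipose, bone}{homogeneous, 240 MeV: profile metrics}
#'   \item{slab}{entrance slab sandwich, 150/240 MeV, k = 9 subbeams with
#'     center shifting: gamma, R80 relative error, profile metrics}
#'   \item{lateral}{opposing bone/air slabs, 150/240 MeV, k = 9 + shifting:
#'     gamma, R80 relative error, mean IDD dose difference, profile
#'     metrics at 30 mm / 50% / 80% of range}
#' }
#'
#' @param seed master seed; all calibration and benchmark run seeds derive
#'   from it deterministically.
#' @param n_histories Monte Carlo histories per run.
#' @param fields field strengths (tesla).
#' @param k_het subbeam count for the heterogeneous phantoms.
#' @param scenarios subset of scenarios to run.
#' @param verbose print progress lines.
#' @return list with `configs` (one data.frame row per evaluated
#'   configuration and its metrics) and `summary` (the worst-case
#'   aggregates over configuration groups; see Details in the package
#'   vignette).
#' @export
benchmark_battery <- function(seed = 1, n_histories = 2e5,
                              fields = c(0.5, 1.5, 3), k_het = 9,
                              scenarios = c("water", "adipose", "bone",
                                            "slab", "lateral"),
                              verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cfg0 <- mc_config(n_histories, seed = seed)
  water <- build_homogeneous("water")

  say("calibrating LUTs (%d energies x %d fields, %g histories each)",
      3L, length(fields), n_histories)
  lut <- build_luts(c(80, 150, 240), fields, cfg0)

  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  bench_cfg <- function(E0, B, salt) {
    cfg <- cfg0
    cfg$seed <- .derive_seed(seed, B, E0, salt = salt)
    cfg
  }

  homo_phantoms <- list(water = water)
  if ("adipose" %in% scenarios) homo_phantoms$adipose <- build_homogeneous("adipose")
  if ("bone" %in% scenarios) homo_phantoms$bone <- build_homogeneous("bone")

  for (mat in intersect(c("water", "adipose", "bone"), scenarios)) {
    ph <- homo_phantoms[[mat]]
    energies <- if (mat == "water") c(80, 150, 240) else 240
    for (E0 in energies) for (B in fields) {
      say("homogeneous %s, %g MeV, %g T", mat, E0, B)
      mc <- simulate_beam(beam_spec(E0), ph, B, bench_cfg(E0, B, salt = 2L))
      yz_mc <- project_grid(mc, "yz")
      rm(mc); gc(FALSE)
      out <- compute_dose(beam_spec(E0), ph, B, lut, k = 1,
                          output = c("yz", "idd"))
      m <- .compare_maps(yz_mc, out$yz, out$idd,
                         profile_energy = E0 == 240 || mat == "water",
                         depths = NULL)
      add_row(scenario = mat, E0 = E0, B = B, k = 1,
              dmean_prox = m$dmean_prox, dmean = m$dmean,
              r80_mc = m$r80_mc, r80_pba = m$r80_pba,
              gamma_pass = m$gamma_pass, gamma_mean = m$gamma_mean,
              max_dcenter = m$max_dcenter, max_dfwhm = m$max_dfwhm)
    }
  }

  het <- list()
  if ("slab" %in% scenarios) het$slab <- build_slab_sandwich()
  if ("lateral" %in% scenarios) het$lateral <- build_lateral_opposing()
  for (sc in names(het)) {
    ph <- het[[sc]]
    for (E0 in c(150, 240)) for (B in fields) {
      say("%s phantom, %g MeV, %g T (k = %d)", sc, E0, B, k_het)
      mc <- simulate_beam(beam_spec(E0), ph, B, bench_cfg(E0, B, salt = 3L))
      yz_mc <- project_grid(mc, "yz")
      rm(mc); gc(FALSE)
      out <- compute_dose(beam_spec(E0), ph, B, lut, k = k_het, shift = TRUE,
                          output = c("yz", "idd"))
      depths <- if (sc == "lateral") {
        r <- r80(idd(yz_mc)); c(30, 0.5 * r, 0.8 * r)
      } else NULL
      m <- .compare_maps(yz_mc, out$yz, out$idd, profile_energy = TRUE,
                         depths = depths)
      add_row(scenario = sc, E0 = E0, B = B, k = k_het,
              dmean_prox = m$dmean_prox, dmean = m$dmean,
              r80_mc = m$r80_mc, r80_pba = m$r80_pba,
              gamma_pass = m$gamma_pass, gamma_mean = m$gamma_mean,
              max_dcenter = m$max_dcenter, max_dfwhm = m$max_dfwhm)
    }
  }

  configs <- do.call(rbind, rows)
  configs$r80_relerr <- 100 * abs(configs$r80_pba - configs$r80_mc) /
    configs$r80_mc
  list(configs = configs, summary = .battery_summary(configs), lut = lut,
       seed = seed, n_histories = n_histories, fields = fields)
}

# metrics for one configuration: MC reference map vs PBA map + IDD
.compare_maps <- function(yz_mc, yz_pba, idd_pba, profile_energy, depths) {
  idd_mc <- idd(yz_mc)
  r80_mc <- r80(idd_mc)
  r80_pba <- r80(idd_pba)
  dmean_prox <- mean_dose_difference(idd_mc, idd_pba,
                                     region = idd_proximal_region(idd_mc))
  dmean <- mean_dose_difference(idd_mc, idd_pba)
  g <- gamma_index(yz_mc, yz_pba)
  max_dc <- NA_real_; max_dw <- NA_real_
  if (profile_energy) {
    if (is.null(depths)) depths <- c(0.2, 0.5, 0.8) * r80_mc
    pm_mc <- profile_metrics(yz_mc, depths)
    pm_pb <- profile_metrics(yz_pba, depths)
    max_dc <- max(abs(pm_pb$center - pm_mc$center))
    max_dw <- max(abs(pm_pb$fwhm - pm_mc$fwhm))
  }
  list(dmean_prox = dmean_prox, dmean = dmean, r80_mc = r80_mc,
       r80_pba = r80_pba, gamma_pass = g$pass_rate, gamma_mean = g$gamma_mean,
       max_dcenter = max_dc, max_dfwhm = max_dw)
}

.battery_summary <- function(cf) {
  water <- cf[cf$scenario == "water", ]
  homo240 <- cf[cf$scenario %in% c("water", "adipose", "bone") & cf$E0 == 240, ]
  slab <- cf[cf$scenario == "slab", ]
  lat <- cf[cf$scenario == "lateral", ]
  het <- rbind(slab, lat)
  s <- list()
  if (nrow(water)) {
    s$water_idd_dmean_prox_worst <- max(abs(water$dmean_prox))
    s$water_r80_shift_worst <- max(abs(water$r80_pba - water$r80_mc))
    s$water_gamma_pass_worst <- min(water$gamma_pass)
    s$water_gamma_mean_worst <- max(water$gamma_mean)
  }
  if (nrow(homo240)) {
    s$homog_deflection_dev_worst <- max(homo240$max_dcenter, na.rm = TRUE)
  }
  if (nrow(het)) {
    s$het_gamma_pass_worst <- min(het$gamma_pass)
    s$het_gamma_mean_worst <- max(het$gamma_mean)
  }
  if (nrow(slab)) {
    s$slab_r80_relerr_worst <- max(slab$r80_relerr)
    s$slab_profile_dev_worst <- max(slab$max_dcenter, slab$max_dfwhm,
                                    na.rm = TRUE)
  }
  if (nrow(lat)) {
    s$lateral_r80_relerr_worst <- max(lat$r80_relerr)
    s$lateral_dmean_150_worst <- max(abs(lat$dmean[lat$E0 == 150]))
    s$lateral_profile_dev_worst <- max(lat$max_dcenter, lat$max_dfwhm,
                                       na.rm = TRUE)
  }
  s
}
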