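#' Build calibration look-up tables from the Monte Carlo engine
#'
#' Runs the Monte Carlo engine for every (energy, field) combination on a
#' homogeneous water phantom and extracts, per 1-mm depth bin: the
#' integrated depth-dose E_dep(z) (MeV per mm per proton) and the fitted
#' seven-parameter lateral profile coefficients for the x plane (parallel
#' to the field; from the XZ-projected map) and the y plane (perpendicular;
#' from the YZ-projected map). Profiles are fitted at every depth where the
#' depth-dose exceeds 1e-3 of its maximum, warm-starting each fit from the
#' previous depth.
#'
#' @param energies beam energies to calibrate (MeV); the classic layout is
#'   40-250 in 10-MeV steps, but any subset (down to a single energy) is
#'   valid -- cubic-spline energy interpolation is exact at grid nodes.
#' @param fields magnetic field strengths (tesla, along +x).
#' @param cfg an [mc_config()]; per-run seeds are derived deterministically
#'   from `cfg$seed`.
#' @param phantom water phantom grid (defaults to the standard ROI).
#' @param sigma entrance spot sigma used for calibration (mm).
#' @param max_failed_frac calibration fails if more than this fraction of
#'   depth fits does not converge.
#' @return object of class `proton_lut` bundling the depth-dose and lateral
#'   tables: `$z` (depth grid), `$tables[[field]][[energy]]` with `e_dep`,
#'   `params_x`, `params_y` (7-column matrices), `fit_diag`.
#' @export
build_luts <- function(energies, fields, cfg = mc_config(),
                       phantom = build_homogeneous("water"),
                       sigma = 3, max_failed_frac = 0.02) {
  stopifnot(all(energies >= 40), all(energies <= 250))
  energies <- sort(unique(energies))
  fields <- sort(unique(fields))
  zc <- voxel_centers(phantom, 3)
  tables <- list()
  for (B in fields) {
    per_e <- list()
    for (E0 in energies) {
      run_seed <- .derive_seed(cfg$seed, B, E0, salt = 1L)
      run_cfg <- cfg; run_cfg$seed <- run_seed
      dg <- simulate_beam(beam_spec(E0, sigma, sigma), phantom, B, run_cfg)
      per_e[[as.character(E0)]] <- .extract_lut_entry(dg, zc, max_failed_frac)
      rm(dg); gc(FALSE)
    }
    tables[[format(B)]] <- per_e
  }
  structure(list(energies = energies, fields = fields, z = zc,
                 sigma = sigma, tables = tables,
                 meta = list(cfg = cfg, spacing = phantom$spacing)),
            class = "proton_lut")
}

# deterministic per-run seed derivation, kept below 2^31
.derive_seed <- function(base, B, E0, salt = 0L) {
  as.integer((as.double(base) * 2654435.0 + B * 1e4 + E0 * 131 + salt * 7919) %%
               2147483629)
}

.extract_lut_entry <- function(dg, zc, max_failed_frac) {
  yz <- project_grid(dg, "yz")
  xz <- project_grid(dg, "xz")
  e_dep <- colSums(yz)                       # MeV per mm slab per proton
  fit_sel <- which(e_dep > 1e-3 * max(e_dep))
  n7 <- c("A", "f_L", "f_R", "x_m", "sigma", "gamma_L", "gamma_R")
  px <- matrix(NA_real_, length(zc), 7, dimnames = list(NULL, n7))
  py <- px
  n_failed <- 0L; rms_x <- rms_y <- rep(NA_real_, length(zc))
  warm_x <- warm_y <- NULL
  xs <- attr(xz, "lat"); ys <- attr(yz, "lat")
  for (i in fit_sel) {
    fx <- .quiet_fit(xs, xz[, i], warm_x)
    fy <- .quiet_fit(ys, yz[, i], warm_y)
    px[i, ] <- unclass(fx$params)[n7]
    py[i, ] <- unclass(fy$params)[n7]
    rms_x[i] <- fx$rms_residual; rms_y[i] <- fy$rms_residual
    if (!fx$converged) n_failed <- n_failed + 1L
    if (!fy$converged) n_failed <- n_failed + 1L
    if (fx$converged && !fx$fallback_gaussian) warm_x <- unclass(fx$params)[n7]
    if (fy$converged && !fy$fallback_gaussian) warm_y <- unclass(fy$params)[n7]
  }
  frac <- n_failed / max(1L, 2L * length(fit_sel))
  if (frac > max_failed_frac) {
    stop(sprintf("calibration error: %.1f%% of lateral fits failed", 100 * frac),
         call. = FALSE)
  }
  # constant-extend parameters outside the fitted depth range
  for (j in 1:7) {
    px[, j] <- .fill_nearest(px[, j])
    py[, j] <- .fill_nearest(py[, j])
  }
  list(e_dep = e_dep, params_x = px, params_y = py,
       fit_diag = list(n_failed = n_failed, n_fits = 2L * length(fit_sel),
                       rms_x = rms_x, rms_y = rms_y, fit_range = range(fit_sel)))
}

.quiet_fit <- function(x, y, warm) {
  withCallingHandlers(
    fit_lateral(x, y, start = warm),
    warning = function(w) invokeRestart("muffleWarning"))
}

.fill_nearest <- function(v) {
  ok <- which(!is.na(v))
  if (!length(ok)) return(v)
  v[seq_len(ok[1] - 1)] <- v[ok[1]]
  n <- length(v)
  if (ok[length(ok)] < n) v[(ok[length(ok)] + 1):n] <- v[ok[length(ok)]]
  # interior gaps (non-converged depths): linear interpolation
  na <- which(is.na(v))
  if (length(na)) v[na] <- approx(ok, v[ok], xout = na, rule = 2)$y
  v
}

#' Interpolate the look-up tables at an arbitrary energy and depth
#'
#' Energy interpolation is a natural cubic spline across the calibrated
#' energy grid, applied independently to the depth-dose and to each lateral
#' parameter at fixed depth (exact at grid energies); depth lookup is
#' linear on the calibration depth grid. Field strengths are never
#' interpolated: `B` must be one of the calibrated values (magnetic
#' deflection is strongly nonlinear in B). Spline overshoot of the lateral
#' parameters is clipped back to the model's validity bounds.
#'
#' @param lut a `proton_lut`.
#' @param E0 energy (MeV) within the calibrated energy range.
#' @param B field (tesla); must match a calibrated value.
#' @param z_eq water-equivalent depths (mm, vectorized).
#' @return list with `e_dep` (MeV/mm per proton; 0 beyond the table) and
#'   `params_x`, `params_y` (length(z_eq) x 7 matrices).
#' @export
lut_interpolate <- function(lut, E0, B, z_eq) {
  stopifnot(inherits(lut, "proton_lut"))
  fi <- which(abs(lut$fields - B) < 1e-9)
  if (!length(fi)) {
    stop("field B = ", B, " T is not calibrated (available: ",
         paste(lut$fields, collapse = ", "), "); no field interpolation",
         call. = FALSE)
  }
  if (E0 < min(lut$energies) - 1e-9 || E0 > max(lut$energies) + 1e-9) {
    stop("E0 outside the calibrated energy grid", call. = FALSE)
  }
  per_e <- lut$tables[[format(lut$fields[fi])]]
  wts <- .spline_weights(lut$energies, E0)
  n7 <- c("A", "f_L", "f_R", "x_m", "sigma", "gamma_L", "gamma_R")
  e_dep <- 0
  px <- matrix(0, length(z_eq), 7, dimnames = list(NULL, n7))
  py <- px
  for (j in seq_along(lut$energies)) {
    if (wts[j] == 0) next
    ent <- per_e[[as.character(lut$energies[j])]]
    e_dep <- e_dep + wts[j] *
      approx(lut$z, ent$e_dep, xout = z_eq, yleft = 0, yright = 0)$y
    for (cjj in 1:7) {
      px[, cjj] <- px[, cjj] + wts[j] *
        approx(lut$z, ent$params_x[, cjj], xout = z_eq, rule = 2)$y
      py[, cjj] <- py[, cjj] + wts[j] *
        approx(lut$z, ent$params_y[, cjj], xout = z_eq, rule = 2)$y
    }
  }
  e_dep[e_dep < 0] <- 0
  list(e_dep = e_dep, params_x = .clip_params(px), params_y = .clip_params(py))
}

# natural-cubic-spline interpolation weights: the interpolant is linear in
# the tabulated values, so interpolate each unit basis vector once
.spline_weights <- function(xs, x0) {
  n <- length(xs)
  if (n == 1L) {
    if (abs(x0 - xs) > 1e-9) stop("single-energy table: E0 must match")
    return(1)
  }
  i <- which(abs(xs - x0) < 1e-9)
  if (length(i)) { w <- numeric(n); w[i] <- 1; return(w) }
  if (n < 4L) {  # too few nodes for a cubic: linear weights
    k <- findInterval(x0, xs, all.inside = TRUE)
    w <- numeric(n)
    t <- (x0 - xs[k]) / (xs[k + 1] - xs[k])
    w[k] <- 1 - t; w[k + 1] <- t
    return(w)
  }
  vapply(seq_len(n), function(j) {
    b <- numeric(n); b[j] <- 1
    splinefun(xs, b, method = "natural")(x0)
  }, numeric(1))
}

.clip_params <- function(p) {
  p[, "sigma"] <- pmax(p[, "sigma"], 0.2)
  p[, "gamma_L"] <- pmin(pmax(p[, "gamma_L"], 1.5), 30)
  p[, "gamma_R"] <- pmin(pmax(p[, "gamma_R"], 1.5), 30)
  p[, "f_L"] <- pmin(pmax(p[, "f_L"], 0), 0.45)
  p[, "f_R"] <- pmin(pmax(p[, "f_R"], 0), 0.45)
  s <- p[, "f_L"] + p[, "f_R"]
  over <- s >= 0.9
  if (any(over)) {
    p[over, "f_L"] <- p[over, "f_L"] * 0.9 / s[over]
    p[over, "f_R"] <- p[over, "f_R"] * 0.9 / s[over]
  }
  p[, "A"] <- pmax(p[, "A"], 1e-12)
  p
}

#' @export
print.proton_lut <- function(x, ...) {
  cat(sprintf("proton_lut: %d energies (%g-%g MeV) x %d fields (%s T), %d depth bins\n",
              length(x$energies), min(x$energies), max(x$energies),
              length(x$fields), paste(x$fields, collapse = "/"), length(x$z)))
  invisible(x)
}

#' Save / load look-up tables
#'
#' `write_lut`/`read_lut` support two formats: `"rds"` (exact binary round
#' trip) and `"tsv"` (plain-text columnar export at full double precision,
#' one row per depth bin per energy per field, also an exact round trip;
#' intended for inspection and interchange).
#'
#' @param lut a `proton_lut`.
#' @param path file path; format inferred from the extension unless given.
#' @param format `"rds"` or `"tsv"`.
#' @export
write_lut <- function(lut, path, format = c("auto", "rds", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "rds"
  }
  if (format == "rds") {
    saveRDS(lut, path)
    return(invisible(path))
  }
  rows <- list()
  for (B in lut$fields) for (E0 in lut$energies) {
    ent <- lut$tables[[format(B)]][[as.character(E0)]]
    df <- data.frame(field = B, energy = E0, z = lut$z, e_dep = ent$e_dep)
    colnames(ent$params_x) <- paste0("x_", colnames(ent$params_x))
    colnames(ent$params_y) <- paste0("y_", colnames(ent$params_y))
    rows[[length(rows) + 1L]] <- cbind(df, ent$params_x, ent$params_y)
  }
  all <- do.call(rbind, rows)
  num <- vapply(all, is.numeric, logical(1))
  all[num] <- lapply(all[num], function(v) format(v, digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# proton_lut sigma=%s", format(lut$sigma, digits = 17)), con)
  write.table(all, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path, format = c("auto", "rds", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "rds"
  }
  if (format == "rds") return(readRDS(path))
  hdr <- readLines(path, n = 1)
  sigma <- as.numeric(sub(".*sigma=", "", hdr))
  d <- read.table(path, header = TRUE, sep = "\t", skip = 1)
  energies <- sort(unique(d$energy)); fields <- sort(unique(d$field))
  z <- sort(unique(d$z))
  n7 <- c("A", "f_L", "f_R", "x_m", "sigma", "gamma_L", "gamma_R")
  tables <- list()
  for (B in fields) {
    per_e <- list()
    for (E0 in energies) {
      s <- d[d$field == B & d$energy == E0, ]
      s <- s[order(s$z), ]
      px <- as.matrix(s[, paste0("x_", n7)]); colnames(px) <- n7
      py <- as.matrix(s[, paste0("y_", n7)]); colnames(py) <- n7
      per_e[[as.character(E0)]] <- list(e_dep = s$e_dep, params_x = px,
                                        params_y = py, fit_diag = NULL)
    }
    tables[[format(B)]] <- per_e
  }
  structure(list(energies = energies, fields = fields, z = z, sigma = sigma,
                 tables = tables, meta = list()),
            class = "proton_lut")
}
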