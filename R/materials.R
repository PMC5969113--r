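#' Material registry for proton transport
#'
#' Built-in tissue materials used by the trajectory integrator, the Monte
#' Carlo engine and the water-equivalent depth scaling. The built-in set is
#' the NIST/PSTAR material family identified by its mean ionization
#' potentials -- liquid water (75 eV), adipose tissue ICRP (63.2 eV,
#' 0.92 g/cm^3), compact bone ICRU (91.9 eV, 1.85 g/cm^3) and dry air
#' (85.7 eV) -- with the matching effective Z/A and standard radiation
#' lengths.
#'
#' Fields per material:
#' \describe{
#'   \item{rho}{mass density, g/cm^3}
#'   \item{I}{mean ionization potential, eV}
#'   \item{ZA}{effective Z/A (dimensionless)}
#'   \item{X0}{radiation length, g/cm^2 (multiple Coulomb scattering)}
#'   \item{lambda_nuc}{nuclear removal length, g/cm^2 (energy independent,
#'     first order); the geometric mean free path in cm is
#'     \code{lambda_nuc / rho}}
#' }
#'
#' @return `material_registry()` returns a data.frame of all registered
#'   materials; `material(name)` returns a single-material list with the
#'   fields above plus `nuclear_mfp` (cm).
#' @examples
#' material("water")$I   # 75 eV
#' material_registry()
#' @export
material_registry <- function() {
  get("registry", envir = .materials_env)
}

.materials_env <- new.env(parent = emptyenv())

# NIST/PSTAR material set: water (liquid), adipose tissue (ICRP),
# compact bone (ICRU), dry air -- the tissues whose mean ionization
# potentials are 75 / 63.2 / 91.9 / 85.7 eV.
.default_materials <- data.frame(
  name       = c("water", "adipose", "bone", "air"),
  rho        = c(1.0, 0.92, 1.85, 1.205e-3),
  I          = c(75, 63.2, 91.9, 85.7),
  ZA         = c(0.5551, 0.5594, 0.5301, 0.4992),
  X0         = c(36.08, 40.0, 16.59, 36.62),
  lambda_nuc = c(120, 120, 120, 120),
  stringsAsFactors = FALSE
)
assign("registry", .default_materials, envir = .materials_env)

#' @rdname material_registry
#' @param name material name (character scalar).
#' @export
material <- function(name) {
  reg <- material_registry()
  i <- match(name, reg$name)
  if (is.na(i)) {
    stop("unknown material '", name, "'; registered: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  }
  m <- as.list(reg[i, ])
  m$nuclear_mfp <- m$lambda_nuc / m$rho
  m
}

#' Register a custom material
#'
#' @param name label; must not clash with a built-in name unless
#'   `overwrite = TRUE`.
#' @param rho mass density (g/cm^3), positive.
#' @param I mean ionization potential (eV), positive.
#' @param ZA effective Z/A, in (0, 1).
#' @param X0 radiation length (g/cm^2), positive.
#' @param lambda_nuc nuclear removal length (g/cm^2), positive.
#' @param overwrite replace an existing entry.
#' @return the registered material, invisibly.
#' @export
register_material <- function(name, rho, I, ZA, X0, lambda_nuc = 120,
                              overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            rho > 0, I > 0, ZA > 0, ZA < 1, X0 > 0, lambda_nuc > 0)
  reg <- material_registry()
  if (name %in% reg$name) {
    if (!overwrite) stop("material '", name, "' already registered", call. = FALSE)
    reg <- reg[reg$name != name, ]
  }
  reg <- rbind(reg, data.frame(name = name, rho = rho, I = I, ZA = ZA,
                               X0 = X0, lambda_nuc = lambda_nuc,
                               stringsAsFactors = FALSE))
  assign("registry", reg, envir = .materials_env)
  invisible(material(name))
}

#' Electronic mass stopping power (Bethe-Bloch)
#'
#' Relativistic Bethe-Bloch electronic stopping power for protons, without
#' shell or density-effect corrections (adequate above ~10 MeV; the pencil
#' beam engine and the Monte Carlo engine share this identical formula, so
#' depth scalings between them are self-consistent).
#'
#' @param E proton kinetic energy (MeV); vectorized. Valid for
#'   0.5 <= E <= 300; energies below 0.5 MeV signal the range-end condition
#'   as an error (callers deposit the residual locally instead).
#' @param mat a material list from [material()].
#' @return mass stopping power, MeV cm^2/g.
#' @examples
#' stopping_power(100, material("water"))  # ~7.29 MeV cm^2/g
#' @export
stopping_power <- function(E, mat) {
  if (any(E < .const$E_CUT)) {
    stop("stopping_power: E below the 0.5 MeV validity floor (range end)",
         call. = FALSE)
  }
  if (any(E > 300)) stop("stopping_power: E above 300 MeV validity ceiling",
                         call. = FALSE)
  .bethe_bloch(E, mat$I, mat$ZA)
}

# core formula, also used by integrators after their own E checks
.bethe_bloch <- function(E, I_eV, ZA) {
  mp <- .const$mp; me <- .const$me
  gamma <- 1 + E / mp
  b2g2 <- (E^2 + 2 * E * mp) / mp^2          # beta^2 gamma^2
  beta2 <- b2g2 / gamma^2
  r <- me / mp
  Tmax <- 2 * me * b2g2 / (1 + 2 * gamma * r + r^2)
  I <- I_eV * 1e-6                           # eV -> MeV
  .const$K * ZA / beta2 * (0.5 * log(2 * me * b2g2 * Tmax / I^2) - beta2)
}

#' Residual proton energy after a given depth (CSDA)
#'
#' Iterative continuous-slowing-down integration: the energy deposited in
#' each step (Bethe-Bloch at the step-midpoint energy) is subtracted from
#' the running kinetic energy. Saturates at 0 at range exhaustion; the
#' residual below the 0.5 MeV floor is treated as locally deposited.
#'
#' @param E0 initial kinetic energy (MeV).
#' @param depth depth(s) along a straight path (mm); vectorized.
#' @param mat material list from [material()].
#' @param step integration step (mm), default 1.
#' @return residual kinetic energy (MeV) at each depth.
#' @export
residual_energy <- function(E0, depth, mat, step = 1) {
  stopifnot(E0 > 0, all(depth >= 0), step > 0)
  dmax <- max(depth)
  n <- ceiling(dmax / step) + 1L
  z <- numeric(n + 1L); Ez <- numeric(n + 1L)
  E <- E0; Ez[1L] <- E0
  lin <- mat$rho / 10                        # g/cm^3 * mm -> g/cm^2
  for (i in seq_len(n)) {
    if (E <= .const$E_CUT) { Ez[i + 1L] <- 0; z[i + 1L] <- z[i] + step; E <- 0; next }
    dE <- .bethe_bloch(E, mat$I, mat$ZA) * lin * step
    Em <- E - dE / 2
    if (Em > .const$E_CUT) dE <- .bethe_bloch(Em, mat$I, mat$ZA) * lin * step
    E <- E - dE
    if (E <= .const$E_CUT) E <- 0
    z[i + 1L] <- z[i] + step
    Ez[i + 1L] <- E
  }
  out <- approx(z, Ez, xout = depth, rule = 2)$y
  out[out < 0] <- 0
  out
}

#' CSDA range of a proton beam
#'
#' Depth at which the residual energy reaches the 0.5 MeV transport floor,
#' from the same continuous-slowing-down integration as [residual_energy()].
#'
#' @inheritParams residual_energy
#' @param step integration step (mm), default 0.1 for sub-voxel accuracy.
#' @return range (mm).
#' @examples
#' csda_range(150, material("water"))  # ~158 mm
#' @export
csda_range <- function(E0, mat, step = 0.1) {
  stopifnot(E0 > .const$E_CUT)
  E <- E0; z <- 0
  lin <- mat$rho / 10
  repeat {
    dE <- .bethe_bloch(E, mat$I, mat$ZA) * lin * step
    Em <- E - dE / 2
    if (Em <= .const$E_CUT) {
      # final partial step: deposit remainder over the proportional distance
      z <- z + step * min(1, (E - .const$E_CUT) / dE)
      break
    }
    dE <- .bethe_bloch(Em, mat$I, mat$ZA) * lin * step
    E <- E - dE
    z <- z + step
    if (E <= .const$E_CUT) break
  }
  z
}
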