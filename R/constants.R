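# Physical constants (MeV-mm-g units unless noted).
# Values must stay in sync with src/mc_engine.cpp.
.const <- list(
  mp    = 938.27208816,   # proton rest energy, MeV
  me    = 0.51099895,     # electron rest energy, MeV
  K     = 0.307075,       # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
  c_mm  = 299.792458,     # speed of light, mm/us (only ratios used)
  E_CUT = 0.5             # transport/stopping-power validity floor, MeV
)

#' Proton momentum from kinetic energy
#'
#' Relativistic momentum p c = sqrt(E^2 + 2 E m_p c^2) of a proton with
#' kinetic energy E; the corresponding gyroradius in a transverse field is
#' p / (0.3 B) (mm with p in MeV/c and B in tesla).
#'
#' @param E kinetic energy (MeV), vectorized.
#' @return momentum (MeV/c).
#' @export
proton_momentum <- function(E) sqrt(E^2 + 2 * E * .const$mp)

# Gyroradius of a proton in a transverse field, mm (p in MeV/c, B in T).
gyroradius_mm <- function(p, B) p / (0.299792458 * B)
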