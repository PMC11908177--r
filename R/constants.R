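# Physical constants and unit conversions.
#
# Working unit system follows the LAMMPS "real" convention:
#   length Angstrom, energy kcal/mol, time fs, mass amu (g/mol),
#   charge elementary charges, temperature Kelvin.

#' @keywords internal
#' @noRd
.const <- list(
  kB        = 0.0019872041,     # Boltzmann constant, kcal/(mol K)
  coulomb   = 332.06371,        # e^2/(4 pi eps0), kcal Angstrom / (mol e^2)
  e_charge  = 1.602176634e-19,  # C
  eps0      = 8.8541878128e-12, # C^2 N^-1 m^-2
  kB_SI     = 1.380649e-23,     # J/K
  avogadro  = 6.02214076e23,
  amu_g     = 1.66053906660e-24,  # g per amu
  # kcal/mol per (amu Angstrom^2/fs^2); LAMMPS real-units mvv2e
  mvv2e     = 48.88821291 * 48.88821291
)

# Kell (1975) polynomial for the density of air-free liquid water at 1 atm,
# t in degrees Celsius, result in kg/m^3 before the final /1000.
.kell_coef <- c(999.83952, 16.945176, -7.9870401e-3, -46.170461e-6,
                105.56302e-9, -280.54253e-12)
.kell_denom <- 16.879850e-3

# Default solvent coefficients of the linear d(T) in eps(T) = 1 + rho(T) d(T),
# obtained by least squares against the packaged experimental water dielectric
# table (inst/extdata/water_dielectric.csv); see fit_d_coefficients().
.default_d <- c(165.5949922478, -0.2943110342463)

# Residues whose pair interactions acquire temperature-scaled well depths.
HYDROPHOBIC_RESIDUES <- c("A", "V", "I", "L", "M")

# The canonical 20-residue alphabet, one-letter codes.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Standard residue (monomer minus water) masses in amu.
AA_MASSES <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.t_min <- 273
.t_max <- 373

.check_temperature <- function(T) {
  if (any(!is.finite(T)) || any(T < .t_min) || any(T > .t_max)) {
    stop("temperature outside the model validity window [",
         .t_min, ", ", .t_max, "] K", call. = FALSE)
  }
  invisible(T)
}
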