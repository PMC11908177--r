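#' Density of liquid water (Kell formulation)
#'
#' Evaluates the Kell polynomial for the density of air-free water at 1 atm.
#' This fixes the solvent density entering the temperature-dependent
#' dielectric constant.
#'
#' @param T temperature in Kelvin; must lie in the liquid window
#'   \[273, 373\] K.
#' @return density in g/cm^3 (vectorised over `T`).
#' @examples
#' water_density(277)    # near the density maximum
#' water_density(373) < water_density(277)
#' @export
water_density <- function(T) {
  .check_temperature(T)
  t <- T - 273.15
  num <- .kell_coef[1] + .kell_coef[2] * t + .kell_coef[3] * t^2 +
    .kell_coef[4] * t^3 + .kell_coef[5] * t^4 + .kell_coef[6] * t^5
  num / (1 + .kell_denom * t) / 1000
}

#' Default coefficients of the linear solvent parameter d(T)
#'
#' The dielectric model is eps(T) = 1 + rho_solv(T) d(T) with
#' d(T) = d\[1\] + d\[2\] T linear in temperature over the liquid range.
#' The defaults were obtained by [fit_d_coefficients()] against the
#' packaged experimental water dielectric table and are frozen here.
#'
#' @return numeric vector `c(intercept, slope)`; units such that
#'   rho (g/cm^3) times d is dimensionless.
#' @export
default_d_coefficients <- function() .default_d

#' Fit the linear solvent parameter d(T) to a dielectric table
#'
#' Least-squares fit of (eps - 1) / rho(T) against T, i.e. the
#' assumption that d depends linearly on temperature over liquid water.
#'
#' @param table data.frame with columns `temperature` (K) and `epsilon`
#'   (relative static dielectric constant). Defaults to the packaged
#'   experimental water table.
#' @return coefficient vector `c(intercept, slope)`.
#' @export
fit_d_coefficients <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "water_dielectric.csv", package = "cgphase")
    table <- utils::read.csv(path)
  }
  stopifnot(all(c("temperature", "epsilon") %in% names(table)))
  d_obs <- (table$epsilon - 1) / water_density(table$temperature)
  fit <- stats::lm(d_obs ~ table$temperature)
  unname(stats::coef(fit))
}

#' Temperature-dependent dielectric constant of the solvent
#'
#' eps(T) = 1 + rho_solv(T) d(T), with the water density from the Kell
#' polynomial and d linear in T.
#'
#' @param T temperature in Kelvin.
#' @param d_coefficients coefficients `c(intercept, slope)` of d(T);
#'   defaults to the packaged fit.
#' @return relative dielectric constant (dimensionless).
#' @examples
#' dielectric_constant(298.15)  # about 78.6 with the default fit
#' @export
dielectric_constant <- function(T, d_coefficients = default_d_coefficients()) {
  .check_temperature(T)
  d <- d_coefficients[1] + d_coefficients[2] * T
  eps <- 1 + water_density(T) * d
  if (any(eps <= 0)) {
    stop("dielectric constant is nonpositive; invalid d coefficients",
         call. = FALSE)
  }
  eps
}

#' Electrostatics parameter set
#'
#' Bundles the ionic composition and solvent-dielectric coefficients used
#' by the screened-Coulomb (Yukawa) interaction.
#'
#' @param ionic_species data.frame with columns `z` (integer valence) and
#'   `c` (molar concentration, mol/L); may have zero rows (pure water).
#' @param d_coefficients coefficients of the linear d(T); see
#'   [default_d_coefficients()].
#' @param yukawa_cutoff cutoff radius of the screened interaction in
#'   Angstrom (default 35).
#' @param shift logical; shift the pair energy so it is exactly zero at
#'   the cutoff (default TRUE).
#' @return object of class `electrostatics_params`.
#' @export
electrostatics_params <- function(ionic_species = data.frame(z = integer(),
                                                             c = numeric()),
                                  d_coefficients = default_d_coefficients(),
                                  yukawa_cutoff = 35,
                                  shift = TRUE) {
  ionic_species <- as.data.frame(ionic_species)
  if (nrow(ionic_species) > 0) {
    stopifnot(all(c("z", "c") %in% names(ionic_species)))
    if (any(ionic_species$c < 0)) {
      stop("ionic concentrations must be nonnegative", call. = FALSE)
    }
  }
  stopifnot(yukawa_cutoff > 0)
  structure(list(ionic_species = ionic_species,
                 d_coefficients = d_coefficients,
                 yukawa_cutoff = yukawa_cutoff,
                 shift = isTRUE(shift)),
            class = "electrostatics_params")
}

#' Inverse Debye screening length
#'
#' kappa^2 = (e^2 / (eps(T) eps0 kB T)) * sum_j z_j^2 c_j, evaluated in SI
#' and returned in 1/Angstrom. kappa = 0 in pure water.
#'
#' @param T temperature in Kelvin.
#' @param electrostatics an [electrostatics_params()] object.
#' @return inverse Debye length in 1/Angstrom.
#' @examples
#' es <- electrostatics_params(data.frame(z = c(1, -1), c = c(0.15, 0.15)))
#' 1 / inverse_debye_length(298.15, es)  # about 7.9 Angstrom
#' @export
inverse_debye_length <- function(T, electrostatics) {
  stopifnot(inherits(electrostatics, "electrostatics_params"))
  .check_temperature(T)
  ions <- electrostatics$ionic_species
  if (nrow(ions) == 0 || sum(ions$c) == 0) return(0)
  if (any(ions$c < 0)) stop("negative ion concentration", call. = FALSE)
  eps_r <- dielectric_constant(T, electrostatics$d_coefficients)
  # number densities in 1/m^3: mol/L -> mol/m^3 -> 1/m^3
  n_j <- ions$c * 1000 * .const$avogadro
  k2 <- .const$e_charge^2 / (eps_r * .const$eps0 * .const$kB_SI * T) *
    sum(ions$z^2 * n_j)                      # 1/m^2
  sqrt(k2) * 1e-10                           # 1/Angstrom
}

#' Screened-Coulomb (Yukawa) pair energy
#'
#' u(r) = C q_i q_j exp(-kappa r) / (eps(T) r), with C the Coulomb constant
#' in kcal Angstrom/(mol e^2). Zero beyond the cutoff; by default the
#' energy is shifted so u(cutoff) = 0 exactly.
#'
#' @param r separation in Angstrom (vectorised); must be > 0.
#' @param q_i,q_j charges in elementary-charge units.
#' @param T temperature in Kelvin.
#' @param electrostatics an [electrostatics_params()] object.
#' @return energy in kcal/mol.
#' @export
yukawa_energy <- function(r, q_i, q_j, T, electrostatics) {
  stopifnot(inherits(electrostatics, "electrostatics_params"))
  if (any(r <= 0)) stop("yukawa_energy: r must be positive", call. = FALSE)
  if (q_i == 0 || q_j == 0) return(rep(0, length(r)))
  eps_r <- dielectric_constant(T, electrostatics$d_coefficients)
  kappa <- inverse_debye_length(T, electrostatics)
  rc <- electrostatics$yukawa_cutoff
  pref <- .const$coulomb * q_i * q_j / eps_r
  u <- pref * exp(-kappa * r) / r
  if (electrostatics$shift) u <- u - pref * exp(-kappa * rc) / rc
  u[r >= rc] <- 0
  u
}

#' Yukawa pair force magnitude
#'
#' Radial force -du/dr of [yukawa_energy()]; the cutoff shift does not
#' affect the force.
#'
#' @inheritParams yukawa_energy
#' @return force in kcal/(mol Angstrom); positive = repulsive.
#' @export
yukawa_force <- function(r, q_i, q_j, T, electrostatics) {
  stopifnot(inherits(electrostatics, "electrostatics_params"))
  if (any(r <= 0)) stop("yukawa_force: r must be positive", call. = FALSE)
  if (q_i == 0 || q_j == 0) return(rep(0, length(r)))
  eps_r <- dielectric_constant(T, electrostatics$d_coefficients)
  kappa <- inverse_debye_length(T, electrostatics)
  pref <- .const$coulomb * q_i * q_j / eps_r
  f <- pref * exp(-kappa * r) * (kappa * r + 1) / r^2
  f[r >= electrostatics$yukawa_cutoff] <- 0
  f
}
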