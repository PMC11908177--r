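#' Pairwise short-range interaction parameters
#'
#' Geometry and shape of the Wang-Frenkel interaction for one residue pair.
#' The well depth is supplied separately because it may be rescaled with
#' temperature.
#'
#' @param sigma contact distance sigma_ij in Angstrom (potential zero).
#' @param mu,nu dimensionless shape/steepness exponents, both >= 1.
#' @param r_cut cutoff R_ij in Angstrom where the potential vanishes;
#'   defaults to 3 sigma.
#' @return object of class `pair_params`.
#' @export
pair_params <- function(sigma, mu = 1, nu = 1, r_cut = 3 * sigma) {
  stopifnot(sigma > 0, mu >= 1, nu >= 1, r_cut > sigma)
  structure(list(sigma = sigma, mu = mu, nu = nu, r_cut = r_cut),
            class = "pair_params")
}

# Canonical Wang-Frenkel normalization guaranteeing a well depth of exactly
# epsilon at the minimum:
#   alpha = 2 nu (R/sigma)^(2 mu) *
#           [ (2 nu + 1) / (2 nu ((R/sigma)^(2 mu) - 1)) ]^(2 nu + 1)
#' @keywords internal
#' @noRd
.wf_alpha <- function(pair) {
  rr <- (pair$r_cut / pair$sigma)^(2 * pair$mu)
  2 * pair$nu * rr *
    ((2 * pair$nu + 1) / (2 * pair$nu * (rr - 1)))^(2 * pair$nu + 1)
}

#' Wang-Frenkel pair energy (attractive branch)
#'
#' Finite-range Lennard-Jones-like potential
#' phi(r) = eps alpha ((sigma/r)^(2mu) - 1) ((R/r)^(2mu) - 1)^(2nu),
#' which is exactly zero at r = sigma and at r = R and has a minimum of
#' depth eps between them. Identically zero for r >= R.
#'
#' @param r separation in Angstrom (vectorised); must be > 0.
#' @param pair a [pair_params()] object.
#' @param epsilon well depth in kcal/mol; must be > 0 for this branch
#'   (negative well depths are handled by [wf_repulsive_energy()]).
#' @return energy in kcal/mol.
#' @export
wf_energy <- function(r, pair, epsilon) {
  stopifnot(inherits(pair, "pair_params"))
  if (any(r <= 0)) stop("wf_energy: r must be positive", call. = FALSE)
  if (epsilon <= 0) {
    stop("wf_energy: epsilon must be positive; use wf_repulsive_energy ",
         "for negative well depths", call. = FALSE)
  }
  u <- .wf_raw(r, pair, epsilon)
  u[r >= pair$r_cut] <- 0
  u
}

# Unclipped WF form (any sign of epsilon), used by both branches.
#' @keywords internal
#' @noRd
.wf_raw <- function(r, pair, epsilon) {
  m2 <- 2 * pair$mu
  epsilon * .wf_alpha(pair) *
    ((pair$sigma / r)^m2 - 1) * ((pair$r_cut / r)^m2 - 1)^(2 * pair$nu)
}

# d/dr of the unclipped WF form.
#' @keywords internal
#' @noRd
.wf_raw_deriv <- function(r, pair, epsilon) {
  m2 <- 2 * pair$mu
  f <- (pair$sigma / r)^m2 - 1
  g <- (pair$r_cut / r)^m2 - 1
  fp <- -m2 * pair$sigma^m2 * r^(-m2 - 1)
  gp <- -m2 * pair$r_cut^m2 * r^(-m2 - 1)
  epsilon * .wf_alpha(pair) *
    (fp * g^(2 * pair$nu) + 2 * pair$nu * f * g^(2 * pair$nu - 1) * gp)
}

#' Location of the Wang-Frenkel minimum
#'
#' Closed form
#' r* = R \[ (1 + 2 nu) / (1 + 2 nu (R/sigma)^(2 mu)) \]^(1/(2 mu)),
#' the unique stationary point between sigma and R.
#'
#' @param pair a [pair_params()] object.
#' @param numeric if TRUE, locate the minimum by bracketed numerical
#'   minimisation instead of the closed form (used as a cross-check; the
#'   two agree to better than 1e-8 sigma).
#' @return r* in Angstrom, with sigma < r* < R.
#' @export
wf_r_star <- function(pair, numeric = FALSE) {
  stopifnot(inherits(pair, "pair_params"))
  if (numeric) {
    opt <- stats::optimize(function(r) .wf_raw(r, pair, 1),
                           lower = pair$sigma, upper = pair$r_cut,
                           tol = 1e-10 * pair$sigma)
    return(opt$minimum)
  }
  m2 <- 2 * pair$mu
  pair$r_cut * ((1 + 2 * pair$nu) /
                  (1 + 2 * pair$nu * (pair$r_cut / pair$sigma)^m2))^(1 / m2)
}

#' Repulsive Wang-Frenkel variant for negative well depths
#'
#' When the temperature-scaled well depth of a pair becomes negative the
#' plain Wang-Frenkel form turns unphysically attractive at contact. This
#' WCA-style construction keeps only a repulsive core that preserves the
#' bead diameter: phi_rep(r) = -phi_WF(r; eps) - eps for r < r*, and 0 for
#' r >= r*, where r* is the stationary point of the WF form. The result is
#' continuous at r*, strictly positive below it, monotonically increasing
#' as r decreases, and divergent at contact.
#'
#' @param r separation in Angstrom (vectorised); must be > 0.
#' @param pair a [pair_params()] object.
#' @param epsilon (negative) well depth in kcal/mol.
#' @return energy in kcal/mol (>= 0 everywhere).
#' @export
wf_repulsive_energy <- function(r, pair, epsilon) {
  stopifnot(inherits(pair, "pair_params"))
  if (any(r <= 0)) {
    stop("wf_repulsive_energy: r must be positive", call. = FALSE)
  }
  if (epsilon >= 0) {
    stop("wf_repulsive_energy: epsilon must be negative", call. = FALSE)
  }
  rs <- wf_r_star(pair)
  u <- -.wf_raw(r, pair, epsilon) - epsilon
  u[r >= rs] <- 0
  # mathematically u >= 0 on (0, r*); clamp float noise at the branch point
  pmax(u, 0)
}

#' Wang-Frenkel force magnitudes
#'
#' Radial forces -du/dr for the attractive and repulsive branches.
#'
#' @inheritParams wf_energy
#' @return force in kcal/(mol Angstrom); positive = repulsive.
#' @export
wf_force <- function(r, pair, epsilon) {
  stopifnot(inherits(pair, "pair_params"), epsilon > 0)
  if (any(r <= 0)) stop("wf_force: r must be positive", call. = FALSE)
  f <- -.wf_raw_deriv(r, pair, epsilon)
  f[r >= pair$r_cut] <- 0
  f
}

#' @rdname wf_force
#' @export
wf_repulsive_force <- function(r, pair, epsilon) {
  stopifnot(inherits(pair, "pair_params"), epsilon < 0)
  if (any(r <= 0)) {
    stop("wf_repulsive_force: r must be positive", call. = FALSE)
  }
  rs <- wf_r_star(pair)
  f <- .wf_raw_deriv(r, pair, epsilon)   # -d/dr of (-phi_WF - eps)
  f[r >= rs] <- 0
  f
}
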