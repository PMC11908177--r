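#' Temperature-scaling coefficients for one residue
#'
#' Coefficients of the parabolic scaling function
#' mu_X(T) = a T^2 + b T + c and the weight alpha_X with which the shift
#' mu_X(T) - mu_X(T_ref) enters the pair well depth.
#'
#' @param a coefficient in kcal/(mol K^2).
#' @param b coefficient in kcal/(mol K).
#' @param c coefficient in kcal/mol.
#' @param alpha dimensionless weight.
#' @param t_ref reference temperature in K (default 298.15); must lie in
#'   \[273, 373\].
#' @return object of class `temp_scaling_params`.
#' @export
temp_scaling_params <- function(a = 0, b = 0, c = 0, alpha = 0,
                                t_ref = 298.15) {
  stopifnot(t_ref >= 273, t_ref <= 373)
  structure(list(a = a, b = b, c = c, alpha = alpha, t_ref = t_ref),
            class = "temp_scaling_params")
}

#' Parabolic scaling function mu_X(T)
#'
#' @param T temperature in Kelvin (vectorised).
#' @param scaling a [temp_scaling_params()] object.
#' @return mu_X(T) = a T^2 + b T + c in kcal/mol.
#' @export
mu_scaling <- function(T, scaling) {
  stopifnot(inherits(scaling, "temp_scaling_params"))
  scaling$a * T^2 + scaling$b * T + scaling$c
}

#' Assemble a coarse-grained force field
#'
#' One bead per residue. `residues` carries the per-residue constants,
#' `pairs` the geometry/shape of every short-range pair interaction,
#' `scaling` the temperature-scaling coefficients (used only for pairs
#' containing a hydrophobic residue: A, V, I, L, M), and `electrostatics`
#' the screened-Coulomb settings.
#'
#' @param residues data.frame with columns `code`, `mass` (amu), `charge`
#'   (e), `sigma` (Angstrom), `epsilon_mpipi` (kcal/mol, reference well
#'   depth of the self pair).
#' @param pairs data.frame with columns `code_i`, `code_j`, `sigma_ij`,
#'   `epsilon_ij_ref`, `mu_ij`, `nu_ij`, and optionally `r_cut` (defaults
#'   to 3 sigma_ij). Pairs are stored symmetrically; either orientation
#'   may be supplied.
#' @param scaling data.frame with columns `code`, `a`, `b`, `c`, `alpha`,
#'   and optionally `t_ref` (default 298.15 K); one row per residue code
#'   appearing in `residues`.
#' @param electrostatics an [electrostatics_params()] object.
#' @param bond list with `r0` (Angstrom) and `k` (kcal/(mol Angstrom^2))
#'   of the harmonic bond U = k (r - r0)^2.
#' @return object of class `cg_forcefield`.
#' @export
forcefield <- function(residues, pairs, scaling,
                       electrostatics = electrostatics_params(),
                       bond = list(r0 = 3.81, k = 9.6)) {
  residues <- as.data.frame(residues)
  pairs <- as.data.frame(pairs)
  scaling <- as.data.frame(scaling)
  need_res <- c("code", "mass", "charge", "sigma", "epsilon_mpipi")
  need_pair <- c("code_i", "code_j", "sigma_ij", "epsilon_ij_ref",
                 "mu_ij", "nu_ij")
  need_sc <- c("code", "a", "b", "c", "alpha")
  stopifnot(all(need_res %in% names(residues)),
            all(need_pair %in% names(pairs)),
            all(need_sc %in% names(scaling)))
  if (any(residues$mass <= 0) || any(residues$sigma <= 0)) {
    stop("residue masses and sigmas must be positive", call. = FALSE)
  }
  if (anyDuplicated(residues$code)) {
    stop("duplicate residue codes", call. = FALSE)
  }
  if (is.null(pairs$r_cut)) pairs$r_cut <- 3 * pairs$sigma_ij
  if (any(pairs$mu_ij < 1) || any(pairs$nu_ij < 1)) {
    stop("pair shape exponents mu, nu must be >= 1", call. = FALSE)
  }
  if (is.null(scaling$t_ref)) scaling$t_ref <- 298.15
  miss <- setdiff(residues$code, scaling$code)
  if (length(miss) > 0) {
    stop("scaling coefficients missing for residue(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  residues$is_hydrophobic <- residues$code %in% HYDROPHOBIC_RESIDUES

  # symmetrise the pair table and index by "I|J" with I <= J
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")
  pairs$key <- key(pairs$code_i, pairs$code_j)
  dup <- duplicated(pairs$key)
  if (any(dup)) {
    # keep the first orientation; verify duplicates agree
    for (k in unique(pairs$key[dup])) {
      rows <- pairs[pairs$key == k,
                    c("sigma_ij", "epsilon_ij_ref", "mu_ij", "nu_ij", "r_cut")]
      if (max(abs(as.matrix(rows) -
                  matrix(as.numeric(rows[1, ]), nrow(rows), 5,
                         byrow = TRUE))) > 1e-12) {
        stop("pair table not symmetric for pair ", k, call. = FALSE)
      }
    }
    pairs <- pairs[!dup, ]
  }
  # completeness over the residues present
  codes <- residues$code
  grid <- expand.grid(i = codes, j = codes, stringsAsFactors = FALSE)
  grid <- grid[grid$i <= grid$j, ]
  missing_pairs <- setdiff(key(grid$i, grid$j), pairs$key)
  if (length(missing_pairs) > 0) {
    stop("pair parameters missing for: ",
         paste(utils::head(missing_pairs, 5), collapse = ", "),
         if (length(missing_pairs) > 5) " ...", call. = FALSE)
  }
  stopifnot(inherits(electrostatics, "electrostatics_params"))
  stopifnot(is.numeric(bond$r0), bond$r0 > 0, is.numeric(bond$k), bond$k > 0)

  rownames(residues) <- residues$code
  rownames(scaling) <- scaling$code
  rownames(pairs) <- pairs$key
  structure(list(residues = residues, pairs = pairs, scaling = scaling,
                 electrostatics = electrostatics,
                 bond = list(r0 = bond$r0, k = bond$k)),
            class = "cg_forcefield")
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("<cg_forcefield>", nrow(x$residues), "residues,",
      nrow(x$pairs), "pair entries\n")
  cat("  bond: r0 =", x$bond$r0, "A, k =", x$bond$k, "kcal/(mol A^2)\n")
  ions <- x$electrostatics$ionic_species
  cat("  ions:", if (nrow(ions) == 0) "none (pure water)" else
    paste0(ions$c, " M (z=", ions$z, ")", collapse = ", "), "\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
.ff_pair_row <- function(ff, i, j) {
  k <- paste(min(i, j), max(i, j), sep = "|")
  row <- ff$pairs[k, ]
  if (is.na(row$sigma_ij)) {
    stop("no pair parameters for (", i, ", ", j, ")", call. = FALSE)
  }
  row
}

#' @keywords internal
#' @noRd
.ff_scaling <- function(ff, code) {
  s <- ff$scaling[code, ]
  if (is.na(s$a)) {
    stop("no scaling coefficients for residue ", code, call. = FALSE)
  }
  temp_scaling_params(s$a, s$b, s$c, s$alpha, s$t_ref)
}

#' @keywords internal
#' @noRd
.ff_pair_params <- function(ff, i, j) {
  row <- .ff_pair_row(ff, i, j)
  pair_params(row$sigma_ij, row$mu_ij, row$nu_ij, row$r_cut)
}

#' Temperature-scaled pair well depth
#'
#' For pairs containing at least one hydrophobic residue (A, V, I, L, M)
#' the effective Wang-Frenkel well depth is
#' eps_ij(T) = 0.5\[eps_ii + alpha_i (mu_i(T) - mu_i(T_ref))\] +
#'             0.5\[eps_jj + alpha_j (mu_j(T) - mu_j(T_ref))\],
#' where eps_xx are the self well depths of the parent (temperature-free)
#' parameter set. At T = T_ref this reduces exactly to the arithmetic mean
#' of the two self depths. The result may be negative, in which case the
#' repulsive branch of the potential applies.
#'
#' For pairs with no hydrophobic member the unscaled tabulated value
#' `epsilon_ij_ref` is returned unchanged at every temperature.
#'
#' @param i,j one-letter residue codes.
#' @param T temperature in Kelvin (vectorised).
#' @param ff a [forcefield()] object.
#' @return well depth in kcal/mol.
#' @export
epsilon_ij <- function(i, j, T, ff) {
  stopifnot(inherits(ff, "cg_forcefield"))
  .check_temperature(T)
  hydro <- c(i, j) %in% HYDROPHOBIC_RESIDUES
  if (!any(hydro)) {
    return(rep(.ff_pair_row(ff, i, j)$epsilon_ij_ref, length(T)))
  }
  half <- function(code) {
    s <- .ff_scaling(ff, code)
    eps_self <- ff$residues[code, "epsilon_mpipi"]
    if (is.na(eps_self)) {
      stop("unknown residue code ", code, call. = FALSE)
    }
    0.5 * (eps_self + s$alpha * (mu_scaling(T, s) - mu_scaling(s$t_ref, s)))
  }
  half(i) + half(j)
}

#' Total short-range + electrostatic pair energy
#'
#' Dispatcher for one residue pair: computes the (possibly
#' temperature-scaled) well depth, routes to the attractive Wang-Frenkel
#' form when it is positive and to the WCA-style repulsive variant when it
#' is negative, and adds the screened-Coulomb term when both beads are
#' charged. A well depth of exactly zero contributes no short-range term.
#'
#' @param r separation in Angstrom (vectorised).
#' @param i,j one-letter residue codes.
#' @param T temperature in Kelvin (scalar).
#' @param ff a [forcefield()] object.
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(r, i, j, T, ff) {
  stopifnot(inherits(ff, "cg_forcefield"), length(T) == 1)
  pair <- .ff_pair_params(ff, i, j)
  eps <- epsilon_ij(i, j, T, ff)
  u <- if (eps > 0) {
    wf_energy(r, pair, eps)
  } else if (eps < 0) {
    wf_repulsive_energy(r, pair, eps)
  } else {
    rep(0, length(r))
  }
  qi <- ff$residues[i, "charge"]
  qj <- ff$residues[j, "charge"]
  if (qi != 0 && qj != 0) {
    u <- u + yukawa_energy(r, qi, qj, T, ff$electrostatics)
  }
  u
}

#' Total pair force magnitude
#'
#' -dU/dr of [pair_energy()] at fixed temperature.
#'
#' @inheritParams pair_energy
#' @return force in kcal/(mol Angstrom); positive = repulsive.
#' @export
pair_force <- function(r, i, j, T, ff) {
  stopifnot(inherits(ff, "cg_forcefield"), length(T) == 1)
  if (any(r <= 0)) stop("pair_force: r must be positive", call. = FALSE)
  pair <- .ff_pair_params(ff, i, j)
  eps <- epsilon_ij(i, j, T, ff)
  f <- if (eps > 0) {
    wf_force(r, pair, eps)
  } else if (eps < 0) {
    wf_repulsive_force(r, pair, eps)
  } else {
    rep(0, length(r))
  }
  qi <- ff$residues[i, "charge"]
  qj <- ff$residues[j, "charge"]
  if (qi != 0 && qj != 0) {
    f <- f + yukawa_force(r, qi, qj, T, ff$electrostatics)
  }
  f
}

#' Write a force field to a parameter-file directory
#'
#' The on-disk layout mirrors supplementary parameter tables: three CSV
#' tables (`residues.csv`, `pairs.csv`, `scaling.csv`) plus a JSON
#' manifest (`manifest.json`) carrying electrostatics, bond constants and
#' the table file names.
#'
#' @param ff a [forcefield()] object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_forcefield <- function(ff, dir) {
  stopifnot(inherits(ff, "cg_forcefield"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- ff$residues[, c("code", "mass", "charge", "sigma", "epsilon_mpipi")]
  prs <- ff$pairs[, c("code_i", "code_j", "sigma_ij", "epsilon_ij_ref",
                      "mu_ij", "nu_ij", "r_cut")]
  scl <- ff$scaling[, c("code", "a", "b", "c", "alpha", "t_ref")]
  utils::write.csv(res, file.path(dir, "residues.csv"), row.names = FALSE)
  utils::write.csv(prs, file.path(dir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(scl, file.path(dir, "scaling.csv"), row.names = FALSE)
  es <- ff$electrostatics
  manifest <- list(
    format = "cgphase-forcefield", version = 1,
    tables = list(residues = "residues.csv", pairs = "pairs.csv",
                  scaling = "scaling.csv"),
    electrostatics = list(
      ionic_species = es$ionic_species,
      d_coefficients = es$d_coefficients,
      yukawa_cutoff = es$yukawa_cutoff,
      shift = es$shift),
    bond = ff$bond)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a force field from a parameter-file directory
#'
#' @param dir directory containing `manifest.json` as written by
#'   [write_forcefield()].
#' @return a [forcefield()] object.
#' @export
read_forcefield <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "cgphase-forcefield")) {
    stop("not a cgphase force-field manifest: ", dir, call. = FALSE)
  }
  res <- utils::read.csv(file.path(dir, manifest$tables$residues))
  prs <- utils::read.csv(file.path(dir, manifest$tables$pairs))
  scl <- utils::read.csv(file.path(dir, manifest$tables$scaling))
  ions <- as.data.frame(manifest$electrostatics$ionic_species)
  if (nrow(ions) == 0) ions <- data.frame(z = integer(), c = numeric())
  es <- electrostatics_params(
    ionic_species = ions,
    d_coefficients = as.numeric(manifest$electrostatics$d_coefficients),
    yukawa_cutoff = manifest$electrostatics$yukawa_cutoff,
    shift = manifest$electrostatics$shift)
  forcefield(res, prs, scl, es,
             bond = list(r0 = manifest$bond$r0, k = manifest$bond$k))
}
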