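# R-side wrappers around the compiled Langevin dynamics core.

# Build flattened per-type-pair interaction tables at one temperature.
# Temperature enters the short-range table only through the well depths;
# sigma, mu, nu and the cutoffs are temperature-independent.
#' @keywords internal
#' @noRd
.pair_tables <- function(sys, ff, T) {
  types <- sort(unique(sys$codes))
  nt <- length(types)
  eps <- sigma <- mu2 <- nu2 <- rcut <- alpha <- rstar <- qq <-
    matrix(0, nt, nt)
  eps_T <- dielectric_constant(T, ff$electrostatics$d_coefficients)
  kappa <- inverse_debye_length(T, ff$electrostatics)
  for (a in seq_len(nt)) for (b in a:nt) {
    i <- types[a]; j <- types[b]
    pp <- .ff_pair_params(ff, i, j)
    e <- epsilon_ij(i, j, T, ff)
    eps[a, b] <- eps[b, a] <- e
    sigma[a, b] <- sigma[b, a] <- pp$sigma
    mu2[a, b] <- mu2[b, a] <- 2 * pp$mu
    nu2[a, b] <- nu2[b, a] <- 2 * pp$nu
    rcut[a, b] <- rcut[b, a] <- pp$r_cut
    alpha[a, b] <- alpha[b, a] <- .wf_alpha(pp)
    rstar[a, b] <- rstar[b, a] <- wf_r_star(pp)
    qi <- ff$residues[i, "charge"]; qj <- ff$residues[j, "charge"]
    qq[a, b] <- qq[b, a] <- .const$coulomb * qi * qj / eps_T
  }
  max_cut <- 1
  if (any(eps != 0)) max_cut <- max(max_cut, rcut[eps != 0])
  if (any(qq != 0)) max_cut <- max(max_cut, ff$electrostatics$yukawa_cutoff)
  list(ntypes = nt, eps = as.vector(t(eps)), sigma = as.vector(t(sigma)),
       mu2 = as.vector(t(mu2)), nu2 = as.vector(t(nu2)),
       rcut = as.vector(t(rcut)), alpha = as.vector(t(alpha)),
       rstar = as.vector(t(rstar)), qq = as.vector(t(qq)),
       kappa = kappa, ycut = ff$electrostatics$yukawa_cutoff,
       yshift = ff$electrostatics$shift, max_cut = max_cut,
       type_index = stats::setNames(seq_len(nt), types))
}

#' @keywords internal
#' @noRd
.type_vector <- function(sys, tables) {
  as.integer(tables$type_index[sys$codes])
}

#' Potential energy and forces of a system
#'
#' Evaluates the full coarse-grained potential (Wang-Frenkel or repulsive
#' variant per pair, Yukawa electrostatics, harmonic bonds; directly
#' bonded pairs are excluded from nonbonded terms) at one temperature.
#'
#' @param sys a `particle_system`.
#' @param ff a [forcefield()] object.
#' @param temperature temperature in Kelvin (sets the scaled well depths,
#'   the dielectric constant and the screening length).
#' @param method `"cell"` for cell-list neighbour search (falls back to
#'   all-pairs automatically when the box holds fewer than 3 cells per
#'   dimension) or `"all"` to force the O(N^2) reference path.
#' @return list with `energy` (kcal/mol) and `forces` (N x 3 matrix,
#'   kcal/(mol Angstrom)).
#' @export
compute_forces <- function(sys, ff, temperature, method = c("cell", "all")) {
  method <- match.arg(method)
  tables <- .pair_tables(sys, ff, temperature)
  cpp_energy_forces(sys$positions, sys$velocities, sys$mass,
                    .type_vector(sys, tables), sys$box, sys$bonds,
                    ff$bond$r0, ff$bond$k, tables,
                    use_cell = (method == "cell"))
}

#' @rdname compute_forces
#' @export
compute_energy <- function(sys, ff, temperature, method = c("cell", "all")) {
  compute_forces(sys, ff, temperature, method)$energy
}

#' Instantaneous kinetic temperature
#'
#' T_kin = 2 KE / (3 N kB) with KE = sum m v^2 / 2 in kcal/mol.
#'
#' @param sys a `particle_system` with velocities.
#' @return temperature in Kelvin.
#' @export
kinetic_temperature <- function(sys) {
  ke <- 0.5 * sum(sys$mass * rowSums(sys$velocities^2)) * .const$mvv2e
  2 * ke / (3 * nrow(sys$positions) * .const$kB)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param sys a `particle_system`.
#' @param temperature target temperature in Kelvin.
#' @param seed integer seed.
#' @param zero_momentum remove the centre-of-mass drift (default TRUE).
#' @return the system with fresh velocities.
#' @export
maxwell_velocities <- function(sys, temperature, seed = 1,
                               zero_momentum = TRUE) {
  n <- nrow(sys$positions)
  sv <- sqrt(.const$kB * temperature / (sys$mass * .const$mvv2e))
  v <- .with_seed(seed, matrix(stats::rnorm(3 * n), n, 3)) * sv
  if (zero_momentum && n > 1) {
    p <- colSums(v * sys$mass)
    v <- sweep(v, 2, p / sum(sys$mass))
  }
  sys$velocities <- v
  sys
}

#' Advance a system by Langevin (or NVE) dynamics
#'
#' Runs `n_steps` of the BAOAB Langevin integrator. With `friction = 0`
#' the thermostat is off and the scheme reduces to plain velocity Verlet
#' (NVE). Deterministic for a given seed.
#'
#' @param sys a `particle_system`.
#' @param ff a [forcefield()] object.
#' @param temperature thermostat setpoint in Kelvin (also fixes the
#'   temperature-scaled interactions).
#' @param n_steps number of steps.
#' @param dt timestep in fs (default 10).
#' @param friction thermostat friction in 1/fs; default 1/5000 fs
#'   (a 5 ps relaxation time). Use 0 for NVE.
#' @param seed integer seed for the thermostat noise stream.
#' @param method neighbour search, see [compute_forces()].
#' @param sample_energy_every if > 0, record the potential and kinetic
#'   energy every that many steps; returned as the `energies` attribute
#'   (data.frame with `pe`, `ke` in kcal/mol).
#' @param tables internal: precomputed interaction tables (cached by
#'   [run_md()] across sampling chunks).
#' @return the advanced `particle_system` (positions unwrapped; use
#'   [wrap_positions()] if wrapped coordinates are needed).
#' @export
run_steps <- function(sys, ff, temperature, n_steps, dt = 10,
                      friction = 1 / 5000, seed = 1,
                      method = c("cell", "all"), sample_energy_every = 0,
                      tables = NULL) {
  method <- match.arg(method)
  stopifnot(dt > 0, n_steps >= 0)
  if (n_steps == 0) return(sys)
  if (is.null(tables)) tables <- .pair_tables(sys, ff, temperature)
  out <- cpp_run_md(sys$positions, sys$velocities, sys$mass,
                    .type_vector(sys, tables), sys$box, sys$bonds,
                    ff$bond$r0, ff$bond$k, tables, dt, friction,
                    temperature, as.integer(n_steps), as.integer(seed),
                    use_cell = (method == "cell"),
                    sample_every = as.integer(sample_energy_every))
  sys$positions <- out$positions
  sys$velocities <- out$velocities
  if (sample_energy_every > 0) {
    attr(sys, "energies") <- data.frame(pe = out$sample_pe,
                                        ke = out$sample_ke)
  }
  sys
}

#' Single integration step
#'
#' One BAOAB update; see [run_steps()].
#'
#' @inheritParams run_steps
#' @return the advanced `particle_system`.
#' @export
step_md <- function(sys, ff, temperature, dt = 10, friction = 1 / 5000,
                    seed = 1, method = c("cell", "all")) {
  run_steps(sys, ff, temperature, n_steps = 1, dt = dt, friction = friction,
            seed = seed, method = method)
}

#' Simulation protocol
#'
#' Bundles the time parameters of a canonical (NVT) run. Times are given
#' in ns and converted internally using the timestep.
#'
#' @param timestep timestep in fs (default 10).
#' @param thermostat_relaxation Langevin relaxation time in ps (default
#'   5).
#' @param equilibration equilibration length in ns (discarded).
#' @param production production length in ns.
#' @param sample_interval observer sampling interval in ns (default 1, the
#'   density-profile convention; use 0.01 for radius-of-gyration runs).
#' @param temperature_grid temperatures in K, all within \[273, 373\].
#' @param seed integer master seed.
#' @return object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(timestep = 10, thermostat_relaxation = 5,
                                equilibration = 1, production = 1,
                                sample_interval = 1,
                                temperature_grid = seq(275, 370, by = 5),
                                seed = 1) {
  stopifnot(timestep > 0, production >= 0, equilibration >= 0,
            sample_interval > 0)
  .check_temperature(temperature_grid)
  structure(list(timestep = timestep,
                 thermostat_relaxation = thermostat_relaxation,
                 equilibration = equilibration, production = production,
                 sample_interval = sample_interval,
                 temperature_grid = temperature_grid,
                 seed = as.integer(seed)),
            class = "simulation_protocol")
}

#' Run a canonical simulation and collect a trajectory
#'
#' Draws Maxwell-Boltzmann velocities, runs the equilibration (discarded),
#' then samples frames every `sample_interval` ns of production.
#' Optional observer functions are called on the current system at every
#' sample. Deterministic given the protocol seed.
#'
#' @param sys a `particle_system`.
#' @param ff a [forcefield()] object.
#' @param protocol a [simulation_protocol()].
#' @param temperature run temperature in K (default: first entry of the
#'   protocol grid).
#' @param observers optional named list of functions `f(sys, time_ns)`;
#'   their returns are collected per frame.
#' @param method neighbour search, see [compute_forces()].
#' @return object of class `cg_trajectory`: list with `frames` (list of
#'   N x 3 wrapped position matrices), `frames_unwrapped`, `times` (ns),
#'   `box`, `temperature`, and `observations`.
#' @export
run_md <- function(sys, ff, protocol,
                   temperature = protocol$temperature_grid[1],
                   observers = NULL, method = c("cell", "all")) {
  stopifnot(inherits(protocol, "simulation_protocol"))
  method <- match.arg(method)
  dt <- protocol$timestep
  friction <- 1 / (protocol$thermostat_relaxation * 1000)  # ps -> fs
  steps_per_ns <- round(1e6 / dt)
  eq_steps <- round(protocol$equilibration * steps_per_ns)
  sample_steps <- max(1L, round(protocol$sample_interval * steps_per_ns))
  n_samples <- floor(protocol$production / protocol$sample_interval)

  tables <- .pair_tables(sys, ff, temperature)
  sys <- maxwell_velocities(sys, temperature, seed = protocol$seed)
  if (eq_steps > 0) {
    sys <- run_steps(sys, ff, temperature, eq_steps, dt = dt,
                     friction = friction, seed = protocol$seed + 1L,
                     method = method, tables = tables)
  }
  frames <- vector("list", n_samples)
  frames_unwrapped <- vector("list", n_samples)
  times <- numeric(n_samples)
  obs <- if (is.null(observers)) NULL else
    stats::setNames(vector("list", length(observers)), names(observers))
  for (k in seq_len(n_samples)) {
    sys <- run_steps(sys, ff, temperature, sample_steps, dt = dt,
                     friction = friction, seed = protocol$seed + 1L + k,
                     method = method, tables = tables)
    frames_unwrapped[[k]] <- sys$positions
    frames[[k]] <- wrap_positions(sys$positions, sys$box)
    times[k] <- k * protocol$sample_interval
    if (!is.null(observers)) {
      for (nm in names(observers)) {
        obs[[nm]][[k]] <- observers[[nm]](sys, times[k])
      }
    }
  }
  structure(list(frames = frames, frames_unwrapped = frames_unwrapped,
                 times = times, box = sys$box, temperature = temperature,
                 mass = sys$mass, chains = sys$chains,
                 observations = obs, final_system = sys),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", length(x$frames), "frames at", x$temperature,
      "K, box", paste(signif(x$box, 5), collapse = " x "), "A\n")
  invisible(x)
}

#' Steepest-descent energy minimisation
#'
#' Backtracking steepest descent on the potential energy; the energy is
#' non-increasing by construction.
#'
#' @param sys a `particle_system`.
#' @param ff a [forcefield()] object.
#' @param temperature temperature fixing the interaction table (K).
#' @param max_steps iteration cap (default 200).
#' @param step0 initial displacement scale in Angstrom (default 0.1).
#' @param ftol stop when the maximum force magnitude falls below this
#'   (kcal/(mol Angstrom), default 1e-4).
#' @return list with the relaxed `system` and the `energy_path` vector.
#' @export
minimize_system <- function(sys, ff, temperature, max_steps = 200,
                            step0 = 0.1, ftol = 1e-4) {
  ef <- compute_forces(sys, ff, temperature)
  e <- ef$energy
  path <- e
  step <- step0
  for (it in seq_len(max_steps)) {
    f <- ef$forces
    fmax <- max(abs(f))
    if (fmax < ftol) break
    trial <- sys
    trial$positions <- sys$positions + step * f / fmax
    ef_trial <- compute_forces(trial, ff, temperature)
    if (ef_trial$energy < e) {
      sys <- trial
      e <- ef_trial$energy
      ef <- ef_trial
      step <- min(step * 1.2, 1.0)
      path <- c(path, e)
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
  }
  list(system = sys, energy_path = path)
}
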