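# Synthetic fixtures with known ground truth. These emulate the schema and
# statistical shape of real inputs (parameter tables, slab density profiles,
# binodals, Rg(T) series, absorbance curves) but never the actual fitted
# values of any published parameter set, so tests cannot silently depend on
# external tables.

#' Generate a complete synthetic force-field parameter set
#'
#' Produces a full 20-residue parameter set with standard residue masses,
#' unit charges on D/E/K/R (and +0.375 on H), seeded-but-plausible sigmas
#' and reference well depths, and Lorentz-like combination rules for the
#' pair table. The `style` controls the temperature scaling of
#' hydrophobic-containing pairs:
#' \describe{
#'   \item{`neutral`}{all alpha = 0, so every well depth is
#'     temperature-independent.}
#'   \item{`attractive`}{well depths grow linearly with temperature, so the
#'     set becomes strongly self-attractive at high T (an LCST-like
#'     caricature).}
#'   \item{`repulsive_at_high_T`}{well depths of hydrophobic pairs decrease
#'     with T, guaranteeing eps_ij(360 K) < 0 < eps_ij(280 K) for at least
#'     one hydrophobic pair (exercises the repulsive branch).}
#'   \item{`repulsive`}{all reference well depths negative, so every pair is
#'     purely repulsive at every temperature (a non-condensing control).}
#' }
#'
#' @param seed integer seed; regeneration under the same seed is
#'   bit-identical.
#' @param style one of `"attractive"`, `"repulsive_at_high_T"`,
#'   `"neutral"`, `"repulsive"`.
#' @param ionic_species optional ion table for the electrostatics (default
#'   pure water).
#' @return a [forcefield()] object.
#' @export
make_param_set <- function(seed = 1,
                           style = c("attractive", "repulsive_at_high_T",
                                     "neutral", "repulsive"),
                           ionic_species = data.frame(z = integer(),
                                                      c = numeric())) {
  style <- match.arg(style)
  codes <- AA_ALPHABET
  rng <- .seeded_rng(seed)
  sigma <- round(5.0 + 1.5 * rng(20), 3)
  eps0 <- round(0.15 + 0.55 * rng(20), 4)
  if (style == "repulsive") eps0 <- -eps0
  charge <- stats::setNames(rep(0, 20), codes)
  charge[c("D", "E")] <- -1
  charge[c("K", "R")] <- 1
  charge["H"] <- 0.375
  residues <- data.frame(code = codes,
                         mass = unname(AA_MASSES[codes]),
                         charge = unname(charge[codes]),
                         sigma = sigma,
                         epsilon_mpipi = eps0)

  # linear scaling (a = 0): alpha*(mu(T) - mu(Tref)) = alpha*b*(T - Tref)
  slope <- switch(style,
                  neutral = 0,
                  attractive = 0.02,
                  repulsive_at_high_T = -0.02,
                  repulsive = 0)
  scaling <- data.frame(code = codes, a = 0,
                        b = slope,
                        c = round(2 + 4 * rng(20), 3),
                        alpha = if (slope == 0) 0 else 1,
                        t_ref = 298.15)

  grid <- expand.grid(code_i = codes, code_j = codes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$code_i <= grid$code_j, ]
  si <- sigma[match(grid$code_i, codes)]
  sj <- sigma[match(grid$code_j, codes)]
  ei <- eps0[match(grid$code_i, codes)]
  ej <- eps0[match(grid$code_j, codes)]
  mu_pool <- c(1, 2, 3)
  pairs <- data.frame(code_i = grid$code_i, code_j = grid$code_j,
                      sigma_ij = (si + sj) / 2,
                      epsilon_ij_ref = (ei + ej) / 2,
                      mu_ij = mu_pool[1 + floor(3 * rng(nrow(grid)) * 0.999999)],
                      nu_ij = 1)
  pairs$r_cut <- 3 * pairs$sigma_ij

  forcefield(residues, pairs, scaling,
             electrostatics = electrostatics_params(ionic_species),
             bond = list(r0 = 3.81, k = 9.6))
}

# Deterministic uniform(0,1) stream independent of the global RNG.
#' @keywords internal
#' @noRd
.seeded_rng <- function(seed) {
  state <- as.integer(seed)
  function(n) {
    out <- numeric(n)
    for (k in seq_len(n)) {
      # Park-Miller minimal standard LCG on doubles
      state <<- (state * 48271) %% 2147483647
      if (state == 0) state <<- 1
      out[k] <- state / 2147483647
    }
    out
  }
}

#' Synthetic slab density profiles with a planted cloud point
#'
#' Below `t_cloud` the per-frame profiles are flat (homogeneous gas) with
#' multiplicative noise; at and above `t_cloud` each frame shows a
#' Gaussian slab spike whose peak exceeds the overall mean by
#' `built_ratio`. Feeding the result to [detect_cloud_point()] must
#' recover `t_cloud` exactly.
#'
#' @param seed integer seed.
#' @param t_cloud planted cloud-point temperature (K); must lie on `grid`.
#' @param grid ascending temperature grid (K).
#' @param n_frames frames per temperature (default 20).
#' @param n_bins profile bins (default 60).
#' @param noise multiplicative noise s.d. (default 0.02).
#' @param built_ratio planted spike peak/mean ratio (default 20).
#' @param mean_density overall mean density in g/cm^3 (default 0.01).
#' @param box_z box length along the profile axis in Angstrom.
#' @return named list (temperature as name) of lists of
#'   `density_profile` objects, sorted by ascending temperature.
#' @export
make_profiles <- function(seed = 1, t_cloud, grid,
                          n_frames = 20, n_bins = 60, noise = 0.02,
                          built_ratio = 20, mean_density = 0.01,
                          box_z = 300) {
  stopifnot(t_cloud %in% grid)
  grid <- sort(grid)
  rng <- .seeded_rng(seed)
  centers <- (seq_len(n_bins) - 0.5) * box_z / n_bins
  out <- list()
  for (Tk in grid) {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (Tk < t_cloud) {
        dens <- rep(mean_density, n_bins)
      } else {
        # Gaussian slab over a flat background, scaled so the overall mean
        # is preserved and peak/mean equals built_ratio exactly
        z0 <- box_z / 2
        w <- box_z * 0.25 / built_ratio
        g <- exp(-(centers - z0)^2 / (2 * w^2))
        m <- mean(g)
        amp <- mean_density * (built_ratio - 1) / (max(g) - m)
        base <- mean_density - amp * m
        if (base < 0) {
          stop("built_ratio too large for this bin count", call. = FALSE)
        }
        dens <- base + amp * g
      }
      if (noise > 0) {
        dens <- dens * (1 + noise * (2 * rng(n_bins) - 1))
      }
      frames[[f]] <- structure(
        list(bin_centers = centers, density = dens,
             temperature = Tk, time = f),
        class = "density_profile")
    }
    out[[as.character(Tk)]] <- frames
  }
  out
}

#' Synthetic binodal (coexistence points) from the exact scaling laws
#'
#' Generates coexistence densities from the law of coexistence densities,
#' rho_dense - rho_dilute = A |T - T_c|^beta, and the law of rectilinear
#' diameters, (rho_dense + rho_dilute)/2 = rho_c + B (T - T_c), exactly as
#' assumed by [fit_binodal()]; optional multiplicative noise.
#'
#' @param seed integer seed.
#' @param t_c critical temperature (K).
#' @param rho_c critical density (g/cm^3).
#' @param A gap amplitude (g/cm^3 K^-beta); B diameter slope
#'   (g/cm^3 / K).
#' @param B see `A`.
#' @param beta critical exponent (default 0.325, 3D Ising).
#' @param noise multiplicative noise s.d. on each density (default 0).
#' @param temperatures coexistence temperatures; for LCST all must exceed
#'   `t_c`.
#' @param lcst orientation flag (default TRUE: gap opens above t_c).
#' @return data.frame with columns `temperature`, `dilute`, `dense`.
#' @export
make_binodal <- function(seed = 1, t_c = 300, rho_c = 0.3, A = 0.05,
                         B = 0.002, beta = 0.325, noise = 0,
                         temperatures = t_c + seq(2, 40, length.out = 10),
                         lcst = TRUE) {
  dt <- if (lcst) temperatures - t_c else t_c - temperatures
  if (any(dt <= 0)) {
    stop("all temperatures must lie on the two-phase side of t_c",
         call. = FALSE)
  }
  gap <- A * dt^beta
  mid <- rho_c + B * (if (lcst) dt else -dt)
  dense <- mid + gap / 2
  dilute <- mid - gap / 2
  if (noise > 0) {
    rng <- .seeded_rng(seed)
    dense <- dense * (1 + noise * (2 * rng(length(dense)) - 1))
    dilute <- dilute * (1 + noise * (2 * rng(length(dilute)) - 1))
  }
  data.frame(temperature = temperatures, dilute = dilute, dense = dense)
}

#' Synthetic radius-of-gyration series with a planted theta temperature
#'
#' Builds nu(T) as a line through nu = 0.5 at `t_theta` (decreasing with T
#' for LCST-type chains) and converts it to mean Rg via the finite-chain
#' scaling relation, so the analysis round trip recovers `t_theta`.
#'
#' @param seed integer seed.
#' @param t_theta planted coil-to-globule temperature (K).
#' @param n_bonds number of bonds in the chain.
#' @param grid temperature grid (K).
#' @param slope d(nu)/dT (default -0.004 K^-1).
#' @param noise multiplicative noise s.d. on Rg (default 0).
#' @param b,gamma scaling constants passed to [flory_rg()].
#' @return data.frame with columns `temperature`, `mean_rg`, `nu_true`.
#' @export
make_rg_series <- function(seed = 1, t_theta = 320, n_bonds = 99,
                           grid = seq(280, 370, by = 10), slope = -0.004,
                           noise = 0, b = 5.5, gamma = 1.1615) {
  nu <- 0.5 + slope * (grid - t_theta)
  nu <- pmin(pmax(nu, 0.06), 0.94)
  rg <- vapply(nu, flory_rg, numeric(1), n_bonds = n_bonds,
               b = b, gamma = gamma)
  if (noise > 0) {
    rng <- .seeded_rng(seed)
    rg <- rg * (1 + noise * (2 * rng(length(rg)) - 1))
  }
  data.frame(temperature = grid, mean_rg = rg, nu_true = nu)
}

#' Synthetic turbidity (absorbance) curve with a planted cloud point
#'
#' Logistic absorbance curve crossing the transmittance-0.5 convention
#' (absorbance 0.301) exactly at `t_cloud`.
#'
#' @param seed integer seed (noise stream).
#' @param t_cloud planted cloud point (K).
#' @param grid temperature grid (K).
#' @param width logistic width (K, default 2).
#' @param a_max plateau absorbance (default 1.2).
#' @param noise additive noise s.d. (default 0).
#' @return data.frame with columns `temperature`, `absorbance`.
#' @export
make_absorbance_curve <- function(seed = 1, t_cloud = 312, grid,
                                  width = 2, a_max = 1.2, noise = 0) {
  thr <- -log10(0.5)
  # logistic through absorbance = thr at t_cloud
  x0 <- t_cloud + width * log(a_max / thr - 1)
  a <- a_max / (1 + exp(-(grid - x0) / width))
  if (noise > 0) {
    rng <- .seeded_rng(seed)
    a <- a + noise * (2 * rng(length(a)) - 1)
  }
  data.frame(temperature = grid, absorbance = a)
}
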