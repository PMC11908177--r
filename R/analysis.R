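# Analysis of slab simulations: density profiles, cloud-point detection,
# coexistence densities, critical-point fitting, chain-size statistics.

#' Mass density profile along a box axis
#'
#' Mass-weighted histogram of bead positions along one axis, converted to
#' g/cm^3. Bins are uniform; the bin width is adjusted to the nearest
#' exact divisor of the box length.
#'
#' @param positions N x 3 coordinate matrix (any wrapping).
#' @param masses length-N masses in amu.
#' @param box box lengths `c(lx, ly, lz)` in Angstrom.
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`, the slab long axis).
#' @param bin_width requested bin width in Angstrom (default 5).
#' @param temperature,time optional metadata stored on the profile.
#' @return object of class `density_profile` with `bin_centers`
#'   (Angstrom), `density` (g/cm^3), `temperature`, `time`.
#' @export
density_profile <- function(positions, masses, box, axis = "z",
                            bin_width = 5, temperature = NA_real_,
                            time = NA_real_) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("empty frame", call. = FALSE)
  d <- match(axis, c("x", "y", "z"))
  if (is.na(d)) stop("axis must be one of x, y, z", call. = FALSE)
  L <- box[d]
  n_bins <- max(1L, round(L / bin_width))
  w <- L / n_bins
  x <- positions[, d]
  x <- x - floor(x / L) * L
  idx <- pmin(floor(x / w) + 1, n_bins)
  m_bin <- vapply(seq_len(n_bins),
                  function(b) sum(masses[idx == b]), numeric(1))
  cross <- prod(box[-d])                  # Angstrom^2
  vol_cm3 <- cross * w * 1e-24
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) * w,
                 density = m_bin * .const$amu_g / vol_cm3,
                 temperature = temperature, time = time),
            class = "density_profile")
}

#' Density profiles for every frame of a trajectory
#'
#' @param traj a `cg_trajectory` from [run_md()].
#' @param axis,bin_width see [density_profile()].
#' @return list of `density_profile` objects, one per frame.
#' @export
trajectory_profiles <- function(traj, axis = "z", bin_width = 5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  lapply(seq_along(traj$frames), function(k) {
    density_profile(traj$frames[[k]], traj$mass, traj$box, axis = axis,
                    bin_width = bin_width, temperature = traj$temperature,
                    time = traj$times[k])
  })
}

#' Detect a cloud point from per-temperature density profiles
#'
#' Operationalises the finite-size spike criterion: at each temperature
#' the per-frame profiles are scanned, a frame "spikes" when its maximum
#' bin density is at least `spike_ratio` times the overall mean density,
#' and the cloud point is the lowest temperature at which the spike is
#' sustained over at least `persistence` consecutive sampled frames.
#'
#' @param profiles_by_temperature list, sorted by strictly ascending
#'   temperature, of per-frame `density_profile` lists (as produced by
#'   [make_profiles()] or [trajectory_profiles()] applied per
#'   temperature).
#' @param spike_ratio peak/mean threshold (default 5).
#' @param persistence required consecutive spiking frames (default 10).
#' @return the cloud-point temperature in K, or `NA` if no temperature
#'   satisfies the criterion.
#' @export
detect_cloud_point <- function(profiles_by_temperature, spike_ratio = 5,
                               persistence = 10) {
  temps <- unname(vapply(profiles_by_temperature,
                         function(fr) fr[[1]]$temperature, numeric(1)))
  if (length(temps) < 2) {
    stop("need profiles at two or more temperatures", call. = FALSE)
  }
  if (any(diff(temps) <= 0)) {
    stop("profiles must be sorted by strictly ascending temperature",
         call. = FALSE)
  }
  for (k in seq_along(temps)) {
    frames <- profiles_by_temperature[[k]]
    spikes <- vapply(frames, function(p) {
      max(p$density) >= spike_ratio * mean(p$density)
    }, logical(1))
    run <- rle(spikes)
    if (any(run$values & run$lengths >= persistence)) return(temps[k])
  }
  NA_real_
}

#' Coexistence densities from slab density profiles
#'
#' Averages the supplied profiles, recentres the dense slab periodically
#' (circular mass-weighted mean), identifies the slab as the contiguous
#' region above the half-height density, and reports the dense density
#' averaged over the slab core and the dilute density averaged over the
#' far field, each excluding an interfacial margin.
#'
#' @param profiles list of `density_profile` objects at one temperature.
#' @param interface_exclusion margin in Angstrom excluded on each side of
#'   the interface from both phases (default 10).
#' @return named numeric `c(dilute = ..., dense = ...)` in g/cm^3.
#' @export
coexistence_densities <- function(profiles, interface_exclusion = 10) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  centers <- profiles[[1]]$bin_centers
  dens <- rowMeans(vapply(profiles, function(p) p$density,
                          numeric(length(centers))))
  n <- length(dens)
  w <- centers[2] - centers[1]
  L <- n * w
  # periodic recentring on the dense phase
  theta <- 2 * pi * centers / L
  wgt <- dens - min(dens)
  if (sum(wgt) <= 0) stop("no identifiable slab (flat profile)",
                          call. = FALSE)
  z0 <- (atan2(sum(wgt * sin(theta)), sum(wgt * cos(theta))) / (2 * pi)) * L
  z0 <- z0 %% L
  shift <- ((centers - z0 + L / 2) %% L)     # slab centre -> L/2
  ord <- order(shift)
  zc <- shift[ord]
  dc <- dens[ord]
  thr <- (max(dc) + min(dc)) / 2
  in_slab <- dc >= thr
  if (!any(in_slab) || all(in_slab)) {
    stop("no identifiable slab", call. = FALSE)
  }
  # contiguous slab region containing the centre
  mid <- which.min(abs(zc - L / 2))
  if (!in_slab[mid]) mid <- which.max(dc)
  lo <- mid; while (lo > 1 && in_slab[lo - 1]) lo <- lo - 1
  hi <- mid; while (hi < n && in_slab[hi + 1]) hi <- hi + 1
  margin_bins <- ceiling(interface_exclusion / w)
  if (lo + margin_bins > hi - margin_bins) {
    stop("slab too narrow for the requested interface exclusion",
         call. = FALSE)
  }
  core <- seq(lo + margin_bins, hi - margin_bins)
  far <- c(seq_len(max(lo - 1 - margin_bins, 0)),
           if (hi + 1 + margin_bins <= n) seq(hi + 1 + margin_bins, n))
  if (length(core) < 1 || length(far) < 1) {
    stop("slab too narrow for the requested interface exclusion",
         call. = FALSE)
  }
  c(dilute = mean(dc[far]), dense = mean(dc[core]))
}

#' Fit a binodal and locate the critical point
#'
#' Simultaneous fit of the law of coexistence densities,
#' rho_dense - rho_dilute = A |T - T_c|^beta, and the law of rectilinear
#' diameters, (rho_dense + rho_dilute)/2 = rho_c + B (T - T_c). For LCST
#' systems the coexistence gap opens above T_c; `lcst = FALSE` mirrors the
#' orientation for UCST data. Given T_c the remaining parameters are
#' linear, so the fit profiles out A, B, rho_c and optimises T_c on a
#' bracket.
#'
#' @param points data.frame with columns `temperature`, `dilute`, `dense`
#'   (>= 4 temperatures).
#' @param lcst logical orientation flag (default TRUE).
#' @param beta critical exponent (default 0.325, 3D Ising).
#' @return object of class `binodal_fit`: the input points plus `t_c`,
#'   `rho_c`, `A`, `B`, `beta`, `lcst` and the residual sum of squares.
#' @export
fit_binodal <- function(points, lcst = TRUE, beta = 0.325) {
  stopifnot(all(c("temperature", "dilute", "dense") %in% names(points)))
  if (nrow(points) < 4) {
    stop("need coexistence data at >= 4 temperatures", call. = FALSE)
  }
  if (any(points$dense <= points$dilute)) {
    stop("dense arm must exceed dilute arm at every temperature",
         call. = FALSE)
  }
  Tv <- if (lcst) points$temperature else -points$temperature
  gap <- points$dense - points$dilute
  mid <- (points$dense + points$dilute) / 2
  sse <- function(tc) {
    dt <- Tv - tc
    if (any(dt <= 0)) return(Inf)
    A <- sum(gap * dt^beta) / sum(dt^(2 * beta))
    fm <- stats::lm(mid ~ dt)
    sum((gap - A * dt^beta)^2) + sum(stats::resid(fm)^2)
  }
  upper <- min(Tv) - 1e-6
  lower <- min(Tv) - 150
  opt <- stats::optimize(sse, c(lower, upper), tol = 1e-8)
  tc <- opt$minimum
  if (!is.finite(opt$objective)) {
    stop("binodal fit failed to converge; check data orientation",
         call. = FALSE)
  }
  dt <- Tv - tc
  A <- sum(gap * dt^beta) / sum(dt^(2 * beta))
  fm <- stats::lm(mid ~ dt)
  rho_c <- unname(stats::coef(fm)[1])
  B <- unname(stats::coef(fm)[2])
  structure(list(points = points,
                 t_c = if (lcst) tc else -tc,
                 rho_c = rho_c, A = A,
                 B = if (lcst) B else -B,
                 beta = beta, lcst = lcst,
                 residual = opt$objective),
            class = "binodal_fit")
}

#' @export
print.binodal_fit <- function(x, ...) {
  cat("<binodal_fit>", if (x$lcst) "LCST" else "UCST",
      sprintf("T_c = %.2f K, rho_c = %.4f g/cm^3 (beta = %.3f, rss = %.3g)\n",
              x$t_c, x$rho_c, x$beta, x$residual))
  invisible(x)
}

#' Unwrap a chain across periodic boundaries
#'
#' Rebuilds continuous coordinates by accumulating minimum-image bond
#' vectors along the backbone.
#'
#' @param positions n x 3 matrix of (possibly wrapped) chain coordinates,
#'   in backbone order.
#' @param box box lengths.
#' @return unwrapped n x 3 matrix.
#' @export
unwrap_chain <- function(positions, box) {
  n <- nrow(positions)
  if (n < 2) return(positions)
  out <- positions
  for (i in 2:n) {
    d <- positions[i, ] - positions[i - 1, ]
    d <- d - box * round(d / box)
    out[i, ] <- out[i - 1, ] + d
  }
  out
}

#' Mass-weighted radius of gyration
#'
#' @param positions n x 3 matrix of unwrapped chain coordinates.
#' @param masses length-n masses (amu).
#' @param max_bond optional sanity threshold in Angstrom: if any
#'   consecutive distance exceeds it, the coordinates are assumed to carry
#'   wrap artifacts and an error is raised. Use `NULL` to skip the check.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(positions, masses = NULL, max_bond = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(masses)) masses <- rep(1, n)
  if (!is.null(max_bond) && n > 1) {
    bl <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                          positions[-n, , drop = FALSE])^2))
    if (any(bl > max_bond)) {
      stop("bond length exceeds ", max_bond,
           " A: coordinates look wrapped; unwrap the chain first",
           call. = FALSE)
    }
  }
  com <- colSums(positions * masses) / sum(masses)
  d2 <- rowSums(sweep(positions, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Finite-chain scaling relation for the radius of gyration
#'
#' Forward map S(nu) = sqrt( gamma (gamma + 1) /
#' (2 (gamma + 2 nu)(gamma + 2 nu + 1)) ) * b * N^nu relating the mean
#' radius of gyration of a finite heteropolymer to its apparent Flory
#' exponent.
#'
#' @param nu Flory exponent.
#' @param n_bonds number of bonds N.
#' @param b prefactor in Angstrom (default 5.5, the geometric mean of a
#'   4.0 Angstrom persistence length and the 3.8 Angstrom C-alpha
#'   spacing).
#' @param gamma shape exponent of the Schultz length distribution
#'   (default 1.1615).
#' @return expected radius of gyration in Angstrom.
#' @export
flory_rg <- function(nu, n_bonds, b = 5.5, gamma = 1.1615) {
  sqrt(gamma * (gamma + 1) /
         (2 * (gamma + 2 * nu) * (gamma + 2 * nu + 1))) * b * n_bonds^nu
}

#' Solve the finite-chain scaling relation for the Flory exponent
#'
#' Numerically inverts [flory_rg()] for nu on (0.05, 0.95). The forward
#' map is strictly increasing in nu for chains with two or more bonds, so
#' the root is unique.
#'
#' @param mean_rg observed mean radius of gyration (Angstrom, > 0).
#' @param n_bonds number of bonds (>= 1).
#' @param b,gamma see [flory_rg()].
#' @return Flory exponent nu.
#' @export
flory_nu <- function(mean_rg, n_bonds, b = 5.5, gamma = 1.1615) {
  stopifnot(mean_rg > 0, n_bonds >= 1)
  f <- function(nu) flory_rg(nu, n_bonds, b, gamma) - mean_rg
  lo <- f(0.05); hi <- f(0.95)
  if (lo * hi > 0) {
    stop("no Flory exponent in (0.05, 0.95) reproduces Rg = ", mean_rg,
         " for N = ", n_bonds, call. = FALSE)
  }
  stats::uniroot(f, c(0.05, 0.95), tol = 1e-12)$root
}

#' Flory exponent series over a temperature grid
#'
#' @param temperatures temperature grid (K).
#' @param mean_rg mean radius of gyration at each temperature (Angstrom).
#' @param n_bonds number of bonds.
#' @param stderr_rg optional standard errors of the Rg means.
#' @param b,gamma see [flory_rg()].
#' @return data.frame with `temperature`, `mean_rg`, `stderr_rg`, `nu`.
#' @export
flory_series <- function(temperatures, mean_rg, n_bonds, stderr_rg = NA,
                         b = 5.5, gamma = 1.1615) {
  nu <- vapply(mean_rg, flory_nu, numeric(1), n_bonds = n_bonds,
               b = b, gamma = gamma)
  data.frame(temperature = temperatures, mean_rg = mean_rg,
             stderr_rg = stderr_rg, nu = nu)
}

#' Coil-to-globule transition temperature
#'
#' Linear interpolation of nu(T) to its first crossing of nu = 0.5 in
#' ascending temperature (the finite-heteropolymer theta point). Warns if
#' the series crosses more than once.
#'
#' @param temperatures ascending temperature grid (K).
#' @param nu Flory exponents at each temperature.
#' @return crossing temperature in K, or `NA` (with an attribute `side`
#'   giving the sign of nu - 0.5) if there is no crossing.
#' @export
coil_globule_temperature <- function(temperatures, nu) {
  stopifnot(length(temperatures) == length(nu), length(nu) >= 2)
  ord <- order(temperatures)
  temperatures <- temperatures[ord]; nu <- nu[ord]
  s <- nu - 0.5
  hits <- sort(unique(c(
    temperatures[s == 0],                       # exact grid crossings
    vapply(which(s[-length(s)] * s[-1] < 0), function(k) {
      temperatures[k] + (0.5 - nu[k]) *
        (temperatures[k + 1] - temperatures[k]) / (nu[k + 1] - nu[k])
    }, numeric(1)))))
  if (length(hits) == 0) {
    out <- NA_real_
    attr(out, "side") <- sign(s[1])
    return(out)
  }
  if (length(hits) > 1) {
    warning("nu(T) crosses 0.5 more than once; using the first crossing")
  }
  hits[1]
}

#' Block averages and standard error
#'
#' Splits a sample series into `n_blocks` contiguous blocks of equal
#' length (any remainder goes to the last block), and reports the mean of
#' the block means and their standard error.
#'
#' @param samples numeric vector.
#' @param n_blocks number of blocks (default 3).
#' @return list with `mean`, `stderr`, `block_means`.
#' @export
block_errors <- function(samples, n_blocks = 3) {
  n <- length(samples)
  if (n < n_blocks) {
    stop("fewer samples (", n, ") than blocks (", n_blocks, ")",
         call. = FALSE)
  }
  size <- n %/% n_blocks
  bm <- vapply(seq_len(n_blocks), function(b) {
    lo <- (b - 1) * size + 1
    hi <- if (b == n_blocks) n else b * size
    mean(samples[lo:hi])
  }, numeric(1))
  list(mean = mean(bm),
       stderr = stats::sd(bm) / sqrt(n_blocks),
       block_means = bm)
}

#' Cloud point from a turbidity (absorbance) curve
#'
#' The cloud point is the temperature at which the transmittance drops to
#' 0.5, i.e. the absorbance first reaches -log10(0.5) = 0.30103 (the
#' Beer-Lambert convention). Located by linear interpolation in ascending
#' temperature.
#'
#' @param temperatures ascending temperatures (K).
#' @param absorbances absorbance values.
#' @param threshold absorbance threshold (default `-log10(0.5)`).
#' @return crossing temperature in K, or `NA` if the curve never reaches
#'   the threshold.
#' @export
absorbance_cloud_point <- function(temperatures, absorbances,
                                   threshold = -log10(0.5)) {
  stopifnot(length(temperatures) == length(absorbances))
  ord <- order(temperatures)
  temperatures <- temperatures[ord]; absorbances <- absorbances[ord]
  s <- absorbances - threshold
  if (s[1] >= 0) return(temperatures[1])
  k <- which(s[-1] >= 0 & s[-length(s)] < 0)
  if (length(k) == 0) return(NA_real_)
  k <- k[1]
  temperatures[k] + (0 - s[k]) * (temperatures[k + 1] - temperatures[k]) /
    (s[k + 1] - s[k])
}
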