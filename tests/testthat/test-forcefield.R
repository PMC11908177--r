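# Force-field module: solvent model, electrostatics, Wang-Frenkel branches,
# temperature-scaled well depths.

test_that("Kell water density has its maximum near 277 K and shrinks on heating", {
  Tg <- seq(273, 373, by = 0.1)
  rho <- water_density(Tg)
  expect_equal(Tg[which.max(rho)], 277.1, tolerance = 0.11)
  expect_equal(water_density(277), 0.99997, tolerance = 1e-4)
  expect_lt(water_density(373), water_density(277))
  expect_error(water_density(272), "validity window")
  expect_error(water_density(374), "validity window")
})

test_that("dielectric constant: vacuum limit, packaged fit, monotone decrease", {
  # rho_solv * d -> 0 gives the vacuum value 1
  expect_equal(dielectric_constant(300, c(0, 0)), 1)
  # the least-squares fit against the packaged table is the oracle for the
  # frozen default coefficients
  d_refit <- fit_d_coefficients()
  expect_equal(d_refit, default_d_coefficients(), tolerance = 1e-8)
  eps_oracle <- 1 + water_density(298.15) * (d_refit[1] + d_refit[2] * 298.15)
  expect_equal(dielectric_constant(298.15), eps_oracle, tolerance = 1e-12)
  expect_equal(dielectric_constant(298.15), 78.6, tolerance = 0.01)
  eps_grid <- dielectric_constant(seq(273, 373, by = 0.5))
  expect_true(all(diff(eps_grid) < 0))
  expect_error(dielectric_constant(300, c(-500, 0)), "nonpositive")
})

test_that("inverse Debye length: pure water, linearity, 150 mM benchmark", {
  pure <- electrostatics_params()
  expect_identical(inverse_debye_length(300, pure), 0)

  salt <- function(c) {
    electrostatics_params(data.frame(z = c(1, -1), c = c(c, c)))
  }
  k1 <- inverse_debye_length(310, salt(0.1))
  k2 <- inverse_debye_length(310, salt(0.2))
  expect_equal(k2^2 / k1^2, 2, tolerance = 1e-12)

  # independent hand evaluation in SI units (CODATA constants)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23; NAv <- 6.02214076e23
  epsr <- dielectric_constant(298.15)
  n <- 0.15 * 1000 * NAv
  kappa_si <- sqrt(e^2 / (epsr * eps0 * kB * 298.15) * 2 * n) * 1e-10
  kappa <- inverse_debye_length(298.15, salt(0.15))
  expect_rel_equal(kappa, kappa_si, 1e-10)
  expect_gt(1 / kappa, 7.7)
  expect_lt(1 / kappa, 8.0)

  expect_error(
    electrostatics_params(data.frame(z = 1, c = -0.1)), "nonnegative")
})

test_that("yukawa energy: neutral beads, cutoff shift, zero-screening limit", {
  es <- electrostatics_params(data.frame(z = c(1, -1), c = c(0.15, 0.15)))
  r <- seq(2, 40, by = 0.5)
  expect_true(all(yukawa_energy(r, 0, 1, 300, es) == 0))
  expect_equal(yukawa_energy(es$yukawa_cutoff, 1, -1, 300, es), 0)
  expect_true(all(yukawa_energy(r[r >= es$yukawa_cutoff], 1, 1, 300, es) == 0))
  # kappa = 0 (pure water) reduces to Coulomb / eps(T), up to the shift
  pure <- electrostatics_params()
  u <- yukawa_energy(5, 1, 1, 300, pure)
  coul <- 332.06371 / dielectric_constant(300)
  expect_equal(u, coul / 5 - coul / pure$yukawa_cutoff, tolerance = 1e-10)
  expect_error(yukawa_energy(0, 1, 1, 300, es), "positive")
})

test_that("parabolic scaling function evaluates as a T^2 + b T + c", {
  expect_equal(mu_scaling(431, temp_scaling_params(0, 0, 5)), 5)
  s <- temp_scaling_params(1e-4, -0.05, 6)
  expect_equal(mu_scaling(300, s), 1e-4 * 9e4 - 15 + 6, tolerance = 1e-12)
  expect_equal(mu_scaling(300, s), 0, tolerance = 1e-12)
})

test_that("scaled well depth reduces to the self-depth mean at T_ref", {
  for (style in c("attractive", "repulsive_at_high_T", "neutral")) {
    ff <- test_ff(style)
    hyd <- c("A", "V", "I", "L", "M")
    for (i in hyd) for (j in c("A", "L", "G", "E", "F")) {
      expected <- 0.5 * (ff$residues[i, "epsilon_mpipi"] +
                           ff$residues[j, "epsilon_mpipi"])
      expect_identical(epsilon_ij(i, j, 298.15, ff), expected)
    }
  }
})

test_that("scaled well depth: alpha = 0 freezes T; style guarantees sign change", {
  ff0 <- test_ff("neutral")
  expect_equal(epsilon_ij("A", "L", 280, ff0), epsilon_ij("A", "L", 360, ff0))
  # non-hydrophobic pairs are never scaled
  ffa <- test_ff("attractive")
  expect_equal(epsilon_ij("G", "S", 280, ffa), epsilon_ij("G", "S", 360, ffa))

  ffr <- test_ff("repulsive_at_high_T")
  hyd <- c("A", "V", "I", "L", "M")
  signs <- sapply(hyd, function(i) {
    c(epsilon_ij(i, i, 280, ffr), epsilon_ij(i, i, 360, ffr))
  })
  expect_true(any(signs[1, ] > 0 & signs[2, ] < 0))
})

test_that("Wang-Frenkel: exact zeros, well depth, r* closed form", {
  set.seed(42)
  for (k in 1:12) {
    sig <- runif(1, 3.5, 7)
    mu <- sample(1:3, 1)
    nu <- sample(1:2, 1)
    pp <- pair_params(sig, mu, nu)
    eps <- runif(1, 0.05, 2)
    expect_identical(wf_energy(sig, pp, eps), 0)
    expect_identical(wf_energy(3 * sig, pp, eps), 0)
    expect_identical(wf_energy(10 * sig, pp, eps), 0)
    # depth via independent numerical minimisation
    opt <- optimize(function(r) wf_energy(r, pp, eps), c(sig, 3 * sig),
                    tol = 1e-12)
    expect_rel_equal(opt$objective, -eps, 1e-6)
    rs <- wf_r_star(pp)
    expect_lt(abs(rs - wf_r_star(pp, numeric = TRUE)), 1e-8 * sig)
    expect_gt(rs, sig)
    expect_lt(rs, 3 * sig)
    # r* scales linearly with sigma at fixed shape
    pp2 <- pair_params(2 * sig, mu, nu)
    expect_rel_equal(wf_r_star(pp2), 2 * rs, 1e-12)
  }
  expect_error(wf_energy(5, pair_params(5), -0.2), "repulsive")
})

test_that("repulsive variant: zero tail, continuity, monotone core", {
  set.seed(43)
  for (k in 1:8) {
    pp <- pair_params(runif(1, 4, 7), sample(1:3, 1), sample(1:2, 1))
    eps <- -runif(1, 0.05, 1.5)
    rs <- wf_r_star(pp)
    expect_identical(wf_repulsive_energy(rs, pp, eps), 0)
    expect_identical(wf_repulsive_energy(1.1 * rs, pp, eps), 0)
    expect_lt(abs(wf_repulsive_energy(rs - 1e-7, pp, eps)), 1e-8)
    r <- seq(0.3 * pp$sigma, rs - 1e-9, length.out = 400)
    u <- wf_repulsive_energy(r, pp, eps)
    expect_true(all(u >= 0))
    expect_true(all(diff(u) < 0))   # decreasing with r = increasing on approach
  }
  expect_error(wf_repulsive_energy(5, pair_params(5), 0.2), "negative")
})

test_that("pair dispatcher: symmetry, repulsive routing, force consistency", {
  ff <- test_ff("repulsive_at_high_T")
  r <- seq(3, 20, by = 0.25)
  for (pair in list(c("A", "L"), c("E", "K"), c("G", "S"))) {
    u1 <- pair_energy(r, pair[1], pair[2], 330, ff)
    u2 <- pair_energy(r, pair[2], pair[1], 330, ff)
    expect_identical(u1, u2)
  }
  # a pair whose well depth went negative is nonnegative everywhere
  hyd <- c("A", "V", "I", "L", "M")
  neg <- hyd[sapply(hyd, function(i) epsilon_ij(i, i, 360, ff) < 0)]
  expect_gt(length(neg), 0)
  u <- pair_energy(r, neg[1], neg[1], 360, ff)
  expect_true(all(u >= 0))

  # force matches the central finite difference of the energy
  for (pair in list(c("A", "L"), c("E", "K"))) {
    pp <- cgphase:::.ff_pair_params(ff, pair[1], pair[2])
    r0 <- 1.2 * pp$sigma
    h <- 1e-6
    fd <- -(pair_energy(r0 + h, pair[1], pair[2], 330, ff) -
              pair_energy(r0 - h, pair[1], pair[2], 330, ff)) / (2 * h)
    expect_rel_equal(pair_force(r0, pair[1], pair[2], 330, ff), fd, 1e-6)
  }
  # zero force at the minimum and beyond the cutoff (attractive branch)
  ffa <- test_ff("attractive")
  pp <- cgphase:::.ff_pair_params(ffa, "A", "A")
  expect_lt(abs(wf_force(wf_r_star(pp), pp, 1)), 1e-9)
  pp_gs <- cgphase:::.ff_pair_params(ffa, "G", "S")
  expect_identical(pair_force(3.5 * pp_gs$sigma, "G", "S", 300, ffa), 0)
})

test_that("branch continuity holds across every packaged parameter set", {
  for (style in c("attractive", "repulsive_at_high_T", "repulsive")) {
    ff <- test_ff(style)
    codes <- c("A", "L", "G", "F")
    for (i in codes) for (j in codes) {
      eps <- epsilon_ij(i, j, 360, ff)
      if (eps >= 0) next
      pp <- cgphase:::.ff_pair_params(ff, i, j)
      rs <- wf_r_star(pp)
      expect_lt(abs(wf_repulsive_energy(rs - 1e-9, pp, eps)), 1e-8)
    }
  }
})

test_that("force field parameter files round-trip losslessly", {
  ff <- test_ff("repulsive_at_high_T")
  dir <- withr::local_tempdir()
  write_forcefield(ff, dir)
  ff2 <- read_forcefield(dir)
  expect_equal(ff2$residues, ff$residues, tolerance = 1e-12)
  expect_equal(ff2$pairs[order(ff2$pairs$key), names(ff$pairs)],
               ff$pairs[order(ff$pairs$key), ], tolerance = 1e-12)
  expect_equal(ff2$scaling, ff$scaling, tolerance = 1e-12)
  expect_equal(ff2$bond, ff$bond)
  expect_equal(ff2$electrostatics$d_coefficients,
               ff$electrostatics$d_coefficients)
  # energies agree exactly through the round trip
  r <- seq(3, 18, by = 0.5)
  expect_equal(pair_energy(r, "A", "M", 355, ff2),
               pair_energy(r, "A", "M", 355, ff), tolerance = 1e-12)
})

test_that("force field validates inputs", {
  ff <- test_ff()
  res <- ff$residues; prs <- ff$pairs; scl <- ff$scaling
  expect_error(forcefield(res, prs[-1, ], scl), "missing")
  expect_error(forcefield(res, prs, scl[-1, ]), "missing")
  bad <- res; bad$mass[1] <- -1
  expect_error(forcefield(bad, prs, scl), "positive")
  expect_true(all(ff$residues[c("A", "V", "I", "L", "M"), "is_hydrophobic"]))
  expect_false(any(ff$residues[setdiff(ff$residues$code,
                                       c("A", "V", "I", "L", "M")),
                               "is_hydrophobic"]))
})
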