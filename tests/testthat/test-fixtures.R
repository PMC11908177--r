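# Fixture generators: every planted ground truth must be recoverable by the
# corresponding analysis operation (the closed-loop test matrix).

test_that("parameter-set styles deliver their contracts", {
  ff0 <- make_param_set(3, "neutral")
  Ts <- c(275, 298.15, 340, 370)
  for (pair in list(c("A", "A"), c("L", "M"), c("V", "G"))) {
    eps <- sapply(Ts, function(T) epsilon_ij(pair[1], pair[2], T, ff0))
    expect_true(all(abs(eps - eps[1]) < 1e-12))
  }
  ffr <- make_param_set(3, "repulsive_at_high_T")
  hyd <- c("A", "V", "I", "L", "M")
  flips <- sapply(hyd, function(i) {
    epsilon_ij(i, i, 280, ffr) > 0 && epsilon_ij(i, i, 360, ffr) < 0
  })
  expect_true(any(flips))
  # direct evaluation of the scaling law confirms the sign change
  i <- hyd[which(flips)[1]]
  s <- temp_scaling_params(ffr$scaling[i, "a"], ffr$scaling[i, "b"],
                           ffr$scaling[i, "c"], ffr$scaling[i, "alpha"])
  manual <- function(T) {
    ffr$residues[i, "epsilon_mpipi"] +
      s$alpha * (mu_scaling(T, s) - mu_scaling(298.15, s))
  }
  expect_equal(epsilon_ij(i, i, 360, ffr), manual(360), tolerance = 1e-12)
  expect_lt(manual(360), 0)
  expect_gt(manual(280), 0)

  ffneg <- make_param_set(3, "repulsive")
  expect_true(all(ffneg$residues$epsilon_mpipi < 0))

  expect_identical(make_param_set(5, "attractive")$pairs,
                   make_param_set(5, "attractive")$pairs)
})

test_that("parameter sets cover the full alphabet and round-trip to disk", {
  ff <- make_param_set(9, "attractive")
  expect_setequal(ff$residues$code,
                  strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_equal(nrow(ff$pairs), 210)
  dir <- withr::local_tempdir()
  write_forcefield(ff, dir)
  ff2 <- read_forcefield(dir)
  expect_equal(epsilon_ij("I", "W", 350, ff2), epsilon_ij("I", "W", 350, ff),
               tolerance = 1e-12)
})

test_that("profile fixture closed loop recovers the planted cloud point", {
  grid <- seq(280, 360, by = 10)
  expect_equal(detect_cloud_point(make_profiles(1, 320, grid)), 320)
  # noise-free profiles behave as an exact step
  clean <- make_profiles(2, 320, grid, noise = 0)
  below <- clean[["310"]][[1]]
  expect_true(all(abs(below$density - mean(below$density)) < 1e-15))
  at <- clean[["320"]][[1]]
  expect_gte(max(at$density) / mean(at$density), 20 - 1e-9)
  # detection is seed-independent
  for (s in c(11, 12, 13)) {
    expect_equal(detect_cloud_point(make_profiles(s, 320, grid)), 320)
  }
})

test_that("binodal fixture closed loop and mirror symmetry", {
  pts <- make_binodal(seed = 2, t_c = 310, rho_c = 0.25, A = 0.04,
                      B = 0.0015, noise = 0)
  fit <- fit_binodal(pts)
  expect_lt(abs(fit$t_c - 310), 0.1)
  expect_lt(abs(fit$rho_c - 0.25), 1e-4)
  expect_lt(fit$residual, 1e-10)
  ucst <- make_binodal(seed = 2, t_c = 310, rho_c = 0.25, A = 0.04,
                       B = -0.0015, noise = 0,
                       temperatures = 310 - seq(2, 40, length.out = 10),
                       lcst = FALSE)
  fitu <- fit_binodal(ucst, lcst = FALSE)
  expect_lt(abs(fitu$t_c - 310), 0.1)
  # the two orientations are exact mirrors of one another
  expect_equal(sort(ucst$dense), sort(pts$dense), tolerance = 1e-12)
  expect_error(make_binodal(t_c = 300, temperatures = c(290, 310, 320, 330)),
               "two-phase")
})

test_that("Rg series fixture closed loop recovers the theta temperature", {
  ser <- make_rg_series(seed = 1, t_theta = 320, n_bonds = 99, noise = 0)
  fl <- flory_series(ser$temperature, ser$mean_rg, n_bonds = 99)
  expect_equal(fl$nu, ser$nu_true, tolerance = 1e-7)
  expect_equal(coil_globule_temperature(fl$temperature, fl$nu), 320,
               tolerance = 0.01)
})

test_that("absorbance fixture crosses the threshold exactly at t_cloud", {
  grid <- seq(295, 335, by = 0.25)
  cv <- make_absorbance_curve(seed = 1, t_cloud = 317.5, grid = grid)
  expect_equal(absorbance_cloud_point(cv$temperature, cv$absorbance), 317.5,
               tolerance = 0.05)
})
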