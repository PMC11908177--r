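# Analysis module: profiles, cloud-point detection, coexistence and
# critical-point fitting, chain statistics, block errors, turbidity.

test_that("density profile bins mass correctly and conserves it", {
  box <- c(20, 20, 100)
  pos <- matrix(c(10, 10, 7), 1, 3)
  p <- density_profile(pos, masses = 110, box, bin_width = 10)
  vol <- 20 * 20 * 10 * 1e-24
  expect_equal(p$density[1], 110 * 1.66053906660e-24 / vol, tolerance = 1e-12)
  expect_true(all(p$density[-1] == 0))

  set.seed(31)
  n <- 10000
  pos <- cbind(runif(n, 0, 20), runif(n, 0, 20), runif(n, 0, 100))
  masses <- runif(n, 60, 190)
  p <- density_profile(pos, masses, box, bin_width = 5)
  w <- p$bin_centers[2] - p$bin_centers[1]
  total <- sum(p$density * 20 * 20 * w * 1e-24) / 1.66053906660e-24
  expect_rel_equal(total, sum(masses), 1e-9)
  # uniform gas: fluctuations bounded (binomial, ~500 beads per bin)
  expect_lt(max(p$density) / mean(p$density), 2)
  expect_error(density_profile(pos[0, , drop = FALSE], numeric(0), box),
               "empty")
})

test_that("cloud point detection: planted spike, persistence, ordering", {
  grid <- seq(300, 340, by = 10)
  profs <- make_profiles(seed = 2, t_cloud = 320, grid = grid)
  expect_equal(detect_cloud_point(profs), 320)

  flat <- make_profiles(seed = 3, t_cloud = 340, grid = grid)
  flat[["340"]] <- lapply(flat[["300"]],          # remove every spike
                          function(p) { p$temperature <- 340; p })
  expect_true(is.na(detect_cloud_point(flat)))

  # a single spiking frame does not satisfy persistence 10
  one <- make_profiles(seed = 4, t_cloud = 340, grid = c(300, 340),
                       n_frames = 20)
  lone <- one[["300"]][[1]]
  lone$density[30] <- lone$density[30] * 400
  one[["340"]] <- one[["300"]]
  one[["340"]][[5]] <- lone
  one[["340"]] <- lapply(one[["340"]], function(p) { p$temperature <- 340; p })
  expect_true(is.na(detect_cloud_point(one, persistence = 10)))
  expect_equal(detect_cloud_point(one, persistence = 1), 340)

  expect_error(detect_cloud_point(rev(profs)), "ascending")
  expect_error(detect_cloud_point(profs["300"]), "two or more")
})

test_that("coexistence densities from a step profile, with periodic centring", {
  mk_step <- function(shift_bins = 0) {
    n <- 60; w <- 5
    centers <- (seq_len(n) - 0.5) * w
    dens <- rep(0.01, n)
    slab <- ((25:36 + shift_bins - 1) %% n) + 1
    dens[slab] <- 0.7
    structure(list(bin_centers = centers, density = dens,
                   temperature = 310, time = 1), class = "density_profile")
  }
  cd <- coexistence_densities(list(mk_step()), interface_exclusion = 10)
  expect_equal(unname(cd["dense"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(cd["dilute"]), 0.01, tolerance = 1e-6)
  # translating the slab by half the box changes nothing
  cd2 <- coexistence_densities(list(mk_step(30)), interface_exclusion = 10)
  expect_equal(cd2, cd, tolerance = 1e-9)

  # gaussian noise: recovered within 3 standard errors
  set.seed(77)
  noisy <- lapply(1:40, function(k) {
    p <- mk_step()
    p$density <- pmax(p$density + rnorm(60, 0, 0.005), 0)
    p
  })
  cdn <- coexistence_densities(noisy, interface_exclusion = 10)
  se <- 0.005 / sqrt(40 * 8)   # >= 8 bins averaged per phase
  expect_lt(abs(cdn["dense"] - 0.7), 3 * se)
  expect_lt(abs(cdn["dilute"] - 0.01), 3 * se)

  flat <- mk_step(); flat$density <- rep(0.3, 60)
  expect_error(coexistence_densities(list(flat)), "slab")
})

test_that("binodal fit recovers planted critical points", {
  pts <- make_binodal(seed = 1, t_c = 300, rho_c = 0.3, A = 0.05,
                      B = 0.002, beta = 0.325, noise = 0)
  fit <- fit_binodal(pts)
  expect_lt(abs(fit$t_c - 300), 0.1)
  expect_lt(abs(fit$rho_c - 0.3), 1e-4)
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$A, 0.05, tolerance = 1e-4)

  # UCST mirror: reflect temperatures about t_c
  mirror <- pts
  mirror$temperature <- 2 * 300 - pts$temperature
  fitu <- fit_binodal(mirror, lcst = FALSE)
  expect_lt(abs(fitu$t_c - 300), 0.1)
  expect_lt(abs(fitu$rho_c - 0.3), 1e-4)

  expect_error(fit_binodal(pts[1:3, ]), "4 temperatures")
  bad <- pts; bad$dense[1] <- bad$dilute[1] - 0.1
  expect_error(fit_binodal(bad), "dense arm")
})

test_that("radius of gyration: closed forms and wrap detection", {
  expect_equal(radius_of_gyration(matrix(5, 4, 3), rep(2, 4)), 0)
  two <- matrix(c(0, 0, 0, 6, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two, c(1, 1)), 3)
  n <- 25; a <- 3.81
  rod <- cbind(a * (seq_len(n) - 1), 0, 0)
  expect_equal(radius_of_gyration(rod), a * sqrt((n^2 - 1) / 12),
               tolerance = 1e-12)
  wrapped <- rod; wrapped[10, 1] <- wrapped[10, 1] + 50
  expect_error(radius_of_gyration(wrapped, max_bond = 2 * a), "unwrap")
  # unwrap reconstructs the rod across a periodic boundary
  box <- c(40, 40, 40)
  ww <- wrap_positions(rod, box)
  expect_equal(radius_of_gyration(unwrap_chain(ww, box)),
               radius_of_gyration(rod), tolerance = 1e-9)
})

test_that("Flory relation: inversion identity, monotonicity, b-linearity", {
  S <- flory_rg(0.5, 100)
  expect_lt(abs(flory_nu(S, 100) - 0.5), 1e-8)
  nus <- seq(0.06, 0.94, length.out = 60)
  fw <- flory_rg(nus, 100)
  expect_true(all(diff(fw) > 0))       # unique root
  expect_equal(flory_rg(0.37, 50, b = 11), 2 * flory_rg(0.37, 50, b = 5.5),
               tolerance = 1e-12)
  expect_error(flory_nu(1e6, 100), "no Flory exponent")
})

test_that("coil-globule temperature: interpolation and tie-breaks", {
  expect_equal(coil_globule_temperature(c(300, 310), c(0.6, 0.4)), 305)
  out <- coil_globule_temperature(c(300, 310, 320), c(0.7, 0.65, 0.6))
  expect_true(is.na(out))
  expect_equal(attr(out, "side"), 1)
  expect_warning(
    tc <- coil_globule_temperature(c(300, 310, 320, 330),
                                   c(0.6, 0.4, 0.6, 0.4)),
    "more than once")
  expect_equal(tc, 305)
})

test_that("block errors: contiguous blocks, remainder handling", {
  be <- block_errors(rep(4.2, 30))
  expect_equal(be$mean, 4.2)
  expect_equal(be$stderr, 0)
  be3 <- block_errors(c(1, 2, 3), 3)
  expect_equal(be3$mean, 2)
  expect_equal(be3$stderr, sd(c(1, 2, 3)) / sqrt(3))
  x <- c(3, 1, 2, 5, 4, 6, 9, 8, 7)
  expect_equal(block_errors(x, 3), block_errors(c(1:9), 3))
  # remainder goes to the last block
  y <- c(1, 1, 2, 2, 3, 3, 3, 3)
  expect_equal(block_errors(y, 3)$block_means, c(1, 2, 3))
  expect_error(block_errors(1:2, 3), "fewer samples")
})

test_that("absorbance cloud point uses the transmittance-0.5 convention", {
  expect_equal(-log10(0.5), 0.30103, tolerance = 1e-5)
  curve <- make_absorbance_curve(seed = 1, t_cloud = 312,
                                 grid = seq(300, 330, by = 0.5))
  expect_equal(absorbance_cloud_point(curve$temperature, curve$absorbance),
               312, tolerance = 0.1)
  flat <- rep(0, 20)
  expect_true(is.na(absorbance_cloud_point(seq(300, 319), flat)))
})
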