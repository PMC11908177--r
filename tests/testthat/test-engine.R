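# Langevin dynamics engine: integrator limits, conservation laws, neighbour
# search equivalence, consistency with the pure-R potential functions.

test_that("free particles move uniformly with forces, friction and noise off", {
  ff <- test_ff()
  # zero out every interaction: uncharged monomers with zero well depths
  ff$pairs$epsilon_ij_ref <- 0
  ff$residues$epsilon_mpipi <- 0
  ff$scaling$alpha <- 0
  pos <- matrix(c(10, 10, 10, 30, 30, 30, 50, 20, 40), 3, 3, byrow = TRUE)
  sys <- particle_system(pos, c("G", "S", "G"), list(1, 2, 3),
                         rep(200, 3), ff)
  sys$velocities <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0, -1), 3, 3,
                           byrow = TRUE) * 1e-3
  v0 <- sys$velocities
  out <- run_steps(sys, ff, 300, n_steps = 50, dt = 10, friction = 0)
  expect_equal(out$velocities, v0, tolerance = 1e-14)
  expect_equal(out$positions, pos + 50 * 10 * v0, tolerance = 1e-10)
})

test_that("total momentum is conserved without friction and noise", {
  ff <- test_ff()
  sys <- two_chain_system(ff)
  sys <- maxwell_velocities(sys, 300, seed = 2)
  out <- run_steps(sys, ff, 300, n_steps = 500, friction = 0, seed = 1)
  p <- colSums(out$velocities * out$mass)
  expect_true(all(abs(p) < 1e-10))
})

test_that("trajectories are bit-identical under the same seed", {
  ff <- test_ff("attractive")
  sys <- two_chain_system(ff)
  prot <- simulation_protocol(equilibration = 0.002, production = 0.005,
                              sample_interval = 0.001,
                              temperature_grid = 320, seed = 9)
  t1 <- run_md(sys, ff, prot)
  t2 <- run_md(sys, ff, prot)
  expect_identical(t1$frames, t2$frames)
  prot$seed <- 10L
  t3 <- run_md(sys, ff, prot)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("run_md samples the requested number of frames", {
  ff <- test_ff()
  sys <- two_chain_system(ff)
  prot <- simulation_protocol(equilibration = 0, production = 0.01,
                              sample_interval = 0.002,
                              temperature_grid = 300, seed = 1)
  obs_count <- 0
  traj <- run_md(sys, ff, prot, observers = list(
    tick = function(s, t) { obs_count <<- obs_count + 1; t }))
  expect_length(traj$frames, 5)      # floor(production / sample_interval)
  expect_equal(obs_count, 5)
  prot$production <- 0
  expect_length(run_md(sys, ff, prot)$frames, 0)
})

test_that("cell list and all-pairs agree on systems up to 200 beads", {
  ff <- test_ff("attractive")
  gas <- gas_system(ff, n = 150, box = 130, codes = c("G", "A", "E", "K"))
  e_cell <- compute_forces(gas, ff, 320, method = "cell")
  e_all <- compute_forces(gas, ff, 320, method = "all")
  expect_equal(e_cell$energy, e_all$energy, tolerance = 1e-12)
  expect_equal(e_cell$forces, e_all$forces, tolerance = 1e-12)

  sys <- two_chain_system(ff)
  expect_equal(compute_energy(sys, ff, 300, "cell"),
               compute_energy(sys, ff, 300, "all"), tolerance = 1e-12)
})

test_that("engine energy equals the hand-summed R potential on 3 beads", {
  ff <- test_ff("repulsive_at_high_T")
  # A-L bonded dimer plus a charged lysine nearby
  pos <- matrix(c(50, 50, 50,
                  54, 50, 50,
                  50, 55, 50), 3, 3, byrow = TRUE)
  sys <- particle_system(pos, c("A", "L", "K"), list(1:2, 3),
                         rep(100, 3), ff)
  Tk <- 340
  r12 <- 4; r13 <- 5; r23 <- sqrt(16 + 25)
  manual <- ff$bond$k * (r12 - ff$bond$r0)^2 +       # bond (nonbonded excluded)
    pair_energy(r13, "A", "K", Tk, ff) +
    pair_energy(r23, "L", "K", Tk, ff)
  expect_equal(compute_energy(sys, ff, Tk), manual, tolerance = 1e-10)
})

test_that("forces equal the negative numerical gradient of the energy", {
  ff <- test_ff("attractive")
  sys <- two_chain_system(ff)
  ef <- compute_forces(sys, ff, 320)
  h <- 1e-5
  for (pick in list(c(1, 1), c(7, 3), c(25, 2))) {
    i <- pick[1]; d <- pick[2]
    sp <- sys; sp$positions[i, d] <- sp$positions[i, d] + h
    sm <- sys; sm$positions[i, d] <- sm$positions[i, d] - h
    fd <- -(compute_energy(sp, ff, 320) - compute_energy(sm, ff, 320)) / (2 * h)
    expect_rel_equal(ef$forces[i, d], fd, 1e-5)
  }
})

test_that("steepest descent decreases the energy monotonically", {
  ff <- test_ff("attractive")
  pos <- cgphase:::.with_seed(8, matrix(runif(3 * 30, 40, 70), 30, 3))
  sys <- particle_system(pos, rep(c("G", "A", "L"), 10),
                         as.list(1:30), rep(110, 3), ff)
  mn <- minimize_system(sys, ff, 300, max_steps = 150)
  expect_true(all(diff(mn$energy_path) < 0))
  expect_lt(tail(mn$energy_path, 1), mn$energy_path[1])
})

test_that("unstable steps raise an error instead of silently exploding", {
  ff <- test_ff()
  sys <- two_chain_system(ff)
  sys$velocities[1, 1] <- 50   # ~5 box lengths per step
  expect_error(run_steps(sys, ff, 300, 10, friction = 0), "unstable")
})

test_that("maxwell velocities hit the setpoint and zero the drift", {
  ff <- test_ff()
  sys <- gas_system(ff, n = 200, box = 150)
  sys <- maxwell_velocities(sys, 320, seed = 6)
  expect_equal(kinetic_temperature(sys), 320, tolerance = 0.15)
  expect_true(all(abs(colSums(sys$velocities * sys$mass)) < 1e-10))
})
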