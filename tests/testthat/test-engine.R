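# Energies, forces, the integrator and its statistical mechanics.

test_that("total energy vanishes at the equilibrium one-phase conformation", {
  frag <- fragment_preset("AT-GC")
  st <- one_phase_conformation(frag, 1.0, thermalize = FALSE)
  expect_equal(total_energy(st, frag), 0, tolerance = 1e-10)
  expect_lt(max(abs(compute_forces(st, frag))), 1e-8)
})

test_that("uniformly compressed straight chain has the closed-form harmonic energy", {
  frag <- fragment_preset("AT")
  st <- one_phase_conformation(frag, 0.9, thermalize = FALSE)
  # 0.9 r0 is below ra: every bond harmonic; trap at its equilibrium length
  p <- segment_params("AT")
  kBT <- physics_constants()$kBT_pN_A
  per_bond <- 0.5 * (p$S / p$r0 / kBT) * (0.1 * p$r0)^2
  e <- total_energy(st, frag, parts = TRUE)
  expect_equal(e$bond, 98 * per_bond, tolerance = 1e-10)
  expect_equal(e$bend, 0)
  expect_equal(e$trap, 0)
})

test_that("a single bent angle contributes (P kBT / 2 r0) theta^2", {
  frag <- fragment_preset("AT")
  st <- one_phase_conformation(frag, 1.0, thermalize = FALSE)
  # rotate the first bead about bead 2 by theta, leaving bond lengths fixed
  theta <- 0.2
  r0 <- frag$r0
  st$positions[1, ] <- st$positions[2, ] +
    c(-r0 * cos(theta), r0 * sin(theta), 0)
  e <- total_energy(st, frag, parts = TRUE)
  expect_equal(e$bond, 0, tolerance = 1e-9)
  expect_equal(e$bend, 0.5 * (95.4 / r0) * theta^2, tolerance = 1e-9)
})

test_that("analytic forces match a central-difference gradient of the energy", {
  for (preset in c("AT-GC", "AT-lambda-GC")) {
    frag <- fragment_preset(preset)
    st <- perturbed_state(frag, x = 1.2, seed = 4)
    f <- compute_forces(st, frag, constrained = FALSE, units = "kBT/A")
    h <- 1e-5
    n <- nrow(st$positions)
    idx <- cbind(c(1, 5, 50, 98, 99), c(1, 2, 3, 1, 1))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      stp <- stm <- st
      stp$positions[i, j] <- stp$positions[i, j] + h
      stm$positions[i, j] <- stm$positions[i, j] - h
      num <- -(total_energy(stp, frag) - total_energy(stm, frag)) / (2 * h)
      expect_equal(f[i, j], num, tolerance = 1e-5,
                   label = sprintf("%s force[%d,%d]", preset, i, j))
    }
  }
})

test_that("internal forces obey Newton's third law", {
  frag <- fragment_preset("AT-GC")
  st <- perturbed_state(frag, x = 1.3, seed = 7)
  f <- compute_forces(st, frag, constrained = FALSE, with_trap = FALSE,
                      units = "kBT/A")
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("without friction the integrator conserves energy (symplectic limit)", {
  frag <- fragment_preset("AT-GC")
  eng <- engine_config(gamma = 0)
  set.seed(5)
  st <- one_phase_conformation(frag, 1.05, eng)
  m <- physics_constants()$bead_mass_Da
  e0 <- total_energy(st, frag) + 0.5 * m * sum(st$velocities^2)
  st2 <- langevin_step(st, frag, eng, n_steps = 1e4, seed = 1)
  e1 <- total_energy(st2, frag) + 0.5 * m * sum(st2$velocities^2)
  expect_lt(abs(e1 - e0) / e0, 1e-4)
})

test_that("identical seeds give bitwise-identical trajectories", {
  frag <- fragment_preset("AT-GC")
  eng <- engine_config()
  set.seed(3)
  st <- one_phase_conformation(frag, 1.2, eng)
  a <- langevin_step(st, frag, eng, n_steps = 2000, seed = 42)
  b <- langevin_step(st, frag, eng, n_steps = 2000, seed = 42)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c2 <- langevin_step(st, frag, eng, n_steps = 2000, seed = 43)
  expect_false(identical(a$positions, c2$positions))
})

test_that("boundary constraints hold exactly over long runs", {
  frag <- fragment_preset("AT-GC")
  eng <- engine_config()
  set.seed(8)
  st <- one_phase_conformation(frag, 1.2, eng)
  st2 <- langevin_step(st, frag, eng, n_steps = 5e4, seed = 11)
  expect_identical(st2$positions[1, ], st$positions[1, ])
  expect_identical(st2$positions[99, 2:3], st$positions[99, 2:3])
  expect_true(st2$positions[99, 1] != st$positions[99, 1])
})

test_that("mean kinetic energy satisfies equipartition at 300 K", {
  frag <- fragment_preset("AT")
  set.seed(12)
  st <- one_phase_conformation(frag, 1.0)
  res <- overstretch:::langevin_run(st, frag, engine_config(), 2, 6,
                                    bond_sample_ns = 0, seed = 21)
  dof <- 97 * 3 + 1     # 97 free beads + x of the trapped end bead
  ke_per_dof <- res$mean_ke / dof
  # s.e. estimated from the thermostat correlation time 1/gamma ~ 43 ps
  n_eff <- 6e3 / 43
  se <- sqrt(0.5 / (dof * n_eff))
  expect_lt(abs(ke_per_dof - 0.5), 3 * se + 0.005)
})

test_that("a trapped bead samples the closed-form positional variance", {
  # 2-bead chain with a negligibly stiff bond: the mobile bead feels the
  # trap almost alone, so var(x) ~ kBT / K_trap
  seg <- segment_params("soft", S = 0.01, r0 = 11 * 3.38, ra_ratio = 1.5,
                        rb_ratio = 3.0, delta = 0, P = 1)
  frag <- dna_fragment(data.frame(segment = "soft", bonds = 1),
                       segments = list(soft = seg), n_beads = 2L,
                       k_trap = 6.129)
  eng <- engine_config(gamma = 0.05)
  set.seed(9)
  st <- one_phase_conformation(frag, 1.0, eng)
  res <- overstretch:::langevin_run(st, frag, eng, 2, 10,
                                    bond_sample_ns = 0, seed = 33)
  expect_equal(res$var_x[2], 1 / 6.129, tolerance = 0.15)
})

test_that("an exploding bond raises an integration-failure error", {
  frag <- fragment_preset("AT")
  set.seed(2)
  st <- one_phase_conformation(frag, 10.5)
  expect_error(langevin_step(st, frag, engine_config(), n_steps = 2000,
                             seed = 1),
               "integration failure")
})

test_that("internal time unit conversions are consistent", {
  pc <- physics_constants()
  expect_equal(pc$kBT_pN_A, 41.419, tolerance = 1e-4)
  expect_equal(pc$tau_fs, 63.32, tolerance = 1e-3)
  expect_equal(pc$r0_A, 37.18)
  # round trip fs -> internal -> fs
  tau <- pc$tau_fs
  expect_equal((100 / tau) * tau, 100)
})
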