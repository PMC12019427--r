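# One-phase starts, point averaging, replicas and curve assembly.

test_that("one-phase conformation starts with zero trap force and the target extension", {
  frag <- fragment_preset("AT-GC")
  st <- one_phase_conformation(frag, 0.8, thermalize = FALSE)
  expect_equal(st$anchor_x - st$positions[99, 1], frag$r_eql)
  lx <- st$positions[99, 1] - st$positions[1, 1]
  expect_equal(lx / frag$L0, 0.8)
  e <- total_energy(st, frag, parts = TRUE)
  expect_equal(e$trap, 0)

  st1 <- one_phase_conformation(frag, 1.0, thermalize = FALSE)
  expect_equal(total_energy(st1, frag, parts = TRUE)$bond, 0,
               tolerance = 1e-12)
  expect_equal(relative_bond_lengths(st1, frag), rep(1, 98))
})

test_that("near-equilibrium mean force follows the series-spring prediction", {
  # convex, bending-stiff chain: quasi-static K_eff = (98/k_bond + 1/K_trap)^-1
  frag <- convex_fragment()
  x <- 1.1                                   # well below ra = 1.5 r0
  pc <- physics_constants()
  k_bond <- 944 / 37.18 / pc$kBT_pN_A        # kBT/A^2
  k_eff <- 1 / (98 / k_bond + 1 / frag$k_trap)
  f_pred <- k_eff * 98 * (x - 1) * 37.18 * pc$kBT_pN_A   # ~94.3 pN
  prot <- stretch_protocol(x_grid = x, t_equil_ns = 5, t_prod_ns = 15,
                           n_replicas = 2, seed = 61)
  # low friction keeps every mode underdamped, so the slow collective
  # stretch mode still relaxes at ~2/gamma instead of gamma/omega^2
  rec <- run_point(frag, x, prot)
  expect_lt(abs(rec$mean_force_pN - f_pred), 3)
})

test_that("a single-segment fragment at mid-plateau pulls near its plateau force", {
  frag <- fragment_preset("AT")
  prot <- stretch_protocol(x_grid = 1.275, t_equil_ns = 20, t_prod_ns = 60,
                           n_replicas = 1, seed = 62)
  rec <- run_point(frag, 1.275, prot)
  fp <- plateau_force(bond_potential(segment_params("AT")))
  expect_lt(abs(rec$mean_force_pN - fp), 4)
  expect_equal(rec$mean_rel_ext, 1.275, tolerance = 0.01)
})

test_that("point records carry replica statistics and are reproducible", {
  frag <- fragment_preset("AT-GC")
  prot <- stretch_protocol(x_grid = 1.0, t_equil_ns = 0.5, t_prod_ns = 1,
                           n_replicas = 3, seed = 63)
  rec <- run_point(frag, 1.0, prot)
  expect_equal(rec$n_replicas, 3L)
  expect_length(rec$replica_force_pN, 3)
  expect_equal(rec$sem_force_pN,
               stats::sd(rec$replica_force_pN) / sqrt(3))
  expect_equal(length(unique(rec$seeds)), 3L)
  expect_equal(sum(rec$segment_extension_A),
               rec$mean_rel_ext * frag$L0, tolerance = 1e-6)
  rec2 <- run_point(frag, 1.0, prot)
  expect_identical(rec$mean_force_pN, rec2$mean_force_pN)

  expect_error(stretch_protocol(t_prod_ns = 0))
})

test_that("bond samples are recorded at the requested cadence", {
  frag <- fragment_preset("AT")
  prot <- stretch_protocol(x_grid = 1.0, t_equil_ns = 0.2, t_prod_ns = 2,
                           n_replicas = 2, bond_sample_ns = 0.1, seed = 64)
  rec <- run_point(frag, 1.0, prot)
  expect_equal(dim(rec$bond_samples), c(2 * 20, 98))
  # holding Lx = L0 suppresses transverse coiling, so the chain carries
  # entropic tension and bonds sit a few percent above r0
  expect_true(all(rec$bond_samples > 0.8 & rec$bond_samples < 2.05))
  expect_gt(median(rec$bond_samples), 0.98)
  expect_lt(median(rec$bond_samples), 1.08)
})

test_that("run_curve assembles independent points and flags failures", {
  frag <- fragment_preset("AT")
  prot <- stretch_protocol(x_grid = c(0.95, 1.0), t_equil_ns = 0.2,
                           t_prod_ns = 1, n_replicas = 2, seed = 65)
  fec <- run_curve(frag, prot)
  expect_s3_class(fec, "fec")
  expect_equal(nrow(fec$table), 2L)
  expect_false(any(fec$table$failed))
  expect_equal(as.data.frame(fec), fec$table)

  prot1 <- stretch_protocol(x_grid = 1.0, t_equil_ns = 0.2, t_prod_ns = 1,
                            n_replicas = 1, seed = 66)
  fec1 <- run_curve(frag, prot1)
  expect_equal(nrow(fec1$table), 1L)

  # an unphysical grid point fails but the curve survives
  protbad <- stretch_protocol(x_grid = c(1.0, 12), t_equil_ns = 0.2,
                              t_prod_ns = 1, n_replicas = 1, seed = 67)
  fecbad <- run_curve(frag, protbad)
  expect_equal(fecbad$table$failed, c(FALSE, TRUE))
  expect_error(run_curve(frag, stretch_protocol(x_grid = numeric(0))),
               "grid")
})

test_that("simulate() on a fragment wraps a replicated point run", {
  frag <- fragment_preset("AT")
  rec <- simulate(frag, nsim = 2, seed = 68, x = 1.0, t_equil_ns = 0.2,
                  t_prod_ns = 1)
  expect_s3_class(rec, "point_record")
  expect_equal(rec$n_replicas, 2L)
})

test_that("tangent correlations decay as the harmonic-bend Boltzmann average predicts", {
  # independent oracle: <cos theta> under p(theta) ~ exp(-k theta^2 / 2) sin(theta).
  # A short free chain is used: interior angles of a long free chain relax
  # through whole-arm rotations and do not equilibrate from a straight
  # start on desk timescales (under tension, as in every protocol run,
  # this pathology is absent).
  frag <- dna_fragment(data.frame(segment = "poly(dA-dT)", bonds = 5),
                       n_beads = 6L)       # P = 95.4 A, k = P/r0 ~ 2.566
  k <- 95.4 / 37.18
  th <- seq(0, pi, length.out = 20001)
  w <- exp(-0.5 * k * th^2) * sin(th)
  cos_th_pred <- sum(cos(th) * w) / sum(w)
  frag$k_trap <- 0                           # no trap: free chain
  # very low friction keeps the arm-rotation modes underdamped so they
  # relax at ~2/gamma rather than the overdamped gamma/omega^2
  eng <- engine_config(last_x_only = FALSE, gamma = 0.003)
  set.seed(70)
  st <- one_phase_conformation(frag, 1.0, eng)
  res <- overstretch:::langevin_run(st, frag, eng, 0, 10,
                                    bond_sample_ns = 0, seed = 71)
  cos1 <- cos2 <- c()
  for (i in 1:1500) {                        # snapshots 0.1 ns apart
    res <- overstretch:::langevin_run(res$state, frag, eng, 0, 0.1,
                                      bond_sample_ns = 0, seed = 71 + i)
    tang <- diff(res$state$positions)
    tang <- tang / sqrt(rowSums(tang^2))
    cos1 <- c(cos1, rowSums(tang[-nrow(tang), ] * tang[-1, ]))
    cos2 <- c(cos2, rowSums(tang[1:(nrow(tang) - 2), ] * tang[3:nrow(tang), ]))
  }
  expect_equal(mean(cos1), cos_th_pred, tolerance = 0.02)
  # geometric decay over bond separation (the discrete analogue of the
  # exponential tangent-correlation decay defining P)
  expect_equal(mean(cos2), mean(cos1)^2, tolerance = 0.03)
})
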