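# The nonconvex bond potential, its hull, bending and the trap.

segments <- c("poly(dA-dT)", "poly(dG-dC)", "lambda-DNA")
reported_plateau <- c("poly(dA-dT)" = 35, "poly(dG-dC)" = 75,
                      "lambda-DNA" = 110)

test_that("bond potential is anchored at r0 and C1 across the branch points", {
  for (nm in segments) {
    pot <- bond_potential(segment_params(nm))
    r0 <- pot$params$r0
    expect_equal(pot$U(r0), 0)
    expect_equal(pot$force(r0), 0)
    # numeric left/right first derivatives agree at ra and rb
    h <- 1e-7 * r0
    for (rc in c(pot$ra, pot$rb)) {
      dl <- (pot$U(rc) - pot$U(rc - h)) / h
      dr <- (pot$U(rc + h) - pot$U(rc)) / h
      scale <- max(abs(dl), 1)
      expect_lt(abs(dl - dr) / scale, 1e-5)
      # analytic force continuous too
      expect_lt(abs(pot$force(rc - 1e-12) - pot$force(rc + 1e-12)), 1e-6)
    }
  }
})

test_that("gap between potential and common tangent equals delta at the midpoint", {
  for (nm in segments) {
    p <- segment_params(nm)
    pot <- bond_potential(p)
    tangent <- function(r) pot$U(pot$ra) +
      (pot$f_plateau / physics_constants()$kBT_pN_A) * (r - pot$ra)
    r <- seq(pot$ra, pot$rb, length.out = 4001)
    gap <- pot$U(r) - tangent(r)
    expect_gte(min(gap), -1e-9)                      # tangent is a lower bound
    expect_equal(max(gap), p$delta, tolerance = 0.005)
    expect_equal(r[which.max(gap)], (pot$ra + pot$rb) / 2,
                 tolerance = 1e-3)
  }
})

test_that("numerical convex-hull plateau force matches the tangent slope and reported values", {
  for (nm in segments) {
    p <- segment_params(nm)
    pot <- bond_potential(p)
    fp_hull <- plateau_force(pot)
    fp_analytic <- p$S * (p$ra_ratio - 1)
    expect_equal(fp_hull, fp_analytic, tolerance = 1e-3)
    expect_lt(abs(fp_hull - reported_plateau[[nm]]), 2)
  }
})

test_that("lower convex envelope touches the potential only at the branch points", {
  # independent hull oracle: grDevices::chull on the sampled curve
  for (nm in segments) {
    pot <- bond_potential(segment_params(nm))
    r <- seq(0.95 * pot$params$r0, 1.05 * pot$rb, length.out = 5000)
    u <- pot$U(r)
    ch <- sort(grDevices::chull(r, u))
    # keep only the lower boundary of the hull: vertices on or below the
    # chord joining the extreme-r vertices
    chord <- u[ch[1]] + (u[ch[length(ch)]] - u[ch[1]]) *
      (r[ch] - r[ch[1]]) / (r[ch[length(ch)]] - r[ch[1]])
    low <- ch[u[ch] <= chord + 1e-9]
    # no lower-hull vertex strictly inside (ra, rb): the envelope touches
    # the curve only at the branch points there
    dr <- r[2] - r[1]
    expect_false(any(r[low] > pot$ra + 2 * dr & r[low] < pot$rb - 2 * dr))
    # the widest lower-hull edge spans exactly ra .. rb
    gaps <- diff(r[low])
    j <- which.max(gaps)
    expect_equal(r[low[j]], pot$ra, tolerance = 1e-3)
    expect_equal(r[low[j + 1]], pot$rb, tolerance = 1e-3)
  }
})

test_that("degenerate convex potential yields the branch-point slope as its hull slope", {
  pot <- bond_potential(convex_segment())
  expect_equal(plateau_force(pot),
               pot$params$S * (pot$params$ra_ratio - 1), tolerance = 1e-3)
})

test_that("custom bump shapes are validated and preserve the plateau force", {
  p <- segment_params("poly(dA-dT)")
  quartic <- function(s) 16 * s^2 * (1 - s)^2
  pot <- bond_potential(p, bump = quartic)
  expect_equal(plateau_force(pot), p$S * (p$ra_ratio - 1), tolerance = 1e-3)
  expect_error(bond_potential(p, bump = function(s) s), "bump")
})

test_that("segment parameter invariants are enforced", {
  expect_error(segment_params("x", S = -1, ra_ratio = 1.1, rb_ratio = 1.2,
                              delta = 1, P = 50), "S")
  expect_error(segment_params("x", S = 900, ra_ratio = 0.9, rb_ratio = 1.2,
                              delta = 1, P = 50), "ra_ratio")
  expect_error(segment_params("x", S = 900, ra_ratio = 1.3, rb_ratio = 1.2,
                              delta = 1, P = 50), "rb_ratio")
  expect_error(segment_params("no-such-segment"), "unknown segment")
})

test_that("harmonic bending matches the Kratky-Porod form for small deviations", {
  P <- 95.4; r0 <- 11 * 3.38
  expect_equal(bending_energy(pi, P), 0)
  theta <- c(0.01, 0.05, 0.1)
  harm <- bending_energy(pi - theta, P)
  kp <- (P / r0) * (1 - cos(theta))
  expect_equal(harm, kp, tolerance = 1e-3)      # agree to O(theta^4)
  expect_error(bending_energy(-0.1, P), "phi")
  expect_error(interior_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
})

test_that("trap force is zero at the equilibrium length and linear in the offset", {
  k <- 6.129
  reql <- 5 * 11 * 3.38
  expect_equal(trap_force(reql, k), 0)
  f1 <- trap_force(reql + 1, k)
  expect_equal(f1, k * physics_constants()$kBT_pN_A, tolerance = 1e-6)
  expect_equal(f1, 253.86, tolerance = 1e-3)
  expect_equal(trap_force(reql + 2, k), 2 * f1)
  expect_error(trap_force(-1, k), "r_d")
})
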