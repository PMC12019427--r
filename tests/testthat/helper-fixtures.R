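# Shared fixtures: tiny custom segments and short-run helpers.

# a purely convex (harmonic-to-linear) segment: delta = 0, narrow
# nonconvex window, very stiff bending -> near-1D harmonic chain
convex_segment <- function(S = 944, P = 1e5, ra = 1.5, rb = 1.6) {
  segment_params("convex-test", S = S, r0 = 11 * 3.38, ra_ratio = ra,
                 rb_ratio = rb, delta = 0, P = P)
}

convex_fragment <- function(n_beads = 99, ...) {
  seg <- convex_segment(...)
  dna_fragment(data.frame(segment = "convex-test", bonds = n_beads - 1L),
               segments = list("convex-test" = seg), n_beads = n_beads)
}

# a random mildly-perturbed chain state for gradient checks
perturbed_state <- function(frag, x = 1.05, scale = 0.8, seed = 99) {
  set.seed(seed)
  st <- one_phase_conformation(frag, x, thermalize = FALSE)
  n <- nrow(st$positions)
  st$positions <- st$positions + matrix(stats::rnorm(3 * n, sd = scale), n, 3)
  st
}

# closed-form mean/variance of a numeric density on a grid
density_moments <- function(r, dens) {
  dr <- diff(r)
  mids <- (dens[-1] + dens[-length(dens)]) / 2
  m0 <- sum(mids * dr)
  m1 <- sum(mids * (r[-1] + r[-length(r)]) / 2 * dr) / m0
  m2 <- sum(mids * ((r[-1] + r[-length(r)]) / 2)^2 * dr) / m0
  c(mean = m1, var = m2 - m1^2)
}
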