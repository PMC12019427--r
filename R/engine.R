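# R-side wrappers around the compiled Langevin core: unit conversion,
# chain states, energies/forces and stepping.

#' Engine configuration
#'
#' Integration settings for the Langevin dynamics.  The time step must be
#' far below the bead oscillation period `Tp = 2 pi sqrt(m r0 / S)`
#' (about 30-43 ps for the built-in segments, versus the 100 fs default).
#'
#' @param dt_fs Integration time step, fs.
#' @param temperature Kelvin.
#' @param gamma Langevin collision frequency, ps^-1; `NULL` means use the
#'   fragment's derived value.
#' @param seed Integer seed for the thermostat noise (and the Maxwell
#'   draw of initial velocities).  `NULL` draws one from R's RNG.
#' @param fix_first Keep the first bead fixed (default TRUE).
#' @param last_x_only Restrict the last bead to motion along x
#'   (default TRUE).
#' @return An object of class `"engine_config"`.
#' @export
engine_config <- function(dt_fs = 100, temperature = 300, gamma = NULL,
                          seed = NULL, fix_first = TRUE, last_x_only = TRUE) {
  stopifnot(dt_fs > 0, temperature > 0)
  structure(list(dt_fs = dt_fs, temperature = temperature, gamma = gamma,
                 seed = seed, fix_first = fix_first,
                 last_x_only = last_x_only),
            class = "engine_config")
}

# Internal-unit parameter list consumed by the compiled core.
frag_internal <- function(frag, temperature = 300, mass = .bead_mass) {
  kBT <- kBT_pN_A(temperature)
  nb <- frag$n_beads - 1L
  seg <- frag$bond_segment
  getp <- function(f) vapply(seg, function(nm) f(frag$segments[[nm]]),
                             numeric(1), USE.NAMES = FALSE)
  S <- getp(function(p) p$S)
  r0 <- getp(function(p) p$r0)
  kl <- S / r0 / kBT
  list(kl = kl,
       r0 = r0,
       ra = getp(function(p) p$ra_ratio) * r0,
       rb = getp(function(p) p$rb_ratio) * r0,
       delta = getp(function(p) p$delta),
       kr = kl,                        # right-branch curvature S/r0
       ka = frag$angle_P / frag$r0,    # kBT per rad^2
       mass = mass,
       ktrap = frag$k_trap,
       reql = frag$r_eql)
}

#' One-phase starting conformation
#'
#' All beads collinear along x with equal spacing `x * r0`, the trap
#' anchor placed at the last bead plus `r_eql` so the trap force is zero,
#' and velocities drawn from the Maxwell distribution at the run
#' temperature (constrained components zeroed).
#'
#' @param frag A [dna_fragment()].
#' @param x Target relative bond length `r/r0` (equals the initial
#'   relative extension `Lx/L0`).
#' @param engine An [engine_config()]; its `temperature` sets the Maxwell
#'   draw.  Velocities use R's RNG (seed it with `set.seed()` or let
#'   [run_point()] manage seeds).
#' @param thermalize Draw Maxwell velocities (default TRUE); otherwise
#'   start at rest.
#' @return An object of class `"chain_state"`: a list with `positions`
#'   (n x 3, Angstrom), `velocities` (n x 3, internal units), `anchor_x`
#'   (Angstrom) and `time_ns`.
#' @export
one_phase_conformation <- function(frag, x, engine = engine_config(),
                                   thermalize = TRUE) {
  stopifnot(inherits(frag, "dna_fragment"), x > 0)
  n <- frag$n_beads
  pos <- cbind(x * frag$r0 * (seq_len(n) - 1), 0, 0)
  vel <- matrix(0, n, 3)
  if (thermalize) {
    sd_v <- 1 / sqrt(.bead_mass)        # internal units, kBT = 1
    vel[] <- stats::rnorm(3L * n, sd = sd_v)
  }
  if (engine$fix_first) vel[1, ] <- 0
  if (engine$last_x_only) vel[n, 2:3] <- 0
  structure(list(positions = pos, velocities = vel,
                 anchor_x = pos[n, 1] + frag$r_eql, time_ns = 0),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("chain_state: %d beads, t = %.3f ns, Lx = %.1f A\n",
              n, x$time_ns, x$positions[n, 1] - x$positions[1, 1]))
  invisible(x)
}

#' Total potential energy of the system
#'
#' Sum of the 98 bond energies, 97 bending energies and the trap energy.
#'
#' @param state A `"chain_state"`.
#' @param frag The [dna_fragment()].
#' @param temperature Kelvin.
#' @param parts Return the bond/bend/trap breakdown instead of the total.
#' @param with_trap Include the trap term (default TRUE).
#' @return Energy in kBT (a number, or a list if `parts`).
#' @export
total_energy <- function(state, frag, temperature = 300, parts = FALSE,
                         with_trap = TRUE) {
  fr <- frag_internal(frag, temperature)
  e <- cg_energy(state$positions, state$anchor_x, fr, with_trap)
  if (parts) e else e$total
}

#' Forces on the beads
#'
#' Analytic negative gradient of [total_energy()].  With
#' `constrained = TRUE` the components the boundary conditions suppress
#' (all of bead 1, y/z of the last bead) are zeroed.
#'
#' @inheritParams total_energy
#' @param constrained Zero the constrained components (default TRUE).
#' @param units `"pN"` (default) or `"kBT/A"`.
#' @return An n x 3 matrix of forces.
#' @export
compute_forces <- function(state, frag, temperature = 300,
                           constrained = TRUE, with_trap = TRUE,
                           units = c("pN", "kBT/A")) {
  units <- match.arg(units)
  fr <- frag_internal(frag, temperature)
  f <- cg_forces(state$positions, state$anchor_x, fr, with_trap, constrained)
  if (units == "pN") f * kBT_pN_A(temperature) else f
}

# Low-level run: advances the state and returns production accumulators.
# Times in ns; seed is the compiled engine's own (R-RNG-independent) seed.
langevin_run <- function(state, frag, engine, t_equil_ns, t_prod_ns,
                         bond_sample_ns = 0.1, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  temperature <- engine$temperature
  tau <- tau_fs(temperature)
  dt_int <- engine$dt_fs / tau
  gamma <- if (is.null(engine$gamma)) frag$gamma else engine$gamma
  gamma_int <- gamma * tau / 1000      # ps^-1 -> per internal time unit
  steps_per_ns <- 1e6 / engine$dt_fs
  n_equil <- as.integer(round(t_equil_ns * steps_per_ns))
  n_prod <- as.integer(round(t_prod_ns * steps_per_ns))
  sample_every <- if (bond_sample_ns > 0)
    as.integer(round(bond_sample_ns * steps_per_ns)) else 0L
  fr <- frag_internal(frag, temperature)
  res <- cg_run(state$positions, state$velocities, state$anchor_x, fr,
                dt_int, gamma_int, n_equil, n_prod, sample_every,
                as.integer(seed), engine$fix_first, engine$last_x_only)
  res$state <- structure(list(positions = res$pos, velocities = res$vel,
                              anchor_x = state$anchor_x,
                              time_ns = state$time_ns + t_equil_ns + t_prod_ns),
                         class = "chain_state")
  res$mean_force_pN <- res$mean_force * kBT_pN_A(temperature)
  res$seed <- seed
  res
}

#' Advance the chain by Langevin dynamics
#'
#' Propagates the state by `n_steps` BAOAB steps (velocity Verlet with an
#' Ornstein-Uhlenbeck velocity update; friction coefficient `m gamma`,
#' noise amplitude `sqrt(2 m gamma kBT)`).  With `gamma = 0` this is plain
#' velocity Verlet (no thermostat).  Identical seed, state and
#' configuration give a bitwise-identical trajectory.
#'
#' @param state A `"chain_state"`.
#' @param frag The [dna_fragment()].
#' @param engine An [engine_config()].
#' @param n_steps Number of time steps.
#' @param seed Integer noise seed (defaults to `engine$seed`, else drawn
#'   from R's RNG).
#' @return The advanced `"chain_state"`.
#' @export
langevin_step <- function(state, frag, engine = engine_config(),
                          n_steps = 1L, seed = NULL) {
  if (is.null(seed)) seed <- engine$seed
  t_ns <- n_steps * engine$dt_fs / 1e6
  res <- langevin_run(state, frag, engine, t_equil_ns = 0,
                      t_prod_ns = t_ns, bond_sample_ns = 0, seed = seed)
  # re-derive exact step count bookkeeping
  res$state$time_ns <- state$time_ns + t_ns
  res$state
}

#' Relative bond lengths of a state
#'
#' @param state A `"chain_state"`.
#' @param frag The [dna_fragment()].
#' @return Numeric vector of the 98 bond lengths divided by `r0`.
#' @export
relative_bond_lengths <- function(state, frag) {
  p <- state$positions
  d <- diff(p)
  sqrt(rowSums(d^2)) / frag$r0
}
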