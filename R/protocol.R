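# The isometric stretching protocol: independent one-phase starts over an
# extension grid, each with discarded equilibration, production averaging
# and replication over seeds.

#' Stretching protocol settings
#'
#' Each point of the force-extension curve is an independent simulation:
#' the chain starts from the one-phase conformation at the target `r/r0`,
#' equilibrates for `t_equil_ns` (discarded), then runs production for
#' `t_prod_ns` during which the trap force and the relative extension
#' `Lx/L0` are averaged over every time step and relative bond lengths are
#' recorded every `bond_sample_ns`.  The point is replicated `n_replicas`
#' times with distinct seeds; the grand mean and the s.e.m. over replica
#' means are reported.
#'
#' The default profile is a desk-scale calibration (50 ns equilibration,
#' 300 ns production, 3 replicas; about 1.5-2 min per point on one CPU);
#' `profile = "full"` selects the long reference profile
#' (50 ns + 650 ns, 5 replicas).  The equilibration stage matters most:
#' one-phase starts inside a plateau need tens of ns to phase-separate,
#' and shorter equilibration biases the mean force high by 1-2 pN.
#'
#' @param x_grid Target `r/r0` values (default 0.8 to 2.0 in steps of
#'   0.025).
#' @param t_equil_ns,t_prod_ns Equilibration / production lengths, ns.
#' @param n_replicas Independent replicas per point.
#' @param bond_sample_ns Bond-length recording cadence, ns.
#' @param seed Base integer seed; per-replica seeds are derived from it.
#' @param profile `"scaled"` (default) or `"full"`.
#' @return An object of class `"stretch_protocol"`.
#' @export
stretch_protocol <- function(x_grid = seq(0.8, 2.0, by = 0.025),
                             t_equil_ns = 50, t_prod_ns = 300,
                             n_replicas = 3L, bond_sample_ns = 0.1,
                             seed = NULL,
                             profile = c("scaled", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    if (missing(t_equil_ns)) t_equil_ns <- 50
    if (missing(t_prod_ns)) t_prod_ns <- 650
    if (missing(n_replicas)) n_replicas <- 5L
  }
  stopifnot(t_equil_ns >= 0, t_prod_ns > 0, n_replicas >= 1)
  structure(list(x_grid = x_grid, t_equil_ns = t_equil_ns,
                 t_prod_ns = t_prod_ns, n_replicas = as.integer(n_replicas),
                 bond_sample_ns = bond_sample_ns, seed = seed,
                 profile = profile),
            class = "stretch_protocol")
}

.replica_seed <- function(base, point_index, replica) {
  ((base %% 1000003L) * 1009L + point_index * 101L + replica) %%
    .Machine$integer.max
}

#' Simulate one point of the force-extension curve
#'
#' Runs `n_replicas` independent simulations from the one-phase
#' conformation at `x` and averages the trap force (every step), the
#' relative extension, the per-bead mean x positions (for per-segment
#' extensions) and collects relative bond-length samples.
#'
#' @param frag A [dna_fragment()].
#' @param x Target relative bond length `r/r0` for the one-phase start.
#' @param protocol A [stretch_protocol()].
#' @param engine An [engine_config()].
#' @param point_index Used when deriving per-replica seeds within a curve.
#' @param keep_samples Keep the bond-length sample matrix (default TRUE).
#' @return An object of class `"point_record"` with elements
#'   `x_target`, `mean_force_pN`, `sem_force_pN`, `replica_force_pN`,
#'   `mean_rel_ext`, `segment_extension_A` (named, time/replica-averaged
#'   per-segment x extensions), `bond_samples` (frames x 98 matrix of
#'   `r/r0`, replicas stacked), `mean_ke_kBT`, `n_replicas`, `seeds`.
#' @export
run_point <- function(frag, x, protocol = stretch_protocol(),
                      engine = engine_config(), point_index = 1L,
                      keep_samples = TRUE) {
  stopifnot(inherits(frag, "dna_fragment"))
  if (protocol$t_prod_ns <= 0) stop("production length must be positive",
                                    call. = FALSE)
  base_seed <- protocol$seed
  if (is.null(base_seed)) base_seed <- sample.int(1000000L, 1)
  nrep <- protocol$n_replicas
  forces <- rel_ext <- ke <- numeric(nrep)
  seg_ext <- NULL
  samples <- vector("list", nrep)
  seeds <- integer(nrep)
  n <- frag$n_beads
  ranges <- frag$segment_ranges
  for (r in seq_len(nrep)) {
    seeds[r] <- .replica_seed(base_seed, point_index, r)
    set.seed(seeds[r])                  # Maxwell initial velocities
    state <- one_phase_conformation(frag, x, engine)
    res <- langevin_run(state, frag, engine, protocol$t_equil_ns,
                        protocol$t_prod_ns,
                        bond_sample_ns = protocol$bond_sample_ns,
                        seed = seeds[r])
    forces[r] <- res$mean_force_pN
    rel_ext[r] <- res$mean_lx / frag$L0
    ke[r] <- res$mean_ke
    ext_r <- res$mean_x[ranges$last_bead] - res$mean_x[ranges$first_bead]
    seg_ext <- if (is.null(seg_ext)) ext_r else seg_ext + ext_r
    if (keep_samples) samples[[r]] <- res$bond_samples / frag$r0
  }
  seg_ext <- seg_ext / nrep
  names(seg_ext) <- ranges$segment
  structure(list(
    x_target = x,
    mean_force_pN = mean(forces),
    sem_force_pN = if (nrep > 1) stats::sd(forces) / sqrt(nrep) else NA_real_,
    replica_force_pN = forces,
    mean_rel_ext = mean(rel_ext),
    segment_extension_A = seg_ext,
    segment_ranges = ranges,
    bond_samples = if (keep_samples) do.call(rbind, samples) else NULL,
    mean_ke_kBT = mean(ke),
    n_replicas = nrep,
    seeds = seeds,
    t_equil_ns = protocol$t_equil_ns,
    t_prod_ns = protocol$t_prod_ns
  ), class = "point_record")
}

#' @export
print.point_record <- function(x, ...) {
  cat(sprintf(
    "point_record: r/r0 start %.3f -> <F_trap> = %.2f pN (s.e.m. %.2f, n = %d), <Lx/L0> = %.4f\n",
    x$x_target, x$mean_force_pN,
    ifelse(is.na(x$sem_force_pN), 0, x$sem_force_pN),
    x$n_replicas, x$mean_rel_ext))
  invisible(x)
}

#' Simulate a force-extension curve
#'
#' Runs [run_point()] for every value of the protocol's extension grid.
#' Points are statistically independent: each restarts from its own
#' one-phase conformation with fresh seeds (no continuation).  A failing
#' point (integration failure) is flagged and the rest of the curve is
#' still returned.
#'
#' @inheritParams run_point
#' @param keep_samples Keep per-point bond samples (memory-heavy for long
#'   grids; default FALSE).
#' @param verbose Print progress.
#' @return An object of class `"fec"`: a list with `table` (data frame
#'   with columns `x_target`, `mean_force_pN`, `sem_force_pN`,
#'   `mean_rel_ext`, `failed`) and `records` (the point records).
#' @export
run_curve <- function(frag, protocol = stretch_protocol(),
                      engine = engine_config(), keep_samples = FALSE,
                      verbose = FALSE) {
  grid <- protocol$x_grid
  if (length(grid) < 1) stop("extension grid is empty", call. = FALSE)
  if (is.null(protocol$seed)) protocol$seed <- sample.int(1000000L, 1)
  records <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rec <- tryCatch(
      run_point(frag, grid[i], protocol, engine, point_index = i,
                keep_samples = keep_samples),
      error = function(e) e)
    if (inherits(rec, "error")) {
      rows[[i]] <- data.frame(x_target = grid[i], mean_force_pN = NA_real_,
                              sem_force_pN = NA_real_,
                              mean_rel_ext = NA_real_, failed = TRUE)
      records[[i]] <- rec
    } else {
      rows[[i]] <- data.frame(x_target = grid[i],
                              mean_force_pN = rec$mean_force_pN,
                              sem_force_pN = rec$sem_force_pN,
                              mean_rel_ext = rec$mean_rel_ext,
                              failed = FALSE)
      records[[i]] <- rec
    }
    if (verbose)
      message(sprintf("x = %.3f: %s", grid[i],
                      if (rows[[i]]$failed) "FAILED"
                      else sprintf("%.2f pN", rows[[i]]$mean_force_pN)))
  }
  structure(list(table = do.call(rbind, rows), records = records,
                 protocol = protocol, fragment = frag),
            class = "fec")
}

#' @export
print.fec <- function(x, ...) {
  cat(sprintf("force-extension curve: %d points, %d replicas/point, %g + %g ns\n",
              nrow(x$table), x$protocol$n_replicas,
              x$protocol$t_equil_ns, x$protocol$t_prod_ns))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.fec <- function(object, ...) {
  tab <- object$table
  cat(sprintf("FEC over Lx/L0 in [%.3f, %.3f]; force range %.1f .. %.1f pN\n",
              min(tab$mean_rel_ext, na.rm = TRUE),
              max(tab$mean_rel_ext, na.rm = TRUE),
              min(tab$mean_force_pN, na.rm = TRUE),
              max(tab$mean_force_pN, na.rm = TRUE)))
  if (any(tab$failed)) cat(sum(tab$failed), "failed point(s)\n")
  invisible(object)
}

#' @export
as.data.frame.fec <- function(x, ...) x$table

#' Simulate replicated stretching of a fragment
#'
#' `simulate()` method: convenience wrapper running [run_point()] at one
#' extension (`nsim` replicas).
#'
#' @param object A [dna_fragment()].
#' @param nsim Number of replicas.
#' @param seed Base seed.
#' @param x Target `r/r0` of the one-phase start (default 1.0).
#' @param ... Further arguments to [stretch_protocol()].
#' @return A `"point_record"`.
#' @export
simulate.dna_fragment <- function(object, nsim = 3, seed = NULL,
                                  x = 1.0, ...) {
  prot <- stretch_protocol(x_grid = x, n_replicas = nsim, seed = seed, ...)
  run_point(object, x, prot)
}
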