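# Deterministic equilibrium references: the zero-temperature quasi-static
# force-extension curve (convex-hull / Maxwell construction applied bond
# by bond) and the fixed-force Boltzmann distribution of a single bond.

#' Quasi-static force-extension curve from the convex hull
#'
#' Replaces every bond's potential by its lower convex envelope and
#' computes the zero-temperature force at an imposed total extension by
#' the common-force construction across the series chain: at force `f`
#' each bond sits at the extension where the hull's slope equals `f`, and
#' each distinct hull slope (one per segment type) produces a flat
#' plateau.  Bending and thermal fluctuations are ignored, so this is the
#' stiff, slowly-stretched limit the simulation should approach.
#'
#' @param frag A [dna_fragment()].
#' @param x_grid Relative extensions `Lx/L0` to evaluate (default
#'   0.8 to 2.0 by 0.005).
#' @return An object of class `"quasi_static_fec"`: list with `table`
#'   (data frame `x`, `force_pN`, non-decreasing) and `plateaus` (data
#'   frame `force_pN`, `x_from`, `x_to`).
#' @examples
#' qs <- quasi_static_fec(fragment_preset("AT-GC"))
#' qs$plateaus   # two plateaus near 34.9 and 74.6 pN
#' @export
quasi_static_fec <- function(frag, x_grid = seq(0.8, 2.0, by = 0.005)) {
  stopifnot(inherits(frag, "dna_fragment"))
  kBT <- kBT_pN_A(300)
  segs <- table(frag$bond_segment)
  nb <- frag$n_beads - 1L
  par <- lapply(names(segs), function(nm) {
    p <- frag$segments[[nm]]
    list(n = as.integer(segs[[nm]]), r0 = p$r0,
         ra = p$ra_ratio * p$r0, rb = p$rb_ratio * p$r0,
         kl = p$S / p$r0 / kBT, kr = p$S / p$r0 / kBT,
         fp = (p$S / p$r0 / kBT) * (p$ra_ratio - 1) * p$r0)
  })
  fps <- sort(unique(vapply(par, `[[`, numeric(1), "fp")))

  # bond extension on the hull at force f (internal units); side resolves
  # the multivalued plateau point
  r_of_f <- function(p, f, side) {
    if (f < p$fp) p$r0 + f / p$kl
    else if (f > p$fp) p$rb + (f - p$fp) / p$kr
    else if (side == "left") p$ra else p$rb
  }
  x_of_f <- function(f, side) {
    sum(vapply(par, function(p) p$n * r_of_f(p, f, side), numeric(1))) /
      frag$L0
  }

  # force needed at the grid ends (strictly monotone away from plateaus)
  f_lo <- stats::uniroot(function(f) x_of_f(f, "left") - min(x_grid),
                         c(-50, max(fps) + 50), tol = 1e-12)$root
  f_hi <- stats::uniroot(function(f) x_of_f(f, "right") - max(x_grid),
                         c(f_lo, max(fps) + 500), tol = 1e-12)$root

  f_nodes <- sort(unique(c(seq(f_lo, f_hi, length.out = 400),
                           fps[fps >= f_lo & fps <= f_hi])))
  xs <- fs <- numeric(0)
  for (f in f_nodes) {
    if (f %in% fps) {
      xs <- c(xs, x_of_f(f, "left"), x_of_f(f, "right"))
      fs <- c(fs, f, f)
    } else {
      xs <- c(xs, x_of_f(f, "left"))
      fs <- c(fs, f)
    }
  }
  force <- stats::approx(xs, fs, xout = x_grid, rule = 2, ties = "ordered")$y
  plateaus <- do.call(rbind, lapply(fps, function(f)
    data.frame(force_pN = f * kBT,
               x_from = x_of_f(f, "left"), x_to = x_of_f(f, "right"))))
  structure(list(table = data.frame(x = x_grid, force_pN = force * kBT),
                 plateaus = plateaus),
            class = "quasi_static_fec")
}

#' @export
print.quasi_static_fec <- function(x, ...) {
  cat("quasi-static (convex hull) force-extension curve\n")
  cat("plateaus:\n")
  print(x$plateaus, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fixed-force Boltzmann distribution of a single bond
#'
#' The probability density of the bond length in the fixed-force (Gibbs)
#' ensemble, `rho(r) proportional to exp(-(U(r) - f r)/kBT)`, normalised
#' by trapezoidal quadrature on a bounded grid.  At the plateau force the
#' tilted potential is a symmetric double well and the density is bimodal
#' with modes near `ra` and `rb`; for a large chain at an imposed
#' extension inside the plateau, the per-bond distribution approaches
#' this fixed-force reference evaluated at the measured mean force.
#'
#' @param pot A [bond_potential()].
#' @param force_pN Applied force, pN (`>= 0`).
#' @param temperature Kelvin.
#' @param n_grid Quadrature grid size (default 1e4).
#' @param r_range Range of `r` in Angstrom (default `[0.5 r0, 1.1 rb]`).
#' @return An object of class `"bond_gibbs"`: list with `r` (Angstrom),
#'   `rel` (`r/r0`), `density` (per Angstrom), `density_rel` (per unit
#'   `r/r0`), `cdf`, and `modes` (in `r/r0`).
#' @export
single_bond_gibbs <- function(pot, force_pN, temperature = 300,
                              n_grid = 1e4, r_range = NULL) {
  stopifnot(inherits(pot, "bond_potential"), force_pN >= 0)
  kBT <- kBT_pN_A(temperature)
  r0 <- pot$params$r0
  if (is.null(r_range)) r_range <- c(0.5 * r0, 1.1 * pot$rb)
  r <- seq(r_range[1], r_range[2], length.out = n_grid)
  w <- -(pot$U(r) - (force_pN / kBT) * r)
  w <- w - max(w)
  dens <- exp(w)
  z <- sum((dens[-1] + dens[-n_grid]) / 2 * diff(r))
  if (!is.finite(z) || z <= 0)
    stop("quadrature failed; enlarge r_range", call. = FALSE)
  dens <- dens / z
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(r)))
  if (abs(cdf[n_grid] - 1) > 1e-3)
    warning("density not fully contained in r_range")
  structure(list(r = r, rel = r / r0, density = dens,
                 density_rel = dens * r0, cdf = cdf / cdf[n_grid],
                 force_pN = force_pN,
                 modes = find_peaks.default(r / r0, dens)),
            class = "bond_gibbs")
}

#' @export
print.bond_gibbs <- function(x, ...) {
  cat(sprintf("single-bond Gibbs density at f = %.2f pN; modes at r/r0 = %s\n",
              x$force_pN, paste(round(x$modes, 3), collapse = ", ")))
  invisible(x)
}

#' Kolmogorov-Smirnov distance between samples and a Gibbs reference
#'
#' @param samples_rel Relative bond-length samples (`r/r0`).
#' @param gibbs A [single_bond_gibbs()] object.
#' @return The sup distance between the empirical CDF and the model CDF.
#' @export
gibbs_ks <- function(samples_rel, gibbs) {
  stopifnot(inherits(gibbs, "bond_gibbs"))
  s <- sort(samples_rel)
  mod <- stats::approx(gibbs$rel, gibbs$cdf, xout = s, rule = 2)$y
  emp_hi <- seq_along(s) / length(s)
  emp_lo <- (seq_along(s) - 1) / length(s)
  max(pmax(abs(emp_hi - mod), abs(emp_lo - mod)))
}
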