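# The nonconvex bond stretching potential, discrete-WLC bending and the
# optical trap.

#' Mechanical parameters of a dsDNA segment type
#'
#' A segment type is defined by six constants: stretch modulus `S` (pN),
#' equilibrium bond length `r0` (Angstrom), the boundaries `ra/r0 < rb/r0`
#' of the nonconvex region of the bond potential, the energy gap `delta`
#' (kBT) between the potential and its convex hull at the midpoint of that
#' region, and the persistence length `P` (Angstrom).  Three segment types
#' are built in (see [dna_segments()]): poly(dA-dT), poly(dG-dC) and
#' torsionally constrained lambda-phage DNA, whose common-tangent plateau
#' forces are about 35, 75 and 110 pN respectively.
#'
#' @param name Segment name.  If the remaining arguments are missing the
#'   name must match a built-in type (aliases `"AT"`, `"GC"`, `"lambda"`
#'   are accepted).
#' @param S Stretch modulus, pN.
#' @param r0 Equilibrium bond length, Angstrom.
#' @param ra_ratio,rb_ratio Start/end of the nonconvex region, as multiples
#'   of `r0`; must satisfy `1 < ra_ratio < rb_ratio`.
#' @param delta Hull gap at the midpoint, kBT; `>= 0`.
#' @param P Persistence length, Angstrom.
#' @return An object of class `"segment_params"`.
#' @examples
#' segment_params("poly(dA-dT)")
#' segment_params("custom", S = 1000, r0 = 37.18, ra_ratio = 1.05,
#'                rb_ratio = 1.8, delta = 5, P = 100)
#' @export
segment_params <- function(name, S, r0 = .r0_default, ra_ratio, rb_ratio,
                           delta, P) {
  if (missing(S)) {
    reg <- .segment_registry()
    key <- .canon_segment(name)
    if (is.na(key)) {
      stop("unknown segment type '", name, "'; built-ins: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    return(reg[[key]])
  }
  stopifnot(is.character(name), length(name) == 1)
  if (!(S > 0)) stop("S must be positive", call. = FALSE)
  if (!(r0 > 0)) stop("r0 must be positive", call. = FALSE)
  if (!(P > 0)) stop("P must be positive", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (!(ra_ratio > 1)) stop("ra_ratio must exceed 1", call. = FALSE)
  if (!(rb_ratio > ra_ratio))
    stop("rb_ratio must exceed ra_ratio", call. = FALSE)
  structure(list(name = name, S = S, r0 = r0, ra_ratio = ra_ratio,
                 rb_ratio = rb_ratio, delta = delta, P = P),
            class = "segment_params")
}

#' @export
print.segment_params <- function(x, ...) {
  cat("dsDNA segment type:", x$name, "\n")
  cat(sprintf("  S = %g pN, r0 = %g A, ra/r0 = %g, rb/r0 = %g\n",
              x$S, x$r0, x$ra_ratio, x$rb_ratio))
  cat(sprintf("  delta = %g kBT, P = %g A, plateau force = %.1f pN\n",
              x$delta, x$P, x$S * (x$ra_ratio - 1)))
  invisible(x)
}

#' Built-in segment parameter registry
#'
#' The three segment types used throughout, as a data frame (one row per
#' type).  poly(dA-dT) and poly(dG-dC) are torsionally unconstrained;
#' the lambda-DNA parameter set describes torsionally constrained
#' lambda-phage dsDNA.
#'
#' @return A data frame with columns `name, S, r0, ra_ratio, rb_ratio,
#'   delta, P`.
#' @export
dna_segments <- function() {
  reg <- .segment_registry()
  do.call(rbind, lapply(reg, function(p)
    data.frame(name = p$name, S = p$S, r0 = p$r0, ra_ratio = p$ra_ratio,
               rb_ratio = p$rb_ratio, delta = p$delta, P = p$P)))
}

.segment_registry <- function() {
  list(
    "poly(dA-dT)" = structure(list(name = "poly(dA-dT)", S = 944,
      r0 = .r0_default, ra_ratio = 1.037, rb_ratio = 2.0, delta = 2,
      P = 95.4), class = "segment_params"),
    "poly(dG-dC)" = structure(list(name = "poly(dG-dC)", S = 1864,
      r0 = .r0_default, ra_ratio = 1.04, rb_ratio = 1.7, delta = 12,
      P = 41.9), class = "segment_params"),
    "lambda-DNA" = structure(list(name = "lambda-DNA", S = 1191,
      r0 = .r0_default, ra_ratio = 1.093, rb_ratio = 1.7, delta = 4,
      P = 616), class = "segment_params")
  )
}

.canon_segment <- function(name) {
  key <- tolower(gsub("[^a-z]", "", tolower(name)))
  map <- c(polydadt = "poly(dA-dT)", at = "poly(dA-dT)",
           polydgdc = "poly(dG-dC)", gc = "poly(dG-dC)",
           lambdadna = "lambda-DNA", lambda = "lambda-DNA")
  if (key %in% names(map)) map[[key]] else NA_character_
}

#' Build the nonconvex bond stretching potential
#'
#' Constructs the piecewise potential `U(r)` for one bond type:
#' a harmonic branch `(S / 2 r0) (r - r0)^2` for `r <= ra`; for
#' `ra <= r <= rb` the tangent line to the harmonic branch at `ra` plus a
#' smooth bump `delta * B(s)` with `s = (r - ra)/(rb - ra)`,
#' `B(s) = sin^2(pi s)` by default; and for `r >= rb` a convex
#' continuation with continuous value and slope and curvature `S/r0`
#' (configurable).  The lower convex envelope of `U` over `[ra, rb]` is the
#' tangent line itself, so the Maxwell (common-tangent) plateau force is
#' `S (ra/r0 - 1)`.
#'
#' @param params A [segment_params()] object.
#' @param right_curvature Curvature of the `r >= rb` branch in pN/Angstrom;
#'   defaults to `S/r0`, the same stiffness as the B-form branch.
#' @param bump The bump shape on the nonconvex region; `"sin2"` (default)
#'   is `sin^2(pi s)`, or supply a function of `s` on `[0, 1]` with
#'   `B(0) = B(1) = 0`, `B'(0) = B'(1) = 0` and `B(1/2) = 1`.
#' @return An object of class `"bond_potential"` with elements `params`,
#'   `ra`, `rb` (Angstrom), `f_plateau` (pN), and vectorised functions
#'   `U(r)` (kBT) and `force(r)` (`-dU/dr`, pN).
#' @examples
#' pot <- bond_potential(segment_params("poly(dA-dT)"))
#' pot$f_plateau                    # ~34.9 pN
#' pot$U(pot$params$r0)             # 0
#' @export
bond_potential <- function(params, right_curvature = NULL, bump = "sin2") {
  stopifnot(inherits(params, "segment_params"))
  kBT <- kBT_pN_A(300)
  r0 <- params$r0
  ra <- params$ra_ratio * r0
  rb <- params$rb_ratio * r0
  kl <- params$S / r0 / kBT             # kBT/A^2
  kr <- if (is.null(right_curvature)) kl else right_curvature / kBT
  dl <- params$delta
  fp <- kl * (ra - r0)                  # kBT/A
  ua <- 0.5 * kl * (ra - r0)^2
  ub <- ua + fp * (rb - ra)

  if (is.character(bump) && identical(bump, "sin2")) {
    Bfun <- function(s) sin(pi * s)^2
    dBfun <- function(s) pi * sin(2 * pi * s)
  } else if (is.function(bump)) {
    Bfun <- bump
    dBfun <- function(s) {
      h <- 1e-6
      (Bfun(pmin(s + h, 1)) - Bfun(pmax(s - h, 0))) /
        (pmin(s + h, 1) - pmax(s - h, 0))
    }
    chk <- abs(c(Bfun(0), Bfun(1), Bfun(0.5) - 1))
    if (any(chk > 1e-8))
      stop("bump must satisfy B(0) = B(1) = 0 and B(1/2) = 1", call. = FALSE)
  } else stop("bump must be \"sin2\" or a function", call. = FALSE)

  U <- function(r) {
    ifelse(r <= ra, 0.5 * kl * (r - r0)^2,
      ifelse(r < rb,
        ua + fp * (r - ra) + dl * Bfun((r - ra) / (rb - ra)),
        ub + fp * (r - rb) + 0.5 * kr * (r - rb)^2))
  }
  force <- function(r) {
    du <- ifelse(r <= ra, kl * (r - r0),
      ifelse(r < rb,
        fp + dl * dBfun((r - ra) / (rb - ra)) / (rb - ra),
        fp + kr * (r - rb)))
    -du * kBT
  }
  structure(list(params = params, ra = ra, rb = rb,
                 f_plateau = params$S * (params$ra_ratio - 1),
                 U = U, force = force,
                 kl_int = kl, kr_int = kr),
            class = "bond_potential")
}

#' @export
print.bond_potential <- function(x, ...) {
  cat("Nonconvex bond potential for", x$params$name, "\n")
  cat(sprintf("  nonconvex region: %.2f .. %.2f A (r/r0 %.3f .. %.3f)\n",
              x$ra, x$rb, x$params$ra_ratio, x$params$rb_ratio))
  cat(sprintf("  hull gap delta = %g kBT, plateau force = %.2f pN\n",
              x$params$delta, x$f_plateau))
  invisible(x)
}

# Lower convex hull (Andrew monotone chain) of points sorted by x.
# Returns indices of hull vertices.
.lower_hull <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      j <- hull[length(hull)]
      k <- hull[length(hull) - 1]
      # drop j if it lies above the chord k -> i
      cross <- (x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Plateau force from the numerical convex hull
#'
#' Computes the overstretching plateau force of a bond potential as the
#' slope of the linear portion of the lower convex envelope of `U(r)`,
#' evaluated by brute force on a dense grid (the Maxwell construction).
#' This is independent of the analytic shortcut `S (ra/r0 - 1)`.
#'
#' @param pot A [bond_potential()] object.
#' @param n_grid Number of grid points (default `1e4`).
#' @return Plateau force in pN.
#' @examples
#' plateau_force(bond_potential(segment_params("poly(dG-dC)")))  # ~74.6
#' @export
plateau_force <- function(pot, n_grid = 1e4) {
  stopifnot(inherits(pot, "bond_potential"))
  r0 <- pot$params$r0
  r <- seq(0.5 * r0, 1.1 * pot$rb, length.out = n_grid)
  u <- pot$U(r)
  h <- .lower_hull(r, u)
  # widest hull edge spans the nonconvex region
  gaps <- diff(r[h])
  j <- which.max(gaps)
  slope <- (u[h[j + 1]] - u[h[j]]) / (r[h[j + 1]] - r[h[j]])
  slope * kBT_pN_A(300)
}

#' Discrete worm-like-chain bending energy
#'
#' Harmonic bending energy `(K/2) (pi - phi)^2` of one interior angle,
#' with `K = P kBT / r0`.  `phi` is the angle at a bead between the vectors
#' to its two neighbours; `phi = pi` is a straight chain and costs nothing.
#' For small deviations this matches the Kratky-Porod form
#' `(P kBT / r0) (1 - cos(pi - phi))` to fourth order.
#'
#' @param phi Interior angle in radians, in `[0, pi]`.  Vectorised.
#' @param P Persistence length, Angstrom.
#' @param r0 Bond length scale, Angstrom.
#' @return Bending energy in kBT.
#' @export
bending_energy <- function(phi, P, r0 = .r0_default) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > pi + 1e-12))
    stop("phi must be a finite angle in [0, pi]", call. = FALSE)
  0.5 * (P / r0) * (pi - phi)^2
}

#' Interior angle at a bead
#'
#' The angle at bead `b` between the vectors `b -> a` and `b -> c`.
#' Errors if either neighbour coincides with `b` (angle undefined).
#'
#' @param a,b,c Coordinate triples (numeric length-3 vectors), Angstrom.
#' @return Angle in radians, in `[0, pi]`.
#' @export
interior_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-10 || nv < 1e-10)
    stop("angle undefined: coincident beads", call. = FALSE)
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Optical-trap force
#'
#' The trap is a harmonic spring of stiffness `k_trap` between the last
#' bead and a fixed anchor, with equilibrium length `r_eql = 5 r0`.  The
#' energy is `(k_trap / 2) (r_d - r_eql)^2`; the force reported is
#' `k_trap (r_d - r_eql)`, positive when the spring is stretched.
#'
#' @param r_d Bead-anchor distance, Angstrom.  Vectorised.
#' @param k_trap Trap stiffness, kBT/Angstrom^2.
#' @param r_eql Trap equilibrium length, Angstrom (default `5 * 37.18`).
#' @param temperature Kelvin, for the kBT -> pN conversion.
#' @return Force in pN.
#' @examples
#' trap_force(5 * 37.18, 6.129)        # 0 at the equilibrium length
#' trap_force(5 * 37.18 + 1, 6.129)    # ~253.9 pN per Angstrom
#' @export
trap_force <- function(r_d, k_trap, r_eql = 5 * .r0_default,
                       temperature = 300) {
  if (any(r_d < 0)) stop("r_d must be >= 0", call. = FALSE)
  k_trap * (r_d - r_eql) * kBT_pN_A(temperature)
}
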