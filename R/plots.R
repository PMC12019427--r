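# Base-graphics plot methods.

#' Plot a simulated force-extension curve
#'
#' Mean trap force against mean relative extension with s.e.m. error
#' bars; optionally overlays the quasi-static convex-hull reference.
#'
#' @param x An object of class `"fec"`.
#' @param oracle Optional [quasi_static_fec()] to overlay.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fec <- function(x, oracle = NULL, ...) {
  tab <- x$table[!x$table$failed, ]
  graphics::plot(tab$mean_rel_ext, tab$mean_force_pN,
                 xlab = expression(L[x] / L[0]),
                 ylab = "trap force (pN)", pch = 19, ...)
  ok <- !is.na(tab$sem_force_pN) & tab$sem_force_pN > 0
  if (any(ok))
    graphics::arrows(tab$mean_rel_ext[ok],
                     tab$mean_force_pN[ok] - tab$sem_force_pN[ok],
                     tab$mean_rel_ext[ok],
                     tab$mean_force_pN[ok] + tab$sem_force_pN[ok],
                     angle = 90, code = 3, length = 0.02)
  if (!is.null(oracle))
    graphics::lines(oracle$table$x, oracle$table$force_pN,
                    col = "grey40", lty = 2)
  invisible(x)
}

#' Plot a nonconvex bond potential and its convex hull
#'
#' @param x A [bond_potential()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bond_potential <- function(x, ...) {
  r0 <- x$params$r0
  r <- seq(0.85 * r0, 1.08 * x$rb, length.out = 600)
  u <- x$U(r)
  graphics::plot(r / r0, u, type = "l", col = "blue",
                 xlab = expression(r / r[0]), ylab = "U (kBT)", ...)
  # hull: harmonic branch up to ra, tangent across, right branch after rb
  hull <- ifelse(r <= x$ra, u,
            ifelse(r >= x$rb, u,
              x$U(x$ra) + (x$f_plateau / kBT_pN_A(300)) * (r - x$ra)))
  graphics::lines(r / r0, hull, col = "grey50", lty = 2)
  graphics::abline(v = c(x$ra, x$rb) / r0, col = "grey80", lty = 3)
  invisible(x)
}

#' Plot a bond-length histogram
#'
#' @param x A [bond_histogram()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bond_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h",
                 xlab = expression(r / r[0]), ylab = expression(rho), ...)
  invisible(x)
}

#' Plot a single-bond Gibbs density
#'
#' @param x A [single_bond_gibbs()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bond_gibbs <- function(x, ...) {
  graphics::plot(x$rel, x$density_rel, type = "l",
                 xlab = expression(r / r[0]), ylab = expression(rho), ...)
  invisible(x)
}
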