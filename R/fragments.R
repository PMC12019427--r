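# Composite 99-bead fragments: per-bond segment assignment, per-angle
# bending constants and the derived Langevin friction and trap stiffness.

#' Build a composite dsDNA fragment
#'
#' A fragment is a chain of `n_beads = 99` beads joined by 98 bonds, each
#' bond carrying the parameters of one segment type, plus a trap between
#' the last bead and a fixed anchor.  With 11 bp per bead the fragment is
#' `98 * 11 = 1078` base pairs and the contour length is
#' `L0 = 98 * r0 = 3643.6` Angstrom.
#'
#' Interior angles sitting on a junction between two segment types take a
#' persistence length according to `angle_policy`: the mean of the two
#' adjacent bonds' `P` (default), the left bond's, or the smaller.
#'
#' The Langevin collision frequency `gamma` and trap stiffness `k_trap`
#' are derived from the `S` and `r0` of one *governing* segment
#' (`gamma = 1/Tp` with `Tp` the oscillation period of a bead on the
#' harmonic branch; `k_trap = 10 S / r0`); see [derive_gamma()] and
#' [derive_ktrap()].
#'
#' @param layout A data frame with columns `segment` and `bonds`, or a list
#'   of `list(segment =, bonds =)` entries; bond counts must sum to 98.
#'   Segment names are looked up in the built-in registry unless supplied
#'   via `segments`.
#' @param segments Optional named list of [segment_params()] objects for
#'   custom segment types.
#' @param governing Name of the segment whose `S`, `r0` set `gamma` and
#'   `k_trap`; default is the first segment in the layout.
#' @param gamma,k_trap Optional explicit overrides (ps^-1 and kBT/A^2).
#' @param angle_policy Junction-angle persistence length rule.
#' @param P_override If given, every interior angle uses this persistence
#'   length (Angstrom) regardless of the bond assignment (used by the
#'   alternating construct).
#' @param n_beads Number of beads (default 99).
#' @return An object of class `"dna_fragment"`.
#' @examples
#' frag <- dna_fragment(data.frame(
#'   segment = c("poly(dA-dT)", "poly(dG-dC)"), bonds = c(49, 49)))
#' frag$bp_total   # 1078
#' @seealso [fragment_preset()], [build_alternating()]
#' @export
dna_fragment <- function(layout, segments = NULL, governing = NULL,
                         gamma = NULL, k_trap = NULL,
                         angle_policy = c("mean", "left", "min"),
                         P_override = NULL, n_beads = 99L) {
  angle_policy <- match.arg(angle_policy)
  if (is.data.frame(layout)) {
    layout <- lapply(seq_len(nrow(layout)), function(i)
      list(segment = as.character(layout$segment[i]),
           bonds = layout$bonds[i]))
  }
  nb <- n_beads - 1L
  counts <- vapply(layout, function(e) as.integer(e$bonds), integer(1))
  if (any(counts < 1)) stop("each layout entry needs >= 1 bond", call. = FALSE)
  if (sum(counts) != nb)
    stop("bond counts sum to ", sum(counts), ", need ", nb, call. = FALSE)

  resolve <- function(nm) {
    if (!is.null(segments) && nm %in% names(segments)) {
      p <- segments[[nm]]
      stopifnot(inherits(p, "segment_params"))
      return(p)
    }
    segment_params(nm)
  }
  seg_names <- vapply(layout, function(e) e$segment, character(1))
  seg_list <- lapply(unique(seg_names), resolve)
  names(seg_list) <- vapply(seg_list, function(p) p$name, character(1))
  canon <- vapply(seg_names, function(nm) resolve(nm)$name, character(1),
                  USE.NAMES = FALSE)

  bond_segment <- rep(canon, counts)
  r0 <- seg_list[[bond_segment[1]]]$r0
  if (!all(vapply(seg_list, function(p) p$r0, numeric(1)) == r0))
    stop("all segments in one fragment must share r0", call. = FALSE)

  bond_P <- vapply(bond_segment, function(nm) seg_list[[nm]]$P, numeric(1),
                   USE.NAMES = FALSE)
  angle_P <- switch(angle_policy,
    mean = (bond_P[-nb] + bond_P[-1]) / 2,
    left = bond_P[-nb],
    min  = pmin(bond_P[-nb], bond_P[-1]))
  if (!is.null(P_override)) angle_P <- rep(P_override, nb - 1L)

  if (is.null(governing)) governing <- canon[1]
  gov <- resolve(governing)
  if (is.null(gamma)) gamma <- derive_gamma(gov)
  if (is.null(k_trap)) k_trap <- derive_ktrap(gov)

  # contiguous same-segment ranges (beads), for per-segment analysis
  runs <- rle(bond_segment)
  ends <- cumsum(runs$lengths)
  ranges <- data.frame(segment = runs$values,
                       first_bead = c(1L, head(ends, -1) + 1L),
                       last_bead = ends + 1L,
                       bonds = runs$lengths,
                       stringsAsFactors = FALSE)

  structure(list(
    n_beads = as.integer(n_beads),
    layout = data.frame(segment = canon, bonds = counts,
                        stringsAsFactors = FALSE),
    segments = seg_list,
    bond_segment = bond_segment,
    angle_P = angle_P,
    governing = gov$name,
    gamma = gamma,            # ps^-1
    k_trap = k_trap,          # kBT/A^2
    r_eql = 5 * r0,
    r0 = r0,
    L0 = nb * r0,
    bp_total = nb * 11L,
    segment_ranges = ranges
  ), class = "dna_fragment")
}

#' @export
print.dna_fragment <- function(x, ...) {
  cat(sprintf("dsDNA fragment: %d beads, %d bonds, %d bp, L0 = %.1f A\n",
              x$n_beads, x$n_beads - 1L, x$bp_total, x$L0))
  lay <- aggregate(bonds ~ segment, data = x$layout, sum)
  for (i in seq_len(nrow(lay)))
    cat(sprintf("  %-22s %2d bonds\n", lay$segment[i], lay$bonds[i]))
  cat(sprintf("  gamma = %.4g ps^-1, K_trap = %.4g kBT/A^2 (from %s)\n",
              x$gamma, x$k_trap, x$governing))
  invisible(x)
}

#' @export
summary.dna_fragment <- function(object, ...) {
  print(object)
  cat("segment ranges (beads):\n")
  print(object$segment_ranges, row.names = FALSE)
  invisible(object)
}

#' Named fragment presets
#'
#' The six constructs studied with this model:
#' \describe{
#'   \item{`"poly(dA-dT)"`, `"poly(dG-dC)"`}{single-segment fragments
#'     (98 bonds of one type) with one overstretching plateau.}
#'   \item{`"poly(dA-dT)-poly(dG-dC)"`}{first half AT, second half GC
#'     (49/49 bonds); two plateaus.}
#'   \item{`"lambda-DNA-poly(dG-dC)"`}{first half lambda, second half GC
#'     (49/49); two plateaus.}
#'   \item{`"poly(dA-dT)-lambda-DNA-poly(dG-dC)"`}{32/33/33 bonds
#'     (about 32.65/33.67/33.67% of the length); three plateaus.}
#'   \item{`"alternating"`}{AT and GC bonds alternating one by one
#'     (49 each), whole-chain persistence length 95.4 Angstrom.}
#' }
#' `gamma`/`K_trap` are derived from the governing segment used for each
#' construct: AT for the AT-containing two-segment and alternating
#' fragments, lambda for the three-segment fragment, and -- as tabulated
#' for that construct -- also AT for the lambda-GC fragment, even though
#' poly(dA-dT) is not part of it.
#'
#' @param name Preset name; short aliases `"AT"`, `"GC"`, `"AT-GC"`,
#'   `"lambda-GC"`, `"AT-lambda-GC"`, `"alternating"` work too.
#' @param ... Passed on to [dna_fragment()] / [build_alternating()]
#'   (e.g. `angle_policy`).
#' @return A `"dna_fragment"`.
#' @examples
#' fragment_preset("AT-GC")
#' @export
fragment_preset <- function(name, ...) {
  key <- gsub("[^a-z]", "", tolower(name))
  AT <- "poly(dA-dT)"; GC <- "poly(dG-dC)"; LAM <- "lambda-DNA"
  lay <- function(...) {
    e <- list(...)
    data.frame(segment = vapply(e, `[[`, "", 1),
               bonds = as.integer(vapply(e, `[[`, "", 2)))
  }
  switch(key,
    polydadt = , at =
      dna_fragment(lay(c(AT, 98)), governing = AT, ...),
    polydgdc = , gc =
      dna_fragment(lay(c(GC, 98)), governing = GC, ...),
    polydadtpolydgdc = , atgc =
      dna_fragment(lay(c(AT, 49), c(GC, 49)), governing = AT, ...),
    lambdadnapolydgdc = , lambdagc =
      dna_fragment(lay(c(LAM, 49), c(GC, 49)), governing = AT, ...),
    polydadtlambdadnapolydgdc = , atlambdagc =
      dna_fragment(lay(c(AT, 32), c(LAM, 33), c(GC, 33)),
                   governing = LAM, ...),
    alternatingpolydadtpolydgdc = , alternating =
      build_alternating(...),
    stop("unknown preset '", name, "'", call. = FALSE)
  )
}

#' Alternating-segment fragment
#'
#' Bonds alternate between two segment types in blocks of
#' `block_len` bonds (default 1 bond = 11 bp), giving an equal fraction of
#' each type.  The whole-fragment persistence length is overridden
#' (default 95.4 Angstrom for the alternating AT/GC construct).  If the
#' block length does not evenly tile the 98 bonds the last block is
#' truncated with a warning.
#'
#' @param blockA,blockB Segment names.
#' @param block_len Block length in bonds.
#' @param P_override Persistence length applied to every angle, Angstrom.
#' @param ... Passed to [dna_fragment()].
#' @return A `"dna_fragment"`.
#' @export
build_alternating <- function(blockA = "poly(dA-dT)", blockB = "poly(dG-dC)",
                              block_len = 1L, P_override = 95.4, ...) {
  nb <- 98L
  block_len <- as.integer(block_len)
  stopifnot(block_len >= 1)
  if (nb %% (2L * block_len) != 0L)
    warning("block length ", block_len, " does not tile ", nb,
            " bonds evenly; last block truncated")
  pattern <- rep(rep(c(blockA, blockB), each = block_len),
                 length.out = nb)
  runs <- rle(pattern)
  layout <- data.frame(segment = runs$values, bonds = runs$lengths)
  dna_fragment(layout, governing = blockA, P_override = P_override, ...)
}

#' Reverse the segment order of a fragment
#'
#' Used to check that segment order has little effect on the
#' force-extension curve: the reversed fragment has exactly the permuted
#' bond assignment.
#'
#' @param frag A `"dna_fragment"`.
#' @return A `"dna_fragment"` with the layout reversed.
#' @export
reverse_fragment <- function(frag) {
  stopifnot(inherits(frag, "dna_fragment"))
  layout <- frag$layout[rev(seq_len(nrow(frag$layout))), , drop = FALSE]
  dna_fragment(layout, segments = frag$segments, governing = frag$governing,
               gamma = frag$gamma, k_trap = frag$k_trap)
}

#' Langevin collision frequency from the bead oscillation period
#'
#' `gamma = 1/Tp`, where `Tp = 2 pi sqrt(m r0 / S)` is the period of a
#' bead of mass `m` on the harmonic branch of the bond potential
#' (stiffness `S/r0`).  Deliberately far below the aqueous friction, to
#' speed conformational sampling.
#'
#' @param params A [segment_params()] object (uses its `S` and `r0`).
#' @param mass Bead mass in Da (default 7150).
#' @return Collision frequency in ps^-1.
#' @examples
#' derive_gamma(segment_params("poly(dA-dT)"))   # ~0.0233 ps^-1
#' @export
derive_gamma <- function(params, mass = .bead_mass) {
  stopifnot(inherits(params, "segment_params"))
  # Tp in seconds: 2 pi sqrt(m_kg * r0_m / S_N)
  Tp <- 2 * pi * sqrt(mass * .amu_kg * params$r0 * 1e-10 / (params$S * 1e-12))
  1 / (Tp * 1e12)
}

#' Optical-trap stiffness from the segment stiffness
#'
#' `K_trap = 10 S / r0`, ten times the harmonic-branch bond stiffness, so
#' the trap is much stiffer than the chain and the protocol approximates
#' an isometric (fixed-extension) experiment.
#'
#' @inheritParams derive_gamma
#' @param temperature Kelvin, for the pN -> kBT conversion.
#' @return Trap stiffness in kBT/Angstrom^2.
#' @examples
#' derive_ktrap(segment_params("poly(dA-dT)"))   # ~6.13 kBT/A^2
#' @export
derive_ktrap <- function(params, temperature = 300) {
  stopifnot(inherits(params, "segment_params"))
  10 * params$S / params$r0 / kBT_pN_A(temperature)
}

#' Per-bond manifest of a fragment
#'
#' @param frag A `"dna_fragment"`.
#' @return A data frame with one row per bond: `bond`, `segment`,
#'   `S_pN`, `ra_ratio`, `rb_ratio`, `delta_kBT`, `P_A`.
#' @export
fragment_manifest <- function(frag) {
  stopifnot(inherits(frag, "dna_fragment"))
  seg <- frag$bond_segment
  getp <- function(f) vapply(seg, function(nm) f(frag$segments[[nm]]),
                             numeric(1))
  data.frame(bond = seq_along(seg), segment = seg,
             S_pN = getp(function(p) p$S),
             ra_ratio = getp(function(p) p$ra_ratio),
             rb_ratio = getp(function(p) p$rb_ratio),
             delta_kBT = getp(function(p) p$delta),
             P_A = getp(function(p) p$P),
             row.names = NULL)
}
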