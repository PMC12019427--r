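# Observables: bond-length distributions and their peaks, per-segment
# extensions and extension shares, and macroscopic-phase classification.

#' Density-normalised histogram of relative bond lengths
#'
#' 200 equal-width bins over the observed range (matching the convention
#' used for the reference distributions), normalised so the area under
#' the histogram is 1.
#'
#' @param samples Numeric vector of `r/r0` values (e.g. pooled from a
#'   [run_point()] record's `bond_samples`).
#' @param bins Number of bins (default 200).
#' @return An object of class `"bond_histogram"`: list with `breaks`,
#'   `mids`, `density`, `counts`, `bin_width`.
#' @export
bond_histogram <- function(samples, bins = 200) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) stop("no samples", call. = FALSE)
  rng <- range(samples)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(1e-6, abs(rng[1]) * 1e-6)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 counts = h$counts, bin_width = diff(h$breaks[1:2]),
                 n = length(samples)),
            class = "bond_histogram")
}

#' @export
print.bond_histogram <- function(x, ...) {
  cat(sprintf("bond_histogram: %d samples, %d bins over [%.3f, %.3f]\n",
              x$n, length(x$mids), min(x$breaks), max(x$breaks)))
  pk <- find_peaks(x)
  if (length(pk)) cat("  peaks at r/r0 =", paste(round(pk, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Locate peaks of a density
#'
#' Local maxima above a prominence threshold (a fraction of the global
#' maximum).  Peaks closer than `merge_bins` bin widths are merged into
#' one (the taller survives), mirroring the observation that nearby peaks
#' of different segments blend into one broader peak.
#'
#' @param x A `"bond_histogram"`, or a numeric vector of locations (then
#'   supply `y`).
#' @param ... Passed to methods.
#' @return Numeric vector of peak locations (possibly empty).
#' @export
find_peaks <- function(x, ...) UseMethod("find_peaks")

#' @rdname find_peaks
#' @param y Density values matching the locations `x`.
#' @param prominence Minimum topographic prominence of a peak (height
#'   above the higher of its flanking saddles), as a fraction of the
#'   maximum density (default 0.05); suppresses sampling-noise maxima.
#' @param merge_bins Merge radius in units of the grid spacing (default 2).
#' @export
find_peaks.default <- function(x, y, prominence = 0.05, merge_bins = 2, ...) {
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (n < 3) return(x[which.max(y)])
  cand <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, logical(1)))
  prom <- vapply(cand, function(i) {
    yi <- y[i]
    lmin <- Inf; j <- i - 1
    while (j >= 1 && y[j] <= yi) { lmin <- min(lmin, y[j]); j <- j - 1 }
    rmin <- Inf; j <- i + 1
    while (j <= n && y[j] <= yi) { rmin <- min(rmin, y[j]); j <- j + 1 }
    base <- c(lmin, rmin)
    base <- base[is.finite(base)]     # a side that runs off the grid
    if (length(base) == 0) return(yi) # counts as fully prominent
    yi - max(base)
  }, numeric(1))
  keep_cand <- prom >= prominence * max(y)
  locs <- x[cand[keep_cand]]
  hts <- y[cand[keep_cand]]
  if (length(locs) <= 1) return(locs)
  width <- merge_bins * stats::median(diff(x))
  ord <- order(hts, decreasing = TRUE)
  keep <- logical(length(locs))
  for (i in ord) {
    if (!any(keep & abs(locs - locs[i]) < width)) keep[i] <- TRUE
  }
  sort(locs[keep])
}

#' @rdname find_peaks
#' @param smooth_bins Boxcar width (bins) applied to the sampled density
#'   before locating maxima (histogram method only; default 5).  Sampled
#'   histograms carry per-bin counting noise that makes the raw argmax of
#'   a broad or flat-topped mode wander by several bins; a short symmetric
#'   boxcar leaves symmetric peak locations unbiased while suppressing
#'   that wander.  Set to 1 to disable.
#' @export
find_peaks.bond_histogram <- function(x, prominence = 0.05, merge_bins = 2,
                                      smooth_bins = 5, ...) {
  y <- x$density
  w <- as.integer(smooth_bins)
  if (w > 1) {
    half <- w %/% 2
    padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
    y <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
    y <- y[half + seq_along(x$density)]
  }
  find_peaks.default(x$mids, y, prominence, merge_bins)
}

#' Per-segment end-to-end x extensions
#'
#' The x distance between the boundary beads of each contiguous segment
#' range, time-averaged over production for a `"point_record"` (the
#' record already carries replica/time-averaged mean bead positions) or
#' instantaneous for a `"chain_state"`.
#'
#' @param obj A `"point_record"` or `"chain_state"`.
#' @param frag The [dna_fragment()] (required for a chain state).
#' @return Named numeric vector of extensions in Angstrom, one entry per
#'   contiguous segment range.
#' @export
segment_end_to_end <- function(obj, frag = NULL) {
  if (inherits(obj, "point_record")) return(obj$segment_extension_A)
  if (inherits(obj, "chain_state")) {
    stopifnot(inherits(frag, "dna_fragment"))
    rg <- frag$segment_ranges
    ext <- obj$positions[rg$last_bead, 1] - obj$positions[rg$first_bead, 1]
    names(ext) <- rg$segment
    return(ext)
  }
  stop("obj must be a point_record or chain_state", call. = FALSE)
}

#' Share of the total extension increment per segment
#'
#' Given per-segment extensions at some stretched state and at a reference
#' state (normally `Lx/L0` near 1.0), returns each segment's fraction of
#' the total increment:
#' `share_i = (ext_i - ref_i) / sum_j (ext_j - ref_j)`.  Fractions sum
#' to 1.
#'
#' @param ext,ext_ref Named numeric vectors from [segment_end_to_end()],
#'   with matching names.
#' @return Named fractions summing to 1.
#' @examples
#' extension_share(c(AT = 2840, GC = 1804), c(AT = 1872, GC = 1771))
#' # AT ~0.967
#' @export
extension_share <- function(ext, ext_ref) {
  if (length(ext) != length(ext_ref) ||
      !identical(names(ext), names(ext_ref)))
    stop("segment lists do not match", call. = FALSE)
  inc <- ext - ext_ref
  tot <- sum(inc)
  if (abs(tot) < 1e-9)
    stop("total extension increment is zero; share undefined", call. = FALSE)
  inc / tot
}

#' Classify segments into macroscopic phases versus mixed states
#'
#' Each bond is labelled "high" if its relative length exceeds a
#' threshold (default: the midpoint `(ra/r0 + rb/r0)/2` of that bond's
#' segment type) and "low" otherwise.  Within each contiguous segment
#' range, the state is called a *macroscopic phase* when the bonds are
#' (nearly) partitioned into at most two contiguous blocks: the largest
#' contiguous low run plus the largest contiguous high run must cover at
#' least `run_fraction` of the segment's bonds.  Interleaved labels give
#' a *mixed* state.
#'
#' @param rel_bonds Numeric vector of 98 relative bond lengths (one frame
#'   or a time average), or a frames x 98 matrix (then the per-bond time
#'   average is classified).
#' @param frag The [dna_fragment()].
#' @param threshold Scalar or length-98 vector overriding the per-segment
#'   midpoint cut.
#' @param run_fraction Coverage needed to call a macroscopic phase
#'   (default 0.9).
#' @return An object of class `"phase_segmentation"`: list with `labels`
#'   (factor low/high per bond), `runs` (data frame of contiguous runs)
#'   and `classification` (named character per segment range:
#'   `"macroscopic"` or `"mixed"`).
#' @export
classify_phases <- function(rel_bonds, frag, threshold = NULL,
                            run_fraction = 0.9) {
  stopifnot(inherits(frag, "dna_fragment"))
  if (is.matrix(rel_bonds)) rel_bonds <- colMeans(rel_bonds)
  nb <- frag$n_beads - 1L
  if (length(rel_bonds) != nb)
    stop("need ", nb, " bond values", call. = FALSE)
  if (is.null(threshold)) {
    threshold <- vapply(frag$bond_segment, function(nm) {
      p <- frag$segments[[nm]]
      (p$ra_ratio + p$rb_ratio) / 2
    }, numeric(1), USE.NAMES = FALSE)
  }
  labels <- factor(ifelse(rel_bonds > threshold, "high", "low"),
                   levels = c("low", "high"))
  rr <- rle(as.character(labels))
  ends <- cumsum(rr$lengths)
  runs <- data.frame(label = rr$values,
                     first_bond = c(1L, head(ends, -1) + 1L),
                     last_bond = ends, length = rr$lengths,
                     stringsAsFactors = FALSE)
  rg <- frag$segment_ranges
  cls <- character(nrow(rg))
  for (i in seq_len(nrow(rg))) {
    idx <- rg$first_bead[i]:(rg$last_bead[i] - 1L)
    lab <- as.character(labels[idx])
    r <- rle(lab)
    best_low <- max(c(0, r$lengths[r$values == "low"]))
    best_high <- max(c(0, r$lengths[r$values == "high"]))
    cls[i] <- if ((best_low + best_high) >= run_fraction * length(idx))
      "macroscopic" else "mixed"
  }
  names(cls) <- rg$segment
  structure(list(labels = labels, runs = runs, classification = cls,
                 threshold = threshold, run_fraction = run_fraction),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("phase segmentation:", sum(x$labels == "high"), "high /",
      sum(x$labels == "low"), "low bonds;",
      nrow(x$runs), "contiguous runs\n")
  for (i in seq_along(x$classification))
    cat(sprintf("  %-22s %s\n", names(x$classification)[i],
                x$classification[i]))
  invisible(x)
}

#' Pool bond samples of a point record by segment
#'
#' @param record A `"point_record"` with `bond_samples`.
#' @param frag The [dna_fragment()].
#' @return Named list of numeric vectors of `r/r0` samples, one per
#'   segment type (bonds of the same type pooled across ranges), plus an
#'   element `"(all)"` with every bond.
#' @export
segment_samples <- function(record, frag) {
  stopifnot(inherits(record, "point_record"), !is.null(record$bond_samples))
  m <- record$bond_samples
  out <- lapply(split(seq_along(frag$bond_segment), frag$bond_segment),
                function(idx) as.numeric(m[, idx]))
  out[["(all)"]] <- as.numeric(m)
  out
}
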