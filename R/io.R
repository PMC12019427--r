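# Run configuration files, output writing and trajectory export.
# All on-disk quantities are in user units (pN, Angstrom, ns, kBT) with
# unit suffixes in the headers.

#' Load a run configuration
#'
#' Reads a YAML configuration describing a run: the fragment (a preset
#' name, or a custom layout with optional custom segment types), protocol
#' and engine settings, the seed and the output directory.  Unknown keys
#' are rejected; defaults are resolved and recorded so the returned
#' config fully reproduces the run.
#'
#' Schema (all sections optional except `fragment`):
#' ```yaml
#' fragment:
#'   preset: poly(dA-dT)-poly(dG-dC)   # or: layout: [{segment:, bonds:}, ...]
#'   # segments: [{name:, S:, r0:, ra_ratio:, rb_ratio:, delta:, P:}, ...]
#' protocol: {x_grid: [1.275], t_equil_ns: 20, t_prod_ns: 100, n_replicas: 3}
#' engine:   {dt_fs: 100, temperature: 300}
#' seed: 1
#' output_dir: out
#' ```
#'
#' @param path Path to a YAML file.
#' @return An object of class `"run_config"`: list with `fragment`
#'   (a [dna_fragment()]), `protocol`, `engine`, `seed`, `output_dir`
#'   and `raw` (the resolved key-value echo).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("fragment", "protocol", "engine", "seed", "output_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(cfg$fragment))
    stop("config needs a 'fragment' section", call. = FALSE)

  segs <- NULL
  if (!is.null(cfg$fragment$segments)) {
    segs <- lapply(cfg$fragment$segments, function(s)
      segment_params(s$name, S = s$S, r0 = if (is.null(s$r0)) .r0_default
                     else s$r0, ra_ratio = s$ra_ratio,
                     rb_ratio = s$rb_ratio, delta = s$delta, P = s$P))
    names(segs) <- vapply(segs, function(p) p$name, character(1))
  }
  frag <- if (!is.null(cfg$fragment$preset)) {
    fragment_preset(cfg$fragment$preset)
  } else if (!is.null(cfg$fragment$layout)) {
    layout <- do.call(rbind, lapply(cfg$fragment$layout, function(e)
      data.frame(segment = e$segment, bonds = e$bonds)))
    dna_fragment(layout, segments = segs,
                 governing = cfg$fragment$governing,
                 gamma = cfg$fragment$gamma, k_trap = cfg$fragment$k_trap)
  } else stop("fragment needs 'preset' or 'layout'", call. = FALSE)

  seed <- cfg$seed
  if (is.null(seed)) seed <- sample.int(1000000L, 1)
  pr <- cfg$protocol
  prot_args <- pr[intersect(names(pr), c("x_grid", "t_equil_ns", "t_prod_ns",
                                         "n_replicas", "bond_sample_ns",
                                         "profile"))]
  if (!is.null(pr) && length(setdiff(names(pr), names(prot_args))))
    stop("unknown protocol keys: ",
         paste(setdiff(names(pr), names(prot_args)), collapse = ", "),
         call. = FALSE)
  if (!is.null(prot_args$x_grid)) prot_args$x_grid <- unlist(prot_args$x_grid)
  protocol <- do.call(stretch_protocol, c(prot_args, list(seed = seed)))
  en <- cfg$engine
  eng_args <- en[intersect(names(en), c("dt_fs", "temperature", "gamma"))]
  if (!is.null(en) && length(setdiff(names(en), names(eng_args))))
    stop("unknown engine keys: ",
         paste(setdiff(names(en), names(eng_args)), collapse = ", "),
         call. = FALSE)
  engine <- do.call(engine_config, c(eng_args, list(seed = seed)))

  raw <- cfg
  raw$seed <- seed
  structure(list(fragment = frag, protocol = protocol, engine = engine,
                 seed = seed,
                 output_dir = if (is.null(cfg$output_dir)) "out"
                 else cfg$output_dir,
                 raw = raw),
            class = "run_config")
}

#' Write a run configuration
#'
#' Serialises the resolved key-value echo of a config so that
#' `load_run_config(write_run_config(cfg, path))` reproduces the run.
#'
#' @param config A `"run_config"` (or the raw list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write simulation outputs
#'
#' Writes `fec.csv` (one row per curve point), `bonds_<x>.csv` files with
#' the recorded relative bond lengths where point records kept them, and
#' a JSON `manifest.json` echoing the configuration, seeds, package
#' version and timestamps.
#'
#' @param fec A [run_curve()] result (or a single `"point_record"`).
#' @param dir Output directory (created if needed).
#' @param config Optional `"run_config"` to echo into the manifest.
#' @return Character vector of written files, invisibly.
#' @export
write_run_outputs <- function(fec, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (inherits(fec, "point_record"))
    fec <- structure(list(table = data.frame(
      x_target = fec$x_target, mean_force_pN = fec$mean_force_pN,
      sem_force_pN = fec$sem_force_pN, mean_rel_ext = fec$mean_rel_ext,
      failed = FALSE), records = list(fec)), class = "fec")
  tab <- fec$table
  names(tab) <- c("x_target_r_over_r0", "mean_force_pN", "sem_force_pN",
                  "mean_rel_ext_Lx_over_L0", "failed")
  fp <- file.path(dir, "fec.csv")
  utils::write.csv(tab, fp, row.names = FALSE)
  files <- c(files, fp)
  for (rec in fec$records) {
    if (!inherits(rec, "point_record") || is.null(rec$bond_samples)) next
    m <- rec$bond_samples
    bf <- file.path(dir, sprintf("bonds_%.4g.csv", rec$x_target))
    df <- data.frame(
      frame = rep(seq_len(nrow(m)), times = ncol(m)),
      bond_index = rep(seq_len(ncol(m)), each = nrow(m)),
      r_over_r0 = as.numeric(m))
    utils::write.csv(df, bf, row.names = FALSE)
    files <- c(files, bf)
  }
  manifest <- list(
    package = "overstretch",
    version = as.character(utils::packageVersion("overstretch")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = basename(files),
    config = if (!is.null(config) && inherits(config, "run_config"))
      config$raw else config,
    seeds = lapply(fec$records, function(r)
      if (inherits(r, "point_record")) r$seeds else NULL))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mf)
  if (length(fec$records) == 0) warning("no records; manifest only")
  invisible(files)
}

#' Write an XYZ trajectory frame
#'
#' Standard XYZ dialect: bead count line, comment line, then one
#' `element x y z` line per bead (element "C"), coordinates in Angstrom.
#' Multiple states append as successive frames.
#'
#' @param states A `"chain_state"` or list of them.
#' @param path Output file.
#' @param comment Comment line prefix.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(states, path, comment = "overstretch frame") {
  if (inherits(states, "chain_state")) states <- list(states)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    p <- st$positions
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("%s t=%.4f ns", comment, st$time_ns), con)
    writeLines(sprintf("C %.4f %.4f %.4f", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}
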