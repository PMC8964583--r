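## Pipeline commands: reproducible orchestration of simulation,
## calibration, reconstruction, FTTC validation and moments with
## file-based I/O. Units at this boundary are lab units (um, kPa, nN,
## s); everything internal is SI. A thin command-line front end lives in
## inst/cli/tfm.R.

#' Read and validate an experiment configuration
#'
#' YAML (or JSON) with lab-unit fields: `substrate: {E_kPa, nu}`,
#' `pixel_size_um`, `frame_rate_fps`, `needle: {speed_um_s,
#' spring_constant_N_m}` (or `calibration` file paths), `piv: {window,
#' overlap, snr_min, nmt_threshold, nmt_epsilon}`, `windows` (list of
#' `{label, xmin_um, xmax_um, ymin_um, ymax_um}`), `paths: {stack,
#' reference, needle_track, pillar_track, out_dir}`, `seed`.
#'
#' @param path Config file path.
#' @return Config list with an added `si` element holding converted SI
#'   values.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$substrate$E_kPa), cfg$substrate$E_kPa > 0,
            !is.null(cfg$pixel_size_um), cfg$pixel_size_um > 0,
            !is.null(cfg$frame_rate_fps), cfg$frame_rate_fps > 0)
  nu <- if (is.null(cfg$substrate$nu)) 0.5 else cfg$substrate$nu
  cfg$si <- list(
    substrate = elastic_substrate(kpa_to_pa(cfg$substrate$E_kPa), nu),
    pixel_size = um_to_m(cfg$pixel_size_um),
    frame_rate = cfg$frame_rate_fps)
  if (!is.null(cfg$needle$speed_um_s)) {
    cfg$si$needle_speed <- um_to_m(cfg$needle$speed_um_s)
  }
  if (!is.null(cfg$windows)) {
    w <- do.call(rbind, lapply(cfg$windows, function(r) {
      data.frame(label = r$label,
                 xmin = um_to_m(r$xmin_um), xmax = um_to_m(r$xmax_um),
                 ymin = um_to_m(r$ymin_um), ymax = um_to_m(r$ymax_um))
    }))
    cfg$si$windows <- search_window_set(w)
  }
  p <- cfg$piv
  cfg$si$piv <- piv_settings(
    window = if (is.null(p$window)) 64L else p$window,
    overlap = if (is.null(p$overlap)) 0.5 else p$overlap,
    snr_min = if (is.null(p$snr_min)) 1.5 else p$snr_min,
    nmt_threshold = if (is.null(p$nmt_threshold)) 2.0 else p$nmt_threshold,
    nmt_epsilon = if (is.null(p$nmt_epsilon)) 0.1 else p$nmt_epsilon)
  cfg
}

## Provenance stamp written into every output directory.
.write_provenance <- function(out_dir, cfg, seed) {
  jsonlite::write_json(
    list(package = "shearTFM",
         version = as.character(utils::packageVersion("shearTFM")),
         seed = seed,
         convention = COORD_CONVENTION,
         config = cfg[setdiff(names(cfg), "si")]),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.read_stack_tiff <- function(path, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    bead_image(p, pixel_size)
  })
}

.write_stack_tiff <- function(images, path) {
  mx <- max(vapply(images, function(im) max(im$pixels), numeric(1)), 1)
  tiff::writeTIFF(lapply(images, function(im) im$pixels / mx), path,
                  bits.per.sample = 16L)
  invisible(mx)
}

.write_track_csv <- function(track, path, role) {
  df <- as.data.frame(track)
  df$role <- ifelse(df$reference, "reference", role)
  utils::write.csv(df[, c("frame", "time_s", "x_px", "y_px", "role")],
                   path, row.names = FALSE)
}

.read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  track_table(df$frame, df$time_s, df$x_px, df$y_px,
              df$role == "reference")
}

#' Simulate command: write a complete synthetic dataset
#'
#' Renders a built-in scenario to disk: bead image stack and reference
#' (16-bit TIFF), ground-truth force CSV, needle track CSV, search
#' window CSV, scenario JSON and provenance.
#'
#' @param out_dir Output directory (created).
#' @param type Scenario type passed to [default_scenario()].
#' @param n_frames,seed Scenario size and seed.
#' @param spec A [bead_field_spec()] (default small 384 px field).
#' @param substrate An [elastic_substrate()] (default 16.5 kPa, nu 0.5).
#' @return Invisibly, the simulation object from
#'   [simulate_shear_experiment()].
#' @export
cmd_simulate <- function(out_dir, type = "colinear", n_frames = 12L,
                         seed = 1L,
                         spec = bead_field_spec(n_beads = 2200L,
                                                image_shape = c(384L, 384L),
                                                seed = seed),
                         substrate = elastic_substrate(16.5e3)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen <- default_scenario(type, n_frames = n_frames, seed = seed)
  sim <- simulate_shear_experiment(scen, spec, substrate)
  .write_stack_tiff(sim$images, file.path(out_dir, "stack.tif"))
  .write_stack_tiff(list(sim$reference), file.path(out_dir, "reference.tif"))
  utils::write.csv(sim$truth_table, file.path(out_dir, "truth_forces.csv"),
                   row.names = FALSE)
  .write_track_csv(sim$needle_track, file.path(out_dir, "needle_track.csv"),
                   "needle")
  w <- as.data.frame(sim$windows)
  w[, -1] <- lapply(w[, -1], m_to_um)
  names(w) <- c("label", "xmin_um", "xmax_um", "ymin_um", "ymax_um")
  utils::write.csv(w, file.path(out_dir, "windows.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(type = type, n_frames = n_frames, seed = seed,
         frame_rate_fps = scen$frame_rate,
         k_needle_N_m = sim$k_needle,
         needle_speed_um_s = m_to_um(sim$needle_speed),
         pixel_size_um = m_to_um(spec$pixel_size),
         E_kPa = substrate$E / .kpa, nu = substrate$nu),
    file.path(out_dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  .write_provenance(out_dir, list(command = "simulate", type = type,
                                  n_frames = n_frames), seed)
  invisible(sim)
}

#' Calibrate command: needle spring constant from track CSVs
#'
#' @param config Config list or path (see [read_experiment_config()]);
#'   needs `paths$needle_track`, `paths$pillar_track`, `needle$speed_um_s`,
#'   `pillar: {length_um, radius_um, E_kPa, nu}` and `paths$out_dir`.
#' @return Invisibly, the [needle_calibration()]; a JSON report is
#'   written to the output directory.
#' @export
cmd_calibrate <- function(config) {
  cfg <- if (is.character(config)) read_experiment_config(config) else config
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- pillar_geometry(um_to_m(cfg$pillar$length_um),
                          um_to_m(cfg$pillar$radius_um),
                          kpa_to_pa(cfg$pillar$E_kPa),
                          if (is.null(cfg$pillar$nu)) 0.5 else cfg$pillar$nu)
  ntrack <- .read_track_csv(cfg$paths$needle_track)
  ptrack <- .read_track_csv(cfg$paths$pillar_track)
  cal <- calibrate_needle(ntrack, ptrack, geom,
                          um_to_m(cfg$needle$speed_um_s),
                          cfg$si$pixel_size)
  jsonlite::write_json(
    list(spring_constant_N_m = cal$spring_constant,
         intercept_nN = n_to_nn(cal$intercept),
         r_squared = cal$r_squared, n_points = cal$n_points,
         pillar_spring_constant_N_m = pillar_spring_constant(geom)),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  .write_provenance(out_dir, cfg, if (is.null(cfg$seed)) NA else cfg$seed)
  invisible(cal)
}

#' Reconstruct command: per-frame patch forces and needle comparison
#'
#' Runs PIV against the reference, the circular-patch fit per frame,
#' computes the net traction force, the needle force from the track, and
#' writes forces, needle-force and comparison CSVs.
#'
#' @param config Config list or path; needs `paths$stack`,
#'   `paths$reference`, `windows`, `piv`, substrate fields, frame rate,
#'   `needle$spring_constant_N_m` (or a calibration JSON path in
#'   `needle$calibration`), `paths$needle_track`, `paths$out_dir`.
#' @return Invisibly, a list with the force sets and the comparison
#'   table.
#' @export
cmd_reconstruct <- function(config) {
  cfg <- if (is.character(config)) read_experiment_config(config) else config
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stack <- .read_stack_tiff(cfg$paths$stack, cfg$si$pixel_size)
  if (length(stack) == 0L) stop("empty image stack")
  reference <- .read_stack_tiff(cfg$paths$reference, cfg$si$pixel_size)[[1]]
  sets <- reconstruct_time_series(stack, reference, cfg$si$windows,
                                  cfg$si$piv, cfg$si$substrate,
                                  cfg$si$frame_rate)
  tab <- force_series_table(sets, cfg$si$windows$label)
  utils::write.csv(tab, file.path(out_dir, "patch_forces.csv"),
                   row.names = FALSE)
  k <- cfg$needle$spring_constant_N_m
  if (is.null(k) && !is.null(cfg$needle$calibration)) {
    k <- jsonlite::read_json(cfg$needle$calibration)$spring_constant_N_m
  }
  cmp <- NULL
  if (!is.null(k) && !is.null(cfg$paths$needle_track)) {
    ntrack <- .read_track_csv(cfg$paths$needle_track)
    nb <- needle_bending_series(ntrack, cfg$si$needle_speed,
                                c(0, 1), cfg$si$pixel_size)
    nf <- needle_force_series(nb, k)
    utils::write.csv(
      data.frame(frame = nb$frame, time_s = nb$time_s,
                 bending_um = m_to_um(nb$bending_m),
                 needle_force_nN = n_to_nn(nf)),
      file.path(out_dir, "needle_force.csv"), row.names = FALSE)
    net <- t(vapply(sets, function(s) {
      n <- net_traction_force(s); c(n$vector, n$magnitude)
    }, numeric(3)))
    times <- vapply(sets, function(s) s$time, numeric(1))
    nf_at <- nf[match(round(times, 6), round(nb$time_s, 6))]
    cmp <- data.frame(frame = vapply(sets, function(s) s$frame_index, numeric(1)),
                      time_s = times,
                      net_traction_nN = n_to_nn(net[, 3]),
                      needle_force_nN = n_to_nn(nf_at),
                      rel_mismatch = ifelse(nf_at > 0,
                                            abs(net[, 3] - nf_at) / nf_at,
                                            NA_real_))
    utils::write.csv(cmp, file.path(out_dir, "force_comparison.csv"),
                     row.names = FALSE)
  }
  .write_provenance(out_dir, cfg, if (is.null(cfg$seed)) NA else cfg$seed)
  invisible(list(sets = sets, comparison = cmp, table = tab))
}

#' FTTC validation command: per-patch method comparison at t = 0
#'
#' Reconstructs the zero-monopole first frame with FTTC (GCV-selected
#' lambda unless overridden), integrates traction in each search window,
#' fits the circular-patch forces on the same field, and writes the
#' per-patch comparison table.
#'
#' @param config Config list or path.
#' @param lambda Optional fixed dimensionless Tikhonov parameter
#'   overriding GCV.
#' @return Invisibly, the comparison data frame (with `lambda_used`
#'   attribute).
#' @export
cmd_validate_fttc <- function(config, lambda = NULL) {
  cfg <- if (is.character(config)) read_experiment_config(config) else config
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stack <- .read_stack_tiff(cfg$paths$stack, cfg$si$pixel_size)
  reference <- .read_stack_tiff(cfg$paths$reference, cfg$si$pixel_size)[[1]]
  fld <- piv_displacement(reference, stack[[1]], cfg$si$piv)
  full <- fill_invalid_vectors(fld)
  if (is.null(lambda)) lambda <- gcv_select_lambda(full, cfg$si$substrate)
  trac <- fttc_reconstruct(full, cfg$si$substrate, lambda)
  wins <- cfg$si$windows
  fttc_f <- t(vapply(seq_len(nrow(wins)), function(k) {
    integrate_window_traction(trac, c(wins$xmin[k], wins$xmax[k],
                                      wins$ymin[k], wins$ymax[k]))
  }, numeric(2)))
  fm <- field_magnitude(fld)
  ctr <- detect_patch_centers(fm, wins)
  rad <- estimate_patch_radius(fm, ctr)
  patches <- lapply(seq_len(nrow(wins)), function(k) {
    circular_patch(wins$label[k], ctr[k, ], rad[k])
  })
  pfs <- fit_patch_forces(fld, patches, cfg$si$substrate)
  cmp <- compare_methods(pfs, fttc_f, wins$label)
  attr(cmp, "lambda_used") <- lambda
  utils::write.csv(cbind(cmp, lambda_used = lambda),
                   file.path(out_dir, "fttc_comparison.csv"),
                   row.names = FALSE)
  .write_provenance(out_dir, cfg, if (is.null(cfg$seed)) NA else cfg$seed)
  invisible(cmp)
}

#' Moments command: monopole/dipole/torque time series
#'
#' Reads a per-frame patch force CSV (as written by
#' [cmd_reconstruct()]) and writes the moments table.
#'
#' @param config Config list or path; needs `paths$forces` (CSV) and
#'   `paths$out_dir`.
#' @return Invisibly, the moments data frame.
#' @export
cmd_moments <- function(config) {
  cfg <- if (is.character(config)) read_experiment_config(config) else config
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$paths$forces) || !file.exists(cfg$paths$forces)) {
    stop("missing per-frame forces file (paths$forces)")
  }
  df <- utils::read.csv(cfg$paths$forces)
  sets <- lapply(split(df, df$frame), function(d) {
    patch_force_set(d$frame[1], d$time_s[1],
                    cbind(um_to_m(d$cx_um), um_to_m(d$cy_um)),
                    cbind(nn_to_n(d$Fx_nN), nn_to_n(d$Fy_nN)))
  })
  sets <- sets[order(as.numeric(names(sets)))]
  mom <- moments_time_series(sets)
  tab <- moments_table(mom)
  utils::write.csv(tab, file.path(out_dir, "moments.csv"), row.names = FALSE)
  .write_provenance(out_dir, cfg, if (is.null(cfg$seed)) NA else cfg$seed)
  invisible(tab)
}
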