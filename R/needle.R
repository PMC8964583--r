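## Microneedle spring-constant calibration from PDMS pillar shearing, and
## per-frame shear-force computation from needle bending.
##
## The needle is moved by a micromanipulator at constant speed; its tip
## lags behind by the bending, and the force follows from the calibrated
## spring constant. Calibration shears the needle against a PDMS
## micropillar of known cantilever stiffness: the slope of pillar force
## versus needle bending is the needle's spring constant.

#' PDMS pillar geometry
#'
#' @param length Pillar length (m).
#' @param radius Pillar radius (m); must be smaller than `length`.
#' @param youngs_modulus PDMS Young's modulus (Pa).
#' @param poisson_ratio Poisson ratio (default 0.5, nearly
#'   incompressible elastomer).
#' @return Object of class `pillar_geometry`.
#' @export
pillar_geometry <- function(length, radius, youngs_modulus,
                            poisson_ratio = 0.5) {
  stopifnot(length > radius, radius > 0, youngs_modulus > 0,
            poisson_ratio >= 0, poisson_ratio <= 0.5)
  structure(list(length = length, radius = radius,
                 E = youngs_modulus, nu = poisson_ratio),
            class = "pillar_geometry")
}

#' Cantilever spring constant of a cylindrical micropillar
#'
#' Euler-Bernoulli tip stiffness `k = 3 E I / L^3` with
#' `I = pi r^4 / 4`. With `include_shear_correction = TRUE` (default)
#' the Timoshenko shear compliance of the short, thick pillar is added:
#' `k = k_EB / (1 + 3 E I / (kappa G A L^2))` with `A = pi r^2`,
#' `G = E / (2 (1 + nu))` and Cowper's shear coefficient for a solid
#' circular section `kappa = 6 (1 + nu) / (7 + 6 nu)`.
#'
#' An optional substrate-warping (base tilt) correction factor can be
#' supplied via `tilt_factor` (multiplies the stiffness; default 1, i.e.
#' off), so its sensitivity can be reported without changing defaults.
#'
#' @param geometry A [pillar_geometry()].
#' @param include_shear_correction Logical (default TRUE).
#' @param tilt_factor Multiplicative base-tilt correction (default 1).
#' @return Spring constant (N/m).
#' @export
pillar_spring_constant <- function(geometry, include_shear_correction = TRUE,
                                   tilt_factor = 1) {
  E <- geometry$E; L <- geometry$length; r <- geometry$radius
  I <- pi * r^4 / 4
  k <- 3 * E * I / L^3
  if (include_shear_correction) {
    G <- E / (2 * (1 + geometry$nu))
    A <- pi * r^2
    kappa <- 6 * (1 + geometry$nu) / (7 + 6 * geometry$nu)
    k <- k / (1 + 3 * E * I / (kappa * G * A * L^2))
  }
  k * tilt_factor
}

#' Tip track table
#'
#' Manual tip positions from phase-contrast frames. At least one
#' reference row (unbent state, before motion starts) is required and
#' must precede all motion rows.
#'
#' @param frame Integer frame numbers.
#' @param time_s Strictly increasing timestamps (s).
#' @param x_px,y_px Tip pixel coordinates.
#' @param reference Logical; TRUE for unbent reference row(s).
#' @return A `track_table` data frame.
#' @export
track_table <- function(frame, time_s, x_px, y_px, reference) {
  stopifnot(all(diff(time_s) > 0), any(reference))
  if (any(!reference) && min(which(!reference)) < max(which(reference))) {
    stop("reference rows must precede motion rows")
  }
  structure(data.frame(frame = frame, time_s = time_s, x_px = x_px,
                       y_px = y_px, reference = reference),
            class = c("track_table", "data.frame"))
}

#' Per-frame needle bending from a tip track
#'
#' The micromanipulator distance is `speed * (t - t_start)` with
#' `t_start` the timestamp of the last reference row; the tip distance is
#' the projection of the tip motion (relative to the reference tip
#' position) onto the movement axis; bending is their difference.
#' Negative bending (slip) is kept but flagged.
#'
#' @param track A [track_table()].
#' @param manipulator_speed Needle drive speed (m/s), positive.
#' @param axis Unit length-2 movement direction (image coordinates).
#' @param pixel_size Pixel size (m).
#' @return Data frame for motion rows: `frame`, `time_s`, `bending_m`,
#'   `tip_distance_m`, `manipulator_m`, `perp_m` (off-axis tip motion,
#'   quality metric), `slip`.
#' @export
needle_bending_series <- function(track, manipulator_speed, axis = c(0, 1),
                                  pixel_size) {
  stopifnot(manipulator_speed > 0, length(axis) == 2L)
  if (!any(track$reference)) stop("track has no reference row")
  axis <- axis / sqrt(sum(axis^2))
  ref_rows <- track[track$reference, , drop = FALSE]
  ref <- c(mean(ref_rows$x_px), mean(ref_rows$y_px))
  t_start <- max(ref_rows$time_s)
  mot <- track[!track$reference, , drop = FALSE]
  dx <- (mot$x_px - ref[1]) * pixel_size
  dy <- (mot$y_px - ref[2]) * pixel_size
  tip <- dx * axis[1] + dy * axis[2]
  perp <- -dx * axis[2] + dy * axis[1]
  manip <- manipulator_speed * (mot$time_s - t_start)
  bend <- manip - tip
  data.frame(frame = mot$frame, time_s = mot$time_s, bending_m = bend,
             tip_distance_m = tip, manipulator_m = manip, perp_m = perp,
             slip = bend < -1e-12)   # sub-pm tolerance against roundoff
}

#' Needle calibration result
#'
#' @param spring_constant Slope (N/m), positive for a valid calibration.
#' @param intercept Fit intercept (N).
#' @param r_squared Coefficient of determination.
#' @param n_points Number of contact frames used.
#' @return Object of class `needle_calibration`.
#' @export
needle_calibration <- function(spring_constant, intercept, r_squared,
                               n_points) {
  stopifnot(spring_constant > 0)
  structure(list(spring_constant = spring_constant, intercept = intercept,
                 r_squared = r_squared, n_points = n_points),
            class = "needle_calibration")
}

#' @export
print.needle_calibration <- function(x, ...) {
  cat(sprintf("Needle calibration: k = %.4g N/m (R^2 = %.4f, n = %d)\n",
              x$spring_constant, x$r_squared, x$n_points))
  invisible(x)
}

#' Calibrate the microneedle spring constant against a PDMS pillar
#'
#' Pillar force (pillar spring constant times on-axis pillar deflection)
#' is regressed on needle bending by ordinary least squares; the slope is
#' the needle's spring constant. The same movement axis must be used for
#' calibration and cell shearing (needle asymmetry).
#'
#' @param needle_track,pillar_track [track_table()]s sharing frames.
#' @param geometry A [pillar_geometry()].
#' @param speed Manipulator speed during calibration (m/s).
#' @param pixel_size Pixel size (m).
#' @param axis Movement axis (default +y).
#' @param include_shear_correction Passed to [pillar_spring_constant()].
#' @return A [needle_calibration()]. Fewer than 3 contact frames or a
#'   non-positive slope raise an error.
#' @export
calibrate_needle <- function(needle_track, pillar_track, geometry, speed,
                             pixel_size, axis = c(0, 1),
                             include_shear_correction = TRUE) {
  k_p <- pillar_spring_constant(geometry, include_shear_correction)
  nb <- needle_bending_series(needle_track, speed, axis, pixel_size)
  p_ref_rows <- pillar_track[pillar_track$reference, , drop = FALSE]
  p_ref <- c(mean(p_ref_rows$x_px), mean(p_ref_rows$y_px))
  pm <- pillar_track[!pillar_track$reference, , drop = FALSE]
  stopifnot(nrow(pm) == nrow(nb), all(pm$frame == nb$frame))
  axis <- axis / sqrt(sum(axis^2))
  defl <- ((pm$x_px - p_ref[1]) * axis[1] +
             (pm$y_px - p_ref[2]) * axis[2]) * pixel_size
  force <- k_p * defl
  if (nrow(nb) < 3L) stop("calibration failed: fewer than 3 contact frames")
  fit <- stats::lm(force ~ nb$bending_m)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failed: non-positive slope (pillar did not deflect?)")
  }
  ss_tot <- sum((force - mean(force))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  needle_calibration(slope, unname(stats::coef(fit)[1]), r2, nrow(nb))
}

#' Shear force time series from needle bending
#'
#' `F(t) = k_needle * bending(t)`.
#'
#' @param bending Numeric per-frame bending (m) or the data frame from
#'   [needle_bending_series()].
#' @param calibration A [needle_calibration()] (or a bare spring
#'   constant in N/m).
#' @return Numeric per-frame force (N).
#' @export
needle_force_series <- function(bending, calibration) {
  k <- if (inherits(calibration, "needle_calibration")) {
    calibration$spring_constant
  } else {
    stopifnot(is.numeric(calibration), calibration > 0)
    calibration
  }
  b <- if (is.data.frame(bending)) bending$bending_m else bending
  k * b
}
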