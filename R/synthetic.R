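## Synthetic data generation: bead images deformed by known traction
## fields, shear-experiment scenarios with exact ground-truth force
## accounting, and pillar-calibration tip tracks. Every dataset carries
## its ground truth; all randomness flows through explicit seeds.

#' Bead field specification
#'
#' Emulates ~50 nm fluorescent marker beads imaged as diffraction-limited
#' Gaussian spots.
#'
#' @param n_beads Number of beads (> 0).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param psf_sigma Gaussian spot sigma (px, >= 0.5).
#' @param intensity Peak spot intensity (a.u.).
#' @param noise_sigma Gaussian read-noise sigma (a.u.).
#' @param pixel_size Pixel size (m); default 0.1625 um (6.5 um camera
#'   pixel, 40x objective).
#' @param seed Integer seed; bead positions are a pure function of it.
#' @return Object of class `bead_field_spec`.
#' @export
bead_field_spec <- function(n_beads = 3000L, image_shape = c(512L, 512L),
                            psf_sigma = 1.5, intensity = 150,
                            noise_sigma = 3, pixel_size = 0.1625e-6,
                            seed = 1L) {
  stopifnot(n_beads > 0, psf_sigma >= 0.5, all(image_shape >= 16),
            pixel_size > 0, noise_sigma >= 0)
  structure(list(n_beads = as.integer(n_beads),
                 image_shape = as.integer(image_shape),
                 psf_sigma = psf_sigma, intensity = intensity,
                 noise_sigma = noise_sigma, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "bead_field_spec")
}

#' Render a synthetic bead image
#'
#' Beads are placed uniformly at random (seeded) in continuous pixel
#' coordinates and rendered as Gaussian spots — a sum of continuous
#' Gaussians, not a warped raster, so sub-pixel displacements carry no
#' interpolation bias. If a displacement function is supplied, each bead
#' is rendered at its displaced position (the substrate material point
#' carries the bead).
#'
#' @param spec A [bead_field_spec()].
#' @param displacement NULL, a constant length-2 displacement (m), or a
#'   function mapping an n x 2 position matrix (m) to n x 2
#'   displacements (m).
#' @param noise_seed Seed for the additive read noise (defaults to
#'   `spec$seed`); bead positions always derive from `spec$seed` alone,
#'   so frames of a time series share the same bead field.
#' @return A [bead_image()].
#' @export
render_bead_image <- function(spec, displacement = NULL,
                              noise_seed = spec$seed) {
  stopifnot(inherits(spec, "bead_field_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  set.seed(spec$seed)
  xb <- stats::runif(spec$n_beads, 0, W - 1)
  yb <- stats::runif(spec$n_beads, 0, H - 1)
  if (!is.null(displacement)) {
    if (is.function(displacement)) {
      pos_m <- cbind(xb, yb) * spec$pixel_size
      u <- displacement(pos_m)
      xb <- xb + u[, 1] / spec$pixel_size
      yb <- yb + u[, 2] / spec$pixel_size
    } else {
      xb <- xb + displacement[1] / spec$pixel_size
      yb <- yb + displacement[2] / spec$pixel_size
    }
  }
  img <- matrix(0, H, W)
  half <- ceiling(4 * spec$psf_sigma)
  s2 <- 2 * spec$psf_sigma^2
  for (b in seq_len(spec$n_beads)) {
    c0 <- floor(xb[b]) + 1L; r0 <- floor(yb[b]) + 1L
    cols <- max(1L, c0 - half):min(W, c0 + half)
    rows <- max(1L, r0 - half):min(H, r0 + half)
    if (length(cols) == 0L || length(rows) == 0L) next
    gx <- exp(-((cols - 1 - xb[b])^2) / s2)
    gy <- exp(-((rows - 1 - yb[b])^2) / s2)
    img[rows, cols] <- img[rows, cols] + spec$intensity * outer(gy, gx)
  }
  if (spec$noise_sigma > 0) {
    set.seed(noise_seed)
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  }
  bead_image(pmax(img, 0), spec$pixel_size)
}

#' Shear-experiment scenario
#'
#' Encodes the design of a microneedle shearing experiment: balanced
#' baseline (dipole) forces, a per-frame external force ramp, the share
#' of the external load carried by each (tension-side) patch, and
#' optional rupture events with load redistribution. Force accounting is
#' exact: at every frame the ground-truth forces sum to the external
#' force.
#'
#' @param patches List of [circular_patch()].
#' @param baseline_forces K x 2 matrix (N), summing to zero (pure dipole
#'   at t = 0).
#' @param external_force_profile n_frames x 2 matrix (N); frame 1 should
#'   be zero (pre-shear).
#' @param load_weights Length-K nonnegative weights summing to 1 (zero
#'   for compression-side patches).
#' @param rupture_events List of `list(frame=, patch_ids=,
#'   redistribution_weights=)`; from `frame` on, listed patches carry
#'   zero force and the resulting force deficit is redistributed over
#'   surviving patches by the (renormalized) redistribution weights.
#' @param frame_rate Frames per second (default 0.85).
#' @param dipole_arm Characteristic dipole arm length (m), used for
#'   monopole/dipole crossover analysis.
#' @param seed Integer seed.
#' @return Object of class `shear_scenario`.
#' @export
shear_scenario <- function(patches, baseline_forces, external_force_profile,
                           load_weights, rupture_events = list(),
                           frame_rate = 0.85, dipole_arm = NULL, seed = 1L) {
  baseline_forces <- matrix(baseline_forces, ncol = 2)
  external_force_profile <- matrix(external_force_profile, ncol = 2)
  K <- length(patches)
  stopifnot(nrow(baseline_forces) == K, length(load_weights) == K,
            all(load_weights >= 0))
  bsum <- colSums(baseline_forces)
  fscale <- max(sqrt(rowSums(baseline_forces^2)), 1e-30)
  if (sqrt(sum(bsum^2)) > 1e-9 * fscale) {
    stop("baseline forces must sum to zero (balanced dipole)")
  }
  if (abs(sum(load_weights) - 1) > 1e-12) stop("load weights must sum to 1")
  for (ev in rupture_events) {
    stopifnot(ev$frame >= 1, length(ev$redistribution_weights) == K,
              abs(sum(ev$redistribution_weights) - 1) < 1e-12)
  }
  structure(list(patches = patches, baseline_forces = baseline_forces,
                 external_force_profile = external_force_profile,
                 load_weights = load_weights,
                 rupture_events = rupture_events,
                 frame_rate = frame_rate, dipole_arm = dipole_arm,
                 seed = as.integer(seed)),
            class = "shear_scenario")
}

#' Ground-truth per-patch forces of a scenario
#'
#' @param scenario A [shear_scenario()].
#' @return List with one K x 2 force matrix (N) per frame; at every
#'   frame the forces sum exactly to that frame's external force.
#' @export
scenario_truth_forces <- function(scenario) {
  K <- length(scenario$patches)
  n <- nrow(scenario$external_force_profile)
  lapply(seq_len(n), function(t) {
    fext <- scenario$external_force_profile[t, ]
    active <- rep(TRUE, K)
    rw <- NULL
    for (ev in scenario$rupture_events) {
      if (t >= ev$frame) {
        active[ev$patch_ids] <- FALSE
        rw <- ev$redistribution_weights
      }
    }
    f <- scenario$baseline_forces + scenario$load_weights %o% fext
    f[!active, ] <- 0
    deficit <- fext - colSums(f)
    if (any(abs(deficit) > 0) && !is.null(rw)) {
      w <- rw; w[!active] <- 0
      if (sum(w) == 0) w[active] <- 1
      w <- w / sum(w)
      f <- f + w %o% deficit
    }
    f
  })
}

#' Built-in scenarios mirroring the experimental phenomenology
#'
#' Three 9-patch scenarios on a ~83 x 83 um field of view
#' (E = 16.5 kPa substrate, 0.85 fps, external ramp to ~100 nN over the
#' series, patch radii 1-3 um):
#' \describe{
#'   \item{perpendicular}{cell elongated along x (major dipole along x),
#'     needle pull along +y carried by the lateral adhesion clusters —
#'     the monopole grows perpendicular to the major dipole, which stays
#'     essentially unchanged.}
#'   \item{colinear}{cell elongated along y, pull along +y carried by
#'     trailing-edge patches — the force balance crosses over from
#'     dipole- to monopole-dominated.}
#'   \item{rupture}{colinear geometry with three tension-side patches
#'     rupturing mid-ramp; their load is redistributed to the surviving
#'     tension-side patches.}
#' }
#'
#' @param type One of "perpendicular", "colinear", "rupture".
#' @param n_frames Number of frames including the zero-force first frame
#'   (default 18, about 20 s at 0.85 fps).
#' @param f_max Final external force magnitude (N; default 100 nN).
#' @param baseline_mag Baseline contractile force per peripheral patch
#'   (N; default 10 nN, a typical focal-adhesion-cluster traction force
#'   for fibroblasts on ~16 kPa gels).
#' @param rupture_frame Frame of the rupture event (rupture type only).
#' @param seed Integer seed.
#' @return A [shear_scenario()].
#' @export
default_scenario <- function(type = c("perpendicular", "colinear", "rupture"),
                             n_frames = 18L, f_max = 100e-9,
                             baseline_mag = 10e-9,
                             rupture_frame = 10L, seed = 1L) {
  type <- match.arg(type)
  cx <- 41.5e-6; cy <- 41.5e-6
  ## 8 peripheral patches on an ellipse + 1 central patch
  ang <- (0:7) * pi / 4
  if (type == "perpendicular") { ax <- 20e-6; ay <- 10e-6 } else { ax <- 10e-6; ay <- 20e-6 }
  px <- cx + ax * cos(ang)
  py <- cy + ay * sin(ang)
  pos <- rbind(cbind(px, py), c(cx, cy))
  radii <- c(rep(c(2e-6, 1.5e-6), 4), 2.5e-6)
  patches <- lapply(1:9, function(k) circular_patch(k, pos[k, ], radii[k]))
  ## contractile baseline: peripheral patches pull toward the center
  bl <- matrix(0, 9, 2)
  for (k in 1:8) {
    d <- c(cx, cy) - pos[k, ]
    bl[k, ] <- baseline_mag * d / sqrt(sum(d^2))
  }
  bl[9, ] <- -colSums(bl)   # central patch balances exactly
  ## external pull along +y, ramping linearly from zero
  ramp <- seq(0, 1, length.out = n_frames)
  fext <- cbind(0, ramp * f_max)
  w <- numeric(9)
  if (type == "perpendicular") {
    ## lateral clusters (x extremes, y ~ center) carry the load
    lateral <- c(1, 5)               # angles 0 and pi
    flank <- c(2, 4, 6, 8)
    w[lateral] <- 0.3; w[flank] <- 0.1
  } else {
    ## the patch under the needle (center) takes most of the load, the
    ## trailing-edge patches (small y; needle pulls +y) the rest
    trailing <- order(pos[1:8, 2])[1:3]
    w[trailing] <- c(0.2, 0.15, 0.15)
    w[9] <- 0.5
  }
  w <- w / sum(w)
  events <- list()
  if (type == "rupture") {
    tr <- order(pos[1:8, 2])[1:3]
    surv_t <- setdiff(which(w > 0), tr)
    rw <- numeric(9); rw[surv_t] <- 1 / length(surv_t)
    events <- list(list(frame = rupture_frame, patch_ids = tr,
                        redistribution_weights = rw))
  }
  shear_scenario(patches, bl, fext, w, events,
                 frame_rate = 0.85,
                 dipole_arm = if (type == "perpendicular") ax else ay,
                 seed = seed)
}

#' Simulate a full shear experiment
#'
#' Generates everything the reconstruction pipeline consumes: a bead
#' image stack deformed by the forward model of the ground-truth forces,
#' the undeformed (post-detachment) reference image, the ground-truth
#' force table, a needle tip track consistent with
#' `F_ext = k_needle * bending`, and the needle force profile.
#'
#' @param scenario A [shear_scenario()].
#' @param spec A [bead_field_spec()].
#' @param substrate An [elastic_substrate()].
#' @param k_needle Needle spring constant (N/m) used to construct the
#'   consistent needle track (default 0.05).
#' @param needle_speed Manipulator speed (m/s; default 5 um/s).
#' @return List: `images` (list of [bead_image()]), `reference`,
#'   `truth` (per-frame K x 2 force matrices), `truth_table` (data
#'   frame, nN), `needle_track` ([track_table()]), `needle_forces`
#'   (per-frame N), `scenario`, `windows` (search window set framing
#'   each patch), `displacement_fn` (per-frame displacement closures).
#' @export
simulate_shear_experiment <- function(scenario, spec, substrate,
                                      k_needle = 0.05,
                                      needle_speed = 5e-6) {
  truth <- scenario_truth_forces(scenario)
  n <- length(truth)
  K <- length(scenario$patches)
  fr <- scenario$frame_rate
  disp_fns <- lapply(seq_len(n), function(t) {
    f <- truth[[t]]
    function(pts) forward_displacement_at(pts, scenario$patches, f, substrate)
  })
  reference <- render_bead_image(spec, NULL, noise_seed = scenario$seed)
  images <- lapply(seq_len(n), function(t) {
    render_bead_image(spec, disp_fns[[t]],
                      noise_seed = scenario$seed + t)
  })
  ## needle track: the manipulator starts moving right after the
  ## reference frame (one frame interval before frame 0); the tip lags
  ## the manipulator by the bending, bending = F_ext / k_needle
  times <- (seq_len(n) - 1) / fr
  t_ref <- -1 / fr
  fmag <- sqrt(rowSums(scenario$external_force_profile^2))
  bend <- fmag / k_needle
  manip <- needle_speed * (times - t_ref)
  tip <- manip - bend                    # on-axis tip distance (m)
  ps <- spec$pixel_size
  ref_xy <- c(spec$image_shape[2], spec$image_shape[1]) / 2 * ps
  ntrack <- track_table(frame = 0:n,
                        time_s = c(t_ref, times),
                        x_px = rep(ref_xy[1] / ps, n + 1),
                        y_px = c(ref_xy[2], ref_xy[2] + tip) / ps,
                        reference = c(TRUE, rep(FALSE, n)))
  wins <- do.call(rbind, lapply(seq_len(K), function(k) {
    p <- scenario$patches[[k]]
    m <- 2.5 * p$radius
    data.frame(label = k, xmin = p$center[1] - m, xmax = p$center[1] + m,
               ymin = p$center[2] - m, ymax = p$center[2] + m)
  }))
  tt <- do.call(rbind, lapply(seq_len(n), function(t) {
    data.frame(frame = t - 1L, time_s = times[t], patch_id = seq_len(K),
               Fx_nN = n_to_nn(truth[[t]][, 1]),
               Fy_nN = n_to_nn(truth[[t]][, 2]),
               ext_Fx_nN = n_to_nn(scenario$external_force_profile[t, 1]),
               ext_Fy_nN = n_to_nn(scenario$external_force_profile[t, 2]))
  }))
  list(images = images, reference = reference, truth = truth,
       truth_table = tt, needle_track = ntrack,
       needle_forces = fmag, scenario = scenario,
       windows = search_window_set(wins), displacement_fn = disp_fns,
       k_needle = k_needle, needle_speed = needle_speed)
}

#' Simulate a pillar-shearing calibration experiment
#'
#' The needle (spring constant `k_needle_true`) is driven at constant
#' speed against a pillar of stiffness `k_p` from its geometry; in
#' contact the two springs share the manipulator displacement:
#' `k_p delta_p = k_n delta_n`, `delta_p + delta_n = speed * t`.
#'
#' @param k_needle_true True needle spring constant (N/m).
#' @param geometry A [pillar_geometry()].
#' @param speed Manipulator speed (m/s; default 2 um/s).
#' @param frames Number of contact frames (default 20).
#' @param noise_px Gaussian tip-position noise sigma (px; default 0).
#' @param seed Integer seed for the noise.
#' @param pixel_size Pixel size (m).
#' @param frame_rate Frames per second (default 0.85).
#' @param include_shear_correction Passed to [pillar_spring_constant()].
#' @return List with `needle` and `pillar` [track_table()]s (one
#'   reference row each) and the true deflections.
#' @export
simulate_pillar_calibration <- function(k_needle_true, geometry,
                                        speed = 2e-6, frames = 20L,
                                        noise_px = 0, seed = 1L,
                                        pixel_size = 0.1625e-6,
                                        frame_rate = 0.85,
                                        include_shear_correction = TRUE) {
  stopifnot(k_needle_true > 0)
  k_p <- pillar_spring_constant(geometry, include_shear_correction)
  times <- seq_len(frames) / frame_rate
  D <- speed * times
  delta_p <- D * k_needle_true / (k_needle_true + k_p)
  delta_n <- D - delta_p
  ## both tips sit at the contact point: tip distance = delta_p
  n_ref <- c(100, 100)
  p_ref <- c(100, 130)
  set.seed(seed)
  noise <- function(n) if (noise_px > 0) stats::rnorm(n, 0, noise_px) else numeric(n)
  needle <- track_table(frame = 0:frames, time_s = c(0, times),
                        x_px = n_ref[1] + c(0, noise(frames)),
                        y_px = n_ref[2] + c(0, delta_p / pixel_size + noise(frames)),
                        reference = c(TRUE, rep(FALSE, frames)))
  pillar <- track_table(frame = 0:frames, time_s = c(0, times),
                        x_px = p_ref[1] + c(0, noise(frames)),
                        y_px = p_ref[2] + c(0, delta_p / pixel_size + noise(frames)),
                        reference = c(TRUE, rep(FALSE, frames)))
  list(needle = needle, pillar = pillar, delta_p = delta_p,
       delta_n = delta_n, k_pillar = k_p)
}
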