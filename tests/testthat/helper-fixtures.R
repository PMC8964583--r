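# Shared fixtures, all built in code.

paam <- function() elastic_substrate(16.5e3, 0.5)

pdms_pillar <- function() pillar_geometry(6e-6, 2e-6, 801.5e3, 0.5)

# PIV-resolution analysis grid over the default ~83 um field of view
analysis_grid <- function(spacing = 2.6e-6) {
  list(x = seq(1e-6, 82e-6, by = spacing), y = seq(1e-6, 82e-6, by = spacing))
}

scenario_windows <- function(scenario, margin = 2.5) {
  search_window_set(do.call(rbind, lapply(seq_along(scenario$patches), function(k) {
    p <- scenario$patches[[k]]
    m <- margin * p$radius
    data.frame(label = k,
               xmin = p$center[1] - m, xmax = p$center[1] + m,
               ymin = p$center[2] - m, ymax = p$center[2] + m)
  })))
}

# Gaussian displacement-field noise with sigma = frac * RMS magnitude
add_field_noise <- function(field, frac, seed) {
  set.seed(seed)
  sdn <- frac * sqrt(mean(field$ux^2 + field$uy^2))
  field$ux <- field$ux + matrix(stats::rnorm(length(field$ux), 0, sdn),
                                nrow(field$ux))
  field$uy <- field$uy + matrix(stats::rnorm(length(field$uy), 0, sdn),
                                nrow(field$uy))
  field
}

# Run the full field-level reconstruction for every frame of a scenario,
# mirroring reconstruct_time_series: per-frame centers, common (median)
# radii frozen after pass 1, then the per-frame least-squares fit.
reconstruct_scenario_fields <- function(scenario, grid, substrate,
                                        noise_frac = 0, seed = 1L) {
  truth <- scenario_truth_forces(scenario)
  wins <- scenario_windows(scenario)
  K <- length(scenario$patches)
  fields <- vector("list", length(truth))
  centers <- vector("list", length(truth))
  radii_f <- vector("list", length(truth))
  for (t in seq_along(truth)) {
    fld <- forward_displacement_field(scenario$patches, truth[[t]], grid,
                                      substrate)
    if (noise_frac > 0) fld <- add_field_noise(fld, noise_frac, seed + t)
    fm <- field_magnitude(fld)
    ctr <- detect_patch_centers(fm, wins)
    radii_f[[t]] <- estimate_patch_radius(fm, ctr)
    fields[[t]] <- fld
    centers[[t]] <- ctr
  }
  radii <- apply(do.call(rbind, radii_f), 2, stats::median)
  lapply(seq_along(truth), function(t) {
    ps <- lapply(seq_len(K), function(k) {
      circular_patch(k, centers[[t]][k, ], radii[k])
    })
    fit_patch_forces(fields[[t]], ps, substrate, frame_index = t - 1L,
                     time = (t - 1) / scenario$frame_rate)
  })
}

# Window-periodic bead image: one wrap-free tile repeated so that every
# interrogation window contains exactly one period; an integer roll of
# the raster is then an exact circular shift inside every window.
periodic_bead_image <- function(tile = 64L, reps = 4L, n_beads = 60L,
                                seed = 11L, pixel_size = 0.1625e-6,
                                sigma = 1.5) {
  set.seed(seed)
  margin <- ceiling(4 * sigma) + 1
  xb <- stats::runif(n_beads, margin, tile - 1 - margin)
  yb <- stats::runif(n_beads, margin, tile - 1 - margin)
  img <- matrix(0, tile, tile)
  for (b in seq_len(n_beads)) {
    cols <- seq_len(tile); rows <- seq_len(tile)
    gx <- exp(-((cols - 1 - xb[b])^2) / (2 * sigma^2))
    gy <- exp(-((rows - 1 - yb[b])^2) / (2 * sigma^2))
    img <- img + 150 * outer(gy, gx)
  }
  big <- img[rep(seq_len(tile), reps), rep(seq_len(tile), reps)]
  bead_image(big, pixel_size)
}

roll_matrix <- function(m, sy, sx) {
  n <- nrow(m); k <- ncol(m)
  m[((seq_len(n) - 1 - sy) %% n) + 1, ((seq_len(k) - 1 - sx) %% k) + 1]
}

# Independent k-space Boussinesq forward multiply (oracle for FTTC):
# standard tangential kernel, written separately from the package path.
kspace_forward <- function(tx, ty, h, E, nu) {
  N <- nrow(tx)
  fidx <- c(0:(N / 2 - 1), -(N / 2):-1)
  k1 <- 2 * pi * fidx / (N * h)
  KX <- matrix(k1, N, N, byrow = TRUE); KY <- matrix(k1, N, N)
  kk <- sqrt(KX^2 + KY^2); kk[1, 1] <- Inf
  pref <- 2 * (1 + nu) / (E * kk^3)
  Gxx <- pref * ((1 - nu) * kk^2 + nu * KY^2)
  Gyy <- pref * ((1 - nu) * kk^2 + nu * KX^2)
  Gxy <- -pref * nu * KX * KY
  T1 <- stats::fft(tx); T2 <- stats::fft(ty)
  U1 <- Gxx * T1 + Gxy * T2
  U2 <- Gxy * T1 + Gyy * T2
  U1[1, 1] <- 0; U2[1, 1] <- 0
  list(ux = Re(stats::fft(U1, inverse = TRUE)) / N^2,
       uy = Re(stats::fft(U2, inverse = TRUE)) / N^2)
}
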