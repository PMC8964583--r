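test_that("center detection finds window-local maxima with deterministic ties", {
  x <- seq(0, 30e-6, by = 1e-6)
  X <- matrix(x, length(x), length(x), byrow = TRUE)
  Y <- matrix(x, length(x), length(x))
  mag <- exp(-((X - 8e-6)^2 + (Y - 12e-6)^2) / (2 * (2e-6)^2)) +
    exp(-((X - 22e-6)^2 + (Y - 20e-6)^2) / (2 * (2e-6)^2))
  fm <- list(x = x, y = x, mag = mag, valid = matrix(TRUE, length(x), length(x)))
  wins <- search_window_set(data.frame(
    label = c("a", "b"),
    xmin = c(3e-6, 17e-6), xmax = c(13e-6, 27e-6),
    ymin = c(7e-6, 15e-6), ymax = c(17e-6, 25e-6)))
  ctr <- detect_patch_centers(fm, wins)
  expect_equal(unname(ctr["a", ]), c(8e-6, 12e-6))
  expect_equal(unname(ctr["b", ]), c(22e-6, 20e-6))
  # plateau of equal maxima: lowest row (y), then lowest column (x)
  mag2 <- matrix(0, length(x), length(x))
  mag2[10:12, 10:12] <- 1
  fm2 <- list(x = x, y = x, mag = mag2, valid = fm$valid)
  w1 <- search_window_set(data.frame(label = "p", xmin = 0, xmax = 30e-6,
                                     ymin = 0, ymax = 30e-6))
  ctr2 <- detect_patch_centers(fm2, w1)
  expect_equal(unname(ctr2[1, ]), c(x[10], x[10]))
  # all-zero window falls back to the centroid with a warning
  expect_warning(c0 <- detect_patch_centers(
    list(x = x, y = x, mag = matrix(0, 31, 31), valid = fm$valid), w1),
    "centroid")
  expect_equal(unname(c0[1, ]), c(15e-6, 15e-6))
})

test_that("radius estimation: Gaussian half-max, neighbor bound, clamping", {
  x <- seq(0, 40e-6, by = 0.5e-6)
  n <- length(x)
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  sig <- 3e-6
  mag <- exp(-((X - 20e-6)^2 + (Y - 20e-6)^2) / (2 * sig^2))
  fm <- list(x = x, y = x, mag = mag, valid = matrix(TRUE, n, n))
  r <- estimate_patch_radius(fm, matrix(c(20e-6, 20e-6), 1, 2))
  # half-max radius of a Gaussian: sigma * sqrt(2 ln 2) = 1.177 sigma
  expect_equal(r, sig * sqrt(2 * log(2)), tolerance = 0.05)
  # two broad-profile centers 8 um apart: neighbor bound at 4 um wins
  magb <- exp(-((X - 16e-6)^2 + (Y - 20e-6)^2) / (2 * (8e-6)^2)) +
    exp(-((X - 24e-6)^2 + (Y - 20e-6)^2) / (2 * (8e-6)^2))
  fmb <- list(x = x, y = x, mag = magb, valid = fm$valid)
  rb <- estimate_patch_radius(fmb, rbind(c(16e-6, 20e-6), c(24e-6, 20e-6)))
  expect_true(all(rb <= 4e-6 + 1e-12))
  # tight profile clamps at the 1 um floor
  magt <- exp(-((X - 20e-6)^2 + (Y - 20e-6)^2) / (2 * (0.3e-6)^2))
  rt <- estimate_patch_radius(list(x = x, y = x, mag = magt, valid = fm$valid),
                              matrix(c(20e-6, 20e-6), 1, 2))
  expect_equal(rt, 1e-6)
})

test_that("forward-inverse round trip recovers forces to near machine precision", {
  sub <- paam()
  scen <- default_scenario("colinear", n_frames = 6L)
  truth <- scenario_truth_forces(scen)
  g <- analysis_grid(5.2e-6)
  fld <- forward_displacement_field(scen$patches, truth[[5]], g, sub)
  fit <- fit_patch_forces(fld, scen$patches, sub)
  expect_lt(max(abs(fit$forces - truth[[5]])) / max(abs(truth[[5]])), 1e-6)
  expect_lt(fit$residual_norm / max(abs(fld$ux)), 1e-8)
  expect_false(fit$diagnostics$rank_deficient)
  # zero field gives zero forces
  z <- displacement_field(g$x, g$y,
                          matrix(0, length(g$y), length(g$x)),
                          matrix(0, length(g$y), length(g$x)))
  fz <- fit_patch_forces(z, scen$patches, sub)
  expect_equal(max(abs(fz$forces)), 0)
})

test_that("fit is linear and rotation-equivariant", {
  sub <- paam()
  p <- list(circular_patch(1, c(15e-6, 20e-6), 2e-6),
            circular_patch(2, c(30e-6, 22e-6), 2e-6))
  f <- rbind(c(2e-9, -1e-9), c(-1e-9, 2e-9))
  g <- list(x = seq(5e-6, 45e-6, by = 4e-6), y = seq(5e-6, 45e-6, by = 4e-6))
  fld <- forward_displacement_field(p, f, g, sub)
  fit1 <- fit_patch_forces(fld, p, sub)
  # doubling all displacements doubles all fitted forces
  fld2 <- fld; fld2$ux <- 2 * fld$ux; fld2$uy <- 2 * fld$uy
  fit2 <- fit_patch_forces(fld2, p, sub)
  expect_equal(fit2$forces, 2 * fit1$forces, tolerance = 1e-9)
  # rotate geometry and field by 90 degrees about the grid center:
  # fitted forces rotate identically
  ctr <- c(25e-6, 25e-6)
  R <- matrix(c(0, 1, -1, 0), 2, 2)   # +90 deg, column-major
  p_rot <- lapply(p, function(pp) {
    circular_patch(pp$id, ctr + as.numeric(R %*% (pp$center - ctr)), pp$radius)
  })
  ny <- length(g$y); nx <- length(g$x)
  ux_r <- matrix(0, ny, nx); uy_r <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      pt <- ctr + as.numeric(R %*% (c(g$x[j], g$y[i]) - ctr))
      jj <- which.min(abs(g$x - pt[1])); ii <- which.min(abs(g$y - pt[2]))
      u_rot <- as.numeric(R %*% c(fld$ux[i, j], fld$uy[i, j]))
      ux_r[ii, jj] <- u_rot[1]; uy_r[ii, jj] <- u_rot[2]
    }
  }
  fld_rot <- displacement_field(g$x, g$y, ux_r, uy_r)
  fit_rot <- fit_patch_forces(fld_rot, p_rot, sub)
  expect_equal(fit_rot$forces, t(apply(fit1$forces, 1, function(v) R %*% v)),
               tolerance = 1e-4)
})

test_that("rank-deficient systems fall back to the minimum-norm solution", {
  sub <- paam()
  p1 <- circular_patch(1, c(20e-6, 20e-6), 2e-6)
  g <- list(x = seq(5e-6, 35e-6, by = 3e-6), y = seq(5e-6, 35e-6, by = 3e-6))
  fld <- forward_displacement_field(list(p1), rbind(c(2e-9, 0)), g, sub)
  # duplicated patch -> exactly collinear columns
  fit <- fit_patch_forces(fld, list(p1, p1), sub)
  expect_true(fit$diagnostics$rank_deficient)
  expect_true(all(is.finite(fit$forces)))
  # minimum-norm solution splits the force between the twins
  expect_equal(colSums(fit$forces), c(2e-9, 0), tolerance = 1e-6)
})

test_that("noisy fits stay within the identifiability bounds", {
  sub <- paam()
  scen <- default_scenario("colinear", n_frames = 12L)
  truth <- scenario_truth_forces(scen)
  g <- analysis_grid()
  fld <- forward_displacement_field(scen$patches, truth[[8]], g, sub)
  f2 <- add_field_noise(fld, 0.05, seed = 7L)
  fit <- fit_patch_forces(f2, scen$patches, sub)
  per_patch <- sqrt(rowSums((fit$forces - truth[[8]])^2)) /
    sqrt(rowSums(truth[[8]]^2))
  expect_lt(max(per_patch), 0.15)
  fex <- scen$external_force_profile[8, ]
  net <- net_traction_force(fit)
  expect_lt(abs(net$magnitude - sqrt(sum(fex^2))) / sqrt(sum(fex^2)), 0.05)
})

test_that("net traction force sums patch vectors", {
  s <- patch_force_set(0L, 0, rbind(c(0, 0), c(1e-5, 0)),
                       rbind(c(1e-9, 0), c(-1e-9, 0)))
  expect_equal(net_traction_force(s)$magnitude, 0)
  s2 <- patch_force_set(0L, 0, rbind(c(0, 0)), rbind(c(0, 2e-9)))
  expect_equal(net_traction_force(s2)$magnitude, 2e-9)
  expect_equal(net_traction_force(s2)$vector, c(0, 2e-9))
})

test_that("image-stack reconstruction tracks the programmed experiment", {
  sub <- paam()
  spec <- bead_field_spec(n_beads = 2200L, image_shape = c(384L, 384L),
                          seed = 4L)
  scen <- default_scenario("colinear", n_frames = 6L, seed = 4L)
  sim <- simulate_shear_experiment(scen, spec, sub)
  # identity stack: every frame equal to the reference -> zero forces
  idstack <- list(sim$reference, sim$reference)
  # zero signal in every window -> documented centroid-fallback warnings
  sets0 <- suppressWarnings(
    reconstruct_time_series(idstack, sim$reference, sim$windows,
                            piv_settings(), sub))
  expect_lt(max(abs(vapply(sets0, function(s) max(abs(s$forces)), numeric(1)))),
            1e-12)
  # ramped monopole: net traction tracks the programmed external force
  sets <- reconstruct_time_series(sim$images, sim$reference, sim$windows,
                                  piv_settings(), sub, scen$frame_rate)
  expect_length(sets, 6L)
  fex <- sqrt(rowSums(scen$external_force_profile^2))
  net <- vapply(sets, function(s) net_traction_force(s)$magnitude, numeric(1))
  rel <- abs(net[fex > 0] - fex[fex > 0]) / fex[fex > 0]
  expect_lt(stats::median(rel), 0.10)
  expect_equal(vapply(sets, function(s) s$time, numeric(1)),
               (0:5) / scen$frame_rate)
  tab <- force_series_table(sets)
  expect_true(all(c("Fx_nN", "Fy_nN", "net_mag_nN", "residual_um") %in% names(tab)))
  expect_equal(nrow(tab), 6L * 9L)
})

test_that("a programmed rupture shows up as a force drop at the right frame", {
  sub <- paam()
  scen <- default_scenario("rupture", n_frames = 10L, rupture_frame = 6L)
  # finer sampling than the default PIV pitch: the post-rupture force
  # floor of a dead adhesion is set by center/radius estimation error,
  # which the 1.3 um grid keeps below 10% of the pre-rupture force
  g <- analysis_grid(1.3e-6)
  sets <- reconstruct_scenario_fields(scen, g, sub)
  pos <- t(vapply(scen$patches, function(p) p$center, numeric(2)))
  ruptured <- order(pos[1:8, 2])[1:3]
  for (k in ruptured) {
    before <- sqrt(sum(sets[[5]]$forces[k, ]^2))
    after <- sqrt(sum(sets[[6]]$forces[k, ]^2))
    expect_lt(after, 0.10 * before)
  }
  # the external force is still balanced after the rupture
  fex <- scen$external_force_profile[8, ]
  net <- net_traction_force(sets[[8]])
  expect_lt(abs(net$magnitude - sqrt(sum(fex^2))) / sqrt(sum(fex^2)), 0.05)
})
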