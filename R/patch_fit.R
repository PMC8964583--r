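## Circular-patch force reconstruction.
##
## Each adhesion is modelled as a disc of uniform traction; per-frame
## force vectors are obtained by unregularized linear least squares
## against the measured displacement field. Because the disc solution is
## integrated over the contact area, the method stays well-posed in the
## presence of a net external force (monopole), where Fourier-space TFM
## fails. Regularization is deliberately omitted from the fit: it biases
## absolute force magnitudes downward, and the absolute net force is the
## quantity compared against the needle force.

#' Search window set
#'
#' User-drawn axis-aligned rectangles, one prospective adhesion per
#' window.
#'
#' @param rectangles Data frame with columns `label`, `xmin`, `xmax`,
#'   `ymin`, `ymax` (m).
#' @return Object of class `search_window_set`.
#' @export
search_window_set <- function(rectangles) {
  stopifnot(is.data.frame(rectangles),
            all(c("label", "xmin", "xmax", "ymin", "ymax") %in% names(rectangles)),
            !anyDuplicated(rectangles$label),
            all(rectangles$xmax > rectangles$xmin),
            all(rectangles$ymax > rectangles$ymin))
  structure(rectangles, class = c("search_window_set", "data.frame"))
}

#' Detect adhesion centers as local maxima within search windows
#'
#' One adhesion is assumed per window; the center is the grid node with
#' the maximal field magnitude inside the window (invalid nodes
#' excluded). Ties break deterministically to the lowest row, then the
#' lowest column. An all-zero or all-invalid window returns the window
#' centroid with a warning.
#'
#' @param field_magnitude Output of [field_magnitude()].
#' @param windows A [search_window_set()].
#' @return K x 2 matrix of center positions (m), rows named by label.
#' @export
detect_patch_centers <- function(field_magnitude, windows) {
  fm <- field_magnitude
  K <- nrow(windows)
  out <- matrix(NA_real_, K, 2, dimnames = list(windows$label, c("x", "y")))
  for (k in seq_len(K)) {
    jx <- which(fm$x >= windows$xmin[k] & fm$x <= windows$xmax[k])
    iy <- which(fm$y >= windows$ymin[k] & fm$y <= windows$ymax[k])
    if (length(jx) == 0L || length(iy) == 0L) {
      stop(sprintf("search window '%s' contains no grid nodes", windows$label[k]))
    }
    sub <- fm$mag[iy, jx, drop = FALSE]
    vld <- fm$valid[iy, jx, drop = FALSE]
    sub[!vld] <- -Inf
    if (all(!vld) || max(sub) <= 0) {
      warning(sprintf("window '%s': no signal; using window centroid",
                      windows$label[k]))
      out[k, ] <- c(mean(c(windows$xmin[k], windows$xmax[k])),
                    mean(c(windows$ymin[k], windows$ymax[k])))
      next
    }
    ## column-major which.max is lowest row first, then column: the
    ## documented deterministic tie-break
    im <- which.max(sub)
    ir <- (im - 1L) %% nrow(sub) + 1L
    ic <- (im - 1L) %/% nrow(sub) + 1L
    out[k, ] <- c(fm$x[jx[ic]], fm$y[iy[ir]])
  }
  out
}

## Bilinear interpolation of a gridded scalar at arbitrary points;
## points outside the grid return NA.
.interp_bilinear <- function(x, y, z, px, py) {
  jx <- findInterval(px, x); iy <- findInterval(py, y)
  ok <- jx >= 1 & jx < length(x) & iy >= 1 & iy < length(y)
  out <- rep(NA_real_, length(px))
  if (!any(ok)) return(out)
  jx <- jx[ok]; iy <- iy[ok]
  tx <- (px[ok] - x[jx]) / (x[jx + 1] - x[jx])
  ty <- (py[ok] - y[iy]) / (y[iy + 1] - y[iy])
  z11 <- z[cbind(iy, jx)]; z12 <- z[cbind(iy, jx + 1)]
  z21 <- z[cbind(iy + 1, jx)]; z22 <- z[cbind(iy + 1, jx + 1)]
  out[ok] <- (1 - ty) * ((1 - tx) * z11 + tx * z12) +
    ty * ((1 - tx) * z21 + tx * z22)
  out
}

#' Estimate per-patch radii from the magnitude map
#'
#' The per-frame radius of each patch is the minimum of (a) half the
#' distance to the nearest other detected center and (b) the radial
#' distance at which the azimuthally averaged magnitude falls to 50% of
#' its center value, clamped to \[`r_min`, `r_max`\]. For a single patch
#' the neighbor bound is omitted.
#'
#' @param field_magnitude Output of [field_magnitude()].
#' @param centers K x 2 matrix from [detect_patch_centers()].
#' @param r_min,r_max Clamp bounds (m); default 1 and 10 um.
#' @param n_dirs Azimuthal sampling directions (default 16).
#' @return Numeric vector of K radii (m).
#' @export
estimate_patch_radius <- function(field_magnitude, centers,
                                  r_min = 1e-6, r_max = 10e-6,
                                  n_dirs = 16L) {
  fm <- field_magnitude
  K <- nrow(centers)
  radii <- numeric(K)
  ang <- (seq_len(n_dirs) - 1) * 2 * pi / n_dirs
  rr <- seq(0, r_max, by = fm$x[2] - fm$x[1]) # radial step = grid spacing
  if (length(rr) < 3L) rr <- seq(0, r_max, length.out = 8L)
  for (k in seq_len(K)) {
    ## azimuthally averaged radial profile
    prof <- vapply(rr, function(r) {
      v <- .interp_bilinear(fm$x, fm$y, fm$mag,
                            centers[k, 1] + r * cos(ang),
                            centers[k, 2] + r * sin(ang))
      mean(v, na.rm = TRUE)
    }, numeric(1))
    c0 <- prof[1]
    r_half <- r_max
    if (is.finite(c0) && c0 > 0) {
      below <- which(prof <= 0.5 * c0 & is.finite(prof))
      below <- below[below > 1]
      if (length(below) > 0) {
        i <- below[1]
        ## linear interpolation between the bracketing radii
        f <- (prof[i - 1] - 0.5 * c0) / (prof[i - 1] - prof[i])
        r_half <- rr[i - 1] + f * (rr[i] - rr[i - 1])
      }
    }
    r_nb <- Inf
    if (K > 1) {
      d <- sqrt((centers[, 1] - centers[k, 1])^2 +
                  (centers[, 2] - centers[k, 2])^2)
      r_nb <- min(d[-k]) / 2
    }
    radii[k] <- min(max(min(r_half, r_nb), r_min), r_max)
  }
  radii
}

#' Per-frame patch force set
#'
#' @param frame_index Integer frame index (0-based; frame 0 has no
#'   monopole).
#' @param time Time (s).
#' @param positions K x 2 patch center positions (m).
#' @param forces K x 2 fitted force vectors (N).
#' @param residual_norm Root-mean-square displacement misfit (m).
#' @param diagnostics Optional list (rank deficiency flag, condition
#'   number, valid-vector count).
#' @return Object of class `patch_force_set`.
#' @export
patch_force_set <- function(frame_index, time, positions, forces,
                            residual_norm = 0, diagnostics = list()) {
  forces <- matrix(forces, ncol = 2)
  positions <- matrix(positions, ncol = 2)
  stopifnot(nrow(forces) == nrow(positions), residual_norm >= 0)
  structure(list(frame_index = frame_index, time = time,
                 positions = positions, forces = forces,
                 residual_norm = residual_norm, diagnostics = diagnostics),
            class = "patch_force_set")
}

#' Fit per-patch force vectors to a displacement field
#'
#' Solves the unregularized linear least-squares problem
#' `min_F || u_measured - A F ||^2` over the valid displacement
#' components, where `A` is the [patch_response_operator()]. A
#' rank-deficient system falls back to the minimum-norm solution and is
#' flagged in the diagnostics.
#'
#' @param field A [displacement_field()].
#' @param patches List of [circular_patch()].
#' @param substrate An [elastic_substrate()].
#' @param frame_index,time Metadata stored in the result.
#' @return A [patch_force_set()].
#' @export
fit_patch_forces <- function(field, patches, substrate,
                             frame_index = 0L, time = 0) {
  K <- length(patches)
  stopifnot(K >= 1L)
  pts <- as.matrix(expand.grid(x = field$x, y = field$y))
  v <- as.vector(t(field$valid))    # expand.grid order: x fastest
  ux <- as.vector(t(field$ux)); uy <- as.vector(t(field$uy))
  pts <- pts[v, , drop = FALSE]
  b <- c(ux[v], uy[v])
  if (length(b) < 2 * K) stop("fewer valid displacement components than unknowns")
  A <- patch_response_operator(pts, patches, substrate)
  qrA <- qr(A)
  rank_def <- qrA$rank < 2 * K
  if (rank_def) {
    f <- as.numeric(MASS::ginv(A) %*% b)
  } else {
    f <- qr.coef(qrA, b)
  }
  resid <- b - as.numeric(A %*% f)
  forces <- cbind(f[seq_len(K)], f[K + seq_len(K)])
  sv <- svd(A, nu = 0, nv = 0)$d
  patch_force_set(frame_index, time,
                  t(vapply(patches, function(p) p$center, numeric(2))),
                  forces,
                  residual_norm = sqrt(mean(resid^2)),
                  diagnostics = list(rank_deficient = rank_def,
                                     condition = max(sv) / max(min(sv), .Machine$double.xmin),
                                     n_valid = sum(v)))
}

#' Net traction force of a patch force set
#'
#' The vector sum of all patch forces; under an external shear force
#' this must balance the needle force (force monopole), which is the
#' method's central validation.
#'
#' @param set A [patch_force_set()].
#' @return List with `vector` (2, N) and `magnitude` (N).
#' @export
net_traction_force <- function(set) {
  v <- colSums(set$forces)
  list(vector = v, magnitude = sqrt(sum(v^2)))
}

#' Reconstruct the per-patch force time series from an image stack
#'
#' Runs PIV of every frame against the post-detachment reference, detects
#' per-frame patch centers inside the search windows on the
#' displacement-magnitude map, determines a common per-patch radius (the
#' median of the per-frame estimates, clamped), then fits per-frame force
#' vectors. Patch centers may move frame to frame; radii are frozen after
#' the first pass.
#'
#' @param image_stack List of [bead_image()], one per frame.
#' @param reference_image Reference [bead_image()] (after cell
#'   detachment).
#' @param windows A [search_window_set()] (m).
#' @param settings A [piv_settings()].
#' @param substrate An [elastic_substrate()].
#' @param frame_rate Frames per second; timestamps are
#'   `frame_index / frame_rate` with 0-based indices.
#' @return List of [patch_force_set()]; common radii in
#'   `attr(, "radii")`, per-frame PIV validity fraction in
#'   `attr(, "valid_fraction")`. Frames with under 50% valid vectors are
#'   flagged in the set diagnostics but still fitted.
#' @export
reconstruct_time_series <- function(image_stack, reference_image, windows,
                                    settings, substrate, frame_rate = 0.85) {
  n <- length(image_stack)
  stopifnot(n >= 1L)
  fields <- vector("list", n)
  centers <- vector("list", n)
  radii_frame <- vector("list", n)
  for (t in seq_len(n)) {
    fld <- piv_displacement(reference_image, image_stack[[t]], settings)
    fm <- field_magnitude(fld)
    ctr <- detect_patch_centers(fm, windows)
    radii_frame[[t]] <- estimate_patch_radius(fm, ctr)
    fields[[t]] <- fld
    centers[[t]] <- ctr
  }
  radii <- apply(do.call(rbind, radii_frame), 2, stats::median)
  radii <- pmin(pmax(radii, 1e-6), 10e-6)
  sets <- vector("list", n)
  vf <- numeric(n)
  for (t in seq_len(n)) {
    patches <- lapply(seq_len(nrow(windows)), function(k) {
      circular_patch(windows$label[k], centers[[t]][k, ], radii[k])
    })
    set <- fit_patch_forces(fields[[t]], patches, substrate,
                            frame_index = t - 1L,
                            time = (t - 1L) / frame_rate)
    vf[t] <- mean(fields[[t]]$valid)
    set$diagnostics$low_valid_fraction <- vf[t] < 0.5
    sets[[t]] <- set
  }
  attr(sets, "radii") <- radii
  attr(sets, "valid_fraction") <- vf
  sets
}

#' Tabulate a force time series in lab units
#'
#' @param sets List of [patch_force_set()].
#' @param labels Optional patch labels.
#' @return Data frame with per-frame, per-patch rows: `frame`, `time_s`,
#'   `patch_id`, `cx_um`, `cy_um`, `Fx_nN`, `Fy_nN`, plus per-frame
#'   `net_Fx_nN`, `net_Fy_nN`, `net_mag_nN`, `residual_um`.
#' @export
force_series_table <- function(sets, labels = NULL) {
  rows <- lapply(sets, function(s) {
    K <- nrow(s$forces)
    net <- net_traction_force(s)
    data.frame(frame = s$frame_index, time_s = s$time,
               patch_id = if (is.null(labels)) seq_len(K) else labels,
               cx_um = m_to_um(s$positions[, 1]),
               cy_um = m_to_um(s$positions[, 2]),
               Fx_nN = n_to_nn(s$forces[, 1]),
               Fy_nN = n_to_nn(s$forces[, 2]),
               net_Fx_nN = n_to_nn(net$vector[1]),
               net_Fy_nN = n_to_nn(net$vector[2]),
               net_mag_nN = n_to_nn(net$magnitude),
               residual_um = m_to_um(s$residual_norm))
  })
  do.call(rbind, rows)
}
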