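## Particle image velocimetry on fluorescent bead images.
##
## Windowed FFT cross-correlation of mean-subtracted interrogation
## windows, three-point Gaussian subpixel peak refinement, peak-ratio SNR
## filtering and the normalized median (universal outlier) test.

#' Bead image container
#'
#' @param pixels Intensity matrix, rows = y (downward), cols = x.
#' @param pixel_size Physical size of one pixel (m).
#' @return Object of class `bead_image`.
#' @export
bead_image <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), min(pixels) >= 0,
            length(pixel_size) == 1L, pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 convention = COORD_CONVENTION), class = "bead_image")
}

#' PIV settings
#'
#' Defaults follow common practice for TFM bead images: 64-pixel windows
#' with 50% overlap, minimum correlation signal-to-noise ratio 1.5, and
#' normalized median test threshold 2.0 with epsilon = 0.1 px.
#'
#' @param window Interrogation window size in pixels; power of two >= 16.
#' @param overlap Window overlap fraction in \[0, 1).
#' @param snr_min Minimum primary/secondary correlation peak ratio.
#' @param nmt_threshold Normalized median test threshold.
#' @param nmt_epsilon Normalization floor of the median test (px).
#' @return Object of class `piv_settings`.
#' @export
piv_settings <- function(window = 64L, overlap = 0.5, snr_min = 1.5,
                         nmt_threshold = 2.0, nmt_epsilon = 0.1) {
  window <- as.integer(window)
  stopifnot(window >= 16L, bitwAnd(window, window - 1L) == 0L,
            overlap >= 0, overlap < 1, snr_min >= 1, nmt_threshold > 0,
            nmt_epsilon >= 0)
  structure(list(window = window, overlap = overlap, snr_min = snr_min,
                 nmt_threshold = nmt_threshold, nmt_epsilon = nmt_epsilon),
            class = "piv_settings")
}

## Wrap a 0-based FFT index into the signed displacement range (-n/2, n/2].
.wrap_shift <- function(idx0, n) ifelse(idx0 > n / 2, idx0 - n, idx0)

## Three-point Gaussian peak interpolation along one axis. Falls back to
## parabolic when any of the three samples is non-positive.
.subpixel_1d <- function(cm1, c0, cp1) {
  if (cm1 > 0 && c0 > 0 && cp1 > 0) {
    den <- log(cm1) + log(cp1) - 2 * log(c0)
    if (den < 0) return((log(cm1) - log(cp1)) / (2 * den))
  }
  den <- cm1 + cp1 - 2 * c0
  if (den < 0) return((cm1 - cp1) / (2 * den))
  0
}

#' Correlation-map peak extraction with SNR validation
#'
#' Finds the primary correlation peak, computes the peak-ratio
#' signal-to-noise ratio (secondary peak searched outside a square
#' exclusion zone around the primary), and flags the vector invalid when
#' the ratio falls below `snr_min`.
#'
#' @param correlation_map Wrapped (FFT-layout) correlation matrix of one
#'   interrogation window pair.
#' @param snr_min Minimum acceptable peak ratio (default 1.5).
#' @param exclusion Half-width in px of the exclusion zone (default 3).
#' @return List with integer `shift` (`c(sx, sy)` px, deformed relative
#'   to reference), `snr`, and `valid`. A featureless (flat) map returns
#'   `snr = 1` and `valid = FALSE`.
#' @export
snr_filter <- function(correlation_map, snr_min = 1.5, exclusion = 3L) {
  cm <- correlation_map
  n_r <- nrow(cm); n_c <- ncol(cm)
  rng <- range(cm)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    return(list(shift = c(0L, 0L), snr = 1, valid = FALSE))
  }
  imax <- which.max(cm)
  pr <- (imax - 1L) %% n_r + 1L
  pc <- (imax - 1L) %/% n_r + 1L
  p1 <- cm[pr, pc]
  ## wrapped Chebyshev distance to the primary peak
  dr <- abs(.wrap_shift((seq_len(n_r) - pr) %% n_r, n_r))
  dc <- abs(.wrap_shift((seq_len(n_c) - pc) %% n_c, n_c))
  excl <- outer(dr <= exclusion, dc <= exclusion, "&")
  p2 <- if (all(excl)) -Inf else max(cm[!excl])
  snr <- if (p1 <= 0) 1 else if (p2 <= 0) Inf else p1 / p2
  sx <- .wrap_shift(pc - 1L, n_c)
  sy <- .wrap_shift(pr - 1L, n_r)
  list(shift = c(sx, sy), peak = c(pr, pc), snr = snr,
       valid = is.finite(p1) && snr >= snr_min)
}

## Cross-correlate one window pair via FFT. Returns the wrapped map whose
## peak sits at the displacement of `g` relative to `f`.
.xcorr_fft <- function(f, g) {
  f <- f - mean(f); g <- g - mean(g)
  Fc <- stats::fft(f); Gc <- stats::fft(g)
  Re(stats::fft(Conj(Fc) * Gc, inverse = TRUE)) / length(f)
}

#' PIV displacement field from a reference/deformed image pair
#'
#' @param reference,deformed [bead_image()] objects of identical shape;
#'   the reference is the relaxed (post-detachment) state.
#' @param settings A [piv_settings()].
#' @param apply_nmt Run the normalized median test after the SNR filter
#'   (default TRUE).
#' @return A [displacement_field()] in meters on the window-center grid
#'   (spacing `window * (1 - overlap)` px). Vectors failing validation
#'   are flagged invalid, not removed.
#' @export
piv_displacement <- function(reference, deformed, settings = piv_settings(),
                             apply_nmt = TRUE) {
  stopifnot(inherits(reference, "bead_image"), inherits(deformed, "bead_image"))
  R <- reference$pixels; D <- deformed$pixels
  if (!all(dim(R) == dim(D))) stop("reference and deformed images differ in shape")
  ps <- reference$pixel_size
  w <- settings$window
  step <- as.integer(round(w * (1 - settings$overlap)))
  if (nrow(R) < w || ncol(R) < w) stop("images smaller than one interrogation window")
  row0 <- seq(1L, nrow(R) - w + 1L, by = step)
  col0 <- seq(1L, ncol(R) - w + 1L, by = step)
  ny <- length(row0); nx <- length(col0)
  ux <- uy <- matrix(0, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  snr <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      rr <- row0[i]:(row0[i] + w - 1L)
      cc <- col0[j]:(col0[j] + w - 1L)
      f <- R[rr, cc]; g <- D[rr, cc]
      if (stats::sd(f) == 0 || stats::sd(g) == 0) next
      cm <- .xcorr_fft(f, g)
      pk <- snr_filter(cm, settings$snr_min)
      snr[i, j] <- pk$snr
      if (!pk$valid) next
      pr <- pk$peak[1]; pc <- pk$peak[2]
      im1 <- if (pr == 1L) w else pr - 1L
      ip1 <- if (pr == w) 1L else pr + 1L
      jm1 <- if (pc == 1L) w else pc - 1L
      jp1 <- if (pc == w) 1L else pc + 1L
      dy <- .subpixel_1d(cm[im1, pc], cm[pr, pc], cm[ip1, pc])
      dx <- .subpixel_1d(cm[pr, jm1], cm[pr, pc], cm[pr, jp1])
      ux[i, j] <- (pk$shift[1] + dx) * ps
      uy[i, j] <- (pk$shift[2] + dy) * ps
      valid[i, j] <- TRUE
    }
  }
  x <- (col0 - 1 + (w - 1) / 2) * ps
  y <- (row0 - 1 + (w - 1) / 2) * ps
  fld <- displacement_field(x, y, ux, uy, valid)
  fld$snr <- snr
  if (apply_nmt) {
    fld <- normalized_median_filter(fld, settings$nmt_threshold,
                                    settings$nmt_epsilon * ps)
  }
  fld
}

#' Normalized median (universal outlier) test
#'
#' Westerweel's neighborhood test applied per component: for each vector
#' the residual `r = |u - median(valid 8-neighbors)| /
#' (median(|neighbors - median|) + epsilon)` is computed; a vector with
#' `r > threshold` in either component is flagged invalid. Vector values
#' are never altered, only validity flags; already-invalid vectors stay
#' invalid and are excluded from the neighborhoods.
#'
#' @param field A [displacement_field()].
#' @param threshold Invalidity threshold (default 2.0).
#' @param epsilon Normalization floor in the field's length unit.
#' @return The field with updated `valid`.
#' @export
normalized_median_filter <- function(field, threshold = 2.0, epsilon = 0.1e-6) {
  ny <- length(field$y); nx <- length(field$x)
  old_valid <- field$valid
  new_valid <- old_valid
  comp <- list(field$ux, field$uy)
  for (u in comp) {
    for (i in seq_len(ny)) {
      for (j in seq_len(nx)) {
        if (!old_valid[i, j]) next
        ii <- max(1L, i - 1L):min(ny, i + 1L)
        jj <- max(1L, j - 1L):min(nx, j + 1L)
        sel <- old_valid[ii, jj, drop = FALSE]
        sel[match(i, ii), match(j, jj)] <- FALSE
        nb <- u[ii, jj, drop = FALSE][sel]
        if (length(nb) < 3L) next
        med <- stats::median(nb)
        rm_ <- stats::median(abs(nb - med))
        r <- abs(u[i, j] - med) / (rm_ + epsilon)
        if (r > threshold) new_valid[i, j] <- FALSE
      }
    }
  }
  field$valid <- new_valid
  field
}

#' Fill invalid vectors by iterated valid-neighbor averaging
#'
#' Replaces invalid vectors by the mean of their valid 8-neighbors,
#' iterating until the grid is full (needed by FTTC, which requires a
#' complete grid; the least-squares patch fit instead simply excludes
#' invalid vectors).
#'
#' @param field A [displacement_field()].
#' @return Field with all nodes valid; filled nodes listed in
#'   `attr(, "filled")`.
#' @export
fill_invalid_vectors <- function(field) {
  filled <- which(!field$valid)
  valid <- field$valid
  ux <- field$ux; uy <- field$uy
  ny <- nrow(valid); nx <- ncol(valid)
  if (!any(valid)) stop("cannot fill a field with no valid vectors")
  while (!all(valid)) {
    prev <- valid
    idx <- which(!valid, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      ii <- max(1L, i - 1L):min(ny, i + 1L)
      jj <- max(1L, j - 1L):min(nx, j + 1L)
      sel <- prev[ii, jj, drop = FALSE]
      if (!any(sel)) next
      ux[i, j] <- mean(ux[ii, jj, drop = FALSE][sel])
      uy[i, j] <- mean(uy[ii, jj, drop = FALSE][sel])
      valid[i, j] <- TRUE
    }
    if (identical(valid, prev)) stop("fill stalled (isolated region)")
  }
  out <- displacement_field(field$x, field$y, ux, uy)
  attr(out, "filled") <- filled
  out
}

#' Displacement magnitude map
#'
#' @param field A [displacement_field()].
#' @return List with `x`, `y`, `mag` (matrix, m) and `valid`.
#' @export
field_magnitude <- function(field) {
  list(x = field$x, y = field$y,
       mag = sqrt(field$ux^2 + field$uy^2), valid = field$valid)
}
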