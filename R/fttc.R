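## Fourier Transform Traction Cytometry with 0th-order Tikhonov
## regularization and GCV parameter selection.
##
## Per wavevector k the Boussinesq operator mapping traction to surface
## displacement is diagonal in the basis (khat, khat_perp):
##   s_parallel(k) = 2 (1+nu)(1-nu) / (E |k|)
##   s_perp(k)     = 2 (1+nu)       / (E |k|)
## The k = 0 mode (the force monopole) is not invertible — the Green's
## function diverges there — so it is excluded and the reconstructed
## traction always sums to zero. This is precisely why FTTC can only be
## used at zero external force and the circular-patch method takes over
## once the needle applies a monopole.
##
## The operator is normalized by its largest singular value so the
## Tikhonov parameter lambda is dimensionless and transferable across
## grids and moduli.

## Per-mode quantities of the padded square grid: wavevectors, normalized
## singular values, and the projections of the displacement spectrum onto
## the parallel/perpendicular singular directions.
.fttc_modes <- function(ux, uy, spacing, substrate) {
  N <- nrow(ux)
  stopifnot(ncol(ux) == N)
  fidx <- c(0:(N %/% 2 - 1), -(N %/% 2):-1)
  k1 <- 2 * pi * fidx / (N * spacing)
  KX <- matrix(k1, N, N, byrow = TRUE)   # x along columns
  KY <- matrix(k1, N, N)
  kk <- sqrt(KX^2 + KY^2)
  kk[1, 1] <- Inf                        # k = 0 handled separately
  E <- substrate$E; nu <- substrate$nu
  s_par <- 2 * (1 + nu) * (1 - nu) / (E * kk)
  s_perp <- 2 * (1 + nu) / (E * kk)
  smax <- max(s_perp)
  khx <- KX / kk; khy <- KY / kk
  U1 <- stats::fft(ux); U2 <- stats::fft(uy)
  upar <- khx * U1 + khy * U2
  uperp <- -khy * U1 + khx * U2
  list(N = N, khx = khx, khy = khy, smax = smax,
       sp = s_par / smax, sq = s_perp / smax,
       upar = upar, uperp = uperp)
}

## Mean-pad the field to a power-of-two square; returns padded matrices
## and the index ranges of the original region.
.fttc_pad <- function(field) {
  ny <- length(field$y); nx <- length(field$x)
  N <- 2^ceiling(log2(max(nx, ny)))
  ux <- matrix(mean(field$ux), N, N)
  uy <- matrix(mean(field$uy), N, N)
  ux[seq_len(ny), seq_len(nx)] <- field$ux
  uy[seq_len(ny), seq_len(nx)] <- field$uy
  list(ux = ux, uy = uy, rows = seq_len(ny), cols = seq_len(nx))
}

#' Traction field container
#'
#' @param x,y Node coordinates (m).
#' @param tx,ty Traction component matrices (Pa), rows = y.
#' @param lambda_used Dimensionless Tikhonov parameter used.
#' @return Object of class `traction_field`.
#' @export
traction_field <- function(x, y, tx, ty, lambda_used = 0) {
  stopifnot(all(is.finite(tx)), all(is.finite(ty)), lambda_used >= 0)
  structure(list(x = x, y = y, tx = tx, ty = ty,
                 spacing = mean(diff(x)), lambda_used = lambda_used,
                 convention = COORD_CONVENTION),
            class = "traction_field")
}

#' FTTC traction reconstruction
#'
#' Inverts the per-wavevector Boussinesq operator with 0th-order
#' Tikhonov filter factors at the given dimensionless `lambda`; the k=0
#' traction is set to zero and the returned stresses are re-centred so
#' they sum to the zero vector exactly. The field is mean-padded to a
#' power-of-two square internally and the apron discarded, which limits
#' wrap-around artifacts of the long-ranged kernel.
#'
#' @param field A full-grid [displacement_field()]; invalid vectors are
#'   gap-filled with [fill_invalid_vectors()] first.
#' @param substrate An [elastic_substrate()].
#' @param lambda Dimensionless regularization parameter (>= 0); the
#'   operator is pre-normalized by its largest singular value.
#' @return A [traction_field()].
#' @export
fttc_reconstruct <- function(field, substrate, lambda = 0) {
  stopifnot(lambda >= 0)
  if (!all(field$valid)) field <- fill_invalid_vectors(field)
  pad <- .fttc_pad(field)
  md <- .fttc_modes(pad$ux, pad$uy, field$spacing, substrate)
  fp <- md$sp / (md$sp^2 + lambda^2)
  fq <- md$sq / (md$sq^2 + lambda^2)
  wpar <- fp * md$upar
  wperp <- fq * md$uperp
  T1 <- (md$khx * wpar - md$khy * wperp) / md$smax
  T2 <- (md$khy * wpar + md$khx * wperp) / md$smax
  T1[1, 1] <- 0 + 0i; T2[1, 1] <- 0 + 0i
  npix <- md$N^2
  tx <- Re(stats::fft(T1, inverse = TRUE)) / npix
  ty <- Re(stats::fft(T2, inverse = TRUE)) / npix
  tx <- tx[pad$rows, pad$cols]; ty <- ty[pad$rows, pad$cols]
  ## zero-mode convention: the operator carries no net-force information,
  ## so the cropped map is re-centred to sum exactly to zero
  tx <- tx - mean(tx); ty <- ty - mean(ty)
  traction_field(field$x, field$y, tx, ty, lambda_used = lambda)
}

#' Generalized cross-validation function of the Tikhonov parameter
#'
#' `V(lambda) = (1/m) ||(I - A(lambda)) u||^2 / [(1/m) tr(I - A(lambda))]^2`
#' evaluated exactly from the per-mode filter factors (the influence
#' operator is diagonal per wavevector in the singular basis). The k=0
#' mode is excluded; `m = 2 (Npix - 1)`.
#'
#' @param field A full-grid [displacement_field()].
#' @param substrate An [elastic_substrate()].
#' @param lambda Dimensionless parameter value(s).
#' @return Numeric V(lambda), vectorized over `lambda`.
#' @export
gcv_function <- function(field, substrate, lambda) {
  if (!all(field$valid)) field <- fill_invalid_vectors(field)
  pad <- .fttc_pad(field)
  md <- .fttc_modes(pad$ux, pad$uy, field$spacing, substrate)
  npix <- md$N^2
  keep <- rep(TRUE, npix); keep[1] <- FALSE   # drop k = 0
  sp <- md$sp[keep]; sq <- md$sq[keep]
  ap2 <- Mod(md$upar[keep])^2 / npix          # Parseval: spatial-domain norm
  aq2 <- Mod(md$uperp[keep])^2 / npix
  m <- 2 * (npix - 1)
  vapply(lambda, function(l) {
    rp <- l^2 / (sp^2 + l^2)                  # 1 - filter factor
    rq <- l^2 / (sq^2 + l^2)
    num <- sum(rp^2 * ap2 + rq^2 * aq2) / m
    den <- (sum(rp + rq) / m)^2
    num / den
  }, numeric(1))
}

#' Select the Tikhonov parameter by generalized cross-validation
#'
#' Minimizes [gcv_function()] over a log-spaced grid of dimensionless
#' lambda values, refined by golden-section search in the bracketing
#' interval. Deterministic.
#'
#' @param field A full-grid [displacement_field()]; an all-zero field is
#'   an error.
#' @param substrate An [elastic_substrate()].
#' @param lambda_range Log10 search bounds (default 1e-8 .. 10).
#' @param n_grid Coarse grid size (default 60).
#' @return The selected dimensionless lambda.
#' @export
gcv_select_lambda <- function(field, substrate,
                              lambda_range = c(1e-8, 10), n_grid = 60L) {
  if (all(field$ux == 0) && all(field$uy == 0)) {
    stop("cannot select lambda for an all-zero displacement field")
  }
  lg <- 10^seq(log10(lambda_range[1]), log10(lambda_range[2]),
               length.out = n_grid)
  v <- gcv_function(field, substrate, lg)
  i <- which.min(v)
  lo <- lg[max(1L, i - 1L)]; hi <- lg[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(l10) gcv_function(field, substrate, 10^l10),
                         interval = log10(c(lo, hi)), tol = 1e-4)
  10^opt$minimum
}

#' Integrate traction stress over a rectangular window
#'
#' `F = sum(stress) * node_area` over grid nodes inside the window — the
#' per-adhesion force estimate of the FTTC baseline.
#'
#' @param traction A [traction_field()].
#' @param window Rectangle `c(xmin, xmax, ymin, ymax)` (m).
#' @return Numeric length-2 force (N).
#' @export
integrate_window_traction <- function(traction, window) {
  jx <- which(traction$x >= window[1] & traction$x <= window[2])
  iy <- which(traction$y >= window[3] & traction$y <= window[4])
  if (length(jx) == 0L || length(iy) == 0L) stop("window contains no grid nodes")
  area <- traction$spacing^2
  c(sum(traction$tx[iy, jx]) * area, sum(traction$ty[iy, jx]) * area)
}

#' Compare circular-patch and FTTC per-patch forces
#'
#' Valid only on a zero-monopole frame (t = 0), where both methods are
#' applicable.
#'
#' @param patch_forces A [patch_force_set()].
#' @param fttc_forces K x 2 matrix of per-window integrated FTTC forces
#'   (N), same window order.
#' @param labels Optional patch labels.
#' @return Data frame with per-patch magnitudes (nN) from both methods
#'   and their relative difference
#'   `|F_patch - F_fttc| / max(F_patch, F_fttc)`.
#' @export
compare_methods <- function(patch_forces, fttc_forces, labels = NULL) {
  fp <- sqrt(rowSums(patch_forces$forces^2))
  ff <- sqrt(rowSums(matrix(fttc_forces, ncol = 2)^2))
  stopifnot(length(fp) == length(ff))
  denom <- pmax(fp, ff)
  data.frame(patch_id = if (is.null(labels)) seq_along(fp) else labels,
             F_patch_nN = n_to_nn(fp), F_fttc_nN = n_to_nn(ff),
             rel_diff = ifelse(denom > 0, abs(fp - ff) / denom, 0))
}
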