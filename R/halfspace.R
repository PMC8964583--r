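## Elastic half-space surface mechanics.
##
## The substrate is modelled as a linear-elastic, isotropic, semi-infinite
## half-space (the gel is thick compared to adhesion sizes and bead depth).
## Only in-plane (tangential) surface tractions and displacements are
## considered. The Boussinesq/Cerruti surface solution gives the in-plane
## displacement at the surface due to an in-plane point force F at the
## origin as u_i = G_ij(r) F_j with
##
##   G_ij(r) = (1+nu) / (pi E |r|) * [ (1-nu) delta_ij + nu rhat_i rhat_j ]
##
## The 1/|r| singularity is removed for finite adhesions by integrating G
## over a disc of uniform traction (the circular-patch solution).

#' Elastic substrate description
#'
#' @param youngs_modulus Young's modulus in Pa; must be positive.
#' @param poisson_ratio Poisson ratio, dimensionless in \[0, 0.5\].
#'   Defaults to 0.5 (incompressible, the standard assumption for
#'   polyacrylamide TFM substrates).
#' @return An object of class `elastic_substrate` with fields `E` and `nu`.
#' @export
elastic_substrate <- function(youngs_modulus, poisson_ratio = 0.5) {
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1L,
            is.finite(youngs_modulus), youngs_modulus > 0,
            is.numeric(poisson_ratio), length(poisson_ratio) == 1L,
            poisson_ratio >= 0, poisson_ratio <= 0.5)
  structure(list(E = youngs_modulus, nu = poisson_ratio),
            class = "elastic_substrate")
}

#' @export
print.elastic_substrate <- function(x, ...) {
  cat(sprintf("Elastic half-space substrate: E = %.4g Pa, nu = %.3g\n",
              x$E, x$nu))
  invisible(x)
}

#' Circular adhesion patch
#'
#' A focal-adhesion patch represented as a disc of uniform traction.
#'
#' @param id Patch identifier (character or integer).
#' @param center Numeric length-2, patch center (m).
#' @param radius Disc radius (m), positive.
#' @param search_window Optional axis-aligned rectangle
#'   `c(xmin, xmax, ymin, ymax)` (m) containing the center.
#' @return Object of class `circular_patch`.
#' @export
circular_patch <- function(id, center, radius, search_window = NULL) {
  stopifnot(length(center) == 2L, is.finite(center),
            length(radius) == 1L, is.finite(radius), radius > 0)
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 4L,
              center[1] >= search_window[1], center[1] <= search_window[2],
              center[2] >= search_window[3], center[2] <= search_window[4])
  }
  structure(list(id = id, center = as.numeric(center),
                 radius = as.numeric(radius),
                 search_window = search_window),
            class = "circular_patch")
}

#' Boussinesq surface Green's tensor for a tangential point force
#'
#' @param separation Numeric length-2 vector from force point to field
#'   point (m); must be nonzero.
#' @param substrate An [elastic_substrate()].
#' @return 2x2 symmetric matrix (m/N); `u = G %*% F`.
#' @details G(r) = G(-r), decays as 1/|r|, and is rotationally
#'   equivariant: G(R r) = R G(r) R^T. At the source point it diverges;
#'   use [disc_displacement()] for finite contact areas.
#' @export
greens_tensor <- function(separation, substrate) {
  stopifnot(length(separation) == 2L, is.finite(separation))
  r <- sqrt(sum(separation^2))
  if (r == 0) stop("greens_tensor: zero separation (singular); use disc_displacement at source points")
  E <- substrate$E; nu <- substrate$nu
  rh <- separation / r
  pref <- (1 + nu) / (pi * E * r)
  pref * ((1 - nu) * diag(2) + nu * outer(rh, rh))
}

## Vectorized point-force displacement: u(points) = G(points - origin) F.
## points: n x 2 (m); returns n x 2 (m).
point_force_displacement <- function(points, origin, force, substrate) {
  rx <- points[, 1] - origin[1]
  ry <- points[, 2] - origin[2]
  r2 <- rx * rx + ry * ry
  r <- sqrt(r2)
  E <- substrate$E; nu <- substrate$nu
  pref <- (1 + nu) / (pi * E * r)
  fx <- force[1]; fy <- force[2]
  rdotf <- (rx * fx + ry * fy) / r2
  ux <- pref * ((1 - nu) * fx + nu * rx * rdotf)
  uy <- pref * ((1 - nu) * fy + nu * ry * rdotf)
  cbind(ux, uy, deparse.level = 0)
}

## Displacement due to a uniform traction q (Pa) over a disc, evaluated at
## arbitrary points (n x 2). The area integral of the Green's tensor is
## reduced exactly to a 1D angular integral: in polar coordinates centred
## on the evaluation point the 1/rho singularity cancels the Jacobian, and
## the radial integral yields the chord length L(phi) of the disc along
## direction phi:
##   u_i(x) = (1+nu)/(pi E) * Int_0^2pi L(phi) [ (1-nu) delta_ij
##                                              + nu e_i(phi) e_j(phi) ] q_j dphi
## with e(phi) = (cos phi, sin phi). For x inside the disc
## L = -b + sqrt(b^2 + a^2 - d^2), b = e . (x - c); for x outside, rays with
## b < 0 and b^2 + a^2 - d^2 > 0 cross the disc with L = 2 sqrt(b^2+a^2-d^2).
## The integrand is periodic and bounded, so a midpoint rule converges fast.
disc_displacement_many <- function(points, center, radius, traction,
                                   substrate, n_angles = 720L) {
  E <- substrate$E; nu <- substrate$nu
  qx <- traction[1]; qy <- traction[2]
  n <- nrow(points)
  out <- matrix(0, n, 2)
  if (qx == 0 && qy == 0) return(out)
  dx <- points[, 1] - center[1]
  dy <- points[, 2] - center[2]
  d2 <- dx * dx + dy * dy
  inside <- d2 < radius^2
  pref <- (1 + nu) / (pi * E)
  assemble <- function(W, cp, sp) {
    ## W: per-node weights L * dphi; cp/sp: matching cos/sin matrices
    I0 <- rowSums(W)
    Icc <- rowSums(W * cp * cp)
    Ics <- rowSums(W * cp * sp)
    Iss <- rowSums(W * sp * sp)
    cbind(pref * ((1 - nu) * I0 * qx + nu * (Icc * qx + Ics * qy)),
          pref * ((1 - nu) * I0 * qy + nu * (Ics * qx + Iss * qy)),
          deparse.level = 0)
  }
  if (any(inside)) {
    ## uniform periodic midpoint rule; the integrand
    ## L(phi) = -b + sqrt(b^2 + a^2 - d^2) is smooth and periodic
    phi <- (seq_len(n_angles) - 0.5) * (2 * pi / n_angles)
    cp <- cos(phi); sp <- sin(phi)
    b <- outer(dx[inside], cp) + outer(dy[inside], sp)
    disc <- b * b + (radius^2 - d2[inside])
    L <- -b + sqrt(pmax(disc, 0))
    cpm <- matrix(cp, sum(inside), n_angles, byrow = TRUE)
    spm <- matrix(sp, sum(inside), n_angles, byrow = TRUE)
    out[inside, ] <- assemble(L * (2 * pi / n_angles), cpm, spm)
  }
  if (any(!inside)) {
    ## exterior points only see the cone |psi| <= asin(a/d) around the
    ## direction to the disc center; substitute sin(psi) = (a/d) sin(u)
    ## to remove the square-root endpoint kinks:
    ##   L dpsi = 2 a cos(u) * (a/d) cos(u) / sqrt(1 - (a/d)^2 sin^2 u) du
    ex <- which(!inside)
    d <- sqrt(d2[ex])
    s <- radius / d                       # sin of cone half-angle
    phi0 <- atan2(-dy[ex], -dx[ex])       # direction toward the center
    u <- (seq_len(n_angles) - 0.5) * pi / n_angles - pi / 2
    su <- sin(u); cu <- cos(u)
    S <- outer(s, su)                     # sin(psi)
    psi <- asin(S)
    phi <- psi + phi0                     # recycles phi0 down columns
    cp <- cos(phi); sp <- sin(phi)
    jac <- outer(s, cu) / sqrt(1 - S * S)
    W <- 2 * radius * matrix(cu, length(ex), n_angles, byrow = TRUE) *
      jac * (pi / n_angles)
    out[ex, ] <- assemble(W, cp, sp)
  }
  out
}

#' Surface displacement from a uniform traction over a circular patch
#'
#' Integrates the Boussinesq Green's tensor over the disc; finite
#' everywhere, including at the patch center where it reduces to the
#' closed form `u = q a (1+nu)(2-nu)/E` (traction-parallel component).
#' Far from the patch it converges to the point-force solution with
#' `F = pi a^2 q`.
#'
#' @param point Numeric length-2 evaluation position (m).
#' @param patch A [circular_patch()].
#' @param traction Numeric length-2 uniform traction vector (Pa).
#' @param substrate An [elastic_substrate()].
#' @param n_angles Angular quadrature nodes (default 720).
#' @return Numeric length-2 displacement (m).
#' @export
disc_displacement <- function(point, patch, traction, substrate,
                              n_angles = 720L) {
  stopifnot(length(point) == 2L, is.finite(point), is.finite(traction),
            patch$radius > 0)
  as.numeric(disc_displacement_many(matrix(point, 1, 2), patch$center,
                                    patch$radius, traction, substrate,
                                    n_angles))
}

## Evaluate the superposed displacement of several loaded patches at
## arbitrary points. Within near_factor radii of a patch the exact disc
## integral is used; beyond, the point-force approximation (relative error
## < 1% past 10 radii, and well below that at the default 5-radius
## threshold boundary for smooth fields).
forward_displacement_at <- function(points, patches, forces, substrate,
                                    near_factor = 5, n_angles = 720L) {
  points <- as.matrix(points)
  u <- matrix(0, nrow(points), 2)
  for (k in seq_along(patches)) {
    p <- patches[[k]]
    f <- as.numeric(forces[k, ])
    if (all(f == 0)) next
    a <- p$radius
    d <- sqrt((points[, 1] - p$center[1])^2 + (points[, 2] - p$center[2])^2)
    near <- d <= near_factor * a
    if (any(near)) {
      q <- f / (pi * a^2)
      u[near, ] <- u[near, ] +
        disc_displacement_many(points[near, , drop = FALSE], p$center, a, q,
                               substrate, n_angles)
    }
    if (any(!near)) {
      u[!near, ] <- u[!near, ] +
        point_force_displacement(points[!near, , drop = FALSE], p$center, f,
                                 substrate)
    }
  }
  u
}

#' Regular-grid displacement field container
#'
#' @param x,y Strictly increasing, equally spaced node coordinates (m).
#' @param ux,uy Displacement component matrices, dimension
#'   `length(y) x length(x)` (rows = y, cols = x).
#' @param valid Logical matrix of the same dimension (default all TRUE).
#' @return Object of class `displacement_field` with `spacing` attached.
#' @export
displacement_field <- function(x, y, ux, uy, valid = NULL) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L || ny >= 2L,
            all(dim(ux) == c(ny, nx)), all(dim(uy) == c(ny, nx)))
  hx <- if (nx > 1) diff(x) else NA_real_
  hy <- if (ny > 1) diff(y) else NA_real_
  h <- c(hx, hy); h <- h[is.finite(h)]
  stopifnot(all(h > 0), diff(range(h)) <= 1e-9 * max(h))
  if (is.null(valid)) valid <- matrix(TRUE, ny, nx)
  stopifnot(all(dim(valid) == c(ny, nx)),
            all(is.finite(ux[valid])), all(is.finite(uy[valid])))
  structure(list(x = x, y = y, ux = ux, uy = uy, valid = valid,
                 spacing = mean(h), convention = COORD_CONVENTION),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("Displacement field: %d x %d nodes, spacing %.3g um, %d%% valid\n",
              length(x$x), length(x$y), m_to_um(x$spacing),
              round(100 * mean(x$valid))))
  invisible(x)
}

#' Forward displacement field from loaded circular patches
#'
#' Superposes the disc solutions of all patches on a regular grid; the
#' uniform traction of patch k is `forces[k, ] / (pi radius_k^2)`.
#'
#' @param patches List of [circular_patch()].
#' @param forces K x 2 matrix of patch forces (N), one row per patch.
#' @param grid List with numeric vectors `x` and `y` (m).
#' @param substrate An [elastic_substrate()].
#' @inheritParams disc_displacement
#' @param near_factor Distance (in patch radii) within which the exact
#'   disc quadrature is used; the point-force form is used beyond.
#' @return A [displacement_field()]. Overlapping patches are allowed but
#'   trigger a warning.
#' @export
forward_displacement_field <- function(patches, forces, grid, substrate,
                                       near_factor = 5, n_angles = 720L) {
  forces <- matrix(forces, ncol = 2)
  stopifnot(nrow(forces) == length(patches))
  if (length(patches) > 1) {
    ctr <- t(vapply(patches, function(p) p$center, numeric(2)))
    rad <- vapply(patches, function(p) p$radius, numeric(1))
    dd <- as.matrix(stats::dist(ctr))
    sumr <- outer(rad, rad, "+")
    diag(dd) <- Inf
    if (any(dd < sumr)) warning("overlapping patches in forward model")
  }
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  u <- forward_displacement_at(pts, patches, forces, substrate,
                               near_factor, n_angles)
  ny <- length(grid$y); nx <- length(grid$x)
  ## expand.grid varies x fastest -> fill by row blocks of constant y
  ux <- matrix(u[, 1], ny, nx, byrow = TRUE)
  uy <- matrix(u[, 2], ny, nx, byrow = TRUE)
  displacement_field(grid$x, grid$y, ux, uy)
}

#' Linear response operator from patch forces to grid displacements
#'
#' Builds the design matrix of the least-squares patch fit: a
#' `2M x 2K` matrix mapping the stacked force vector
#' `(Fx_1..Fx_K, Fy_1..Fy_K)` to stacked displacements
#' `(ux_1..ux_M, uy_1..uy_M)` at the given points.
#'
#' @param grid_points M x 2 matrix of evaluation positions (m).
#' @param patches List of [circular_patch()].
#' @param substrate An [elastic_substrate()].
#' @inheritParams forward_displacement_field
#' @return Numeric matrix, finite entries; applying it to a force vector
#'   equals [forward_displacement_field()] sampled at `grid_points`.
#' @export
patch_response_operator <- function(grid_points, patches, substrate,
                                    near_factor = 5, n_angles = 720L) {
  grid_points <- as.matrix(grid_points)
  M <- nrow(grid_points); K <- length(patches)
  stopifnot(M >= 1L, K >= 1L)
  A <- matrix(0, 2 * M, 2 * K)
  for (k in seq_len(K)) {
    for (j in 1:2) {
      f <- matrix(0, 1, 2); f[j] <- 1
      u <- forward_displacement_at(grid_points, patches[k], f, substrate,
                                   near_factor, n_angles)
      A[seq_len(M), (j - 1) * K + k] <- u[, 1]
      A[M + seq_len(M), (j - 1) * K + k] <- u[, 2]
    }
  }
  A
}
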