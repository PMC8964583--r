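## Force monopole, dipole and torque analysis.
##
## With an external shear force, linear and angular momentum of the
## traction pattern are no longer conserved, so the first moment depends
## on the reference point. All moments here are taken about the
## force-magnitude-weighted contractile center, and that convention is
## stamped into every output.

#' Contractile center of a force distribution
#'
#' The force-magnitude-weighted centroid of the adhesion positions,
#' `x_c = sum(|F_k| x_k) / sum(|F_k|)`.
#'
#' @param positions K x 2 positions (m).
#' @param forces K x 2 force vectors (N); at least one must be nonzero.
#' @return Numeric length-2 position (m).
#' @export
contractile_center <- function(positions, forces) {
  positions <- matrix(positions, ncol = 2)
  forces <- matrix(forces, ncol = 2)
  w <- sqrt(rowSums(forces^2))
  if (sum(w) == 0) stop("contractile center undefined: all forces are zero")
  c(sum(w * positions[, 1]), sum(w * positions[, 2])) / sum(w)
}

#' Force moments of a patch force distribution
#'
#' Computes, about the contractile center x_c:
#' monopole `M = sum F_k`; first-moment tensor
#' `D_ij = sum (x_k - x_c)_i F_kj`; the signed eigenvalues of the
#' symmetric part `(D + D^T)/2` ordered by magnitude (major/minor dipole
#' moments; negative = contractile); and the torque
#' `tau = sum [(x_k - x_c) x F_k]_z`.
#'
#' When the monopole vanishes, all moments are translation invariant;
#' with a monopole, shifting the reference by `d` changes `D` by
#' `-d %o% M`, which is why the contractile-center convention is fixed.
#'
#' @param positions K x 2 positions (m).
#' @param forces K x 2 forces (N).
#' @param time Timestamp (s) stored in the result.
#' @return Object of class `force_moments`: fields `time`, `monopole`,
#'   `monopole_mag`, `dipole_major`, `dipole_minor` (N m, signed),
#'   `major_axis` (unit vector), `torque` (N m), `contractile_center`.
#' @export
force_moments <- function(positions, forces, time = 0) {
  positions <- matrix(positions, ncol = 2)
  forces <- matrix(forces, ncol = 2)
  stopifnot(nrow(positions) == nrow(forces))
  xc <- contractile_center(positions, forces)
  r <- sweep(positions, 2, xc)
  M <- colSums(forces)
  D <- t(r) %*% forces                    # D_ij = sum r_i F_j
  S <- (D + t(D)) / 2
  eg <- eigen(S, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  major <- eg$values[ord[1]]; minor <- eg$values[ord[2]]
  axis <- eg$vectors[, ord[1]]
  if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  tau <- sum(r[, 1] * forces[, 2] - r[, 2] * forces[, 1])
  structure(list(time = time, monopole = M,
                 monopole_mag = sqrt(sum(M^2)),
                 dipole_major = major, dipole_minor = minor,
                 major_axis = axis, torque = tau,
                 contractile_center = xc,
                 convention = "moments about magnitude-weighted contractile center"),
            class = "force_moments")
}

#' Moments time series from per-frame patch force sets
#'
#' @param sets List of [patch_force_set()].
#' @return List of [force_moments()] (or, for all-zero frames, a
#'   placeholder with zero monopole and `undefined = TRUE`).
#' @export
moments_time_series <- function(sets) {
  lapply(sets, function(s) {
    if (all(s$forces == 0)) {
      structure(list(time = s$time, monopole = c(0, 0), monopole_mag = 0,
                     dipole_major = NA_real_, dipole_minor = NA_real_,
                     major_axis = c(NA_real_, NA_real_), torque = NA_real_,
                     contractile_center = c(NA_real_, NA_real_),
                     undefined = TRUE),
                class = "force_moments")
    } else {
      force_moments(s$positions, s$forces, s$time)
    }
  })
}

#' Tabulate a moments time series in lab units
#'
#' @param moments List of [force_moments()].
#' @return Data frame: `time_s`, `M0x_nN`, `M0y_nN`, `M0_nN`,
#'   `Dmajor_nNum`, `Dminor_nNum`, `torque_nNum`, `axis_angle_deg`,
#'   `xc_um`, `yc_um`.
#' @export
moments_table <- function(moments) {
  rows <- lapply(moments, function(m) {
    data.frame(time_s = m$time,
               M0x_nN = n_to_nn(m$monopole[1]),
               M0y_nN = n_to_nn(m$monopole[2]),
               M0_nN = n_to_nn(m$monopole_mag),
               Dmajor_nNum = m$dipole_major / (.nn * .um),
               Dminor_nNum = m$dipole_minor / (.nn * .um),
               torque_nNum = m$torque / (.nn * .um),
               axis_angle_deg = atan2(m$major_axis[2], m$major_axis[1]) * 180 / pi,
               xc_um = m_to_um(m$contractile_center[1]),
               yc_um = m_to_um(m$contractile_center[2]))
  })
  do.call(rbind, rows)
}
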