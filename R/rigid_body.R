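#' Translational alignment of a snapshot to a reference
#'
#' Shifts a coordinate set so that the centroid of the selected atoms
#' coincides with the reference selection's centroid.
#'
#' @param snapshot,reference n x 3 Cartesian coordinate matrices (Angstrom).
#' @param selection Integer indices of the atoms to align on (default all).
#' @return The shifted snapshot (same shape as input).
#' @export
align_translation <- function(snapshot, reference,
                              selection = seq_len(nrow(reference))) {
  snapshot <- as_coord_matrix(snapshot)
  reference <- as_coord_matrix(reference)
  if (length(selection) == 0) stop("empty selection", call. = FALSE)
  shift <- colMeans(reference[selection, , drop = FALSE]) -
    colMeans(snapshot[selection, , drop = FALSE])
  sweep(snapshot, 2, shift, "+")
}

#' Optimal rigid rotation of a snapshot onto a reference
#'
#' Least-squares proper rotation (covariance SVD with a determinant
#' correction, i.e. the Kabsch solution) over the selected atoms of two
#' translationally aligned coordinate sets. Reports the coordinate r.m.s.d.
#' over the selection before and after applying the rotation about the
#' selection centroid.
#'
#' @param snapshot,reference n x 3 Cartesian matrices, already
#'   translationally aligned on the selection.
#' @param selection Atom indices used in the fit (>= 3, non-collinear).
#' @return A list: `R` (3 x 3 proper rotation, `det = +1`), `euler`
#'   (z-y-z angles in degrees, see [euler_zyz()]), `rmsd_before`,
#'   `rmsd_after` (Angstrom).
#' @export
fit_rotation <- function(snapshot, reference,
                         selection = seq_len(nrow(reference))) {
  snapshot <- as_coord_matrix(snapshot)
  reference <- as_coord_matrix(reference)
  if (length(selection) < 3) {
    stop("rotation fit needs at least 3 selected atoms", call. = FALSE)
  }
  X <- snapshot[selection, , drop = FALSE]
  Y <- reference[selection, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) selection: rotation is not determined",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$v %*% Dm %*% t(sv$u)        # maps snapshot frame onto reference
  rmsd_before <- sqrt(mean(rowSums((X - Y)^2)))
  rmsd_after <- sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  list(R = R, euler = euler_zyz(R),
       rmsd_before = rmsd_before, rmsd_after = rmsd_after)
}

#' Euler angles in the z-y-z convention
#'
#' Decomposes a proper rotation as `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)`,
#' returning `(phi, theta, psi)` in degrees with `theta` in `[0, 180]`. At
#' the gimbal degeneracy (`theta ~ 0` or `180`) only `phi + psi` (resp.
#' `phi - psi`) is determined; the tie-break assigns the full azimuth to
#' `phi` and sets `psi = 0`, and the result is flagged.
#'
#' @param R A 3 x 3 proper rotation matrix.
#' @return Named numeric `(phi, theta, psi)` in degrees, with attribute
#'   `gimbal` (logical).
#' @export
euler_zyz <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == 3))
  c33 <- max(-1, min(1, R[3, 3]))
  theta <- acos(c33)
  gimbal <- abs(abs(c33) - 1) < 1e-12
  if (gimbal) {
    # theta ~ 0: R = Rz(phi + psi); theta ~ 180: R = Rz(phi - psi) Ry(180).
    # Either way only one azimuth is determined; phi carries it, psi = 0.
    phi <- if (c33 > 0) atan2(R[2, 1], R[1, 1]) else
      atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  } else {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  out <- c(phi = phi, theta = theta, psi = psi) * 180 / pi
  attr(out, "gimbal") <- gimbal
  out
}

#' @rdname euler_zyz
#' @param phi,theta,psi Angles in degrees.
#' @export
euler_zyz_matrix <- function(phi, theta, psi) {
  rz <- function(a) rotation_about_axis(c(0, 0, 1), a * pi / 180)
  ry <- function(a) rotation_about_axis(c(0, 1, 0), a * pi / 180)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

# Axis-angle reading of a rotation: signed magnitude (always >= 0 here) and
# the rotation-vector components in degrees.
rotation_vector <- function(R) {
  tr <- max(-1, min(3, sum(diag(R))))
  ang <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (ang < 1e-12) return(c(angle = 0, wx = 0, wy = 0, wz = 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  out <- c(ang, ang * w) * 180 / pi
  names(out) <- c("angle", "wx", "wy", "wz")
  out
}

#' Rotation fits of every snapshot of an ensemble
#'
#' For each snapshot and each symmetry copy: translationally align the
#' selection to the reference, fit the optimal rigid rotation, and record
#' the z-y-z Euler angles, the axis-angle rotation vector, and the r.m.s.d.
#' before/after alignment.
#'
#' @param ens An [ensemble()].
#' @param reference Reference Cartesian coordinates (defaults to the
#'   ensemble's parent model).
#' @param selection Atom indices used in the fit (default all atoms). For a
#'   model with marked C-alpha-like atoms pass their indices.
#' @return A tibble of class `rotation_fit`: one row per (copy, snapshot)
#'   with `copy`, `snapshot`, `phi`, `theta`, `psi`, `angle`, `wx`, `wy`,
#'   `wz`, `rmsd_before`, `rmsd_after`.
#' @export
ensemble_rotation_fits <- function(ens, reference = NULL, selection = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  lat <- model_lattice(ens$model)
  if (is.null(reference)) {
    reference <- frac_to_orth(lat, coord_matrix(ens$model))
  }
  copies <- copy_index(ens$model)
  if (is.null(selection)) selection <- seq_len(nrow(ens$model))
  xyz <- ensemble_cartesian(ens)
  rows <- list()
  for (cp in sort(unique(copies[selection]))) {
    sel_cp <- intersect(selection, which(copies == cp))
    if (length(sel_cp) < 3) next
    for (sidx in seq_len(n_snapshots(ens))) {
      snap <- xyz[, , sidx]
      snap <- align_translation(snap, reference, sel_cp)
      fit <- fit_rotation(snap, reference, sel_cp)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        copy = cp, snapshot = sidx,
        phi = fit$euler[["phi"]], theta = fit$euler[["theta"]],
        psi = fit$euler[["psi"]],
        angle = rotation_vector(fit$R)[["angle"]],
        wx = rotation_vector(fit$R)[["wx"]],
        wy = rotation_vector(fit$R)[["wy"]],
        wz = rotation_vector(fit$R)[["wz"]],
        rmsd_before = fit$rmsd_before, rmsd_after = fit$rmsd_after)
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("rotation_fit", class(tibble::tibble())))
}

# Unwrap an angle series (degrees): shift each value by multiples of 360 to
# minimize the jump from its predecessor, so SDs are not inflated by
# +-180 wrap-around.
unwrap_degrees <- function(x) {
  if (length(x) < 2) return(x)
  out <- x
  for (i in 2:length(x)) {
    d <- out[i] - out[i - 1]
    out[i] <- out[i] - 360 * round(d / 360)
  }
  out
}

#' Per-copy rotation statistics
#'
#' Standard deviations of the (continuity-unwrapped) Euler angles, the
#' r.m.s. rotation-vector amplitude, and trajectory-wide r.m.s.d.s before
#' and after alignment (root of the mean squared per-snapshot r.m.s.d.) with
#' the fractional reduction.
#'
#' @param fits A [ensemble_rotation_fits()] tibble.
#' @return A tibble: one row per copy with `sd_phi`, `sd_theta`, `sd_psi`
#'   (degrees), `rms_angle` (degrees, amplitude of the fitted rotations),
#'   `rmsd_before`, `rmsd_after` (Angstrom), `reduction` (fraction; `NA`
#'   when the ensemble is static).
#' @export
rotation_statistics <- function(fits) {
  fits |>
    dplyr::group_by(.data$copy) |>
    dplyr::arrange(.data$snapshot, .by_group = TRUE) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_phi = stats::sd(unwrap_degrees(.data$phi)),
      sd_theta = stats::sd(unwrap_degrees(.data$theta)),
      sd_psi = stats::sd(unwrap_degrees(.data$psi)),
      rms_angle = sqrt(mean(.data$angle^2)),
      rmsd_before = sqrt(mean(.data$rmsd_before^2)),
      rmsd_after = sqrt(mean(.data$rmsd_after^2)),
      .groups = "drop") |>
    dplyr::mutate(reduction = ifelse(
      .data$rmsd_before > 1e-12,
      1 - .data$rmsd_after / .data$rmsd_before, undefined_value()))
}

#' Rotation statistics with and without an excluded atom subset
#'
#' Re-runs the rotation fit twice — once on the full selection, once with
#' `excluded` removed — and reports the per-copy Euler-SD differences. This
#' is the probe for internal motion leaking into an apparent rigid-body
#' rotation: a genuinely rigid ensemble is insensitive to the exclusion,
#' while a local conformational switch inflates the angle SDs only when its
#' atoms are part of the fit.
#'
#' @param ens An [ensemble()].
#' @param reference Reference Cartesian coordinates (default: parent model).
#' @param selection Atom indices of the full fit selection.
#' @param excluded Atom indices to drop (must be a proper subset).
#' @return A list with tibbles `full`, `reduced` (see
#'   [rotation_statistics()]) and `delta` (per-copy SD differences,
#'   full - reduced).
#' @export
subset_excluded_fit <- function(ens, reference = NULL,
                                selection = seq_len(nrow(ens$model)),
                                excluded) {
  if (!all(excluded %in% selection)) {
    stop("excluded atoms must be part of the selection", call. = FALSE)
  }
  reduced_sel <- setdiff(selection, excluded)
  if (length(reduced_sel) < 3) {
    stop("exclusion leaves fewer than 3 atoms in the selection",
         call. = FALSE)
  }
  full <- rotation_statistics(
    ensemble_rotation_fits(ens, reference, selection))
  reduced <- rotation_statistics(
    ensemble_rotation_fits(ens, reference, reduced_sel))
  delta <- dplyr::inner_join(full, reduced, by = "copy",
                             suffix = c("_full", "_reduced")) |>
    dplyr::transmute(copy = .data$copy,
                     d_sd_phi = .data$sd_phi_full - .data$sd_phi_reduced,
                     d_sd_theta = .data$sd_theta_full - .data$sd_theta_reduced,
                     d_sd_psi = .data$sd_psi_full - .data$sd_psi_reduced)
  list(full = full, reduced = reduced, delta = delta)
}
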