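#' Detector geometry
#'
#' Flat detector at normal incidence, beam along +z hitting the detector
#' plane at `distance` mm; pixel (px, py) sits at lab position
#' `((px - cx) * pixel, (py - cy) * pixel, distance)`.
#'
#' @param distance Sample-to-detector distance, mm (> 0).
#' @param pixel Pixel size, mm (> 0).
#' @param center Beam-center pixel, fractional pixels `c(cx, cy)`.
#' @param wavelength X-ray wavelength, Angstrom (> 0).
#' @param dims Image dimensions `c(nx, ny)` in pixels.
#' @param polarization Fraction of the beam with E-field along the
#'   polarization azimuth, in `[0, 1]`; 0.5 is unpolarized.
#' @param polarization_azimuth Azimuth of the polarization plane, degrees.
#' @param saturation Overload threshold in ADU (16-bit default 65535).
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(distance, pixel, center, wavelength,
                              dims = c(512L, 512L), polarization = 0.5,
                              polarization_azimuth = 0,
                              saturation = 65535) {
  if (distance <= 0 || pixel <= 0 || wavelength <= 0) {
    stop("distance, pixel size and wavelength must be positive",
         call. = FALSE)
  }
  if (polarization < 0 || polarization > 1) {
    stop("polarization fraction must lie in [0, 1]", call. = FALSE)
  }
  if (center[1] < 1 || center[1] > dims[1] ||
      center[2] < 1 || center[2] > dims[2]) {
    stop("beam center must lie inside the image", call. = FALSE)
  }
  structure(list(distance = distance, pixel = pixel, center = center,
                 wavelength = wavelength, dims = as.integer(dims),
                 polarization = polarization,
                 polarization_azimuth = polarization_azimuth,
                 saturation = saturation),
            class = "detector_geometry")
}

#' Crystal orientation setting
#'
#' The 3x3 setting matrix maps fractional Miller indices to the
#' laboratory-frame scattering vector (Angstrom^-1) at goniometer zero; a
#' per-image rotation by `phi` degrees about a stated laboratory axis is
#' applied on top.
#'
#' @param A 3x3 setting matrix (columns are the reciprocal cell vectors in
#'   the lab frame); defaults from `lat` with a*, b*, c* along the lab axes.
#' @param phi Goniometer angle, degrees.
#' @param axis Laboratory rotation axis (default x).
#' @param lat Optional [lattice()] used to build a default `A`.
#' @return An object of class `orientation_setting`.
#' @export
orientation_setting <- function(A = NULL, phi = 0, axis = c(1, 0, 0),
                                lat = NULL) {
  if (is.null(A)) {
    if (is.null(lat)) stop("supply A or a lattice", call. = FALSE)
    A <- t(solve(orthogonalization_matrix(lat)))
  }
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) < 1e-15) stop("setting matrix is singular", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(A = A, phi = phi, axis = axis),
            class = "orientation_setting")
}

setting_rotation <- function(setting) {
  rotation_about_axis(setting$axis, setting$phi * pi / 180)
}

#' Detector image container
#'
#' @param counts Numeric matrix (nx x ny) of pixel values in ADU.
#' @param geometry A [detector_geometry()].
#' @param orientation An [orientation_setting()] or `NULL`.
#' @param mask Logical matrix of bad/overloaded/beamstop pixels (`TRUE` =
#'   masked); defaults to all unmasked plus the geometry's saturation
#'   threshold.
#' @param meta Free-form metadata list.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(counts, geometry, orientation = NULL,
                           mask = NULL, meta = list()) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == geometry$dims))
  if (is.null(mask)) {
    mask <- counts >= geometry$saturation
  }
  stopifnot(all(dim(mask) == dim(counts)), all(is.finite(counts[!mask])))
  structure(list(counts = counts, mask = mask, geometry = geometry,
                 orientation = orientation, meta = meta),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector image> %dx%d px, %d masked, phi=%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$mask),
              if (is.null(x$orientation)) "?" else
                format(x$orientation$phi)))
  invisible(x)
}

pixel_lab_positions <- function(geom, px, py) {
  cbind((px - geom$center[1]) * geom$pixel,
        (py - geom$center[2]) * geom$pixel,
        geom$distance)
}

#' Map detector pixels to fractional Miller indices
#'
#' Each pixel's scattering vector is `s_lab = (u - z_hat) / lambda` with `u`
#' the unit vector from the sample to the pixel; the goniometer rotation is
#' undone and the inverse setting matrix applied, giving the continuous
#' (fractional) `hkl` the pixel samples on the Ewald sphere.
#'
#' @param px,py Numeric vectors of pixel coordinates (1-based, fractional
#'   allowed).
#' @param geom A [detector_geometry()].
#' @param setting An [orientation_setting()].
#' @return An n x 3 matrix of fractional `h, k, l`.
#' @export
pixel_to_hkl <- function(px, py, geom, setting) {
  pos <- pixel_lab_positions(geom, px, py)
  u <- pos / sqrt(rowSums(pos^2))
  s_lab <- sweep(u, 2, c(0, 0, 1)) / geom$wavelength
  Rg <- setting_rotation(setting)
  hkl <- t(solve(setting$A) %*% (t(Rg) %*% t(s_lab)))
  colnames(hkl) <- c("h", "k", "l")
  hkl
}

#' Project fractional Miller indices onto the detector
#'
#' Inverse of [pixel_to_hkl()] for reflections lying on (or near) the Ewald
#' sphere: the scattered-beam direction is intersected with the detector
#' plane. Reflections scattering away from the detector give `NA`.
#'
#' @param hkl n x 3 matrix of fractional Miller indices.
#' @param geom A [detector_geometry()].
#' @param setting An [orientation_setting()].
#' @return A tibble: `px`, `py`, and `excitation` — the distance of the
#'   reflection from the Ewald sphere in Angstrom^-1 (0 means exactly
#'   diffracting).
#' @export
hkl_to_pixel <- function(hkl, geom, setting) {
  hkl <- as_coord_matrix(hkl)
  Rg <- setting_rotation(setting)
  s_lab <- t(Rg %*% setting$A %*% t(hkl))
  kout <- sweep(s_lab, 2, c(0, 0, 1 / geom$wavelength), "+")
  klen <- sqrt(rowSums(kout^2))
  excitation <- klen - 1 / geom$wavelength
  dirz <- kout[, 3] / klen
  ok <- dirz > 1e-6
  t_hit <- ifelse(ok, geom$distance / (kout[, 3] / klen), NA_real_)
  x <- kout[, 1] / klen * t_hit
  y <- kout[, 2] / klen * t_hit
  tibble::tibble(px = x / geom$pixel + geom$center[1],
                 py = y / geom$pixel + geom$center[2],
                 excitation = excitation)
}

# Combined polarization x solid-angle factor per pixel, normalized to 1 at
# the beam center. Polarization: for fraction p with E along azimuth a0,
# P = p (1 - sin^2(2 theta) cos^2(a - a0)) + (1-p)(1 - sin^2(2 theta)
# sin^2(a - a0)); p = 1/2 gives the unpolarized (1 + cos^2 2theta)/2.
# Solid angle: cos^3 of the pixel obliquity for a flat detector.
geometry_factors <- function(geom) {
  nx <- geom$dims[1]; ny <- geom$dims[2]
  px <- matrix(seq_len(nx), nx, ny)
  py <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dx <- (px - geom$center[1]) * geom$pixel
  dy <- (py - geom$center[2]) * geom$pixel
  r2 <- dx^2 + dy^2
  hyp <- sqrt(r2 + geom$distance^2)
  cos_t2 <- geom$distance / hyp              # cos(2 theta) = obliquity cos
  sin_t2_sq <- r2 / (r2 + geom$distance^2)
  az <- atan2(dy, dx) - geom$polarization_azimuth * pi / 180
  p <- geom$polarization
  P <- p * (1 - sin_t2_sq * cos(az)^2) + (1 - p) * (1 - sin_t2_sq * sin(az)^2)
  Omega <- cos_t2^3
  P * Omega
}

#' Polarization and solid-angle correction
#'
#' Divides every pixel by the combined polarization factor and per-pixel
#' solid angle (relative to the beam-center pixel), in one floating-point
#' pass. The correction is an invertible per-pixel scaling: `undo = TRUE`
#' multiplies the factors back.
#'
#' @param img A [detector_image()].
#' @param undo Apply the inverse instead.
#' @return A corrected [detector_image()].
#' @export
correct_geometry <- function(img, undo = FALSE) {
  stopifnot(inherits(img, "detector_image"))
  if (is.null(img$geometry)) stop("image has no geometry", call. = FALSE)
  f <- geometry_factors(img$geometry)
  counts <- if (undo) img$counts * f else img$counts / f
  detector_image(counts, img$geometry, img$orientation, img$mask,
                 c(img$meta, list(corrected = !undo)))
}

#' Mode filter (Bragg-peak rejection)
#'
#' Replaces each unmasked pixel with the representative value of the most
#' populated `bin_width`-ADU bin among the unmasked values in its
#' `kernel x kernel` neighborhood. Sharp outliers (Bragg spikes) vanish;
#' the smooth diffuse background survives. Ties go to the lowest bin;
#' borders use the truncated neighborhood; masks propagate, and a pixel
#' whose whole neighborhood is masked becomes masked.
#'
#' @param img A [detector_image()].
#' @param kernel Odd neighborhood edge in pixels (default 15).
#' @param bin_width Histogram bin width in ADU (default 1).
#' @return A filtered [detector_image()].
#' @export
mode_filter <- function(img, kernel = 15L, bin_width = 1) {
  stopifnot(inherits(img, "detector_image"))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) {
    stop("kernel must be an odd pixel count >= 3", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  res <- mode_filter_cpp(img$counts, img$mask, kernel, bin_width)
  detector_image(res$values, img$geometry, img$orientation, res$mask,
                 c(img$meta, list(mode_filtered = TRUE)))
}

# Dense-array view of a map for fast trilinear lookup, indexed by integer
# supercell indices with recorded offsets.
map_dense <- function(map) {
  lo <- c(min(map$ih), min(map$ik), min(map$il))
  hi <- c(max(map$ih), max(map$ik), max(map$il))
  d <- hi - lo + 1L
  arr <- array(0, d)
  mmask <- array(FALSE, d)
  idx <- cbind(map$ih - lo[1] + 1L, map$ik - lo[2] + 1L,
               map$il - lo[3] + 1L)
  lin <- idx[, 1] + d[1] * (idx[, 2] - 1L + d[2] * (idx[, 3] - 1L))
  arr[lin] <- map$intensity
  mmask[lin] <- map_measured(map)
  list(arr = arr, measured = mmask, lo = lo, hi = hi, dims = d,
       row = {
         r <- array(NA_integer_, d); r[lin] <- seq_len(nrow(map)); r
       })
}

# Trilinear interpolation of a map at continuous supercell indices (n x 3).
# Unmeasured/out-of-range corners drop out with weight renormalization;
# points with no measured corner are NA.
trilinear_lookup <- function(dense, u) {
  n <- nrow(u)
  f0 <- floor(u)
  fr <- u - f0
  val <- numeric(n)
  wsum <- numeric(n)
  for (corner in 0:7) {
    db <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    ci <- sweep(f0, 2, db, "+")
    w <- (if (db[1] == 1) fr[, 1] else 1 - fr[, 1]) *
      (if (db[2] == 1) fr[, 2] else 1 - fr[, 2]) *
      (if (db[3] == 1) fr[, 3] else 1 - fr[, 3])
    inb <- ci[, 1] >= dense$lo[1] & ci[, 1] <= dense$hi[1] &
      ci[, 2] >= dense$lo[2] & ci[, 2] <= dense$hi[2] &
      ci[, 3] >= dense$lo[3] & ci[, 3] <= dense$hi[3]
    lin <- rep(NA_integer_, n)
    lin[inb] <- (ci[inb, 1] - dense$lo[1] + 1L) +
      dense$dims[1] * ((ci[inb, 2] - dense$lo[2]) +
                         dense$dims[2] * (ci[inb, 3] - dense$lo[3]))
    ok <- inb & !is.na(lin)
    ok[ok] <- dense$measured[lin[ok]]
    val[ok] <- val[ok] + w[ok] * dense$arr[lin[ok]]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  out <- ifelse(wsum > 1e-12, val / wsum, NA_real_)
  out
}

#' Simulate a diffraction image from a 3D intensity map
#'
#' Every pixel is mapped to its fractional Miller index and assigned the
#' trilinear interpolation of the map over the eight nearest grid points
#' (weights proportional to 1 - the index-space distance along each axis,
#' renormalized over measured corners). Pixels outside the map support are
#' masked.
#'
#' @param map A [diffuse_map()].
#' @param geom A [detector_geometry()].
#' @param setting An [orientation_setting()].
#' @param apply_corrections Multiply by the polarization/solid-angle factor
#'   (so that [correct_geometry()] recovers the plain interpolation).
#' @return A [detector_image()].
#' @export
simulate_image <- function(map, geom, setting, apply_corrections = FALSE) {
  map <- as_diffuse_map(map)
  sa <- attr(map, "sampling")
  nx <- geom$dims[1]; ny <- geom$dims[2]
  px <- rep(seq_len(nx), ny)
  py <- rep(seq_len(ny), each = nx)
  hkl <- pixel_to_hkl(px, py, geom, setting)
  u <- sweep(hkl, 2, sa, "*")
  dense <- map_dense(map)
  vals <- trilinear_lookup(dense, u)
  counts <- matrix(vals, nx, ny)
  mask <- is.na(counts)
  counts[mask] <- 0
  if (apply_corrections) counts <- counts * geometry_factors(geom)
  detector_image(counts, geom, setting, mask)
}

#' Integrate a rotation series onto a reciprocal grid
#'
#' Each unmasked pixel of each image is mapped to its fractional Miller
#' index and assigned to the nearest supercell grid point (`round(h * na)`
#' etc., half-way ties rounding half-up); per-point count-weighted means
#' over all images are returned. Points beyond the grid's resolution cutoff
#' are excluded.
#'
#' @param images A list of [detector_image()]s sharing a geometry, each with
#'   its own orientation.
#' @param grid A [reciprocal_grid()].
#' @return A [diffuse_map()] with an extra `n_obs` column (contributing
#'   pixel count); points never touched are unmeasured.
#' @export
integrate_images <- function(images, grid) {
  stopifnot(length(images) >= 1, inherits(grid, "reciprocal_grid"))
  sa <- grid_sampling(grid)
  dense <- map_dense(diffuse_map(grid, numeric(nrow(grid))))
  sums <- numeric(nrow(grid))
  cnts <- numeric(nrow(grid))
  for (img in images) {
    geom <- img$geometry
    keep <- !img$mask
    if (!any(keep)) next
    nx <- geom$dims[1]
    pidx <- which(keep)
    px <- ((pidx - 1L) %% nx) + 1L
    py <- ((pidx - 1L) %/% nx) + 1L
    hkl <- pixel_to_hkl(px, py, geom, img$orientation)
    u <- sweep(hkl, 2, sa, "*")
    ci <- floor(u + 0.5)                       # round half up
    inb <- ci[, 1] >= dense$lo[1] & ci[, 1] <= dense$hi[1] &
      ci[, 2] >= dense$lo[2] & ci[, 2] <= dense$hi[2] &
      ci[, 3] >= dense$lo[3] & ci[, 3] <= dense$hi[3]
    if (!any(inb)) next
    lin <- (ci[inb, 1] - dense$lo[1] + 1L) +
      dense$dims[1] * ((ci[inb, 2] - dense$lo[2]) +
                         dense$dims[2] * (ci[inb, 3] - dense$lo[3]))
    row <- dense$row[lin]                      # NA for points off the sphere
    ok <- !is.na(row)
    if (!any(ok)) next
    v <- img$counts[pidx][inb][ok]
    acc <- rowsum(cbind(v, 1), row[ok])
    at <- as.integer(rownames(acc))
    sums[at] <- sums[at] + acc[, 1]
    cnts[at] <- cnts[at] + acc[, 2]
  }
  if (!any(cnts > 0)) {
    stop("no pixel maps into the grid", call. = FALSE)
  }
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  out <- diffuse_map(grid, vals, measured = cnts > 0,
                     provenance = "observed")
  out$n_obs <- cnts
  out
}

#' Reindex a map by a twofold rotation
#'
#' Moves the value at `(h, k, l)` to `(h, -k, -l)` for the twofold about h
#' (`"2h"`), and analogously for `"2k"`, `"2l"`; `"identity"` is a no-op.
#' Each operation is an involution.
#'
#' @param map A [diffuse_map()].
#' @param op One of `"identity"`, `"2h"`, `"2k"`, `"2l"`.
#' @return A [diffuse_map()].
#' @export
reindex_map <- function(map, op = c("identity", "2h", "2k", "2l")) {
  op <- match.arg(op)
  map <- as_diffuse_map(map)
  signs <- switch(op, identity = c(1, 1, 1), `2h` = c(1, -1, -1),
                  `2k` = c(-1, 1, -1), `2l` = c(-1, -1, 1))
  key <- function(a, b, c) (a * 4096 + b) * 4096 + c
  src <- key(signs[1] * map$ih, signs[2] * map$ik, signs[3] * map$il)
  pos <- match(key(map$ih, map$ik, map$il), src)
  if (anyNA(pos)) {
    stop("grid is not closed under the requested operation", call. = FALSE)
  }
  diffuse_map(map, map$intensity[pos],
              measured = map_measured(map)[pos],
              provenance = map_provenance(map))
}
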