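#' Render a synthetic rotation series
#'
#' Produces detector images with the statistical structure the processing
#' chain assumes: each pixel carries the trilinear interpolation of a smooth
#' diffuse map at its fractional Miller index, optionally multiplied by the
#' polarization/solid-angle factor; a sharp Bragg spike is added to the
#' single pixel nearest each integer-index reflection that intersects the
#' Ewald sphere; finally the image is Poisson-sampled and clipped to the
#' 16-bit range. The saturated-pixel count is recorded per image.
#'
#' @param map A [diffuse_map()] (smooth diffuse signal).
#' @param geom A [detector_geometry()].
#' @param settings A list of [orientation_setting()]s, one per image.
#' @param bragg Optional `bragg_set` (integer Miller indices + intensities)
#'   providing the spikes.
#' @param noise_seed Integer seed for Poisson sampling, or `NULL` for a
#'   noiseless render.
#' @param apply_corrections Multiply the diffuse signal by the geometric
#'   factors (default `TRUE`).
#' @param bragg_width Ewald-sphere excitation tolerance in Angstrom^-1
#'   within which a reflection is considered diffracting (default 2e-3).
#' @return A list of [detector_image()]s; each `$meta` records the
#'   orientation angle, the seed, and `n_saturated`.
#' @export
render_images <- function(map, geom, settings, bragg = NULL,
                          noise_seed = NULL, apply_corrections = TRUE,
                          bragg_width = 2e-3) {
  map <- as_diffuse_map(map)
  rng <- if (!is.null(noise_seed)) local_rng(noise_seed)
  out <- vector("list", length(settings))
  for (i in seq_along(settings)) {
    setting <- settings[[i]]
    img <- simulate_image(map, geom, setting,
                          apply_corrections = apply_corrections)
    counts <- img$counts
    if (!is.null(bragg)) {
      proj <- hkl_to_pixel(cbind(bragg$h, bragg$k, bragg$l), geom, setting)
      hit <- !is.na(proj$px) & abs(proj$excitation) < bragg_width &
        proj$px >= 1 & proj$px <= geom$dims[1] &
        proj$py >= 1 & proj$py <= geom$dims[2]
      if (any(hit)) {
        ix <- round(proj$px[hit]); iy <- round(proj$py[hit])
        for (r in seq_along(ix)) {
          counts[ix[r], iy[r]] <- counts[ix[r], iy[r]] +
            bragg$intensity[which(hit)[r]]
        }
      }
    }
    if (!is.null(rng)) {
      keep <- !img$mask
      counts[keep] <- rng$rpois(sum(keep), pmax(counts[keep], 0))
    }
    n_sat <- sum(counts > 65535)
    counts[counts > 65535] <- 65535
    counts[counts < 0] <- 0
    out[[i]] <- detector_image(counts, geom, setting, img$mask,
                               meta = list(phi = setting$phi,
                                           noise_seed = noise_seed,
                                           n_saturated = n_sat))
  }
  out
}

#' Evenly spaced goniometer settings for a rotation series
#'
#' @param lat A [lattice()] providing the default setting matrix.
#' @param n Number of images.
#' @param start,step Goniometer start angle and per-image increment,
#'   degrees.
#' @param axis Laboratory rotation axis.
#' @return A list of [orientation_setting()]s.
#' @export
rotation_series <- function(lat, n, start = 0, step = 1,
                            axis = c(1, 0, 0)) {
  lapply(seq_len(n) - 1L, function(i) {
    orientation_setting(lat = lat, phi = start + i * step, axis = axis)
  })
}
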