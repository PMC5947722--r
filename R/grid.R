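#' Reciprocal-space sampling grid
#'
#' Builds the set of reciprocal-lattice points of a (super)cell out to a
#' resolution cutoff. Physical Miller indices `h, k, l` are quoted in
#' unit-cell units; the per-axis `sampling` factor places points at
#' multiples of `1/sampling` (a 2x2x2 supercell samples twice as finely, at
#' half-integer indices). Internally each point is an integer index triple
#' `ih, ik, il` of the supercell box, avoiding floating-point keys.
#'
#' The grid is centrosymmetric about the origin and every included point has
#' d-spacing >= `d_min`.
#'
#' @param lat Unit-cell [lattice()] (physical indices refer to this cell).
#' @param d_min Resolution cutoff in Angstrom (default 1.6).
#' @param sampling Integer triple of per-axis sampling factors; defaults to
#'   `lat$multiplicity` (1 for a plain unit-cell grid).
#' @param include_origin Keep the (0,0,0) point (default `TRUE`).
#' @return A tibble of class `reciprocal_grid` with columns `ih, ik, il`
#'   (integer supercell indices), `h, k, l` (physical indices), `s`
#'   (|s| = 1/d, Angstrom^-1). Attributes: `lattice`, `sampling`, `d_min`.
#' @export
reciprocal_grid <- function(lat, d_min = 1.6, sampling = lat$multiplicity,
                            include_origin = TRUE) {
  stopifnot(is_lattice(lat), d_min > 0)
  sampling <- as.integer(sampling)
  if (length(sampling) != 3L || any(sampling < 1L)) {
    stop("sampling must be an integer triple with components >= 1",
         call. = FALSE)
  }
  # conservative per-axis index bounds from the direct cell edges
  hmax <- ceiling(sampling * c(lat$a, lat$b, lat$c) / d_min)
  idx <- expand.grid(ih = seq(-hmax[1], hmax[1]),
                     ik = seq(-hmax[2], hmax[2]),
                     il = seq(-hmax[3], hmax[3]))
  h <- idx$ih / sampling[1]
  k <- idx$ik / sampling[2]
  l <- idx$il / sampling[3]
  s <- s_modulus(lat, h, k, l)
  keep <- s <= 1 / d_min + 1e-12
  if (!include_origin) keep <- keep & s > 0
  out <- tibble::tibble(ih = as.integer(idx$ih[keep]),
                        ik = as.integer(idx$ik[keep]),
                        il = as.integer(idx$il[keep]),
                        h = h[keep], k = k[keep], l = l[keep], s = s[keep])
  new_reciprocal_grid(out, lat, sampling, d_min)
}

new_reciprocal_grid <- function(tbl, lat, sampling, d_min) {
  structure(tibble::as_tibble(tbl),
            lattice = lat, sampling = as.integer(sampling), d_min = d_min,
            class = c("reciprocal_grid", class(tibble::tibble())))
}

#' @rdname reciprocal_grid
#' @param grid A `reciprocal_grid`.
#' @export
grid_lattice <- function(grid) attr(grid, "lattice")

#' @rdname reciprocal_grid
#' @export
grid_sampling <- function(grid) attr(grid, "sampling")

#' @rdname reciprocal_grid
#' @export
grid_d_min <- function(grid) attr(grid, "d_min")

#' Periodic box of a grid
#'
#' The direct-space box whose reciprocal lattice the grid samples: the unit
#' cell scaled by the sampling factors.
#'
#' @param grid A [reciprocal_grid()].
#' @return A [lattice()].
#' @export
grid_box <- function(grid) {
  supercell_lattice(grid_lattice(grid), grid_sampling(grid))
}

grids_congruent <- function(a, b) {
  la <- grid_lattice(a); lb <- grid_lattice(b)
  isTRUE(all.equal(unlist(la[c("a", "b", "c", "alpha", "beta", "gamma")]),
                   unlist(lb[c("a", "b", "c", "alpha", "beta", "gamma")]),
                   tolerance = 1e-9)) &&
    identical(grid_sampling(a), grid_sampling(b)) &&
    nrow(a) == nrow(b) &&
    all(a$ih == b$ih & a$ik == b$ik & a$il == b$il)
}

#' Per-shell assignment of grid points
#'
#' Concentric spherical shells in |s|, each of thickness equal to the
#' reciprocal voxel diagonal of the sampled box
#' |(1/(na*a), 1/(nb*b), 1/(nc*c))|, starting at 0.
#'
#' @param grid A [reciprocal_grid()] (or a diffuse map built on one).
#' @return Integer shell index (1-based) per point.
#' @export
shell_index <- function(grid) {
  as.integer(floor(grid$s / shell_thickness(grid))) + 1L
}

#' @rdname shell_index
#' @export
shell_thickness <- function(grid) {
  lat <- grid_lattice(grid)
  sa <- grid_sampling(grid)
  sqrt(sum((1 / (sa * c(lat$a, lat$b, lat$c)))^2))
}
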