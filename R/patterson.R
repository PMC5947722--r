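#' Anisotropic component of Bragg intensities
#'
#' Subtracts the spline-interpolated radial mean from a set of Bragg
#' intensities — the same shell/natural-spline machinery used for diffuse
#' maps ([anisotropic_map()]) applied to `I(hkl)`.
#'
#' @param bragg A `bragg_set` from [mean_intensities()].
#' @return A `bragg_set` with `intensity` replaced by the anisotropic
#'   residual and a `measured` column (points outside the spline support are
#'   unmeasured).
#' @export
anisotropic_bragg <- function(bragg) {
  stopifnot(inherits(bragg, "bragg_set"))
  res <- anisotropic_map(as_diffuse_map(bragg))
  out <- tibble::as_tibble(bragg)
  out$intensity <- res$intensity
  out$sigma <- NA_real_
  out$measured <- res$measured
  structure(out, lattice = attr(bragg, "lattice"),
            sampling = attr(bragg, "sampling"),
            d_min = attr(bragg, "d_min"),
            class = c("bragg_set", class(tibble::tibble())))
}

#' Patterson map by FFT of intensities
#'
#' Unnormalized discrete Fourier transform of an intensity map with zero
#' phases: `P(x) = sum_hkl I(hkl) exp(2 pi i hkl . x)` on a fractional grid
#' of the sampled box. Unmeasured points are zero-filled (the fill fraction
#' is recorded); the input is Friedel-completed by averaging each point with
#' its mate. The origin value equals the sum of the (completed) input
#' intensities, and the map is real and centrosymmetric for
#' Friedel-symmetric input.
#'
#' @param map A [diffuse_map()] or `bragg_set`.
#' @param dims Optional integer triple of output grid dimensions; defaults
#'   to twice the reciprocal index range per axis, rounded up to even.
#' @return An object of class `patterson_map`: `values` (3D array over box
#'   fractions `0, 1/N, ...`), `box` lattice, `fill_fraction`,
#'   `max_imag_residue`.
#' @export
patterson_fft <- function(map, dims = NULL) {
  map <- as_diffuse_map(map)
  meas <- map_measured(map)
  if (!any(meas)) stop("all points are unmeasured", call. = FALSE)
  ih <- map$ih[meas]; ik <- map$ik[meas]; il <- map$il[meas]
  I <- map$intensity[meas]
  if (is.null(dims)) {
    rng <- function(v) 2L * (2L * max(abs(v), 1L) + 1L)
    dims <- c(rng(map$ih), rng(map$ik), rng(map$il))
    dims <- dims + dims %% 2L
  }
  dims <- as.integer(dims)
  A <- array(0, dims)
  Cnt <- array(0L, dims)
  lin <- function(h, k, l) {
    1L + (h %% dims[1]) + dims[1] * ((k %% dims[2]) +
                                       dims[2] * (l %% dims[3]))
  }
  # deposit each point at its own index and its Friedel mate, then average
  idx <- c(lin(ih, ik, il), lin(-ih, -ik, -il))
  dep <- rowsum(c(I, I), idx)
  cnt <- rowsum(rep(1L, 2L * length(I)), idx)
  where <- as.integer(rownames(dep))
  A[where] <- dep / cnt
  Cnt[where] <- cnt
  nz <- Cnt > 0L
  ft <- stats::fft(A)                  # sum A exp(-2 pi i jk/N); A is
  P <- Re(ft)                          # (Friedel-) symmetric, so real
  structure(list(values = P, box = grid_box(map),
                 fill_fraction = 1 - sum(nz) / prod(dims),
                 max_imag_residue = max(abs(Im(ft)))),
            class = "patterson_map")
}

#' @export
print.patterson_map <- function(x, ...) {
  cat(sprintf("<patterson map> %s grid, origin %.4g, fill %.2f%% zero\n",
              paste(dim(x$values), collapse = "x"), x$values[1, 1, 1],
              100 * x$fill_fraction))
  invisible(x)
}

#' Planar section of a Patterson map
#'
#' Extracts the plane at a fixed fractional coordinate along one axis.
#'
#' @param pmap A `patterson_map` from [patterson_fft()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param at Fractional coordinate of the plane in `[0, 1)` (snapped to the
#'   nearest grid plane).
#' @param sigma_scaled Divide values by the SD of the whole map.
#' @return A matrix (the plane), with `dimnames` giving the fractional
#'   coordinates of the remaining two axes.
#' @export
patterson_section <- function(pmap, axis = c("x", "y", "z"), at = 0,
                              sigma_scaled = FALSE) {
  axis <- match.arg(axis)
  d <- dim(pmap$values)
  ax <- match(axis, c("x", "y", "z"))
  idx <- (round(at * d[ax]) %% d[ax]) + 1L
  plane <- switch(axis,
                  x = pmap$values[idx, , ],
                  y = pmap$values[, idx, ],
                  z = pmap$values[, , idx])
  other <- setdiff(1:3, ax)
  dimnames(plane) <- list(
    sprintf("%.4f", (seq_len(d[other[1]]) - 1) / d[other[1]]),
    sprintf("%.4f", (seq_len(d[other[2]]) - 1) / d[other[2]]))
  if (sigma_scaled) plane <- plane / stats::sd(pmap$values)
  plane
}

#' Radially averaged |P| of a Patterson map
#'
#' Mean absolute Patterson value in shells of minimum-image distance |r|
#' (Angstrom), for distance-dependence analysis of correlation length.
#'
#' @param pmap A `patterson_map` from [patterson_fft()].
#' @param shell_width Shell thickness in Angstrom (default 1).
#' @return A tibble: `r_mid`, `mean_abs`, `n_points`.
#' @export
patterson_radial <- function(pmap, shell_width = 1) {
  d <- dim(pmap$values)
  fr <- list((seq_len(d[1]) - 1) / d[1],
             (seq_len(d[2]) - 1) / d[2],
             (seq_len(d[3]) - 1) / d[3])
  fr <- lapply(fr, function(v) ifelse(v >= 0.5, v - 1, v))  # min image
  g <- expand.grid(x = fr[[1]], y = fr[[2]], z = fr[[3]])
  M <- orthogonalization_matrix(pmap$box)
  xyz <- as.matrix(g) %*% t(M)
  r <- sqrt(rowSums(xyz^2))
  tibble::tibble(shell = floor(r / shell_width),
                 v = abs(as.vector(pmap$values))) |>
    dplyr::group_by(.data$shell) |>
    dplyr::summarise(mean_abs = mean(.data$v), n_points = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(r_mid = (.data$shell + 0.5) * shell_width) |>
    dplyr::select("r_mid", "mean_abs", "n_points")
}
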