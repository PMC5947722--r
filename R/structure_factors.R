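#' Structure factors of one snapshot by direct summation
#'
#' Computes `f(hkl) = sum_j occ_j f_j(|s|) exp(2 pi i (h x_j + k y_j + l
#' z_j))` over all atoms, with `(h, k, l)` the physical (possibly
#' half-integer) indices of the grid and `(x, y, z)` fractional in the unit
#' cell — equivalently, integer supercell indices against box-fractional
#' coordinates, which is how the compiled kernel evaluates it. No per-atom B
#' smearing is applied: disorder enters through the ensemble, not through
#' this operation.
#'
#' @param grid A [reciprocal_grid()].
#' @param model An [atomic_model()] whose lattice matches the grid's box, or
#'   a bare n x 3 coordinate matrix (box-fractional) together with `model`
#'   via `coords`.
#' @param coords Optional n x 3 matrix of box-fractional coordinates
#'   overriding the model's own (a snapshot of the same atom list).
#' @return A tibble of class `structure_factor_set`: grid columns plus a
#'   complex column `f`.
#' @export
structure_factors <- function(grid, model, coords = NULL) {
  stopifnot(inherits(grid, "reciprocal_grid"), inherits(model, "atomic_model"))
  if (is.null(coords)) coords <- coord_matrix(model)
  coords <- as_coord_matrix(coords)
  if (nrow(coords) != nrow(model)) {
    stop("coordinate set does not match the model's atom count",
         call. = FALSE)
  }
  f <- complex(real = numeric(nrow(grid)), imaginary = numeric(nrow(grid)))
  for (el in unique(model$element)) {
    sel <- model$element == el
    S <- sf_phase_sum_cpp(grid$ih, grid$ik, grid$il,
                          coords[sel, , drop = FALSE], model$occ[sel])
    f <- f + form_factor(el, grid$s) * S
  }
  out <- tibble::as_tibble(grid)
  out$f <- f
  structure(out, lattice = grid_lattice(grid),
            sampling = grid_sampling(grid), d_min = grid_d_min(grid),
            class = c("structure_factor_set", class(tibble::tibble())))
}

# Pure-R term-by-term reference used by the test-suite oracles; O(points x
# atoms), exact mirror of the definition.
structure_factors_reference <- function(grid, model, coords = NULL) {
  if (is.null(coords)) coords <- coord_matrix(model)
  f <- vapply(seq_len(nrow(grid)), function(p) {
    ph <- 2 * pi * (grid$ih[p] * coords[, 1] + grid$ik[p] * coords[, 2] +
                      grid$il[p] * coords[, 3])
    ff <- vapply(seq_len(nrow(model)),
                 function(j) form_factor(model$element[j], grid$s[p]),
                 numeric(1))
    sum(model$occ * ff * complex(real = cos(ph), imaginary = sin(ph)))
  }, complex(1))
  out <- tibble::as_tibble(grid)
  out$f <- f
  out
}

#' Bragg intensities from the mean structure factor
#'
#' `I(hkl) = |<f_n(hkl)>|^2` over the snapshots — the intensity of the mean
#' structure, which is what Bragg diffraction measures — with
#' `sigma(I) = sqrt(I)`.
#'
#' @param sf_list A list of `structure_factor_set`s on a common grid, or a
#'   `diffuse_accumulator` ([accumulate_diffuse()]) holding the running sum of `f`.
#' @return A tibble of class `bragg_set`: grid columns plus `intensity` and
#'   `sigma`.
#' @export
mean_intensities <- function(sf_list) {
  if (inherits(sf_list, "diffuse_accumulator")) {
    mean_f <- sf_list$sum_f / sf_list$n
    grid <- sf_list$grid
  } else {
    if (length(sf_list) < 1) stop("need at least one snapshot", call. = FALSE)
    grid <- sf_list[[1]]
    fmat <- vapply(sf_list, function(s) s$f, complex(nrow(grid)))
    if (is.null(dim(fmat))) fmat <- matrix(fmat, nrow = 1)
    mean_f <- rowMeans(fmat)
  }
  out <- tibble::as_tibble(grid[c("ih", "ik", "il", "h", "k", "l", "s")])
  out$intensity <- Mod(mean_f)^2
  out$sigma <- sqrt(out$intensity)
  structure(out, lattice = grid_lattice(grid),
            sampling = grid_sampling(grid), d_min = grid_d_min(grid),
            class = c("bragg_set", class(tibble::tibble())))
}

#' Ensemble B factors
#'
#' Crystallographic displacement parameter `B = (8 pi^2 / 3) <|dr|^2>` per
#' atom from the Cartesian coordinate variance about the ensemble mean;
#' optional per-group (residue-like) averaging.
#'
#' @param ens An [ensemble()] with at least two snapshots.
#' @param grouping Optional integer/factor vector, one entry per atom;
#'   groups are averaged (e.g. residue ids). `NULL` keeps per-atom values.
#' @return A tibble with columns `atom` (or `group`) and `B` (Angstrom^2).
#' @export
ensemble_b_factors <- function(ens, grouping = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  n <- n_snapshots(ens)
  if (n < 2) stop("B factors need at least two snapshots", call. = FALSE)
  xyz <- ensemble_cartesian(ens)      # natoms x 3 x n
  mu <- apply(xyz, c(1, 2), mean)
  dev2 <- sweep(xyz, c(1, 2), mu)^2
  msd <- apply(dev2, 1, sum) / n      # <|dr|^2> per atom
  B <- (8 * pi^2 / 3) * msd
  if (is.null(grouping)) {
    return(tibble::tibble(atom = seq_along(B), B = B))
  }
  tibble::tibble(group = grouping, B = B) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(B = mean(.data$B), .groups = "drop")
}
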