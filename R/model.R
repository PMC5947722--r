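#' Atomic models
#'
#' An `atomic_model` is a tibble with one row per atom — columns `element`,
#' fractional coordinates `x`, `y`, `z` in `[0, 1)` of its cell, and
#' `occ`upancy — carrying its [lattice()] as an attribute. All generators and
#' structure-factor routines consume and produce this shape.
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z`, `occ`
#'   (occupancy defaults to 1 if absent).
#' @param lat The [lattice()] the fractional coordinates refer to.
#' @param wrap Wrap coordinates into `[0, 1)` (default `TRUE`).
#' @return A tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms, lat, wrap = TRUE) {
  stopifnot(is_lattice(lat))
  atoms <- tibble::as_tibble(atoms)
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  needed <- c("element", "x", "y", "z", "occ")
  if (!all(needed %in% names(atoms))) {
    stop("atoms must have columns element, x, y, z (and optionally occ)",
         call. = FALSE)
  }
  atoms <- atoms[needed]
  if (wrap) {
    atoms$x <- wrap_frac(atoms$x)
    atoms$y <- wrap_frac(atoms$y)
    atoms$z <- wrap_frac(atoms$z)
  }
  structure(atoms, lattice = lat,
            class = c("atomic_model", class(tibble::tibble())))
}

#' @rdname atomic_model
#' @param model An `atomic_model`.
#' @export
model_lattice <- function(model) attr(model, "lattice")

coord_matrix <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

#' Random compact cluster of scatterers in one asymmetric unit
#'
#' Builds a toy "molecule": `n_atoms` carbon-like scatterers uniformly
#' distributed in a cube of edge `extent` Angstrom, placed so the cluster
#' sits inside one asymmetric unit of the cell (the region with fractional
#' coordinates below roughly 1/2 along x and y). Deterministic for a fixed
#' seed.
#'
#' @param lat A [lattice()]; the cluster lives in this cell.
#' @param n_atoms Number of atoms (>= 1).
#' @param extent Cube edge in Angstrom; must be smaller than the shortest
#'   cell edge.
#' @param seed Integer seed for the cluster's own random stream.
#' @param element Element symbol for every atom (default "C").
#' @return An [atomic_model()].
#' @export
toy_asymmetric_unit <- function(lat, n_atoms, extent, seed,
                                element = "C") {
  stopifnot(is_lattice(lat))
  if (n_atoms < 1) stop("n_atoms must be >= 1", call. = FALSE)
  shortest <- min(lat$a, lat$b, lat$c)
  if (extent >= shortest) {
    stop(sprintf(
      "extent (%.3g A) must be smaller than the shortest cell edge (%.3g A)",
      extent, shortest), call. = FALSE)
  }
  rng <- local_rng(seed)
  xyz_A <- matrix(rng$runif(3L * n_atoms, 0, extent), ncol = 3)
  # anchor the cluster near the cell origin, offset so it cannot collide
  # with its own symmetry mates for modest extents
  origin_A <- c(0.05 * lat$a, 0.05 * lat$b, 0.05 * lat$c)
  frac <- orth_to_frac(lat, sweep(xyz_A, 2, origin_A, "+"))
  atomic_model(
    tibble::tibble(element = element,
                   x = frac[, 1], y = frac[, 2], z = frac[, 3], occ = 1),
    lat)
}

# The four symmetry operators of space group P4(1), acting on fractional
# coordinates: identity, two-fold screw, and the two four-fold screws.
p41_operators <- function() {
  list(
    function(p) cbind( p[, 1],  p[, 2], p[, 3]),
    function(p) cbind(-p[, 1], -p[, 2], p[, 3] + 0.5),
    function(p) cbind(-p[, 2],  p[, 1], p[, 3] + 0.25),
    function(p) cbind( p[, 2], -p[, 1], p[, 3] + 0.75)
  )
}

#' Expand an asymmetric unit to the full P4(1) cell
#'
#' Applies the four P4(1) operators (x, y, z), (-x, -y, z+1/2),
#' (-y, x, z+1/4), (y, -x, z+3/4) and wraps the images into `[0, 1)`. The
#' cell must be tetragonal (a = b, all angles 90 degrees).
#'
#' @param au An [atomic_model()] holding the asymmetric unit.
#' @param lat Optional target [lattice()]; defaults to the model's own.
#' @return An [atomic_model()] with 4x the atoms, in symmetry-copy blocks
#'   (a `copy` attribute records the block index of each atom).
#' @export
expand_p41 <- function(au, lat = model_lattice(au)) {
  stopifnot(inherits(au, "atomic_model"))
  if (abs(lat$a - lat$b) > 1e-9 ||
      any(abs(c(lat$alpha, lat$beta, lat$gamma) - 90) > 1e-9)) {
    stop("P4(1) expansion needs a tetragonal cell: a = b, angles 90",
         call. = FALSE)
  }
  p <- coord_matrix(au)
  blocks <- purrr::map(p41_operators(), function(op) {
    q <- wrap_frac(op(p))
    tibble::tibble(element = au$element,
                   x = q[, 1], y = q[, 2], z = q[, 3], occ = au$occ)
  })
  out <- atomic_model(dplyr::bind_rows(blocks), lat)
  attr(out, "copy") <- rep(seq_along(blocks), each = nrow(au))
  out
}

#' Tile a cell model into a supercell
#'
#' Replicates the model on an `na x nb x nc` grid of cells. Unit-cell
#' fractional coordinate x of copy i becomes (x + i)/na (similarly for y,
#' z), and the returned model carries the supercell lattice (edges scaled by
#' the layout).
#'
#' @param model An [atomic_model()] of one cell.
#' @param layout Integer triple `(na, nb, nc)`, components >= 1.
#' @return An [atomic_model()] in the supercell box.
#' @export
build_supercell <- function(model, layout = c(2L, 2L, 2L)) {
  stopifnot(inherits(model, "atomic_model"))
  layout <- as.integer(layout)
  if (length(layout) != 3L || any(layout < 1L)) {
    stop("layout must be an integer triple with components >= 1",
         call. = FALSE)
  }
  lat <- model_lattice(model)
  super <- supercell_lattice(lat, layout)
  shifts <- expand.grid(i = seq_len(layout[1]) - 1L,
                        j = seq_len(layout[2]) - 1L,
                        k = seq_len(layout[3]) - 1L)
  base_copy <- attr(model, "copy") %||% rep(1L, nrow(model))
  p <- coord_matrix(model)
  blocks <- purrr::pmap(shifts, function(i, j, k) {
    tibble::tibble(element = model$element,
                   x = (p[, 1] + i) / layout[1],
                   y = (p[, 2] + j) / layout[2],
                   z = (p[, 3] + k) / layout[3],
                   occ = model$occ)
  })
  out <- atomic_model(dplyr::bind_rows(blocks), super)
  ncell_copies <- max(base_copy)
  attr(out, "copy") <- as.integer(
    rep(seq_len(nrow(shifts)) - 1L, each = nrow(model)) * ncell_copies +
      rep(base_copy, nrow(shifts)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symmetry-copy index of each atom
#'
#' After [expand_p41()] and/or [build_supercell()] each atom belongs to one
#' rigid symmetry copy of the asymmetric unit; this returns that index
#' (1-based), or all-1 for a model never expanded.
#'
#' @param model An [atomic_model()].
#' @return Integer vector, one entry per atom.
#' @export
copy_index <- function(model) {
  attr(model, "copy") %||% rep(1L, nrow(model))
}
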