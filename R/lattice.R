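#' Crystal lattice geometry
#'
#' A `lattice` records the unit-cell edges and angles, the Laue group of the
#' diffraction pattern, and the supercell multiplicity (how many unit cells
#' are tiled along each axis). It owns the direct and reciprocal metric: all
#' fractional/orthogonal conversions and d-spacings in the package are
#' computed from it.
#'
#' @param a,b,c Cell edges in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param laue_group Laue symbol of the diffraction pattern. Supported:
#'   `"P4/m"` (tetragonal, the 8-operation group of a P4(1) crystal) and
#'   `"P1"` (Friedel pair only).
#' @param multiplicity Integer triple `(na, nb, nc)`: supercell layout.
#'
#' @return An object of class `lattice`.
#' @examples
#' lat <- lattice(48.499, 48.499, 63.430, laue_group = "P4/m")
#' d_spacing(lat, h = 1, k = 0, l = 0) # == a for an orthogonal cell
#' @export
lattice <- function(a, b = a, c, alpha = 90, beta = 90, gamma = 90,
                    laue_group = "P1", multiplicity = c(1L, 1L, 1L)) {
  edges <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(edges)) || any(edges <= 0)) {
    stop("cell edges must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  laue_group <- match.arg(laue_group, c("P1", "P4/m"))
  multiplicity <- as.integer(multiplicity)
  if (length(multiplicity) != 3L || any(is.na(multiplicity)) ||
      any(multiplicity < 1L)) {
    stop("multiplicity must be an integer triple with components >= 1",
         call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         laue_group = laue_group, multiplicity = multiplicity),
    class = "lattice"
  )
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf(
    "<lattice> a=%.4g b=%.4g c=%.4g A  angles %.4g %.4g %.4g  Laue %s  layout %s\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$laue_group,
    paste(x$multiplicity, collapse = "x")))
  invisible(x)
}

is_lattice <- function(x) inherits(x, "lattice")

#' Orthogonalization matrix of a lattice
#'
#' Standard crystallographic convention: **a** along x, **b** in the xy
#' plane. Columns are the cell vectors in Angstrom; `M %*% frac` gives
#' orthogonal coordinates.
#'
#' @param lat A [lattice()].
#' @return A 3x3 numeric matrix.
#' @export
orthogonalization_matrix <- function(lat) {
  stopifnot(is_lattice(lat))
  ca <- cos(lat$alpha * pi / 180)
  cb <- cos(lat$beta * pi / 180)
  cg <- cos(lat$gamma * pi / 180)
  sg <- sin(lat$gamma * pi / 180)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(
    lat$a, lat$b * cg, lat$c * cb,
    0,     lat$b * sg, lat$c * (ca - cb * cg) / sg,
    0,     0,          lat$c * v / sg
  ), nrow = 3, byrow = TRUE)
}

#' Convert coordinates between fractional and orthogonal frames
#'
#' @param lat A [lattice()].
#' @param xyz Numeric matrix (n x 3) of coordinates.
#' @return An n x 3 matrix in the other frame (Angstrom or fractional).
#' @export
frac_to_orth <- function(lat, xyz) {
  xyz <- as_coord_matrix(xyz)
  t(orthogonalization_matrix(lat) %*% t(xyz))
}

#' @rdname frac_to_orth
#' @export
orth_to_frac <- function(lat, xyz) {
  xyz <- as_coord_matrix(xyz)
  t(solve(orthogonalization_matrix(lat)) %*% t(xyz))
}

as_coord_matrix <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  storage.mode(xyz) <- "double"
  stopifnot(ncol(xyz) == 3)
  xyz
}

#' Resolution of reflections
#'
#' d-spacing (Angstrom) and scattering-vector modulus |s| = 1/d (Angstrom^-1,
#' no 2*pi factor) of physical Miller indices, which may be fractional on a
#' supercell lattice.
#'
#' @param lat A [lattice()].
#' @param h,k,l Numeric vectors of (possibly fractional) Miller indices.
#' @return Numeric vector.
#' @export
d_spacing <- function(lat, h, k, l) 1 / s_modulus(lat, h, k, l)

#' @rdname d_spacing
#' @export
s_modulus <- function(lat, h, k, l) {
  M <- orthogonalization_matrix(lat)
  # reciprocal cell vectors are the rows of M^-1
  Minv <- solve(M)
  hkl <- cbind(h, k, l)
  s <- hkl %*% Minv
  sqrt(rowSums(s^2))
}

#' Lattice of the supercell implied by a unit cell's multiplicity
#'
#' Edges are multiplied by the layout; the supercell is treated as one big
#' P1 box (its own multiplicity is 1,1,1).
#'
#' @param lat A [lattice()] with the desired `multiplicity`.
#' @param layout Optional integer triple overriding `lat$multiplicity`.
#' @return A [lattice()] for the supercell box.
#' @export
supercell_lattice <- function(lat, layout = lat$multiplicity) {
  layout <- as.integer(layout)
  lattice(lat$a * layout[1], lat$b * layout[2], lat$c * layout[3],
          lat$alpha, lat$beta, lat$gamma,
          laue_group = lat$laue_group, multiplicity = c(1L, 1L, 1L))
}

#' Wrap fractional coordinates into [0, 1)
#'
#' @param x Numeric vector or matrix of fractional coordinates.
#' @return Same shape, each value reduced modulo 1 into `[0, 1)`.
#' @export
wrap_frac <- function(x) {
  w <- x - floor(x)
  # guard against 1 - eps rounding back up to exactly 1
  w[w >= 1] <- 0
  w
}
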