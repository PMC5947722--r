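# Shared toy fixtures, built in code.

toy_lattice <- function(a = 36, c = 48, layout = c(2L, 2L, 2L)) {
  lattice(a, a, c, laue_group = "P4/m", multiplicity = layout)
}

# A small orthorhombic P1 cell for geometry-only tests.
p1_lattice <- function(a = 10, b = 12, c = 14) {
  lattice(a, b, c, laue_group = "P1")
}

toy_crystal <- function(n_atoms = 20, extent = 8, seed = 7,
                        lat = toy_lattice(), layout = lat$multiplicity) {
  au <- toy_asymmetric_unit(lat, n_atoms, extent, seed = seed)
  build_supercell(expand_p41(au), layout)
}

small_grid <- function(lat = p1_lattice(), hmax = 2) {
  # a full centrosymmetric index box, no resolution cropping
  idx <- expand.grid(ih = -hmax:hmax, ik = -hmax:hmax, il = -hmax:hmax)
  tbl <- tibble::tibble(
    ih = as.integer(idx$ih), ik = as.integer(idx$ik),
    il = as.integer(idx$il),
    h = idx$ih, k = idx$ik, l = idx$il,
    s = s_modulus(lat, idx$ih, idx$ik, idx$il))
  diffusekit:::new_reciprocal_grid(tbl, lat, c(1L, 1L, 1L), 1 / max(tbl$s))
}

# Hand-made structure-factor sets with unit form factor, for analytic
# Guinier examples.
unit_sf_set <- function(grid, frac_positions) {
  f <- Reduce(`+`, lapply(seq_len(nrow(frac_positions)), function(j) {
    ph <- 2 * pi * (grid$ih * frac_positions[j, 1] +
                      grid$ik * frac_positions[j, 2] +
                      grid$il * frac_positions[j, 3])
    complex(real = cos(ph), imaginary = sin(ph))
  }))
  out <- tibble::as_tibble(grid)
  out$f <- f
  attr(out, "lattice") <- attr(grid, "lattice")
  attr(out, "sampling") <- attr(grid, "sampling")
  attr(out, "d_min") <- attr(grid, "d_min")
  out
}

# Independent quaternion (Horn) superposition oracle for the Kabsch fit.
quaternion_rotation_oracle <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  rmsd_after <- sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  list(R = R, rmsd_after = rmsd_after)
}
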