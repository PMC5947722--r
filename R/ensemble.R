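#' Displacement (motion) models for ensemble generation
#'
#' Describes the displacement statistics a sampled ensemble should have:
#'
#' * `independent_gaussian` — every Cartesian coordinate perturbed i.i.d.
#'   `N(0, sigma^2)` (an Einstein crystal).
#' * `liquid_like` — jointly Gaussian displacements whose per-axis
#'   covariance between atoms i and j is `sigma^2 exp(-r_ij / gamma)`, with
#'   `r_ij` the mean-structure inter-atomic distance — correlated motion
#'   with correlation length `gamma`.
#' * `rigid_body` — each symmetry copy independently rotated about its
#'   centroid (axis uniform on the sphere, angle `N(0, rot_sd^2)` degrees)
#'   and translated `N(0, trans_sd^2 I)` Angstrom.
#' * `loop_flip` — a subset of atoms jumps between two alternative
#'   conformations as a symmetric two-state Markov chain (switch probability
#'   `switch_prob` per snapshot); all other atoms get an additive
#'   independent-Gaussian background of width `sigma`.
#'
#' @param kind One of `"independent_gaussian"`, `"liquid_like"`,
#'   `"rigid_body"`, `"loop_flip"`.
#' @param sigma Per-coordinate displacement SD in Angstrom (>= 0).
#' @param gamma Correlation length in Angstrom (> 0; `liquid_like` only).
#' @param rot_sd Rotation SD in degrees (`rigid_body` only).
#' @param trans_sd Translation SD in Angstrom (`rigid_body` only).
#' @param flip_atoms Integer indices of the flipping atoms (`loop_flip`).
#' @param conf_a,conf_b Two alternative Cartesian coordinate sets (n_flip x
#'   3, Angstrom) for the flipping atoms (`loop_flip`).
#' @param switch_prob Per-snapshot switching probability in `[0, 1]`
#'   (default 0.01).
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(kind = c("independent_gaussian", "liquid_like",
                                  "rigid_body", "loop_flip"),
                         sigma = 0, gamma = NULL, rot_sd = NULL,
                         trans_sd = NULL, flip_atoms = NULL, conf_a = NULL,
                         conf_b = NULL, switch_prob = 0.01) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (kind == "liquid_like") {
    if (is.null(gamma) || gamma <= 0) {
      stop("liquid_like needs gamma > 0", call. = FALSE)
    }
  }
  if (kind == "rigid_body") {
    if (is.null(rot_sd) || is.null(trans_sd) || rot_sd < 0 || trans_sd < 0) {
      stop("rigid_body needs rot_sd >= 0 (degrees) and trans_sd >= 0 (A)",
           call. = FALSE)
    }
  }
  if (kind == "loop_flip") {
    if (is.null(flip_atoms) || length(flip_atoms) == 0) {
      stop("loop_flip needs a non-empty flip_atoms index set", call. = FALSE)
    }
    conf_a <- as_coord_matrix(conf_a)
    conf_b <- as_coord_matrix(conf_b)
    if (nrow(conf_a) != length(flip_atoms) ||
        nrow(conf_b) != length(flip_atoms)) {
      stop("conf_a/conf_b must have one row per flip atom", call. = FALSE)
    }
    if (switch_prob < 0 || switch_prob > 1) {
      stop("switch_prob must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(kind = kind, sigma = sigma, gamma = gamma, rot_sd = rot_sd,
                 trans_sd = trans_sd, flip_atoms = flip_atoms,
                 conf_a = conf_a, conf_b = conf_b,
                 switch_prob = switch_prob),
            class = "motion_model")
}

#' Coordinate ensembles
#'
#' An `ensemble` is an ordered stack of snapshots of one atom list: a
#' `natoms x 3 x n_snapshots` array of box-fractional coordinates (left
#' unwrapped so displaced molecules stay intact; structure factors are
#' translation-phase exact either way), together with the parent
#' [atomic_model()], the generator seed, and an arbitrary snapshot-spacing
#' label.
#'
#' @param model The parent [atomic_model()].
#' @param coords `natoms x 3 x n` array of box-fractional coordinates.
#' @param seed Integer seed recorded for provenance.
#' @param spacing Free-text snapshot spacing label.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(model, coords, seed = NA_integer_,
                     spacing = "arbitrary") {
  stopifnot(inherits(model, "atomic_model"))
  d <- dim(coords)
  if (length(d) != 3 || d[1] != nrow(model) || d[2] != 3) {
    stop("coords must be a natoms x 3 x n_snapshots array congruent with ",
         "the model", call. = FALSE)
  }
  structure(list(model = model, coords = coords, seed = seed,
                 spacing = spacing),
            class = "ensemble")
}

#' @rdname ensemble
#' @param ens An `ensemble`.
#' @export
n_snapshots <- function(ens) dim(ens$coords)[3]

#' @rdname ensemble
#' @param i Snapshot index.
#' @export
snapshot_coords <- function(ens, i) ens$coords[, , i, drop = TRUE]

#' @rdname ensemble
#' @export
ensemble_cartesian <- function(ens) {
  lat <- model_lattice(ens$model)
  M <- orthogonalization_matrix(lat)
  d <- dim(ens$coords)
  flat <- matrix(aperm(ens$coords, c(2, 1, 3)), nrow = 3)
  out <- M %*% flat
  aperm(array(out, c(3, d[1], d[3])), c(2, 1, 3))
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d atoms x %d snapshots (seed %s, spacing %s)\n",
              nrow(x$model), n_snapshots(x), x$seed, x$spacing))
  invisible(x)
}

#' Sample a synthetic ensemble under a motion model
#'
#' Draws `n_snapshots` coordinate snapshots of `model` with the displacement
#' statistics described by `motion` (see [motion_model()]). Displacements
#' are sampled in Cartesian Angstrom and converted back to box-fractional
#' coordinates without wrapping. Deterministic for a fixed seed.
#'
#' @param model An [atomic_model()].
#' @param motion A [motion_model()].
#' @param n_snapshots Number of snapshots (>= 1).
#' @param seed Integer seed; the ensemble uses its own random stream.
#' @return An [ensemble()].
#' @export
sample_ensemble <- function(model, motion, n_snapshots, seed) {
  stopifnot(inherits(model, "atomic_model"),
            inherits(motion, "motion_model"))
  if (n_snapshots < 1) stop("n_snapshots must be >= 1", call. = FALSE)
  lat <- model_lattice(model)
  rng <- local_rng(seed)
  X0 <- frac_to_orth(lat, coord_matrix(model))   # natoms x 3, Angstrom
  n <- nrow(X0)
  ns <- as.integer(n_snapshots)
  xyz <- switch(
    motion$kind,
    independent_gaussian = {
      base <- array(X0, c(n, 3, ns))
      if (motion$sigma > 0) {
        base + array(rng$rnorm(n * 3 * ns, sd = motion$sigma), c(n, 3, ns))
      } else base
    },
    liquid_like = sample_liquid_like(X0, motion, ns, rng),
    rigid_body = sample_rigid_body(X0, copy_index(model), motion, ns, rng),
    loop_flip = sample_loop_flip(X0, motion, ns, rng)
  )
  # back to box-fractional, unwrapped
  Minv <- solve(orthogonalization_matrix(lat))
  flat <- Minv %*% matrix(aperm(xyz, c(2, 1, 3)), nrow = 3)
  frac <- aperm(array(flat, c(3, n, ns)), c(2, 1, 3))
  ensemble(model, frac, seed = as.integer(seed))
}

sample_liquid_like <- function(X0, motion, ns, rng) {
  n <- nrow(X0)
  if (motion$sigma == 0) return(array(X0, c(n, 3, ns)))
  D <- as.matrix(stats::dist(X0))
  C <- motion$sigma^2 * exp(-D / motion$gamma)
  L <- tryCatch(t(chol(C)), error = function(e) {
    jitter <- 1e-10 * motion$sigma^2
    tryCatch(t(chol(C + diag(jitter, n))), error = function(e2) {
      stop("liquid-like covariance is not positive definite, even after a ",
           "1e-10 jitter: ", conditionMessage(e2), call. = FALSE)
    })
  })
  Z <- matrix(rng$rnorm(n * 3 * ns), nrow = n)
  U <- L %*% Z                                  # n x (3 ns), N(0, C) columns
  array(X0, c(n, 3, ns)) + array(U, c(n, 3, ns))
}

sample_rigid_body <- function(X0, copies, motion, ns, rng) {
  n <- nrow(X0)
  out <- array(NA_real_, c(n, 3, ns))
  ucopies <- sort(unique(copies))
  for (cp in ucopies) {
    sel <- which(copies == cp)
    Xc <- X0[sel, , drop = FALSE]
    cen <- colMeans(Xc)
    Xrel <- sweep(Xc, 2, cen)
    for (s in seq_len(ns)) {
      ax <- rng$rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      ang <- rng$rnorm(1, sd = motion$rot_sd) * pi / 180
      R <- rotation_about_axis(ax, ang)
      tr <- rng$rnorm(3, sd = motion$trans_sd)
      out[sel, , s] <- sweep(Xrel %*% t(R), 2, cen + tr, "+")
    }
  }
  out
}

sample_loop_flip <- function(X0, motion, ns, rng) {
  n <- nrow(X0)
  flips <- motion$flip_atoms
  others <- setdiff(seq_len(n), flips)
  # symmetric two-state Markov chain, starting in state A
  switches <- rng$runif(ns) < motion$switch_prob
  state <- cumsum(switches) %% 2 == 1           # FALSE = A, TRUE = B
  out <- array(X0, c(n, 3, ns))
  if (motion$sigma > 0 && length(others) > 0) {
    out[others, , ] <- out[others, , , drop = FALSE] +
      array(rng$rnorm(length(others) * 3 * ns, sd = motion$sigma),
            c(length(others), 3, ns))
  }
  for (s in seq_len(ns)) {
    out[flips, , s] <- if (state[s]) motion$conf_b else motion$conf_a
  }
  out
}

# Proper rotation by `angle` radians about unit axis `ax` (Rodrigues).
rotation_about_axis <- function(ax, angle) {
  K <- matrix(c(0, ax[3], -ax[2],
                -ax[3], 0, ax[1],
                ax[2], -ax[1], 0), nrow = 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
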