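ref_cluster <- function(n = 12, seed = 5) {
  set.seed(seed)
  matrix(runif(3 * n, 0, 10), ncol = 3)
}

test_that("translational alignment matches selection centroids exactly", {
  ref <- ref_cluster()
  shifted <- sweep(ref, 2, c(1, 2, 3), "+")
  expect_equal(align_translation(shifted, ref), ref, tolerance = 1e-12)
  expect_equal(align_translation(ref, ref), ref, tolerance = 1e-15)
  set.seed(1)
  rnd <- sweep(ref, 2, rnorm(3, sd = 4), "+")
  sel <- c(2, 5, 7, 11)
  out <- align_translation(rnd, ref, sel)
  expect_equal(colMeans(out[sel, ]), colMeans(ref[sel, ]),
               tolerance = 1e-12)
  expect_error(align_translation(rnd, ref, integer()), "empty")
})

test_that("rotation fit recovers exact rigid rotations", {
  ref <- ref_cluster()
  fit0 <- fit_rotation(ref, ref)
  expect_equal(fit0$R, diag(3), tolerance = 1e-12)
  expect_equal(fit0$rmsd_before, 0, tolerance = 1e-12)
  expect_equal(fit0$rmsd_after, 0, tolerance = 1e-12)

  Rz5 <- diffusekit:::rotation_about_axis(c(0, 0, 1), 5 * pi / 180)
  rot <- ref %*% t(Rz5)
  fit <- fit_rotation(rot, ref)
  expect_lt(fit$rmsd_after, 1e-9)
  ang <- diffusekit:::rotation_vector(fit$R)
  expect_equal(ang[["angle"]], 5, tolerance = 1e-9)
  # fitted rotation maps the snapshot back onto the reference
  expect_equal(fit$R %*% Rz5, diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)

  # degenerate collinear selection is rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rotation(line, line + 0.1), "collinear|degenerate")
})

test_that("noisy fits agree with the quaternion superposition oracle", {
  ref <- ref_cluster(20, seed = 8)
  set.seed(3)
  for (rep in 1:5) {
    R0 <- diffusekit:::rotation_about_axis(
      rnorm(3) |> (\(a) a / sqrt(sum(a^2)))(), runif(1, -0.3, 0.3))
    snap <- ref %*% t(R0) + matrix(rnorm(60, sd = 0.3), ncol = 3)
    snap <- align_translation(snap, ref)
    fit <- fit_rotation(snap, ref)
    oracle <- quaternion_rotation_oracle(snap, ref)
    expect_equal(fit$rmsd_after, oracle$rmsd_after, tolerance = 1e-9)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
    expect_lte(fit$rmsd_after, fit$rmsd_before + 1e-12)
  }
})

test_that("z-y-z Euler decomposition round-trips and handles gimbal", {
  expect_equal(unclass(euler_zyz(diag(3))), c(phi = 0, theta = 0, psi = 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  ez <- euler_zyz(diffusekit:::rotation_about_axis(c(0, 0, 1), 5 * pi / 180))
  expect_equal(ez[["phi"]] + ez[["psi"]], 5, tolerance = 1e-9)
  expect_equal(ez[["theta"]], 0, tolerance = 1e-9)
  expect_true(attr(ez, "gimbal"))

  set.seed(7)
  for (rep in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- diffusekit:::rotation_about_axis(ax, runif(1, -3, 3))
    e <- euler_zyz(R)
    expect_equal(euler_zyz_matrix(e[["phi"]], e[["theta"]], e[["psi"]]), R,
                 tolerance = 1e-10)
  }
})

test_that("static ensembles give zero angle SDs and flagged reductions", {
  crystal <- toy_crystal(n_atoms = 5, lat = toy_lattice(20, 24),
                         layout = c(1L, 1L, 1L))
  ens <- sample_ensemble(crystal, motion_model("independent_gaussian",
                                               sigma = 0), 5, seed = 2)
  st <- rotation_statistics(ensemble_rotation_fits(ens))
  expect_equal(nrow(st), 4)          # four P4(1) copies
  expect_true(all(st$sd_phi < 1e-9 & st$sd_theta < 1e-9 &
                    st$sd_psi < 1e-9))
  expect_true(all(is.na(st$reduction)))
})

test_that("pure rigid rotations are recovered at the generator amplitude", {
  crystal <- toy_crystal(n_atoms = 8, lat = toy_lattice(24, 30),
                         layout = c(1L, 1L, 1L))
  rot_sd <- 2
  ens <- sample_ensemble(crystal,
                         motion_model("rigid_body", rot_sd = rot_sd,
                                      trans_sd = 0), 500, seed = 9)
  st <- rotation_statistics(ensemble_rotation_fits(ens))
  # rms fitted rotation amplitude ~ rot_sd within MC error (4 x 500 fits)
  expect_equal(mean(st$rms_angle), rot_sd, tolerance = 0.1)
  expect_true(all(st$reduction > 0.9))
})

test_that("internal motion leaks into the rotation fit (the pitfall)", {
  crystal <- toy_crystal(n_atoms = 8, lat = toy_lattice(24, 30),
                         layout = c(1L, 1L, 1L))
  ens <- sample_ensemble(crystal,
                         motion_model("independent_gaussian", sigma = 0.3),
                         200, seed = 4)
  st <- rotation_statistics(ensemble_rotation_fits(ens))
  # angle SDs are strictly positive even though no rigid rotation exists...
  expect_true(all(st$rms_angle > 0))
  # ...but the alignment buys little: most displacement is internal
  expect_true(all(st$reduction < 0.3))
})

test_that("excluding atoms from a rigid ensemble barely changes the SDs", {
  crystal <- toy_crystal(n_atoms = 10, lat = toy_lattice(24, 30),
                         layout = c(1L, 1L, 1L))
  ens <- sample_ensemble(crystal,
                         motion_model("rigid_body", rot_sd = 2,
                                      trans_sd = 0), 300, seed = 14)
  sel <- which(copy_index(crystal) == 1)
  res <- subset_excluded_fit(ens, selection = sel, excluded = sel[1:3])
  expect_lt(max(abs(res$delta$d_sd_theta)), 0.35)
  expect_error(subset_excluded_fit(ens, selection = sel, excluded = 99L),
               "part of the selection")
  expect_error(subset_excluded_fit(ens, selection = sel,
                                   excluded = sel[-(1:2)]), "fewer than 3")
})

test_that("a loop flip inflates psi SD and exclusion removes it", {
  lat <- toy_lattice(24, 30, layout = c(1L, 1L, 1L))
  model <- toy_crystal(n_atoms = 12, lat = lat, layout = c(1L, 1L, 1L))
  sel <- which(copy_index(model) == 1)
  flips <- sel[9:12]
  xyz0 <- frac_to_orth(lat, diffusekit:::coord_matrix(model))
  conf_a <- xyz0[flips, ]
  # conformation B: the loop tip swings about an oblique axis through its
  # own centroid, mimicking a discrete conformational change
  axis <- c(1, 1, 1) / sqrt(3)
  Rf <- diffusekit:::rotation_about_axis(axis, 25 * pi / 180)
  cen <- colMeans(conf_a)
  conf_b <- sweep(sweep(conf_a, 2, cen) %*% t(Rf), 2, cen, "+")
  m <- motion_model("loop_flip", sigma = 0, flip_atoms = flips,
                    conf_a = conf_a, conf_b = conf_b, switch_prob = 0.2)
  ens <- sample_ensemble(model, m, 300, seed = 6)
  res <- subset_excluded_fit(ens, selection = sel, excluded = flips)
  full1 <- res$full[res$full$copy == 1, ]
  red1 <- res$reduced[res$reduced$copy == 1, ]
  expect_gt(full1$sd_psi, 0)
  expect_gt(full1$sd_theta, 0)
  # excluding the flipping tip collapses the apparent rotation
  expect_lt(red1$sd_psi, full1$sd_psi)
  expect_lt(red1$sd_theta + red1$sd_phi,
            full1$sd_theta + full1$sd_phi)

  # specificity: excluding an equally sized rigid subset changes psi far
  # less than excluding the flipping subset
  ctrl <- subset_excluded_fit(ens, selection = sel, excluded = sel[1:4])
  ctrl1_d <- abs(ctrl$delta$d_sd_psi[ctrl$delta$copy == 1])
  flip_d <- abs(res$delta$d_sd_psi[res$delta$copy == 1])
  expect_lt(ctrl1_d, flip_d)
})
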