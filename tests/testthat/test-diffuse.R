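test_that("identical snapshots give zero diffuse intensity", {
  lat <- p1_lattice()
  grid <- small_grid(lat, hmax = 2)
  sf <- unit_sf_set(grid, matrix(c(0.2, 0.3, 0.4), 1))
  D <- finalize_diffuse(accumulate_diffuse(list(sf, sf, sf)))
  expect_true(all(abs(D$intensity) <= 1e-9 * max(Mod(sf$f)^2)))
  expect_error(finalize_diffuse(accumulate_diffuse(list(sf))),
               "two snapshots")
})

test_that("the two-position single atom gives the parity pattern", {
  lat <- p1_lattice()
  grid <- small_grid(lat, hmax = 2)
  s1 <- unit_sf_set(grid, matrix(c(0, 0, 0), 1))
  s2 <- unit_sf_set(grid, matrix(c(0.5, 0, 0), 1))
  D <- finalize_diffuse(accumulate_diffuse(list(s1, s2)))
  # <|f|^2> = 1; |<f>|^2 = 1 (even h) or 0 (odd h)
  expect_equal(D$intensity, ifelse(grid$ih %% 2 == 0, 0, 1),
               tolerance = 1e-12)
})

test_that("a Gaussian single atom follows the Einstein-model closed form", {
  lat <- p1_lattice(14, 14, 14)
  grid <- small_grid(lat, hmax = 3)
  model <- atomic_model(
    tibble::tibble(element = "C", x = 0.5, y = 0.5, z = 0.5), lat)
  sigma <- 0.3
  n <- 4000
  ens <- sample_ensemble(model,
                         motion_model("independent_gaussian", sigma = sigma),
                         n, seed = 31)
  D <- guinier_map(ens, grid)
  f2 <- form_factor("C", grid$s)^2
  pred <- 1 - exp(-4 * pi^2 * sigma^2 * grid$s^2)
  off <- grid$s > 0
  ratio <- (D$intensity / f2)[off] * n / (n - 1)
  expect_equal(ratio, pred[off], tolerance = 0.15)
  expect_gt(cor(ratio, pred[off]), 0.99)
  # variance non-negativity within accumulation round-off
  expect_true(all(D$intensity >= -1e-9 * max(Mod(D$intensity))))
})

test_that("chunked accumulation is an exact algebraic identity", {
  lat <- p1_lattice(15, 15, 15)
  grid <- small_grid(lat, hmax = 2)
  model <- toy_asymmetric_unit(lat, 6, 5, seed = 8)
  ens <- sample_ensemble(model,
                         motion_model("independent_gaussian", sigma = 0.4),
                         1000, seed = 3)
  one <- finalize_diffuse(accumulate_diffuse(ens, grid))

  chunkmap <- function(sizes) {
    stopifnot(sum(sizes) == 1000)
    start <- cumsum(c(1, head(sizes, -1)))
    parts <- purrr::map2(start, sizes, function(s0, len) {
      sub <- ensemble(ens$model,
                      ens$coords[, , s0:(s0 + len - 1), drop = FALSE])
      accumulate_diffuse(sub, grid)
    })
    finalize_diffuse(merge_accumulators(parts))
  }
  scale <- max(abs(one$intensity))
  expect_lt(max(abs(chunkmap(rep(5, 200))$intensity - one$intensity)),
            1e-12 * scale)
  expect_lt(max(abs(chunkmap(c(100, 900))$intensity - one$intensity)),
            1e-12 * scale)
  # single partial finalizes to itself
  single <- merge_accumulators(list(accumulate_diffuse(ens, grid)))
  expect_equal(finalize_diffuse(single)$intensity, one$intensity,
               tolerance = 1e-15)
})

test_that("radial profiles average within voxel-diagonal shells", {
  lat <- p1_lattice()
  grid <- small_grid(lat, hmax = 3)
  const <- diffuse_map(grid, rep(3.25, nrow(grid)))
  prof <- radial_profile(const)
  expect_true(all(abs(prof$intensity[prof$n_points > 0] - 3.25) < 1e-12))
  expect_equal(sum(prof$n_points), nrow(grid))
  thick <- shell_thickness(grid)
  expect_equal(thick, sqrt(sum(1 / c(10, 12, 14)^2)))
  expect_true(all(diff(prof$s_mid) - thick < 1e-12))

  quad <- diffuse_map(grid, grid$s^2)
  p2 <- radial_profile(quad)
  pop <- p2$n_points > 0
  expect_true(all(abs(p2$intensity[pop] - p2$s_mid[pop]^2) <
                    (2 * p2$s_mid[pop] + thick) * thick))

  # brute-force per-shell means
  idx <- floor(grid$s / thick) + 1
  brute <- tapply(quad$intensity, idx, mean)
  expect_equal(unname(p2$intensity[as.integer(names(brute))]),
               unname(as.vector(brute)), tolerance = 1e-12)
})

test_that("anisotropic subtraction removes radial structure", {
  lat <- p1_lattice(20, 22, 24)
  grid <- small_grid(lat, hmax = 5)
  const <- diffuse_map(grid, rep(2, nrow(grid)))
  a0 <- anisotropic_map(const)
  expect_true(all(abs(a0$intensity[a0$measured]) < 1e-12))

  # a purely radial Gaussian leaves a tiny residual once the shells are
  # thin relative to its width (shell thickness is set by the cell)
  lat_big <- p1_lattice(60, 62, 64)
  grid_big <- small_grid(lat_big, hmax = 24)
  radial <- diffuse_map(grid_big, exp(-grid_big$s^2 / 0.1))
  ar <- anisotropic_map(radial)
  expect_lt(max(abs(ar$intensity[ar$measured])),
            0.01 * max(radial$intensity))

  # shell-mean residual bias is small relative to the residual magnitude
  # over the complete shells of the analysis band
  bumpy <- diffuse_map(grid_big, exp(-grid_big$s^2 / 0.1) *
                         (1 + 0.5 * sin(40 * grid_big$h / 24) *
                            cos(30 * grid_big$k / 24)))
  ab <- anisotropic_map(bumpy)
  res <- decomposition_residuals(ab, s_min = 3 * shell_thickness(ab))
  keep <- res$complete & res$n_points > 0
  expect_gt(sum(keep), 5)
  expect_true(all(res$ratio[keep] <= 0.05))

  tiny <- diffuse_map(small_grid(lat, hmax = 1), rep(1, 27))
  expect_error(anisotropic_map(tiny), "4 populated shells")
})

test_that("P4/m symmetrization averages orbits and is idempotent", {
  lat <- toy_lattice(20, 24, layout = c(1L, 1L, 1L))
  grid <- small_grid(lat, hmax = 2)
  attr(grid, "lattice") <- lat

  imp <- rep(0, nrow(grid))
  imp[grid$ih == 1 & grid$ik == 0 & grid$il == 0] <- 8
  m <- diffuse_map(grid, imp)
  sym <- symmetrize_laue(m, "P4/m")
  orbit <- (abs(grid$ih) == 1 & grid$ik == 0 | grid$ih == 0 &
              abs(grid$ik) == 1) & grid$il == 0
  expect_equal(sym$intensity[orbit], rep(2, 4), tolerance = 1e-12)
  expect_true(all(sym$intensity[!orbit] == 0))

  set.seed(2)
  noise <- diffuse_map(grid, rnorm(nrow(grid)))
  s1 <- symmetrize_laue(noise, "P4/m")
  s2 <- symmetrize_laue(s1, "P4/m")
  expect_equal(s2$intensity, s1$intensity, tolerance = 1e-12)
  expect_equal(symmetrize_laue(s1, "P4/m")$intensity, s1$intensity,
               tolerance = 1e-12)
  # symmetric input is unchanged; the measured mean is preserved
  expect_equal(mean(s1$intensity), mean(noise$intensity),
               tolerance = 1e-12)
  expect_error(symmetrize_laue(noise, "P6/m"), "unsupported|Laue")
})

test_that("pearson correlation honors affine invariance and flags degeneracy", {
  lat <- p1_lattice()
  grid <- small_grid(lat, hmax = 1)
  set.seed(9)
  A <- diffuse_map(grid, rnorm(nrow(grid)))
  B <- diffuse_map(grid, 2 * A$intensity + 7)
  expect_equal(map_cor(A, A), 1.0, tolerance = 1e-12)
  expect_equal(map_cor(A, B), 1.0, tolerance = 1e-12)
  expect_equal(map_cor(A, diffuse_map(grid, -A$intensity)), -1.0,
               tolerance = 1e-12)

  # five-point hand oracle
  x <- c(1, 2, 4, 7, 11); y <- c(2, 1, 5, 6, 13)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  g5 <- grid[1:5, ]
  attr(g5, "lattice") <- lat; attr(g5, "sampling") <- c(1L, 1L, 1L)
  attr(g5, "d_min") <- 1
  expect_equal(map_cor(diffuse_map(g5, x), diffuse_map(g5, y)), r_hand,
               tolerance = 1e-12)

  const <- diffuse_map(grid, rep(1, nrow(grid)))
  expect_true(is.na(map_cor(A, const)))
  two <- diffuse_map(grid, A$intensity,
                     measured = seq_len(nrow(grid)) <= 2)
  expect_true(is.na(map_cor(two, two)))
})

test_that("shell CC series flags thin shells and tracks construction", {
  lat <- p1_lattice(20, 22, 24)
  grid <- small_grid(lat, hmax = 6)
  set.seed(11)
  base <- rnorm(nrow(grid))
  A <- diffuse_map(grid, base)
  expect_true(all(abs(stats::na.omit(shell_cc(A, A)$cc) - 1) < 1e-12))

  # correlated at low resolution only
  cut <- stats::median(grid$s)
  mixed <- ifelse(grid$s < cut, base, rnorm(nrow(grid)))
  B <- diffuse_map(grid, mixed)
  cc <- shell_cc(A, B)
  thick <- diffusekit:::shell_thickness(A)
  pop <- cc$n_points >= 30
  low <- cc$s_mid < cut - thick & pop   # shells fully below the boundary
  high <- cc$s_mid > cut + thick & pop
  expect_gt(min(cc$cc[low], na.rm = TRUE), 0.9)
  expect_lt(mean(abs(cc$cc[high]), na.rm = TRUE), 0.5)

  thin <- diffuse_map(grid, base, measured = seq_len(nrow(grid)) %in%
                        order(grid$s)[1:5])
  cc_thin <- shell_cc(thin, thin)
  expect_true(all(is.na(cc_thin$cc[cc_thin$n_points < 3])))
})

test_that("CC_sym is 1 for symmetric maps and small for antisymmetric noise", {
  lat <- toy_lattice(20, 24, layout = c(1L, 1L, 1L))
  grid <- small_grid(lat, hmax = 3)
  attr(grid, "lattice") <- lat
  set.seed(4)
  noise <- diffuse_map(grid, rnorm(nrow(grid)))
  sym <- symmetrize_laue(noise, "P4/m")
  expect_equal(cc_sym(sym, "P4/m"), 1.0, tolerance = 1e-12)

  # construction with orbit sums of zero: correlation with the (all-zero
  # mean) symmetrized image is undefined-or-zero; check the direct formula
  anti <- diffuse_map(grid, noise$intensity - sym$intensity)
  anti_sym <- symmetrize_laue(anti, "P4/m")
  expect_lt(max(abs(anti_sym$intensity)), 1e-10)

  # white noise: CC_sym concentrates near sqrt(1/orbit size)
  key <- diffusekit:::orbit_key(
    diffusekit:::laue_images(grid$ih, grid$ik, grid$il, "P4/m"))
  mean_orbit <- mean(table(key))
  ccs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    cc_sym(diffuse_map(grid, rnorm(nrow(grid))), "P4/m")
  }, numeric(1))
  expect_equal(mean(ccs), sqrt(1 / mean_orbit), tolerance = 0.2)
})

test_that("diffuse_compare symmetrizes and reports the standard statistics", {
  lat <- toy_lattice(16, 20, layout = c(1L, 1L, 1L))
  grid <- reciprocal_grid(lat, d_min = 2.5)
  model <- expand_p41(toy_asymmetric_unit(lat, 5, 5, seed = 2))
  e1 <- sample_ensemble(model, motion_model("liquid_like", sigma = 0.3,
                                            gamma = 4), 300, seed = 1)
  e2 <- sample_ensemble(model, motion_model("liquid_like", sigma = 0.3,
                                            gamma = 4), 300, seed = 2)
  cmp <- diffuse_compare(guinier_map(e1, grid), guinier_map(e2, grid))
  expect_gt(cmp$r_oc, 0.9)
  expect_true(cmp$r_oc_aniso > 0.5)
  expect_true(all(stats::na.omit(cmp$shell_cc$cc) >= -1 &
                    stats::na.omit(cmp$shell_cc$cc) <= 1))
  gl <- glance(cmp)
  expect_equal(gl$r_oc, cmp$r_oc)
})
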