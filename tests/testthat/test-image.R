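std_geom <- function(dims = c(64L, 64L), polarization = 0.9,
                     az = 20) {
  detector_geometry(distance = 100, pixel = 0.4,
                    center = (dims + 1) / 2, wavelength = 1.2,
                    dims = dims, polarization = polarization,
                    polarization_azimuth = az)
}

test_that("geometric factors match a scalar oracle and normalize at center", {
  geom <- std_geom(c(16L, 16L))
  f <- diffusekit:::geometry_factors(geom)
  # scalar per-pixel oracle from first principles
  for (px in c(1, 5, 16)) {
    for (py in c(2, 9, 16)) {
      dx <- (px - geom$center[1]) * geom$pixel
      dy <- (py - geom$center[2]) * geom$pixel
      cos2t <- geom$distance / sqrt(dx^2 + dy^2 + geom$distance^2)
      sin2t2 <- 1 - cos2t^2
      azim <- atan2(dy, dx) - geom$polarization_azimuth * pi / 180
      P <- geom$polarization * (1 - sin2t2 * cos(azim)^2) +
        (1 - geom$polarization) * (1 - sin2t2 * sin(azim)^2)
      expect_equal(f[px, py], P * cos2t^3, tolerance = 1e-12)
    }
  }
  # beam center (between pixels here): factor -> 1 at zero obliquity
  geom2 <- detector_geometry(100, 0.4, c(8, 8), 1.2, dims = c(16L, 16L))
  f2 <- diffusekit:::geometry_factors(geom2)
  expect_equal(f2[8, 8], 1, tolerance = 1e-12)
  # unpolarized limit: (1 + cos^2 2theta)/2 at any azimuth
  geom3 <- detector_geometry(100, 0.4, c(8, 8), 1.2, dims = c(16L, 16L),
                             polarization = 0.5)
  f3 <- diffusekit:::geometry_factors(geom3)
  dx <- (16 - 8) * 0.4; c2 <- 100 / sqrt(dx^2 + 100^2)
  expect_equal(f3[16, 8], (1 + c2^2) / 2 * c2^3, tolerance = 1e-12)
})

test_that("correct_geometry inverts a synthesized flat * P * Omega image", {
  geom <- std_geom()
  flat <- 250
  counts <- flat * diffusekit:::geometry_factors(geom)
  img <- detector_image(counts, geom)
  corr <- correct_geometry(img)
  expect_equal(corr$counts, matrix(flat, 64, 64), tolerance = 1e-9)
  # invertible per-pixel scaling
  back <- correct_geometry(corr, undo = TRUE)
  expect_equal(back$counts, counts, tolerance = 1e-12)
})

test_that("pixel -> hkl respects Bragg's relation and inverts", {
  lat <- p1_lattice(20, 22, 24)
  geom <- std_geom()
  setting <- orientation_setting(lat = lat, phi = 13, axis = c(1, 0, 0))
  # beam-center pixel -> the origin of reciprocal space
  h0 <- pixel_to_hkl(geom$center[1], geom$center[2], geom, setting)
  expect_equal(as.vector(h0), c(0, 0, 0), tolerance = 1e-12)

  px <- c(3.2, 40.5, 61); py <- c(10, 33.7, 58)
  hkl <- pixel_to_hkl(px, py, geom, setting)
  # |s| from the cell metric equals 2 sin(theta)/lambda from the pixel angle
  smod <- s_modulus(lat, hkl[, 1], hkl[, 2], hkl[, 3])
  r <- sqrt(((px - geom$center[1]) * geom$pixel)^2 +
              ((py - geom$center[2]) * geom$pixel)^2)
  twotheta <- atan2(r, geom$distance)
  expect_equal(smod, 2 * sin(twotheta / 2) / geom$wavelength,
               tolerance = 1e-9)
  # forward projection returns the original pixels with zero excitation
  back <- hkl_to_pixel(hkl, geom, setting)
  expect_equal(back$px, px, tolerance = 1e-9)
  expect_equal(back$py, py, tolerance = 1e-9)
  expect_equal(back$excitation, rep(0, 3), tolerance = 1e-12)
})

test_that("a pixel at the (1,0,0) Bragg angle indexes at h = 1", {
  a <- 20
  lat <- p1_lattice(a, 22, 24)
  geom <- detector_geometry(100, 0.1, c(1, 256), 1.2, dims = c(512L, 512L))
  setting <- orientation_setting(lat = lat, phi = 0)
  # place a* so that its reflection diffracts: rotate the crystal about y
  # by the Bragg angle theta for d = a
  theta <- asin(geom$wavelength / (2 * a))
  Ry <- diffusekit:::rotation_about_axis(c(0, 1, 0), theta)
  setting$A <- Ry %*% setting$A
  # the diffracted beam leaves at 2 theta in the xz plane
  px_hit <- geom$distance * tan(2 * theta) / geom$pixel + geom$center[1]
  hkl <- pixel_to_hkl(px_hit, geom$center[2], geom, setting)
  expect_equal(as.vector(hkl), c(1, 0, 0), tolerance = 1e-6)
})

test_that("mode filter keeps constants, kills spikes, masks properly", {
  geom <- std_geom(c(40L, 40L))
  # a constant image maps to its own bin representative everywhere
  # (bin lower edge + half width; integerized again on raster write)
  const <- detector_image(matrix(100, 40, 40), geom)
  mf <- mode_filter(const, kernel = 15, bin_width = 1)
  expect_true(all(mf$counts == 100.5))
  expect_true(all(abs(mf$counts - const$counts) <= 0.5))

  spiked <- matrix(100, 40, 40)
  spiked[20, 20] <- 10000
  ms <- mode_filter(detector_image(spiked, geom), 15, 1)
  expect_equal(ms$counts[20, 20], 100.5, tolerance = 1e-12)
  expect_equal(ms$counts[21, 20], 100.5, tolerance = 1e-12)
  # output values come only from occupied bins of the input
  expect_true(all(ms$counts %in% c(100.5)))

  # masked pixels are excluded and propagate
  msk <- matrix(FALSE, 40, 40); msk[1:16, 1:16] <- TRUE
  img <- detector_image(spiked, geom, mask = msk)
  mm <- mode_filter(img, 15, 1)
  expect_true(all(mm$mask[1:16, 1:16]))
  expect_error(mode_filter(const, kernel = 4), "odd")
})

test_that("trilinear interpolation matches an independent oracle", {
  lat <- p1_lattice()
  grid <- small_grid(lat, hmax = 3)
  set.seed(13)
  vals <- rnorm(nrow(grid))
  m <- diffuse_map(grid, vals)
  dense <- diffusekit:::map_dense(m)
  lookup <- function(i, j, k) vals[which(grid$ih == i & grid$ik == j &
                                           grid$il == k)]
  set.seed(14)
  u <- cbind(runif(50, -2.5, 2.4), runif(50, -2.5, 2.4),
             runif(50, -2.5, 2.4))
  got <- diffusekit:::trilinear_lookup(dense, u)
  for (r in 1:50) {
    f0 <- floor(u[r, ]); fr <- u[r, ] - f0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * lookup(f0[1] + dx, f0[2] + dy, f0[3] + dz)
    }
    expect_equal(got[r], acc, tolerance = 1e-12)
  }
  # exact grid points return exactly the stored value
  expect_equal(diffusekit:::trilinear_lookup(dense,
                                             cbind(1, -2, 3))[1],
               lookup(1, -2, 3), tolerance = 1e-15)
})

test_that("simulating from a constant map gives a constant image", {
  lat <- p1_lattice(20, 22, 24)
  grid <- reciprocal_grid(lat, d_min = 3)
  m <- diffuse_map(grid, rep(7.5, nrow(grid)))
  geom <- std_geom()
  setting <- orientation_setting(lat = lat, phi = 0)
  img <- simulate_image(m, geom, setting)
  inside <- !img$mask
  expect_gt(sum(inside), 1000)
  expect_true(all(abs(img$counts[inside] - 7.5) < 1e-9))
})

test_that("integration conserves pixels and recovers constants", {
  lat <- p1_lattice(20, 22, 24)
  grid <- reciprocal_grid(lat, d_min = 3)
  geom <- std_geom()
  settings <- rotation_series(lat, 4, start = 0, step = 2)
  imgs <- lapply(settings, function(st)
    detector_image(matrix(42, 64, 64), geom, st))
  intg <- integrate_images(imgs, grid)
  expect_true(all(abs(intg$intensity[intg$measured] - 42) < 1e-12))
  # every unmasked pixel lands on exactly one grid point or is out of range
  hkl <- pixel_to_hkl(rep(1:64, 64), rep(1:64, each = 64), geom,
                      settings[[1]])
  u <- round(hkl)
  in_sphere <- s_modulus(lat, u[, 1], u[, 2], u[, 3]) <= 1 / 3 + 1e-12
  expect_equal(sum(intg$n_obs) / 4, sum(in_sphere))
})

test_that("reindexing operations form the expected two-fold group", {
  lat <- p1_lattice()
  grid <- small_grid(lat, hmax = 3)
  set.seed(15)
  m <- diffuse_map(grid, rnorm(nrow(grid)))
  for (op in c("2h", "2k", "2l")) {
    expect_equal(reindex_map(reindex_map(m, op), op)$intensity,
                 m$intensity, tolerance = 1e-15, info = op)
  }
  expect_equal(reindex_map(m, "identity")$intensity, m$intensity)

  imp <- rep(0, nrow(grid))
  imp[grid$ih == 1 & grid$ik == 2 & grid$il == 3] <- 5
  mi <- reindex_map(diffuse_map(grid, imp), "2h")
  expect_equal(mi$intensity[grid$ih == 1 & grid$ik == -2 & grid$il == -3],
               5)
  expect_equal(sum(mi$intensity), 5)

  # a P4/m-symmetrized map is invariant under the l two-fold
  lat4 <- toy_lattice(20, 24, layout = c(1L, 1L, 1L))
  g4 <- small_grid(lat4, hmax = 3)
  attr(g4, "lattice") <- lat4
  sym <- symmetrize_laue(diffuse_map(g4, rnorm(nrow(g4))), "P4/m")
  expect_equal(reindex_map(sym, "2l")$intensity, sym$intensity,
               tolerance = 1e-12)
})

test_that("rendered Bragg spikes stand out and the mode filter removes them", {
  lat <- p1_lattice(20, 22, 24)
  grid <- reciprocal_grid(lat, d_min = 3)
  smooth <- diffuse_map(grid, 200 * exp(-grid$s^2 / 0.05))
  geom <- std_geom(c(64L, 64L), polarization = 0.5, az = 0)
  settings <- rotation_series(lat, 2, step = 1)
  bragg_pts <- grid[grid$s > 0 & abs(grid$h %% 1) < 1e-9 &
                      abs(grid$k %% 1) < 1e-9 & abs(grid$l %% 1) < 1e-9, ]
  bragg <- structure(tibble::tibble(
    h = bragg_pts$h, k = bragg_pts$k, l = bragg_pts$l,
    intensity = 5e4), class = c("bragg_set", "tbl_df", "tbl", "data.frame"))

  clean <- render_images(smooth, geom, settings, bragg = NULL,
                         apply_corrections = FALSE, noise_seed = NULL)
  spiked <- render_images(smooth, geom, settings, bragg = bragg,
                          apply_corrections = FALSE, noise_seed = NULL,
                          bragg_width = 0.01)
  hits <- which(spiked[[1]]$counts != clean[[1]]$counts, arr.ind = TRUE)
  expect_gt(nrow(hits), 0)
  # spikes exceed 10x the local median
  for (r in seq_len(min(nrow(hits), 5))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    nb <- clean[[1]]$counts[max(1, i - 3):min(64, i + 3),
                            max(1, j - 3):min(64, j + 3)]
    expect_gt(spiked[[1]]$counts[i, j], 10 * stats::median(nb))
  }
  # the mode filter brings spike pixels back to within the counting noise
  # of the spike-free render (3 sigma_Poisson at the local level)
  filt <- mode_filter(spiked[[1]], kernel = 15, bin_width = 1)
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    ref <- clean[[1]]$counts[i, j]
    expect_lt(abs(filt$counts[i, j] - ref), 3 * sqrt(max(ref, 1)))
  }
  # zero map, no Bragg, no noise -> all-zero images
  zero <- render_images(diffuse_map(grid, rep(0, nrow(grid))), geom,
                        settings, apply_corrections = FALSE)
  expect_true(all(zero[[1]]$counts == 0))
  # determinism of the Poisson stage
  n1 <- render_images(smooth, geom, settings, noise_seed = 5)
  n2 <- render_images(smooth, geom, settings, noise_seed = 5)
  expect_identical(n1[[1]]$counts, n2[[1]]$counts)
})

test_that("simulate -> filter -> correct -> integrate round-trips a map", {
  lat <- p1_lattice(20, 22, 24)
  grid <- reciprocal_grid(lat, d_min = 3)
  target <- diffuse_map(grid, 150 * exp(-grid$s^2 / 0.05) *
                          (1 + 0.4 * sin(2 * grid$h) * cos(grid$k)))
  geom <- detector_geometry(60, 0.8, c(48.5, 48.5), 1.2,
                            dims = c(96L, 96L), polarization = 0.9,
                            polarization_azimuth = 20)
  settings <- rotation_series(lat, 8, start = 0, step = 8)
  imgs <- render_images(target, geom, settings, apply_corrections = TRUE)
  processed <- lapply(imgs, function(im)
    correct_geometry(mode_filter(im, kernel = 5, bin_width = 1)))
  intg <- integrate_images(processed, grid)
  joint <- intg$measured
  expect_gt(sum(joint), 200)
  expect_gt(cor(intg$intensity[joint], target$intensity[joint]), 0.95)
})
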