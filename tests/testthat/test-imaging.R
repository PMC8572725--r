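sphere_mask <- function(d, centre_vox, radius_vox) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  m <- (g$x - centre_vox[1])^2 + (g$y - centre_vox[2])^2 +
    (g$z - centre_vox[3])^2 <= radius_vox^2
  array(m, d)
}

test_that("Otsu threshold separates a bimodal intensity mixture", {
  set.seed(1)
  x <- c(rnorm(500, 10, 1), rnorm(500, 100, 5))
  t <- otsu_threshold(x)
  expect_gt(t, 20); expect_lt(t, 90)
  expect_true(is.na(otsu_threshold(rep(3, 10))))
})

test_that("Gaussian smoothing preserves total intensity", {
  set.seed(2)
  img <- array(runif(16 * 16 * 8), c(16, 16, 8))
  sm <- gaussian_smooth3d(img, c(1, 1, 0.5))
  expect_equal(dim(sm), dim(img))
  # replicate-padded convolution conserves a constant image exactly
  const <- array(5, c(8, 8, 4))
  expect_equal(gaussian_smooth3d(const, 1.5), const, tolerance = 1e-9)
})

test_that("distance transform equals the brute-force oracle", {
  set.seed(3)
  cases <- list(
    list(d = c(16, 12, 8), vx = c(1, 1, 1)),
    list(d = c(12, 16, 6), vx = c(1, 1, 2)),
    list(d = c(10, 10, 10), vx = c(0.5, 0.8, 1.7)))
  for (cs in cases) {
    m <- array(runif(prod(cs$d)) < 0.6, cs$d)
    got <- distance_transform3d(m, cs$vx)
    want <- oracle_edt(m, cs$vx)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # all-foreground mask -> Inf everywhere
  allfg <- array(TRUE, c(4, 4, 4))
  expect_true(all(distance_transform3d(allfg) == Inf))
  # boundary voxel sits one spacing from background
  m2 <- array(FALSE, c(8, 8, 8)); m2[3:6, 3:6, 3:6] <- TRUE
  edt <- distance_transform3d(m2, c(1, 1, 1))
  expect_equal(edt[3, 4, 4], 1)
})

test_that("segmentation recovers spheres with near-analytic volume", {
  d <- c(32, 32, 16); vx <- c(1, 1, 2)
  m <- sphere_mask(d, c(16, 16, 8), 8)   # radius 8 in x/y voxels
  img <- array(0, d); img[m] <- 100
  lab <- segment_nuclei(img, vx, smooth_sigma = 1, min_volume = 20)
  expect_equal(max(lab), 1)
  vol_vox <- sum(lab == 1)
  # analytic sphere volume in voxel units (anisotropic z handled by the
  # mask itself being built in voxel space here)
  expect_lt(abs(vol_vox - sum(m)) / sum(m), 0.1)

  # two well-separated nuclei give two labels
  img2 <- array(0, c(48, 24, 12))
  img2[sphere_mask(c(48, 24, 12), c(12, 12, 6), 5)] <- 100
  img2[sphere_mask(c(48, 24, 12), c(36, 12, 6), 5)] <- 100
  lab2 <- segment_nuclei(img2, c(1, 1, 1), smooth_sigma = 1,
                         min_volume = 20)
  expect_equal(max(lab2), 2)

  # blank image -> zero labels, not an error
  expect_equal(max(segment_nuclei(array(0, c(8, 8, 4)), c(1, 1, 1))), 0)
})

test_that("LoG detection finds planted spots at voxel accuracy", {
  d <- c(24, 24, 12); vx <- c(0.1, 0.1, 0.2)
  mk <- function(centres) {
    img <- array(0, d)
    cx <- (seq_len(d[1]) - 0.5) * vx[1]
    cy <- (seq_len(d[2]) - 0.5) * vx[2]
    cz <- (seq_len(d[3]) - 0.5) * vx[3]
    for (i in seq_len(nrow(centres)))
      img <- img + 100 * outer(outer(
        exp(-(cx - centres[i, 1])^2 / (2 * 0.15^2)),
        exp(-(cy - centres[i, 2])^2 / (2 * 0.15^2))),
        exp(-(cz - centres[i, 3])^2 / (2 * 0.15^2)))
    img
  }
  one <- mk(matrix(c(1.23, 1.17, 1.3), 1))
  f1 <- detect_foci(one, vx, sigma = 0.15, quality_min = 10)
  expect_equal(nrow(f1), 1)
  expect_lt(max(abs(c(f1$x - 1.23, f1$y - 1.17)), abs(f1$z - 1.3)), 0.21)
  expect_equal(f1$diameter, 2 * sqrt(3) * 0.15)

  # blank channel -> empty result
  f0 <- detect_foci(array(0, d), vx, sigma = 0.15, quality_min = 10)
  expect_equal(nrow(f0), 0)

  # two spots >= 4 sigma apart resolve into two foci
  two <- mk(rbind(c(0.8, 1.2, 1.2), c(1.6, 1.2, 1.2)))
  f2 <- detect_foci(two, vx, sigma = 0.15, quality_min = 10)
  expect_equal(nrow(f2), 2)
})

test_that("focus distances honour the mask and exclusion rule", {
  d <- c(24, 24, 24)
  m <- sphere_mask(d, c(12, 12, 12), 8)
  lab <- array(0L, d); lab[m] <- 1L
  foci <- data.frame(vx = c(12, 12, 2), vy = c(12, 12, 2),
                     vz = c(12, 12, 2),
                     x = NA, y = NA, z = NA, quality = 1,
                     intensity = 1, diameter = 1)
  out <- focus_periphery_distance(lab, foci, c(1, 1, 1))
  # centre focus: distance about the radius
  expect_lt(abs(out$distance[1] - 8), 1.1)
  expect_false(out$excluded[1])
  # focus outside every nucleus is excluded
  expect_true(out$excluded[3])
  expect_true(is.na(out$distance[3]))
  # distances never exceed the inradius
  edt <- distance_transform3d(lab > 0, c(1, 1, 1))
  expect_lte(max(edt[is.finite(edt)]), 8 + 1)
})

test_that("planted foci are measured to within a voxel end to end", {
  cfg <- tiny_config(seed = 14)
  scenes <- render_nuclei(cfg, n_nuclei = 6)
  det <- 0; tot <- 0; errs <- c()
  for (sc in scenes) {
    masks <- segment_nuclei(sc$stack[, , , 1], sc$voxel_size)
    foci <- detect_foci(sc$stack[, , , 2], sc$voxel_size,
                        sigma = cfg$focus_sigma,
                        quality_min = cfg$focus_amp / 4)
    meas <- focus_periphery_distance(masks, foci, sc$voxel_size)
    tin <- sc$truth[sc$truth$inside, ]
    tot <- tot + nrow(tin)
    for (i in seq_len(nrow(tin))) {
      dd <- sqrt((meas$x - tin$x[i])^2 + (meas$y - tin$y[i])^2 +
                   (meas$z - tin$z[i])^2)
      j <- which.min(dd)
      if (length(j) && dd[j] < 0.3 && !meas$excluded[j]) {
        det <- det + 1
        errs <- c(errs, abs(meas$distance[j] - tin$distance[i]))
      }
    }
  }
  expect_gte(det / tot, 0.9)
  expect_lte(mean(errs), max(cfg$voxel_size))
})
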