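test_that("center of mass is the unweighted foreground centroid", {
  ann <- annulus_mask_ref(128, c(64, 64), 12, 20)
  expect_equal(unname(center_of_mass(ann)), c(64, 64), tolerance = 0.01)
  shifted <- matrix(0L, 128, 128)
  shifted[which(ann == 1L, arr.ind = TRUE) + rep(c(3L, 4L), each = sum(ann))] <- 1L
  expect_equal(unname(center_of_mass(shifted)), c(67, 68), tolerance = 0.01)
  single <- matrix(0L, 32, 32); single[10, 20] <- 1L
  expect_equal(unname(center_of_mass(single)), c(10, 20))
  expect_error(center_of_mass(matrix(0L, 8, 8)), "empty")
})

test_that("ray boundaries find the annulus wall at every angle", {
  ann <- annulus_mask_ref(128, c(64.5, 64.5), 20, 30)
  for (ang in c(0, 45, 90, 133, 218, 301)) {
    rb <- ray_boundaries(ann, c(64.5, 64.5), ang)
    expect_false(is.null(rb))
    expect_equal(unname(rb[1]), 20, tolerance = 0.5)
    expect_equal(unname(rb[2]), 30, tolerance = 0.5)
  }
})

test_that("rays take the innermost run and flag gaps invalid", {
  ann <- annulus_mask_ref(128, c(64.5, 64.5), 20, 30)
  # noise speck beyond the epicardium on the 0-degree ray
  speck <- ann; speck[64:65, 105:106] <- 1L
  rb <- ray_boundaries(speck, c(64.5, 64.5), 0)
  expect_equal(unname(rb[1]), 20, tolerance = 0.5)
  expect_equal(unname(rb[2]), 30, tolerance = 0.5)
  # C-shape: ray through the gap is invalid
  cs <- render_stack(make_phantom(shape = "c_shape", grid_size = 128,
                                  r_endo = 20, r_epi = 30))$truth$myo_mask
  org <- c(64.5, 64.5)
  expect_null(ray_boundaries(cs, org, 0))       # gap centered on +x axis
  expect_false(is.null(ray_boundaries(cs, org, 180)))
})

test_that("polar transform has the standard dimensions and samples correctly", {
  ann <- annulus_mask_ref(128, c(64.5, 64.5), 20, 30)
  img <- matrix(7.5, 128, 128)
  p <- to_polar(img, ann)
  expect_equal(dim(p$values), c(20, 360))
  expect_equal(p$C, 20)
  expect_true(all(p$valid))
  expect_true(all(abs(p$values - 7.5) < 1e-9))
  # radial-distance field: each column is a linear ramp endo -> epi
  rr <- sqrt((row(img) - 64.5)^2 + (col(img) - 64.5)^2)
  pr <- to_polar(rr, ann)
  for (j in c(1, 91, 200)) {
    expected <- seq(pr$endo_radius[j], pr$epi_radius[j], length.out = 20)
    expect_equal(pr$values[, j], expected, tolerance = 0.1)
  }
})

test_that("polar resampling is invariant to global translation", {
  # the implicit motion-correction property: same annulus, shifted, gives the
  # same polar image up to interpolation error
  grid <- 128
  img_field <- function(ctr) {
    rr <- sqrt((row(matrix(0, grid, grid)) - ctr[1])^2 +
                 (col(matrix(0, grid, grid)) - ctr[2])^2)
    cos(rr / 4) + 0.5 * rr / 30
  }
  c1 <- c(64.5, 64.5); c2 <- c1 + c(4, -3)
  m1 <- annulus_mask_ref(grid, c1, 20, 30)
  m2 <- annulus_mask_ref(grid, c2, 20, 30)
  p1 <- to_polar(img_field(c1), m1)
  p2 <- to_polar(img_field(c2), m2)
  rel_rms <- sqrt(mean((p1$values - p2$values)^2)) /
    sqrt(mean(p1$values^2))
  expect_lt(rel_rms, 0.01)
})

test_that("inverse transform reproduces smooth fields within 2%", {
  grid <- 128
  ann <- annulus_mask_ref(grid, c(64.5, 64.5), 20, 30)
  rr <- sqrt((row(matrix(0, grid, grid)) - 64.5)^2 +
               (col(matrix(0, grid, grid)) - 64.5)^2)
  field <- 1000 + 40 * (rr - 20)            # smooth radial T1 gradient, ms
  p <- to_polar(field, ann)
  back <- from_polar(p$values, ann)
  sel <- back$support == 1L
  expect_gt(sum(sel), 0.9 * sum(ann))
  err <- abs(back$values[sel] - field[sel])
  expect_lt(max(err) / diff(range(field[ann == 1L])), 0.02)
  # constant map stays constant
  const <- matrix(1100, 20, 360)
  bc <- from_polar(const, ann)
  expect_true(all(abs(bc$values[bc$support == 1L] - 1100) < 1e-6))
})

test_that("angular interpolation wraps across the 0/360 seam", {
  ann <- annulus_mask_ref(128, c(64.5, 64.5), 20, 30)
  # polar map linear in angle with a wrap-consistent profile
  pm <- matrix(rep(cos(seq(0, 359) * pi / 180), each = 20), 20, 360)
  back <- from_polar(pm, ann)
  idx <- which(back$support == 1L, arr.ind = TRUE)
  ang <- atan2(-(idx[, 1] - 64.5), idx[, 2] - 64.5) * 180 / pi
  near_seam <- which(abs(((ang + 180) %% 360) - 180) < 2)
  expect_gt(length(near_seam), 0)
  vals <- back$values[back$support == 1L][near_seam]
  expect_true(all(abs(vals - cos(ang[near_seam] * pi / 180)) < 0.01))
})
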