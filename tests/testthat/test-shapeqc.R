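test_that("area filter removes sub-5cm2 objects and keeps the largest", {
  m <- matrix(0L, 64, 64)
  m[10:29, 10:24] <- 1L                     # 300 px = 1323 mm2 at 2.1 mm
  m[45:54, 45:49] <- 1L                     # 50 px = 220.5 mm2 < 500 mm2
  out <- area_filter(m, pixel_spacing = 2.1)
  expect_equal(sum(out), 300)
  expect_true(all(out[10:29, 10:24] == 1L))
  expect_true(all(out[45:54, 45:49] == 0L))
  # idempotence
  expect_identical(area_filter(out, 2.1), out)
  # large single annulus untouched
  ann <- annulus_mask_ref(96, c(48, 48), 14, 24)
  expect_identical(area_filter(ann, 2.1), ann)
  # everything below threshold -> empty
  tiny <- matrix(0L, 64, 64); tiny[1:5, 1:5] <- 1L
  expect_equal(sum(area_filter(tiny, 2.1)), 0)
})

test_that("Euler number counts components minus holes (8-connected)", {
  expect_identical(euler_number(disk_mask(64, c(32, 32), 12)), 1L)
  expect_identical(euler_number(annulus_mask_ref(64, c(32, 32), 8, 14)), 0L)
  two_holes <- disk_mask(64, c(32, 32), 15)
  two_holes[28:30, 25:27] <- 0L
  two_holes[34:36, 36:38] <- 0L
  expect_identical(euler_number(two_holes), -1L)
  expect_identical(euler_number(matrix(0L, 8, 8)), 0L)
  # diagonal foreground chain is one 8-connected object
  diag2 <- matrix(0L, 8, 8); diag2[cbind(2:6, 2:6)] <- 1L
  expect_identical(euler_number(diag2), 1L)
})

test_that("Euler number holds over random disk/annulus geometry", {
  set.seed(42)
  for (i in 1:20) {
    r1 <- sample(3:10, 1); r2 <- r1 + sample(3:8, 1)
    ctr <- c(sample(25:40, 1), sample(25:40, 1))
    expect_identical(euler_number(disk_mask(64, ctr, r2)), 1L)
    expect_identical(euler_number(annulus_mask_ref(64, ctr, r1, r2)), 0L)
  }
})

test_that("eccentricity matches the analytic moment ellipse", {
  expect_lt(eccentricity(disk_mask(96, c(48, 48), 25)), 0.05)
  seg <- matrix(0L, 64, 64); seg[32, 10:54] <- 1L
  expect_gt(eccentricity(seg), 0.99)
  # semi-axes a = 2b -> sqrt(1 - 1/4) = sqrt(3)/2
  ell <- ellipse_mask(128, c(64, 64), 40, 20)
  expect_equal(eccentricity(ell), sqrt(3) / 2, tolerance = 0.01)
  expect_error(eccentricity(matrix(0L, 8, 8)), "empty")
})

test_that("eccentricity agrees with an independent moments implementation", {
  # oracle: EBImage regionprops-style moments
  set.seed(7)
  for (i in 1:5) {
    a <- sample(20:40, 1); b <- sample(10:19, 1)
    m <- ellipse_mask(128, c(64, 64), a, b)
    mom <- EBImage::computeFeatures.moment(m)
    expect_equal(eccentricity(m), unname(mom[1, "m.eccentricity"]),
                 tolerance = 0.02)
  }
})

test_that("shape verdicts implement the annulus rule", {
  ann <- annulus_mask_ref(96, c(48, 48), 14, 24)
  v <- assess_shape(ann)
  expect_true(v$proper)
  expect_identical(v$reason, "ok")
  vd <- assess_shape(disk_mask(96, c(48, 48), 20))
  expect_false(vd$proper)
  expect_identical(vd$reason, "bad_euler")
  # elliptical annulus elongated past the 0.65 limit
  ell_ann <- matrix(as.integer(ellipse_mask(160, c(80, 80), 60, 18) == 1L &
                                 ellipse_mask(160, c(80, 80), 45, 10) == 0L),
                    160, 160)
  expect_identical(euler_number(ell_ann), 0L)
  ve <- assess_shape(ell_ann)
  expect_gt(ve$eccentricity, 0.65)
  expect_false(ve$proper)
  expect_identical(ve$reason, "bad_eccentricity")
  vempty <- assess_shape(matrix(0L, 16, 16))
  expect_false(vempty$proper)
  expect_identical(vempty$reason, "empty")
})

test_that("refinement recovers known affine perturbations with high Dice", {
  m <- annulus_mask_ref(96, c(48.5, 48.5), 14, 24)
  cases <- list(c(5, -3, 0, 1), c(-10, 4, 15, 0.92), c(2, 3, -9, 1.08),
                c(10, 10, -15, 1.1))
  for (cs in cases) {
    mk <- cardiot1:::transform_mask(m, cs[1], cs[2], cs[3], cs[4])
    r <- refine(mk, m)
    expect_true(r$applied)
    expect_gte(dice(r$mask, mk), 0.95)
  }
  # pure translation recovered within a pixel
  mk <- cardiot1:::transform_mask(m, 5, -3, 0, 1)
  r <- refine(mk, m)
  expect_lte(max(abs(r$transform[c("dy", "dx")] - c(5, -3))), 1)
})

test_that("refinement respects the exclusion rule and identity fixed point", {
  m <- annulus_mask_ref(96, c(48, 48), 14, 24)
  # improper reference (disk): no refinement possible
  r <- refine(m, disk_mask(96, c(48, 48), 20))
  expect_false(r$applied)
  # identity: mask_k equals mask_inf
  r2 <- refine(m, m)
  expect_true(r2$applied)
  expect_equal(r2$overlap, 1)
  expect_identical(r2$mask, m)
  # refinement never does worse than the untransformed reference mask
  set.seed(3)
  for (i in 1:5) {
    mk <- cardiot1:::transform_mask(m, sample(-8:8, 1), sample(-8:8, 1),
                                    stats::runif(1, -12, 12),
                                    stats::runif(1, 0.92, 1.08))
    r <- refine(mk, m)
    expect_gte(r$overlap, dice(m, mk))
  }
  # both masks empty -> exclusion
  r3 <- refine(matrix(0L, 32, 32), matrix(0L, 32, 32))
  expect_false(r3$applied)
})
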