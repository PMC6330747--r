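test_that("noiseless signals are fitted to sub-ms accuracy", {
  tis <- make_ti_schedule(1000)
  for (t1_true in c(400, 850, 1000, 1250, 1500)) {
    f <- fit_pixel(ir_signal(t1_true, 1, tis), tis)
    expect_true(f$converged)
    expect_lt(abs(f$t1 - t1_true), 0.5)
    expect_lt(abs(f$amplitude - 1), 1e-3)
    expect_lt(f$residual, 1e-6)
  }
})

test_that("noisy fits match a dense grid-search oracle", {
  # oracle: exhaustive 2-D grid over (T1, A) at 1 ms x 0.001 resolution,
  # entirely independent of the profiled fitter
  grid_oracle <- function(y, tis) {
    t1s <- seq(900, 1100, by = 1)
    As <- seq(0.9, 1.1, by = 0.001)
    F <- outer(tis, t1s, function(ti, t1) abs(1 - 2 * exp(-ti / t1)))
    best <- c(Inf, NA, NA)
    for (ai in seq_along(As)) {
      rss <- colSums((y - As[ai] * F)^2)
      i <- which.min(rss)
      if (rss[i] < best[1]) best <- c(rss[i], t1s[i], As[ai])
    }
    best[2]
  }
  tis <- make_ti_schedule(1000)
  clean <- ir_signal(1000, 1, tis)
  set.seed(101)
  err_fit <- err_oracle <- numeric(60)
  for (i in 1:60) {
    y <- abs(clean + rnorm(11, 0, 0.02))
    err_fit[i] <- fit_pixel(y, tis)$t1 - 1000
    err_oracle[i] <- grid_oracle(y, tis) - 1000
  }
  expect_lt(abs(mean(abs(err_fit)) - mean(abs(err_oracle))), 1)
  expect_lt(mean(abs(err_fit)), 15)       # SNR 50: errors of a few ms
})

test_that("fit enforces the minimum-data rule and degenerate input", {
  tis <- make_ti_schedule(1000)
  y <- ir_signal(1000, 1, tis)
  expect_error(fit_pixel(y[1:7], tis[1:7]), "insufficient")
  expect_silent(fit_pixel(y[1:8], tis[1:8]))
  f0 <- fit_pixel(rep(0, 11), tis)
  expect_false(f0$converged)
})

test_that("map reconstruction fits every valid polar cell", {
  st <- render_stack(make_phantom(grid_size = 96, r_endo = 14, r_epi = 22))
  ps <- lapply(1:11, function(k) to_polar(st$images[, , k],
                                          st$truth$masks[[k]]))
  pm <- reconstruct_map(ps, st$tis)
  expect_equal(dim(pm$values), c(20, 360))
  expect_gte(mean(pm$valid), 0.99)
  expect_lt(median(abs(pm$values - 1100), na.rm = TRUE), 5)
  expect_equal(pm$n_images_used, 11)
})

test_that("slice gate rejects stacks with fewer than 8 usable images", {
  st <- render_stack(make_phantom())
  ps <- lapply(1:11, function(k) to_polar(st$images[, , k],
                                          st$truth$masks[[k]]))
  expect_error(reconstruct_map(ps[1:7], st$tis[1:7]),
               class = "cardiot1_slice_rejected")
  expect_silent(reconstruct_map(ps[1:8], st$tis[1:8]))
})

test_that("cells keep fitting when single rays drop out", {
  st <- render_stack(make_phantom())
  ps <- lapply(1:11, function(k) to_polar(st$images[, , k],
                                          st$truth$masks[[k]]))
  # invalidate ray 90 in one image only: cell still has 10 observations
  ps[[3]]$valid[90] <- FALSE
  pm <- reconstruct_map(ps, st$tis)
  expect_true(all(pm$valid[, 90]))
  # median over the column: the outermost cells sit on the wall boundary and
  # carry partial-volume error regardless of how many TIs contribute
  expect_lt(median(abs(pm$values[, 90] - 1100)), 5)
  # invalidate the same ray in 4 images: below the 8-observation floor
  for (k in 1:4) ps[[k]]$valid[90] <- FALSE
  pm2 <- reconstruct_map(ps, st$tis)
  expect_false(any(pm2$valid[, 90]))
})

test_that("mean wall thickness averages the per-ray radial extent", {
  ann <- annulus_mask_ref(128, c(64.5, 64.5), 20, 30)
  p <- to_polar(matrix(0, 128, 128), ann)
  expect_equal(mean_wall_thickness(p), 10, tolerance = 0.5)
  one <- list(endo_radius = 5, epi_radius = 12, valid = TRUE)
  expect_equal(mean_wall_thickness(one), 7)
  none <- list(endo_radius = numeric(0), epi_radius = numeric(0),
               valid = logical(0))
  expect_error(mean_wall_thickness(none), "valid rays")
})

test_that("pruning keeps a mid-wall band one-third of wall thickness", {
  ann <- annulus_mask_ref(128, c(64.5, 64.5), 20, 32)   # thickness 12
  pr <- prune_mask(ann)
  expect_true(all(pr[ann == 0L] == 0L))                 # subset
  expect_lt(sum(pr), sum(ann))
  rr <- sqrt((row(ann) - 64.5)^2 + (col(ann) - 64.5)^2)
  radii <- rr[pr == 1L]
  expect_equal(mean(radii), 26, tolerance = 1)          # mid-wall
  expect_lte(diff(range(radii)), 6)                     # ~1/3 of 12, + grid
  # thin wall: band collapses to the skeleton
  thin <- annulus_mask_ref(64, c(32.5, 32.5), 10, 12)
  prt <- prune_mask(thin)
  expect_true(all(prt[thin == 0L] == 0L))
  expect_lt(sum(prt), sum(thin))
})

test_that("pruned band is a strict subset over random phantom geometry", {
  set.seed(5)
  for (i in 1:5) {
    r1 <- sample(10:16, 1); r2 <- r1 + sample(6:12, 1)
    ann <- annulus_mask_ref(96, c(48.5, 48.5), r1, r2)
    pr <- prune_mask(ann)
    expect_true(all(pr <= ann))
    expect_lt(sum(pr), sum(ann))
    expect_gt(sum(pr), 0)
  }
})

test_that("T1 summary applies the 850-1500 ms acceptance window", {
  mk_map <- function(vals) {
    v <- matrix(NA_real_, 4, 4)
    v[1, seq_along(vals)] <- vals
    m <- matrix(0L, 4, 4); m[1, seq_along(vals)] <- 1L
    list(structure(list(values = v, support = m), class = "cartesian_t1_map"),
         m)
  }
  mm <- mk_map(c(900, 1000, 1600))
  s <- summarize_t1(list(mm[[1]]), list(mm[[2]]))
  expect_equal(s$global_t1, 950)
  expect_equal(s$n_pixels_used, 2L)
  expect_equal(s$n_pixels_excluded, 1L)
  # endpoints are inclusive
  mm2 <- mk_map(c(850, 1500))
  expect_equal(summarize_t1(list(mm2[[1]]), list(mm2[[2]]))$global_t1, 1175)
  # constant maps
  mm3 <- mk_map(c(1100, 1100, 1100))
  s3 <- summarize_t1(list(mm3[[1]], mm3[[1]]), list(mm3[[2]], mm3[[2]]))
  expect_equal(s3$global_t1, 1100)
  expect_equal(s3$regional_t1, c(1100, 1100))
  # one slice entirely out of range: NA with warning, other unaffected
  mm4 <- mk_map(c(2000, 2000))
  expect_warning(s4 <- summarize_t1(list(mm3[[1]], mm4[[1]]),
                                    list(mm3[[2]], mm4[[2]])), "slice 2")
  expect_equal(s4$regional_t1, c(1100, NA))
  expect_equal(s4$global_t1, 1100)
})

test_that("T1 error grows monotonically with noise (replicate-averaged)", {
  tis <- make_ti_schedule(1000)
  clean <- ir_signal(1100, 1, tis)
  set.seed(77)
  med_err <- vapply(c(0.01, 0.04, 0.12), function(sd) {
    median(vapply(1:20, function(i) {
      abs(fit_pixel(abs(clean + rnorm(11, 0, sd)), tis)$t1 - 1100)
    }, 0))
  }, 0)
  expect_true(all(diff(med_err) >= 0))
})
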