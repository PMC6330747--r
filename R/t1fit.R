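# Model basis |1 - 2 exp(-TI/T1)| evaluated for a TI vector at a grid of T1
# values; TI = Inf rows are exactly 1 (full recovery).
.ir_basis <- function(tis, t1s) {
  outer(tis, t1s, function(ti, t1) abs(1 - 2 * exp(-ti / t1)))
}

# Profiled residual sum of squares: for fixed T1 the model A * f(TI) is linear
# in A with closed-form optimum A = sum(y f) / sum(f^2), so the 2-parameter
# fit reduces to a 1-D search over T1.
.profiled_rss <- function(signals, tis, t1) {
  f <- abs(1 - 2 * exp(-tis / t1))
  den <- sum(f^2)
  if (den == 0) return(sum(signals^2))
  sum(signals^2) - sum(signals * f)^2 / den
}

#' Pixel-wise two-parameter inversion-recovery fit
#'
#' Least-squares fit of the magnitude inversion-recovery model
#' `A |1 - 2 exp(-TI/T1)|` to one pixel's intensities over the TI schedule.
#' For fixed T1 the amplitude has a closed-form optimum, so the fit is a
#' profiled 1-D search over T1: a log-spaced grid over `t1_range` (dense
#' enough to bracket every null-point local minimum of the magnitude model)
#' followed by golden-section refinement of the best bracket. The TI = Inf
#' sample enters the residual analytically as `signal - A`.
#'
#' @param signals Numeric vector of pixel intensities, one per TI.
#' @param tis Inversion times in ms (`Inf` allowed), same length.
#' @param t1_range Search range for T1 in ms (default 100-3000).
#' @param min_points Minimum number of (signal, TI) pairs required (default 8,
#'   matching the slice-level reconstruction rule).
#' @return List of class `t1_fit`: `t1` (ms), `amplitude`, `residual` (RMS fit
#'   error), `converged`.
#' @examples
#' tis <- make_ti_schedule(1000)
#' fit_pixel(ir_signal(1000, 1, tis), tis)$t1
#' @export
fit_pixel <- function(signals, tis, t1_range = c(100, 3000), min_points = 8) {
  keep <- is.finite(signals) & !is.na(tis)
  signals <- signals[keep]; tis <- tis[keep]
  if (length(signals) != length(tis)) stop("signals and tis lengths differ")
  if (length(signals) < min_points) {
    stop(sprintf("insufficient data: %d pairs supplied, %d required",
                 length(signals), min_points))
  }
  if (all(signals == 0)) {
    return(structure(list(t1 = NA_real_, amplitude = 0, residual = 0,
                          converged = FALSE), class = "t1_fit"))
  }
  grid <- exp(seq(log(t1_range[1L]), log(t1_range[2L]), length.out = 80))
  rss <- vapply(grid, function(t1) .profiled_rss(signals, tis, t1), 0)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(t1) .profiled_rss(signals, tis, t1),
                         c(lo, hi), tol = 1e-4)
  t1 <- opt$minimum
  f <- abs(1 - 2 * exp(-tis / t1))
  A <- sum(signals * f) / sum(f^2)
  res <- sqrt(mean((signals - A * f)^2))
  structure(list(t1 = t1, amplitude = A, residual = res,
                 converged = A > 0 && t1 > t1_range[1L] * 1.001 &&
                   t1 < t1_range[2L] * 0.999),
            class = "t1_fit")
}

#' Reconstruct a polar T1 map from a stack of polar images
#'
#' Fits the two-parameter inversion-recovery model at every cell of the
#' `C x n_rays` polar grid, using for each cell only the TIs whose image was
#' successfully segmented and whose ray is valid. A slice is reconstructed
#' only when at least `min_images` successfully segmented T1-weighted images
#' are available (the acquisition yields 11); the same threshold is applied
#' per cell as a conservative extension, and cells with fewer valid
#' observations or non-converged fits are marked invalid rather than fatal.
#'
#' @param polar_stack List of [to_polar()] results, one per usable TI.
#' @param tis Inversion times (ms, `Inf` allowed) matching `polar_stack`.
#' @param min_images Minimum usable images per slice and observations per
#'   cell (default 8).
#' @param t1_range T1 search range in ms.
#' @return Object of class `polar_t1_map`: `values` (`C x n_rays`, ms, NA
#'   where invalid), `valid`, `n_images_used`, `endo_radius`, `epi_radius`
#'   (per-ray medians over the stack, px).
#' @section Slice rejection: if fewer than `min_images` polar images are
#'   supplied the slice cannot be reconstructed and an error of class
#'   `cardiot1_slice_rejected` is signaled (distinct from per-cell
#'   invalidity).
#' @export
reconstruct_map <- function(polar_stack, tis, min_images = 8,
                            t1_range = c(100, 3000)) {
  stopifnot(length(polar_stack) == length(tis))
  if (length(polar_stack) < min_images) {
    stop(structure(class = c("cardiot1_slice_rejected", "error", "condition"),
                   list(message = sprintf(
                     "slice rejected: %d successfully segmented images, %d required",
                     length(polar_stack), min_images), call = sys.call())))
  }
  C <- polar_stack[[1L]]$C
  n_rays <- length(polar_stack[[1L]]$angles)
  for (p in polar_stack) stopifnot(p$C == C, length(p$angles) == n_rays)
  values <- matrix(NA_real_, C, n_rays)
  valid <- matrix(FALSE, C, n_rays)
  grid <- exp(seq(log(t1_range[1L]), log(t1_range[2L]), length.out = 80))
  for (j in seq_len(n_rays)) {
    use <- vapply(polar_stack, function(p) p$valid[j], TRUE)
    if (sum(use) < min_images) next
    tis_j <- tis[use]
    Y <- vapply(polar_stack[use], function(p) p$values[, j], numeric(C))
    # vectorized coarse profile over the T1 grid for all C cells of this ray
    F <- .ir_basis(tis_j, grid)                       # n_use x 80
    den <- colSums(F^2)
    num <- Y %*% F                                    # C x 80
    rss <- rowSums(Y^2) - sweep(num^2, 2, den, "/")
    for (m in seq_len(C)) {
      y <- Y[m, ]
      if (all(y == 0) || !all(is.finite(y))) next
      i <- which.min(rss[m, ])
      lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
      opt <- stats::optimize(function(t1) .profiled_rss(y, tis_j, t1),
                             c(lo, hi), tol = 1e-4)
      t1 <- opt$minimum
      if (t1 > t1_range[1L] * 1.001 && t1 < t1_range[2L] * 0.999) {
        values[m, j] <- t1
        valid[m, j] <- TRUE
      }
    }
  }
  endo <- apply(vapply(polar_stack, function(p) p$endo_radius,
                       numeric(n_rays)), 1, stats::median, na.rm = TRUE)
  epi <- apply(vapply(polar_stack, function(p) p$epi_radius,
                      numeric(n_rays)), 1, stats::median, na.rm = TRUE)
  structure(list(values = values, valid = valid,
                 n_images_used = length(polar_stack),
                 endo_radius = endo, epi_radius = epi, C = C),
            class = "polar_t1_map")
}

#' Mean myocardium wall thickness from polar geometry
#'
#' @param polar A [to_polar()] result (or any object with per-ray
#'   `endo_radius`, `epi_radius` and `valid`).
#' @return Mean over valid rays of `epi_radius - endo_radius`, in pixels.
#' @export
mean_wall_thickness <- function(polar) {
  v <- which(if (is.logical(polar$valid)) polar$valid else
    is.finite(polar$endo_radius))
  if (length(v) == 0L) stop("no valid rays: wall thickness undefined")
  mean(polar$epi_radius[v] - polar$endo_radius[v])
}

#' Prune sub-endocardial and sub-epicardial border pixels
#'
#' Mimics the manual practice of excluding the blood- and fat-adjacent border
#' of the wall from T1 averaging: the 1-pixel-wide skeleton (central contour)
#' of the segmented annulus is extracted and dilated with a disc so the
#' retained band's full width is `fraction` (default one-third) of the mean
#' wall thickness. The band is intersected with the input mask, so the output
#' is always a subset of it. A wall 3 px thick or thinner keeps just the
#' skeleton.
#'
#' @param mask Proper (annular) binary myocardium mask.
#' @param wall_thickness Mean wall thickness in pixels (e.g. from
#'   [mean_wall_thickness()]); estimated from the mask's own polar geometry
#'   when omitted.
#' @param fraction Retained fraction of the wall thickness (default 1/3;
#'   configurable, as the choice is conventional rather than principled).
#' @return Binary matrix, subset of `mask`.
#' @export
prune_mask <- function(mask, wall_thickness = NULL, fraction = 1 / 3) {
  stopifnot(any(mask != 0))
  if (is.null(wall_thickness)) {
    geom <- to_polar(matrix(0, nrow(mask), ncol(mask)), mask, C = 2)
    wall_thickness <- mean_wall_thickness(geom)
  }
  skel <- skeletonize(mask)
  lab <- label8(skel)
  if (max(lab) > 1L) {
    warning("skeleton disconnected; keeping largest fragment")
    sizes <- tabulate(lab[lab > 0L])
    skel <- matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
  }
  radius <- round(wall_thickness * fraction / 2)
  band <- dilate_disc(skel, radius)
  matrix(as.integer(band == 1L & mask != 0), nrow(mask), ncol(mask))
}

#' Global and regional T1 summary
#'
#' Averages the reconstructed T1 values over the pruned myocardium of each
#' slice (regional T1) and over all slices (global T1). Pixels with T1
#' outside the physiological acceptance range for native myocardium at 1.5 T
#' (850-1500 ms, endpoints included) are excluded from the averages. A slice
#' in which no pixel survives gets a regional value of NA with a warning;
#' other slices are unaffected.
#'
#' @param maps List of [from_polar()] results (class `cartesian_t1_map`),
#'   one per reconstructed slice.
#' @param pruned_masks List of pruned binary masks, same length and grids.
#' @param accept_range Inclusive T1 acceptance range in ms (default
#'   `c(850, 1500)`).
#' @return List of class `t1_summary`: `global_t1` (ms), `regional_t1`
#'   (per-slice ms, NA where undefined), `n_pixels_used`,
#'   `n_pixels_excluded`.
#' @examples
#' # pixels {900, 1000, 1600}: 1600 falls outside 850-1500 -> mean 950
#' @export
summarize_t1 <- function(maps, pruned_masks, accept_range = c(850, 1500)) {
  stopifnot(length(maps) >= 1L, length(maps) == length(pruned_masks))
  regional <- rep(NA_real_, length(maps))
  used <- excluded <- integer(length(maps))
  all_vals <- numeric(0)
  for (s in seq_along(maps)) {
    vals <- maps[[s]]$values[pruned_masks[[s]] != 0]
    vals <- vals[is.finite(vals)]
    keep <- vals >= accept_range[1L] & vals <= accept_range[2L]
    used[s] <- sum(keep)
    excluded[s] <- sum(!keep)
    if (used[s] == 0L) {
      warning(sprintf("slice %d: no pixels within the acceptance range", s))
      next
    }
    regional[s] <- mean(vals[keep])
    all_vals <- c(all_vals, vals[keep])
  }
  if (length(all_vals) == 0L) stop("no slice has pixels within the acceptance range")
  structure(list(global_t1 = mean(all_vals), regional_t1 = regional,
                 n_pixels_used = used, n_pixels_excluded = excluded),
            class = "t1_summary")
}

#' @export
print.t1_summary <- function(x, ...) {
  cat(sprintf("t1_summary: global T1 = %.1f ms over %d slices (%d px used, %d excluded)\n",
              x$global_t1, length(x$regional_t1), sum(x$n_pixels_used),
              sum(x$n_pixels_excluded)))
  for (s in seq_along(x$regional_t1)) {
    cat(sprintf("  slice %d: %s ms (n=%d)\n", s,
                ifelse(is.na(x$regional_t1[s]), "NA",
                       sprintf("%.1f", x$regional_t1[s])), x$n_pixels_used[s]))
  }
  invisible(x)
}
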