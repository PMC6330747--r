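#' Center of mass of a binary mask
#'
#' Unweighted centroid of the foreground pixel coordinates. Placing the polar
#' origin here for every T1-weighted image is what gives the polar transform
#' its implicit correction of global translational heart motion.
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return Numeric `c(row, col)` with subpixel precision.
#' @export
center_of_mass <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("center of mass of an empty mask is undefined")
  c(row = mean(idx[, 1L]), col = mean(idx[, 2L]))
}

# Radial profile of a mask along one ray; returns the innermost contiguous
# foreground run as (endo, epi) radii in pixels, or NULL if the ray never
# crosses the mask. `step` is the radial sampling step in pixels.
.ray_run <- function(mask, origin, angle_deg, step = 0.25) {
  nr <- nrow(mask); nc <- ncol(mask)
  th <- angle_deg * pi / 180
  drow <- -sin(th); dcol <- cos(th)
  rmax <- sqrt(nr^2 + nc^2)
  rs <- seq(0, rmax, by = step)
  rows <- origin[1L] + rs * drow
  cols <- origin[2L] + rs * dcol
  inside <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  rs <- rs[inside]
  if (length(rs) == 0L) return(NULL)
  v <- bilinear_sample(mask, origin[1L] + rs * drow, origin[2L] + rs * dcol) >= 0.5
  if (!any(v)) return(NULL)
  d <- diff(c(FALSE, v, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  c(endo = rs[starts[1L]], epi = rs[ends[1L]])
}

#' Endocardial and epicardial radii along one ray
#'
#' Walks a ray from the polar origin outward and returns the radii of the
#' first and last sample of the innermost contiguous myocardium run (the ring
#' nearest the cavity; detached specks further out are ignored). Rays that
#' never cross the mask - e.g. through the gap of a broken annulus - are
#' invalid.
#'
#' @param mask Binary myocardium mask.
#' @param origin Polar origin `c(row, col)`, typically [center_of_mass()].
#' @param angle Ray angle in degrees, counter-clockwise from the +x (column)
#'   axis of the displayed image.
#' @return Named numeric `c(endo, epi)` in pixels, or `NULL` if invalid.
#' @export
ray_boundaries <- function(mask, origin, angle) {
  .ray_run(mask, origin, angle)
}

#' Polar resampling of the segmented myocardium
#'
#' Resamples the myocardium intensities of one T1-weighted image onto a
#' uniform `C x n_rays` polar grid centered at the center-of-mass of its own
#' segmentation: `n_rays` rays at 1 degree spacing, and along each ray `C`
#' samples uniformly spaced in radius from the endocardial to the epicardial
#' boundary (both endpoints included), with bilinear interpolation of the
#' image. `C = 20` exceeds the maximum expected wall thickness (15 px) so the
#' transform loses no data. Because each image is resampled about its own mask
#' centroid and normalized per-ray to its own wall, the polar images of all
#' TIs are mutually aligned without explicit registration.
#'
#' @param image Intensity matrix.
#' @param mask Binary myocardium mask on the same grid (should have passed
#'   shape QC).
#' @param C Samples per ray (default 20).
#' @param n_rays Number of rays (default 360).
#' @param origin Optional polar origin override `c(row, col)`.
#' @return Object of class `polar_image`: `values` (`C x n_rays` matrix, NA on
#'   invalid rays), `origin`, `endo_radius`, `epi_radius` (per-ray, px),
#'   `valid` (per-ray logical), `C`, `angles` (degrees).
#' @export
to_polar <- function(image, mask, C = 20, n_rays = 360, origin = NULL) {
  if (!any(mask != 0)) stop("cannot polar-transform an empty mask")
  stopifnot(all(dim(image) == dim(mask)), C >= 2, n_rays >= 4)
  if (is.null(origin)) origin <- center_of_mass(mask)
  angles <- seq(0, 360 - 360 / n_rays, by = 360 / n_rays)
  values <- matrix(NA_real_, C, n_rays)
  endo <- epi <- rep(NA_real_, n_rays)
  valid <- rep(FALSE, n_rays)
  frac <- seq(0, 1, length.out = C)
  for (j in seq_len(n_rays)) {
    run <- .ray_run(mask, origin, angles[j])
    if (is.null(run)) next
    endo[j] <- run[1L]; epi[j] <- run[2L]; valid[j] <- TRUE
    rs <- run[1L] + frac * (run[2L] - run[1L])
    th <- angles[j] * pi / 180
    values[, j] <- bilinear_sample(image, origin[1L] - rs * sin(th),
                                   origin[2L] + rs * cos(th))
  }
  structure(list(values = values, origin = origin, endo_radius = endo,
                 epi_radius = epi, valid = valid, C = C, angles = angles),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("polar_image: %d x %d, %d/%d valid rays, origin (%.1f, %.1f)\n",
              x$C, length(x$angles), sum(x$valid), length(x$valid),
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

# Periodic linear interpolation of a per-ray quantity at arbitrary angles
# (degrees); v has one entry per ray at 360/n spacing, NAs on invalid rays.
.interp_ray <- function(v, angle_deg) {
  n <- length(v)
  step <- 360 / n
  pos <- (angle_deg %% 360) / step
  i0 <- floor(pos) %% n
  f <- pos - floor(pos)
  v[i0 + 1L] * (1 - f) + v[(i0 + 1L) %% n + 1L] * f
}

#' Inverse polar transform of a fitted T1 map
#'
#' Maps a `C x n_rays` polar T1 map back onto the Cartesian grid of a
#' reference segmentation (by convention the mask of the shortest-TI image).
#' Each foreground pixel of the reference mask is assigned the bilinear
#' interpolation of the polar map at its (normalized radial position, angle);
#' angle interpolation wraps across the 359->0 degree seam. Pixels whose
#' angle falls on invalid rays, or whose radius lies outside the reference
#' wall, are dropped from the support.
#'
#' @param polar_map `C x n_rays` numeric matrix of fitted T1 values (ms), NA
#'   where invalid; e.g. the `values` of a [reconstruct_map()] result.
#' @param reference_mask Binary mask defining the output support.
#' @param origin Polar origin used for the reference geometry; default the
#'   reference mask's center of mass.
#' @return List of class `cartesian_t1_map`: `values` (matrix, ms, NA outside
#'   support) and `support` (binary matrix).
#' @export
from_polar <- function(polar_map, reference_mask, origin = NULL) {
  if (!any(reference_mask != 0)) stop("empty reference mask")
  if (is.null(origin)) origin <- center_of_mass(reference_mask)
  C <- nrow(polar_map); n_rays <- ncol(polar_map)
  geom <- to_polar(matrix(0, nrow(reference_mask), ncol(reference_mask)),
                   reference_mask, C = 2, n_rays = n_rays, origin = origin)
  idx <- which(reference_mask != 0, arr.ind = TRUE)
  dy <- idx[, 1L] - origin[1L]
  dx <- idx[, 2L] - origin[2L]
  r <- sqrt(dy^2 + dx^2)
  ang <- (atan2(-dy, dx) * 180 / pi) %% 360
  endo <- .interp_ray(geom$endo_radius, ang)
  epi <- .interp_ray(geom$epi_radius, ang)
  mfrac <- (r - endo) / pmax(epi - endo, .Machine$double.eps)
  ok <- is.finite(mfrac) & mfrac >= -0.05 & mfrac <= 1.05
  mfrac <- pmin(pmax(mfrac, 0), 1)
  # bilinear interpolation on the polar grid with angular wrap
  m <- mfrac * (C - 1)
  i0 <- pmin(floor(m), C - 2); fi <- m - i0
  step <- 360 / n_rays
  pos <- ang / step
  j0 <- floor(pos) %% n_rays; fj <- pos - floor(pos)
  j1 <- (j0 + 1) %% n_rays
  at <- function(i, j) polar_map[cbind(i + 1L, j + 1L)]
  vals <- at(i0, j0) * (1 - fi) * (1 - fj) + at(i0 + 1, j0) * fi * (1 - fj) +
    at(i0, j1) * (1 - fi) * fj + at(i0 + 1, j1) * fi * fj
  ok <- ok & is.finite(vals)
  out <- matrix(NA_real_, nrow(reference_mask), ncol(reference_mask))
  out[idx[ok, , drop = FALSE]] <- vals[ok]
  support <- matrix(0L, nrow(reference_mask), ncol(reference_mask))
  support[idx[ok, , drop = FALSE]] <- 1L
  structure(list(values = out, support = support, origin = origin),
            class = "cartesian_t1_map")
}
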