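#' Area filter for raw myocardium segmentations
#'
#' Removes every 8-connected component whose physical area is below 5 cm^2
#' (500 mm^2) and, of the survivors, keeps only the largest. This cleans up
#' the small spurious blobs a pixel classifier produces away from the heart.
#'
#' @param mask Binary matrix (0/1).
#' @param pixel_spacing In-plane pixel spacing in mm (default 2.1).
#' @param min_area_cm2 Area threshold in cm^2 (default 5); components with
#'   area strictly below it are removed.
#' @return Binary matrix with at most one connected component (possibly empty).
#' @export
area_filter <- function(mask, pixel_spacing = 2.1, min_area_cm2 = 5) {
  stopifnot(pixel_spacing > 0)
  lab <- label8(mask)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L])
  area_mm2 <- sizes * pixel_spacing^2
  keep <- which(area_mm2 >= min_area_cm2 * 100)
  if (length(keep) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  largest <- keep[which.max(sizes[keep])]
  matrix(as.integer(lab == largest), nrow(mask), ncol(mask))
}

#' Euler number of a binary region
#'
#' Connected components minus holes, with 8-connected foreground (and the dual
#' 4-connected background). A filled disk has Euler number 1; the annular
#' myocardium of a short-axis slice has exactly one hole (the blood pool) and
#' Euler number 0. Computed with the 2 x 2 quad-count formula, which is exact
#' for this connectivity convention.
#'
#' @param mask Binary matrix (0/1).
#' @return Integer Euler number (0 for an empty mask).
#' @export
euler_number <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  p <- rbind(0L, cbind(0L, m, 0L), 0L)
  nr <- nrow(p); nc <- ncol(p)
  a <- p[-nr, -nc]; b <- p[-nr, -1]; c <- p[-1, -nc]; d <- p[-1, -1]
  s <- a + b + c + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a == 1L & d == 1L) | (b == 1L & c == 1L)))
  as.integer((q1 - q3 - 2L * qd) / 4L)
}

#' Eccentricity of a binary region
#'
#' Eccentricity of the ellipse having the same normalized second central
#' moments as the foreground: 0 for a circle, approaching 1 for a line
#' segment. Used to flag elongated, non-cardiac segmentations.
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return Eccentricity in `[0, 1]`.
#' @export
eccentricity <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("eccentricity of an empty mask is undefined")
  y <- idx[, 1L] - mean(idx[, 1L])
  x <- idx[, 2L] - mean(idx[, 2L])
  # normalized second central moments (regionprops convention: + 1/12 for
  # the unit-square pixel footprint)
  uyy <- mean(y^2) + 1 / 12
  uxx <- mean(x^2) + 1 / 12
  uxy <- mean(x * y)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  sqrt(max(0, 1 - l2 / l1))
}

#' Shape plausibility verdict for a myocardium segmentation
#'
#' A segmented myocardium is anatomically plausible in a short-axis slice when
#' it is a single annulus: Euler number 0 and eccentricity at most
#' `ecc_max` (default 0.65, the maximum observed over manually segmented
#' training myocardia). Anything else is marked improper and becomes a
#' candidate for refinement.
#'
#' @param mask Binary matrix.
#' @param ecc_max Maximum allowed eccentricity (default 0.65).
#' @return List of class `shape_verdict`: `euler`, `eccentricity`, `proper`,
#'   and `reason` (one of `"ok"`, `"bad_euler"`, `"bad_eccentricity"`,
#'   `"empty"`).
#' @export
assess_shape <- function(mask, ecc_max = 0.65) {
  if (!any(mask != 0)) {
    return(structure(list(euler = 0L, eccentricity = NA_real_,
                          proper = FALSE, reason = "empty"),
                     class = "shape_verdict"))
  }
  eu <- euler_number(mask)
  ec <- eccentricity(mask)
  reason <- if (eu != 0L) "bad_euler" else if (ec > ecc_max) "bad_eccentricity" else "ok"
  structure(list(euler = eu, eccentricity = ec,
                 proper = reason == "ok", reason = reason),
            class = "shape_verdict")
}

#' @export
print.shape_verdict <- function(x, ...) {
  cat(sprintf("shape_verdict: euler=%d ecc=%.3f %s (%s)\n", x$euler,
              x$eccentricity, if (x$proper) "proper" else "improper",
              x$reason))
  invisible(x)
}

# Dice overlap used internally by the refinement objective (the public
# evaluation version lives in evalstats).
.dice_fast <- function(a, b) {
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Refine an improper segmentation against the longest-TI mask
#'
#' When the segmentation of a T1-weighted image fails the shape check, the
#' (reliable, high-contrast) mask from the infinite-TI image of the same slice
#' is affinely registered - translation, rotation and scaling - to maximize
#' Dice overlap with the improper mask, and the transformed copy replaces it.
#' If the longest-TI mask is itself improper no refinement is possible and the
#' image must be excluded from fitting.
#'
#' The search seeds translation at the centroid offset between the two masks,
#' sweeps a coarse grid (rotation +/- 15 deg step 3, scale 0.9-1.1 step 0.05,
#' local translation +/- 2 px), then hill-climbs with halved steps. The
#' identity transform is always kept as a candidate, so the refined overlap
#' never falls below that of the untransformed longest-TI mask.
#'
#' @param mask_k Improper binary segmentation to refine.
#' @param mask_inf Binary segmentation of the infinite-TI image.
#' @param max_rot Rotation search half-range in degrees.
#' @param scale_range Scale search range (length 2).
#' @return List of class `refinement_result`: `mask` (the refined mask),
#'   `transform` (`dy`, `dx`, `rot_deg`, `scale`), `overlap` (Dice between
#'   refined mask and `mask_k`), and `applied` (FALSE when `mask_inf` is
#'   improper or both masks are empty; the caller must then exclude the
#'   image).
#' @export
refine <- function(mask_k, mask_inf, max_rot = 15, scale_range = c(0.9, 1.1)) {
  no_refine <- function() {
    structure(list(mask = mask_k,
                   transform = c(dy = 0, dx = 0, rot_deg = 0, scale = 1),
                   overlap = NA_real_, applied = FALSE),
              class = "refinement_result")
  }
  if (!any(mask_inf != 0)) return(no_refine())
  if (!assess_shape(mask_inf)$proper) return(no_refine())
  if (!any(mask_k != 0)) {
    # nothing to align to; fall back to the reliable mask untransformed
    res <- no_refine(); res$mask <- mask_inf; res$applied <- TRUE
    res$overlap <- 0
    return(res)
  }
  # work on a cropped region around both masks for speed; coordinates are
  # offset back at the end (the transform parameters are crop-invariant)
  idx_all <- which(mask_k != 0 | mask_inf != 0, arr.ind = TRUE)
  pad <- 14L
  r0 <- max(1L, min(idx_all[, 1L]) - pad); r1 <- min(nrow(mask_k), max(idx_all[, 1L]) + pad)
  c0 <- max(1L, min(idx_all[, 2L]) - pad); c1 <- min(ncol(mask_k), max(idx_all[, 2L]) + pad)
  mk <- mask_k[r0:r1, c0:c1, drop = FALSE]
  mi <- mask_inf[r0:r1, c0:c1, drop = FALSE]
  pivot <- unname(colMeans(which(mi != 0, arr.ind = TRUE)))
  ck <- unname(colMeans(which(mk != 0, arr.ind = TRUE)))
  d0 <- round(ck - pivot)
  eval_t <- function(p) {
    .dice_fast(transform_mask(mi, p[1L], p[2L], p[3L], p[4L],
                              pivot = pivot), mk)
  }
  best <- c(dy = 0, dx = 0, rot_deg = 0, scale = 1)     # identity candidate
  best_d <- eval_t(best)
  # stage 1: translation about the centroid seed at identity rotation/scale
  for (ddy in -3:3) for (ddx in -3:3) {
    p <- c(dy = d0[1L] + ddy, dx = d0[2L] + ddx, rot_deg = 0, scale = 1)
    d <- eval_t(p)
    if (d > best_d) { best <- p; best_d <- d }
  }
  tr <- c(best[["dy"]], best[["dx"]])
  if (all(tr == 0)) tr <- d0                       # identity may have won
  # stage 2: rotation x scale grid with small translation tweaks
  for (rot in seq(-max_rot, max_rot, by = 3)) {
    for (sc in seq(scale_range[1L], scale_range[2L], by = 0.05)) {
      for (ddy in -1:1) for (ddx in -1:1) {
        p <- c(dy = tr[1L] + ddy, dx = tr[2L] + ddx, rot_deg = rot,
               scale = sc)
        d <- eval_t(p)
        if (d > best_d) { best <- p; best_d <- d }
      }
    }
  }
  # local hill-climbing with halved steps
  steps <- c(dy = 1, dx = 1, rot_deg = 1.5, scale = 0.025)
  for (round in 1:3) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_along(best)) for (sgn in c(-1, 1)) {
        p <- best; p[i] <- p[i] + sgn * steps[i]
        d <- eval_t(p)
        if (d > best_d) { best <- p; best_d <- d; improved <- TRUE }
      }
    }
    steps <- steps / 2
  }
  pivot_full <- pivot + c(r0 - 1L, c0 - 1L)
  structure(list(mask = transform_mask(mask_inf, best[1L], best[2L],
                                       best[3L], best[4L],
                                       pivot = pivot_full),
                 transform = best, overlap = best_d, applied = TRUE),
            class = "refinement_result")
}

#' Is a segmentation successful after QC?
#'
#' A segmentation counts as successful when a proper-shaped mask results,
#' whether or not automatic refinement was applied. This is the single
#' predicate the map reconstruction uses to count usable images per slice.
#'
#' @param mask Binary mask after post-processing and (optional) refinement.
#' @param ecc_max Maximum allowed eccentricity.
#' @return Logical.
#' @export
segmentation_successful <- function(mask, ecc_max = 0.65) {
  assess_shape(mask, ecc_max = ecc_max)$proper
}
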