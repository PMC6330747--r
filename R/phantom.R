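#' Inversion-time schedule of a slice-interleaved T1 mapping acquisition
#'
#' Builds the 11-point inversion-time (TI) schedule used by free-breathing
#' slice-interleaved T1 mapping: an effectively infinite TI (full recovery,
#' encoded as `Inf`) followed by two interleaved trains starting at 115 ms and
#' 350 ms, each incremented four times by the cardiac cycle duration RR.
#'
#' @param rr_interval Cardiac cycle duration RR in ms (default 1000).
#' @return Numeric vector of length 11:
#'   `c(Inf, 115, 115 + RR, ..., 115 + 4 RR, 350, 350 + RR, ..., 350 + 4 RR)`.
#' @examples
#' make_ti_schedule(1000)
#' @export
make_ti_schedule <- function(rr_interval = 1000) {
  if (!is.numeric(rr_interval) || length(rr_interval) != 1L ||
      !is.finite(rr_interval) || rr_interval <= 0) {
    stop("rr_interval must be a single positive finite number (ms)")
  }
  c(Inf, 115 + rr_interval * 0:4, 350 + rr_interval * 0:4)
}

#' Magnitude inversion-recovery signal
#'
#' Two-parameter magnitude inversion-recovery model with perfect inversion:
#' \deqn{S(TI) = A \, |1 - 2 e^{-TI/T_1}|.}
#' `TI = Inf` is handled analytically and returns `A` (full recovery).
#'
#' @param t1 Longitudinal relaxation time in ms (> 0). Vectorized.
#' @param amplitude Equilibrium signal amplitude A (>= 0).
#' @param ti Inversion time in ms, or `Inf`. Vectorized.
#' @return Signal value(s), same shape as the broadcast of the arguments.
#' @examples
#' ir_signal(1000, 1, Inf)              # 1
#' ir_signal(1000, 1, 1000 * log(2))    # 0 (null point)
#' @export
ir_signal <- function(t1, amplitude, ti) {
  if (any(t1 <= 0)) stop("t1 must be positive (ms)")
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  # exp(-Inf) is exactly 0 in IEEE arithmetic, so TI = Inf yields exactly A
  amplitude * abs(1 - 2 * exp(-ti / t1))
}

#' Phantom configuration
#'
#' Parameters of the synthetic short-axis cardiac phantom: an annular
#' myocardium (T1 `t1_myo`) around a circular blood pool (T1 `t1_blood`) on a
#' background of T1 `t1_background`, imaged at the 11 TIs of
#' [make_ti_schedule()] with optional per-image rigid translation (respiratory
#' motion surrogate) and additive Gaussian noise.
#'
#' Defaults mirror a 1.5 T free-breathing protocol: 256 x 256 matrix at
#' 2.1 mm pixel spacing, RR = 1000 ms, native myocardium T1 1100 ms, blood
#' 1700 ms, a short-T1 background (300 ms), and a wall thickness within the
#' 15-pixel maximum seen in short-axis stacks.
#'
#' @param grid_size Image matrix size in pixels (square).
#' @param pixel_spacing In-plane pixel spacing in mm.
#' @param center Annulus center `c(row, col)`; default image center.
#' @param r_endo,r_epi Endocardial / epicardial radii in pixels
#'   (`r_epi - r_endo <= 15`).
#' @param t1_myo,t1_blood,t1_background Tissue T1 values in ms.
#' @param amplitude Global equilibrium signal scale (arbitrary units).
#' @param pd_blood,pd_background Equilibrium signal of blood and background
#'   relative to myocardium (proton density / inflow surrogate). Blood is
#'   brighter than myocardium (default 1.6) and the air background nearly
#'   dark (default 0.1), which is what gives the fully recovered
#'   (infinite-TI) image its high myocardium-to-blood contrast.
#' @param rr_interval Cardiac cycle duration in ms.
#' @param noise_sd SD of additive zero-mean noise (signal units).
#' @param noise_model `"gaussian"` (default) or `"rician"` (Gaussian on the
#'   complex channels before magnitude).
#' @param motion_amplitude Maximum per-image rigid translation in pixels
#'   (uniform in `[-motion_amplitude, motion_amplitude]` per axis).
#' @param shape `"annulus"` (concentric circles), `"ellipse"` (elliptical
#'   annulus, axis ratio `ellipse_ratio`), or `"c_shape"` (annulus broken by a
#'   `gap_deg`-wide angular gap) - the latter two exercise the shape QC gate.
#' @param ellipse_ratio Major/minor semi-axis ratio for `shape = "ellipse"`.
#' @param gap_deg Angular gap width in degrees for `shape = "c_shape"`.
#' @param seed Integer RNG seed; fixed seed gives bit-identical stacks.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 256, pixel_spacing = 2.1,
                           center = NULL, r_endo = 20, r_epi = 32,
                           t1_myo = 1100, t1_blood = 1700,
                           t1_background = 300, amplitude = 1,
                           pd_blood = 1.6, pd_background = 0.1,
                           rr_interval = 1000, noise_sd = 0,
                           noise_model = c("gaussian", "rician"),
                           motion_amplitude = 0,
                           shape = c("annulus", "ellipse", "c_shape"),
                           ellipse_ratio = 2, gap_deg = 60, seed = 1L) {
  shape <- match.arg(shape)
  noise_model <- match.arg(noise_model)
  if (is.null(center)) center <- c(grid_size, grid_size) / 2 + 0.5
  stopifnot(grid_size >= 32, pixel_spacing > 0,
            r_endo > 0, r_epi > r_endo, r_epi < grid_size / 2,
            t1_myo > 0, t1_blood > 0, t1_background > 0,
            amplitude >= 0, pd_blood > 0, pd_background >= 0,
            rr_interval > 0, noise_sd >= 0,
            motion_amplitude >= 0)
  if (r_epi - r_endo > 15) {
    stop("wall thickness r_epi - r_endo must not exceed 15 pixels")
  }
  structure(list(grid_size = grid_size, pixel_spacing = pixel_spacing,
                 center = center, r_endo = r_endo, r_epi = r_epi,
                 t1_myo = t1_myo, t1_blood = t1_blood,
                 t1_background = t1_background, amplitude = amplitude,
                 pd_blood = pd_blood, pd_background = pd_background,
                 rr_interval = rr_interval, noise_sd = noise_sd,
                 noise_model = noise_model,
                 motion_amplitude = motion_amplitude, shape = shape,
                 ellipse_ratio = ellipse_ratio, gap_deg = gap_deg,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Squared elliptical radius of every pixel relative to a center; ratio > 1
# stretches the x (column) axis.
.radius_field <- function(grid_size, center, ratio = 1) {
  rows <- matrix(seq_len(grid_size) - center[1L], grid_size, grid_size)
  cols <- matrix(seq_len(grid_size) - center[2L], grid_size, grid_size,
                 byrow = TRUE)
  sqrt(rows^2 + (cols / ratio)^2)
}

#' Ground-truth myocardium mask for a phantom geometry
#'
#' @param config A [phantom_config()].
#' @param center Optional center override `c(row, col)` (used to emulate
#'   rigid translation exactly, by re-rendering the geometry).
#' @return Integer 0/1 matrix of size `grid_size` x `grid_size`.
#' @export
phantom_mask <- function(config, center = config$center) {
  ratio <- if (config$shape == "ellipse") config$ellipse_ratio else 1
  r <- .radius_field(config$grid_size, center, ratio)
  m <- (r >= config$r_endo & r <= config$r_epi)
  if (config$shape == "c_shape") {
    rows <- matrix(seq_len(config$grid_size) - center[1L],
                   config$grid_size, config$grid_size)
    cols <- matrix(seq_len(config$grid_size) - center[2L],
                   config$grid_size, config$grid_size, byrow = TRUE)
    ang <- atan2(-rows, cols) * 180 / pi           # CCW from +x, degrees
    half <- config$gap_deg / 2
    m <- m & !(ang > -half & ang < half)
  }
  matrix(as.integer(m), config$grid_size, config$grid_size)
}

# Per-pixel T1 and equilibrium-amplitude fields for a (possibly shifted)
# phantom geometry.
.t1_field <- function(config, center = config$center) {
  ratio <- if (config$shape == "ellipse") config$ellipse_ratio else 1
  r <- .radius_field(config$grid_size, center, ratio)
  f <- matrix(config$t1_background, config$grid_size, config$grid_size)
  f[r < config$r_endo] <- config$t1_blood
  f[phantom_mask(config, center) == 1L] <- config$t1_myo
  f
}

.amp_field <- function(config, center = config$center) {
  ratio <- if (config$shape == "ellipse") config$ellipse_ratio else 1
  r <- .radius_field(config$grid_size, center, ratio)
  a <- matrix(config$amplitude * config$pd_background,
              config$grid_size, config$grid_size)
  a[r < config$r_endo] <- config$amplitude * config$pd_blood
  a[phantom_mask(config, center) == 1L] <- config$amplitude
  a
}

#' Render a synthetic T1-weighted stack with ground truth
#'
#' Produces one magnitude image per TI of the schedule. Each image is the
#' noiseless inversion-recovery signal field of the phantom geometry rigidly
#' translated by that TI's motion draw (the geometry is re-rendered at the
#' shifted center, so translation is exact and the truth masks stay binary),
#' plus zero-mean noise of SD `noise_sd`.
#'
#' @param config A [phantom_config()].
#' @return A list of class `t1w_stack` with elements `images` (array
#'   `grid_size x grid_size x 11`), `tis`, `pixel_spacing`, and `truth`
#'   (class `phantom_truth`: `myo_mask` at the reference center, `t1_field`,
#'   `motion_trace` 11 x 2 matrix of (dy, dx), `ti_schedule`, and `masks`,
#'   the per-TI shifted truth masks).
#' @examples
#' st <- render_stack(phantom_config(grid_size = 64, r_endo = 10, r_epi = 16))
#' dim(st$images)
#' @export
render_stack <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  tis <- make_ti_schedule(config$rr_interval)
  n <- config$grid_size
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  shifts <- matrix(0, length(tis), 2L, dimnames = list(NULL, c("dy", "dx")))
  if (config$motion_amplitude > 0) {
    shifts[] <- stats::runif(2L * length(tis), -config$motion_amplitude,
                             config$motion_amplitude)
    shifts <- round(shifts)                       # rigid integer translation
  }
  images <- array(0, c(n, n, length(tis)))
  masks <- vector("list", length(tis))
  for (k in seq_along(tis)) {
    ctr <- config$center + shifts[k, ]
    field <- ir_signal(.t1_field(config, ctr), .amp_field(config, ctr),
                       tis[k])
    if (config$noise_sd > 0) {
      if (config$noise_model == "rician") {
        field <- sqrt((field + stats::rnorm(n * n, 0, config$noise_sd))^2 +
                        stats::rnorm(n * n, 0, config$noise_sd)^2)
      } else {
        field <- field + stats::rnorm(n * n, 0, config$noise_sd)
      }
    }
    images[, , k] <- field
    masks[[k]] <- phantom_mask(config, ctr)
  }
  truth <- structure(list(myo_mask = phantom_mask(config),
                          t1_field = .t1_field(config),
                          amplitude_field = .amp_field(config),
                          motion_trace = shifts, ti_schedule = tis,
                          masks = masks),
                     class = "phantom_truth")
  structure(list(images = images, tis = tis,
                 pixel_spacing = config$pixel_spacing, truth = truth,
                 config = config),
            class = "t1w_stack")
}

#' @export
print.t1w_stack <- function(x, ...) {
  cat(sprintf("t1w_stack: %d x %d, %d inversion times (%.1f mm spacing)\n",
              dim(x$images)[1L], dim(x$images)[2L], length(x$tis),
              x$pixel_spacing))
  invisible(x)
}
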