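# Shared fixtures: all geometry is generated in code at test time.

# Small centered annulus phantom; deterministic under `seed`.
make_phantom <- function(grid_size = 64, r_endo = 10, r_epi = 16,
                         noise_sd = 0, motion_amplitude = 0, seed = 1L, ...) {
  phantom_config(grid_size = grid_size, r_endo = r_endo, r_epi = r_epi,
                 center = c(grid_size, grid_size) / 2 + 0.5,
                 noise_sd = noise_sd, motion_amplitude = motion_amplitude,
                 seed = seed, ...)
}

# Binary disk / annulus / ellipse masks built from first principles (not via
# the phantom module), for QC oracle tests.
disk_mask <- function(n, center, r) {
  d2 <- (row(matrix(0, n, n)) - center[1])^2 + (col(matrix(0, n, n)) - center[2])^2
  matrix(as.integer(d2 <= r^2), n, n)
}

annulus_mask_ref <- function(n, center, r1, r2) {
  d2 <- (row(matrix(0, n, n)) - center[1])^2 + (col(matrix(0, n, n)) - center[2])^2
  matrix(as.integer(d2 >= r1^2 & d2 <= r2^2), n, n)
}

ellipse_mask <- function(n, center, a, b) {
  # a = semi-axis along columns (x), b = along rows (y)
  yy <- row(matrix(0, n, n)) - center[1]
  xx <- col(matrix(0, n, n)) - center[2]
  matrix(as.integer((xx / a)^2 + (yy / b)^2 <= 1), n, n)
}

# Segmentation training pair from a randomized phantom (longest-TI image).
make_training_pair <- function(seed, grid_size = 64, noise_sd = 0.05) {
  set.seed(seed)
  pc <- phantom_config(grid_size = grid_size,
                       r_endo = sample(8:12, 1), r_epi = sample(14:18, 1),
                       center = c(grid_size / 2 + 0.5, grid_size / 2 + 0.5) +
                         stats::runif(2, -6, 6),
                       noise_sd = noise_sd, seed = seed)
  st <- render_stack(pc)
  list(image = normalize_intensity(st$images[, , 1L]),
       label = st$truth$masks[[1L]])
}
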