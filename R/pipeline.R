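#' Run configuration for the analysis pipeline
#'
#' Collects the thresholds of the workflow; the defaults are the standard
#' values of the method: 20 x 360 polar grid, at least 8 usable images per
#' slice, the 850-1500 ms native-T1 acceptance window at 1.5 T, eccentricity
#' limit 0.65, 5 cm^2 area filter, and a pruning band one-third of the mean
#' wall thickness.
#'
#' @param C Polar samples per ray.
#' @param n_rays Number of polar rays.
#' @param min_images Minimum successfully segmented images per slice.
#' @param accept_range Inclusive T1 acceptance range (ms).
#' @param eccentricity_max Shape-QC eccentricity limit.
#' @param area_min_cm2 Area-filter threshold (cm^2).
#' @param prune_fraction Retained fraction of wall thickness when pruning.
#' @param t1_range T1 fit search range (ms).
#' @param seed RNG seed recorded in provenance.
#' @return Object of class `run_config`.
#' @export
run_config <- function(C = 20, n_rays = 360, min_images = 8,
                       accept_range = c(850, 1500), eccentricity_max = 0.65,
                       area_min_cm2 = 5, prune_fraction = 1 / 3,
                       t1_range = c(100, 3000), seed = 1L) {
  stopifnot(C >= 2, n_rays >= 4, min_images >= 1, all(accept_range > 0),
            eccentricity_max > 0, area_min_cm2 > 0, prune_fraction > 0)
  structure(list(C = C, n_rays = n_rays, min_images = min_images,
                 accept_range = accept_range,
                 eccentricity_max = eccentricity_max,
                 area_min_cm2 = area_min_cm2,
                 prune_fraction = prune_fraction, t1_range = t1_range,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Segmenter interfaces
#'
#' The pipeline takes any function `f(image, ti_index)` returning a binary
#' mask. Three constructors cover the usual cases: a trained network, a
#' ground-truth stub (phantom truth masks, for testing the downstream
#' pipeline independently of training quality), and a directory of
#' pre-computed PNG masks named `mask_<k>.png`.
#'
#' @param net A trained `segnet`; images are normalized and, if needed,
#'   center-cropped/padded to the network input size and the mask mapped
#'   back.
#' @return A segmenter function.
#' @export
segmenter_network <- function(net) {
  force(net)
  function(image, ti_index) {
    img <- normalize_intensity(image)
    side <- net$config$input_size
    if (!all(dim(img) == side)) {
      img2 <- pad_crop(img, side)
      mask <- segment(img2, net)
      pad_crop(mask, nrow(image))
    } else {
      segment(img, net)
    }
  }
}

#' @rdname segmenter_network
#' @param masks List of binary masks, one per TI.
#' @export
segmenter_truth <- function(masks) {
  force(masks)
  function(image, ti_index) masks[[ti_index]]
}

#' @rdname segmenter_network
#' @param dir Directory containing `mask_<k>.png` files.
#' @export
segmenter_dir <- function(dir) {
  force(dir)
  function(image, ti_index) {
    f <- file.path(dir, sprintf("mask_%d.png", ti_index))
    if (!file.exists(f)) stop("missing mask file: ", f)
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
  }
}

#' Symmetric zero-pad or center-crop a matrix to a square size
#'
#' @param m Matrix.
#' @param size Target side length.
#' @return `size x size` matrix.
#' @export
pad_crop <- function(m, size) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, size, size)
  src_r <- seq_len(min(nr, size)) + max(0L, (nr - size) %/% 2L)
  src_c <- seq_len(min(nc, size)) + max(0L, (nc - size) %/% 2L)
  dst_r <- seq_along(src_r) + max(0L, (size - nr) %/% 2L)
  dst_c <- seq_along(src_c) + max(0L, (size - nc) %/% 2L)
  out[dst_r, dst_c] <- m[src_r, src_c]
  if (is.integer(m)) out <- matrix(as.integer(out), size, size)
  out
}

#' Process one slice: segmentation, QC, polar fitting, pruning
#'
#' Implements the per-slice workflow: every T1-weighted image is segmented,
#' area-filtered and shape-assessed; improper masks are refined against the
#' longest-TI (infinite-TI) mask or excluded; if at least `min_images` images
#' survive, their polar transforms (each about its own mask centroid) are
#' fitted pixel-wise and the polar map is inverse-transformed onto the mask
#' of the shortest finite TI, which is then pruned for the T1 averages.
#'
#' @param images Array `H x W x K` of T1-weighted images.
#' @param tis Inversion times (ms, `Inf` allowed), length `K`.
#' @param segmenter A segmenter function (see [segmenter_network()]).
#' @param config A [run_config()].
#' @param pixel_spacing In-plane spacing in mm.
#' @return List of class `slice_result`: `status` (`"ok"` or `"rejected"`),
#'   `map` (`cartesian_t1_map` or NULL), `pruned_mask`, `polar_map`, `qc`
#'   (per-image data.frame: ti, euler, eccentricity, proper, refined,
#'   excluded), and `unreliable` (TRUE when more than `max_invalid_rays` of
#'   the polar rays are invalid in any usable image, e.g. for a barely
#'   closed ring).
#' @param max_invalid_rays Invalid-ray count above which the slice is flagged
#'   unreliable (default 90 of 360).
#' @export
process_slice <- function(images, tis, segmenter, config = run_config(),
                          pixel_spacing = 2.1, max_invalid_rays = 90) {
  K <- length(tis)
  stopifnot(dim(images)[3L] == K)
  masks <- vector("list", K)
  qc <- data.frame(ti = tis, euler = NA_integer_, eccentricity = NA_real_,
                   proper = FALSE, refined = FALSE, excluded = TRUE)
  raw <- vector("list", K)
  for (k in seq_len(K)) {
    m <- segmenter(images[, , k], k)
    m <- area_filter(m, pixel_spacing = pixel_spacing,
                     min_area_cm2 = config$area_min_cm2)
    raw[[k]] <- m
    v <- assess_shape(m, ecc_max = config$eccentricity_max)
    qc$euler[k] <- v$euler
    qc$eccentricity[k] <- v$eccentricity
    qc$proper[k] <- v$proper
  }
  k_inf <- which.max(tis)          # Inf sorts last among the TIs
  for (k in seq_len(K)) {
    if (qc$proper[k]) {
      masks[[k]] <- raw[[k]]
      qc$excluded[k] <- FALSE
    } else {
      r <- refine(raw[[k]], if (qc$proper[k_inf]) raw[[k_inf]] else
        matrix(0L, nrow(images), ncol(images)))
      if (r$applied && segmentation_successful(r$mask,
                                               config$eccentricity_max)) {
        masks[[k]] <- r$mask
        qc$refined[k] <- TRUE
        qc$excluded[k] <- FALSE
      }
    }
  }
  usable <- which(!qc$excluded)
  if (length(usable) < config$min_images) {
    return(structure(list(status = "rejected", map = NULL,
                          pruned_mask = NULL, polar_map = NULL, qc = qc),
                     class = "slice_result"))
  }
  polar_stack <- lapply(usable, function(k) {
    to_polar(images[, , k], masks[[k]], C = config$C, n_rays = config$n_rays)
  })
  unreliable <- any(vapply(polar_stack,
                           function(p) sum(!p$valid), 0L) > max_invalid_rays)
  pmap <- tryCatch(
    reconstruct_map(polar_stack, tis[usable], min_images = config$min_images,
                    t1_range = config$t1_range),
    cardiot1_slice_rejected = function(e) NULL)
  if (is.null(pmap)) {
    return(structure(list(status = "rejected", map = NULL,
                          pruned_mask = NULL, polar_map = NULL, qc = qc),
                     class = "slice_result"))
  }
  k_ref <- usable[which.min(tis[usable])]      # shortest finite TI reference
  ref_mask <- masks[[k_ref]]
  cmap <- from_polar(pmap$values, ref_mask)
  wall <- mean_wall_thickness(list(endo_radius = pmap$endo_radius,
                                   epi_radius = pmap$epi_radius,
                                   valid = is.finite(pmap$endo_radius)))
  pruned <- prune_mask(ref_mask, wall_thickness = wall,
                       fraction = config$prune_fraction)
  structure(list(status = "ok", map = cmap, pruned_mask = pruned,
                 polar_map = pmap, qc = qc, unreliable = unreliable,
                 reference_ti = tis[k_ref]),
            class = "slice_result")
}

#' Run the full analysis for one patient
#'
#' Applies [process_slice()] to each slice of a patient's stack set and
#' summarizes the surviving slices into global and regional T1. Slices that
#' fail reconstruction are reported in the QC table, not fatal; if no slice
#' reconstructs, the patient is reported as failed.
#'
#' @param stacks List of per-slice stacks; each element either a `t1w_stack`
#'   (from [render_stack()] or [read_stack()]) or a list with `images`,
#'   `tis`, `pixel_spacing`.
#' @param segmenter A segmenter function, or a list of them (one per slice,
#'   e.g. truth stubs).
#' @param config A [run_config()].
#' @return List of class `patient_result`: `summary` (`t1_summary` or NULL),
#'   `slices` (list of `slice_result`), `qc` (row-bound per-image QC table
#'   with a `slice` column), `status`.
#' @export
run_patient <- function(stacks, segmenter, config = run_config()) {
  slices <- vector("list", length(stacks))
  for (s in seq_along(stacks)) {
    st <- stacks[[s]]
    seg <- if (is.list(segmenter) && !is.function(segmenter)) segmenter[[s]] else segmenter
    slices[[s]] <- process_slice(st$images, st$tis, seg, config,
                                 pixel_spacing = st$pixel_spacing %||% 2.1)
  }
  ok <- which(vapply(slices, function(x) x$status == "ok", TRUE))
  qc <- do.call(rbind, lapply(seq_along(slices), function(s) {
    cbind(slice = s, slices[[s]]$qc)
  }))
  if (length(ok) == 0L) {
    return(structure(list(summary = NULL, slices = slices, qc = qc,
                          status = "failed"), class = "patient_result"))
  }
  summary <- summarize_t1(lapply(slices[ok], `[[`, "map"),
                          lapply(slices[ok], `[[`, "pruned_mask"),
                          accept_range = config$accept_range)
  structure(list(summary = summary, slices = slices, qc = qc,
                 status = "ok"), class = "patient_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- I/O --------------------------------------------------------------------

#' Write / read a T1-weighted stack as NIfTI with a JSON TI sidecar
#'
#' One 3-D NIfTI volume per slice stack (third dimension = TI index) plus a
#' JSON sidecar holding the inversion times (`Inf` encoded as the string
#' `"Inf"`) and the pixel spacing. On reading, images are sorted by TI with
#' `Inf` last and padded/cropped symmetrically to `target_size`.
#'
#' @param stack A `t1w_stack` (or list with `images`, `tis`,
#'   `pixel_spacing`).
#' @param path Output path (`.nii` or `.nii.gz`); the sidecar is written next
#'   to it with extension `.json`.
#' @return `write_stack` returns `path` invisibly; `read_stack` a
#'   `t1w_stack`.
#' @export
write_stack <- function(stack, path) {
  img <- RNifti::asNifti(stack$images,
                         pixdim = rep(stack$pixel_spacing %||% 2.1, 2))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  tis <- as.character(stack$tis)
  jsonlite::write_json(list(inversion_times_ms = tis,
                            pixel_spacing_mm = stack$pixel_spacing %||% 2.1),
                       sidecar, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @param target_size Output matrix size (default 256).
#' @export
read_stack <- function(path, target_size = 256) {
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) {
    stop("missing TI sidecar for ", path, " (expected ", sidecar, ")")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$inversion_times_ms)) {
    stop("sidecar ", sidecar, " lacks inversion_times_ms")
  }
  tis <- as.numeric(meta$inversion_times_ms)     # "Inf" -> Inf
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) != 3L || dim(arr)[3L] != length(tis)) {
    stop("volume and sidecar TI count disagree for ", path)
  }
  ord <- order(tis)                               # Inf sorts last
  arr <- arr[, , ord, drop = FALSE]
  tis <- tis[ord]
  out <- array(0, c(target_size, target_size, length(tis)))
  for (k in seq_along(tis)) out[, , k] <- pad_crop(arr[, , k], target_size)
  structure(list(images = out, tis = tis,
                 pixel_spacing = meta$pixel_spacing_mm %||% 2.1),
            class = "t1w_stack")
}

#' Write a binary mask as 16-bit PNG
#'
#' @param mask Binary matrix.
#' @param path Output `.png` path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path,
                dpi = NULL)
  invisible(path)
}

#' Write a Cartesian T1 map as NIfTI (float, ms)
#'
#' @param map A `cartesian_t1_map`.
#' @param path Output path.
#' @param pixel_spacing In-plane spacing in mm.
#' @export
write_t1_map <- function(map, path, pixel_spacing = 2.1) {
  v <- map$values
  v[!is.finite(v)] <- 0
  RNifti::writeNifti(RNifti::asNifti(v, pixdim = rep(pixel_spacing, 2)), path,
                     datatype = "float")
  invisible(path)
}

#' Per-image QC report as JSON lines
#'
#' @param qc QC data.frame from [run_patient()] (columns slice, ti, euler,
#'   eccentricity, proper, refined, excluded).
#' @param path Output file; one JSON object per line.
#' @export
write_qc_report <- function(qc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(qc))) {
    row <- as.list(qc[i, ])
    row$ti <- as.character(row$ti)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
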