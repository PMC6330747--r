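# Shared low-level image helpers. Matrix convention throughout the package:
# element [i, j] is row i (y, increasing downward when displayed) and column j
# (x). Angles are measured in degrees counter-clockwise from the +x (column)
# axis as the image is displayed, i.e. direction (drow, dcol) =
# (-sin(theta), cos(theta)).

# Bilinear interpolation of matrix `img` at fractional coordinates
# (rows, cols), 1-based. Points outside the grid get `outside`.
bilinear_sample <- function(img, rows, cols, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # clamp edge-exact coordinates (rows == nr, cols == nc)
  edge <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc & !ok
  r0[edge] <- pmin(r0[edge], nr - 1); c0[edge] <- pmin(c0[edge], nc - 1)
  fr[edge] <- rows[edge] - r0[edge]; fc[edge] <- cols[edge] - c0[edge]
  ok <- ok | edge
  out <- rep(outside, length(rows))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- r0k + (c0k - 1) * nr
    out[ok] <- img[i00] * (1 - frk) * (1 - fck) +
      img[i00 + 1] * frk * (1 - fck) +
      img[i00 + nr] * (1 - frk) * fck +
      img[i00 + nr + 1] * frk * fck
  }
  out
}

# 8-connected labeling of a binary matrix. EBImage::bwlabel is 4-connected;
# labels touching diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(a) { while (parent[a] != a) a <- parent[a] <- parent[parent[a]]; a }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (off[2L] > 0) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr, if (off[2L] > 0) 2:nc else seq_len(nc - 1L)]
    touch <- which(a > 0L & b > 0L & a != b)
    for (t in touch) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Gaussian blur of a matrix by separable 1-D convolution (replicated edges).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {           # convolve columns with k
    top <- m[rep(1L, half), , drop = FALSE]
    bot <- m[rep(nrow(m), half), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# Warp an image by arbitrary per-pixel source coordinates (inverse mapping).
warp_bilinear <- function(img, src_rows, src_cols, outside = 0) {
  matrix(bilinear_sample(img, as.vector(src_rows), as.vector(src_cols),
                         outside = outside),
         nrow(img), ncol(img))
}

# Rigid/affine transform of a binary mask: scale and rotate about `pivot`
# (default its centroid), then translate by (dy, dx). Inverse-mapped,
# bilinearly interpolated, re-thresholded at 0.5.
transform_mask <- function(mask, dy = 0, dx = 0, rot_deg = 0, scale = 1,
                           pivot = NULL) {
  if (is.null(pivot)) {
    idx <- which(mask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(mask)
    pivot <- colMeans(idx)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  th <- -rot_deg * pi / 180           # CCW in displayed image (y down)
  rows <- matrix(seq_len(nr), nr, nc) - pivot[1L] - dy
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - pivot[2L] - dx
  sr <- (cos(th) * rows - sin(th) * cols) / scale + pivot[1L]
  sc <- (sin(th) * rows + cos(th) * cols) / scale + pivot[2L]
  v <- warp_bilinear(mask, sr, sc)
  matrix(as.integer(v >= 0.5), nr, nc)
}

# Zhang-Suen morphological thinning to a 1-pixel-wide skeleton.
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  shift <- function(m, dr, dc) m[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      pad[2:(nr + 1L), 2:(nc + 1L)] <- img
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (phase == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- img == 1L & bsum >= 2L & bsum <= 6L & a == 1L & cond
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Dilate a binary mask with a disc structuring element of given radius.
dilate_disc <- function(mask, radius) {
  if (radius < 1) return(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::dilate(mask != 0, brush)
  matrix(as.integer(out != 0), nrow(mask), ncol(mask))
}
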