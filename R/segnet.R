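# U-Net style fully convolutional segmenter, implemented directly on R
# arrays. Tensors are [H, W, N, C] (channel last; with R's column-major
# storage this makes the reshape between the spatial and the channel view a
# zero-copy dim change). Convolutions are im2col gathers followed by BLAS
# matrix multiplication; gradients are hand-derived per layer. This keeps the
# whole network dependency-free and fully deterministic under a seed.

#' Per-image intensity normalization
#'
#' Subtracts the mean and divides by the standard deviation of the pixel
#' intensities, mapping every T1-weighted image onto a common dynamic range
#' before segmentation.
#'
#' @param image Numeric matrix with more than one distinct intensity.
#' @return Matrix with mean 0 and SD 1.
#' @export
normalize_intensity <- function(image) {
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: constant image cannot be normalized")
  }
  (image - mean(image)) / s
}

#' Network configuration
#'
#' Architecture and optimization hyperparameters of the segmenter. Two
#' presets: `"tiny"` (depth 3, 10 base kernels, 64 px input) trains on a CPU in
#' minutes and is ample for phantom geometry; `"full_scale"` (depth 5, 34
#' base kernels, 256 px input) has approximately 9 million parameters.
#'
#' @param preset `"tiny"` or `"full_scale"`, or `NULL` to set fields
#'   directly.
#' @param input_size Input image size in pixels (divisible by `2^depth`).
#' @param depth Number of resolution levels.
#' @param base_kernels Kernel count at the first level; doubles per
#'   down-step, halves per up-step.
#' @param dropout_p Dropout probability inside each bottleneck.
#' @param conv_size Spatial convolution kernel size (3).
#' @param learning_rate,weight_decay Adam learning rate and L2 weight decay.
#' @param iterations,batch_size Training schedule.
#' @param seed RNG seed for initialization, batching, augmentation, dropout.
#' @return Object of class `network_config`.
#' @export
network_config <- function(preset = c("tiny", "full_scale"),
                           input_size = NULL, depth = NULL,
                           base_kernels = NULL, dropout_p = NULL,
                           conv_size = 3, learning_rate = 0.001,
                           weight_decay = 0.001, iterations = 300,
                           batch_size = 6, seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    d <- switch(preset,
                tiny = list(input_size = 64, depth = 3, base_kernels = 10,
                            dropout_p = 0.2),
                full_scale = list(input_size = 256, depth = 5,
                                   base_kernels = 34, dropout_p = 0.5))
    if (is.null(input_size)) input_size <- d$input_size
    if (is.null(depth)) depth <- d$depth
    if (is.null(base_kernels)) base_kernels <- d$base_kernels
    if (is.null(dropout_p)) dropout_p <- d$dropout_p
  }
  stopifnot(depth >= 2, base_kernels >= 1, dropout_p >= 0, dropout_p <= 1,
            conv_size == 3, learning_rate > 0, iterations >= 1,
            batch_size >= 1)
  if (input_size %% 2^depth != 0) {
    stop("input_size must be divisible by 2^depth")
  }
  structure(list(input_size = input_size, depth = depth,
                 base_kernels = base_kernels, dropout_p = dropout_p,
                 conv_size = conv_size, learning_rate = learning_rate,
                 weight_decay = weight_decay, iterations = iterations,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "network_config")
}

# ---- layer primitives -------------------------------------------------------

.im2col_idx <- function(H, W, N) {
  # gather indices into a zero-padded (H+2) x (W+2) x N channel slab:
  # [H*W*N, 9], tap order (di fastest); one gather per input channel covers
  # the whole batch
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  plane <- (H + 2L) * (W + 2L)
  base <- rep((seq_len(N) - 1L) * plane, each = H * W)
  idx <- matrix(0L, H * W * N, 9L)
  t <- 0L
  for (dj in 0:2) for (di in 0:2) {
    t <- t + 1L
    idx[, t] <- rep((i + di) + (j + dj - 1L) * (H + 2L), N) + base
  }
  idx
}

.conv_fwd <- function(X, K, b, idx) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  Co <- length(b)
  if (nrow(K) == Ci) {                       # 1x1 convolution
    M <- X
    dim(M) <- c(H * W * N, Ci)
  } else {
    Xp <- array(0, c(H + 2L, W + 2L, N, Ci))
    Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
    M <- matrix(0, H * W * N, 9L * Ci)
    for (c in seq_len(Ci)) {
      slab <- Xp[, , , c]
      M[, (c - 1L) * 9L + 1:9] <- slab[idx]
    }
  }
  Y <- M %*% K + rep(b, each = H * W * N)
  dim(Y) <- c(H, W, N, Co)
  list(out = Y, cache = list(M = M, dimX = d, Co = Co))
}

.conv_bwd <- function(dY, K, cache, idx) {
  d <- cache$dimX; H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  Co <- cache$Co
  dYm <- dY
  dim(dYm) <- c(H * W * N, Co)
  dK <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, K)
  if (nrow(K) == Ci) {
    dim(dM) <- d
    return(list(dX = dM, dK = dK, db = db))
  }
  dXp <- array(0, c(H + 2L, W + 2L, N, Ci))
  slab_len <- (H + 2L) * (W + 2L) * N
  slab <- numeric(slab_len)
  for (c in seq_len(Ci)) {
    slab[] <- 0
    for (t in 1:9) {
      col <- dM[, (c - 1L) * 9L + t]
      slab[idx[, t]] <- slab[idx[, t]] + col
    }
    dXp[, , , c] <- slab
  }
  list(dX = dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dK = dK, db = db)
}

.bn_fwd <- function(X, gamma, beta, state, name, training, momentum = 0.1,
                    eps = 1e-5) {
  d <- dim(X); C <- d[4L]
  Xm <- X
  dim(Xm) <- c(prod(d[1:3]), C)
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(Xm^2) - mu^2
    state[[paste0(name, ".mean")]] <-
      (1 - momentum) * state[[paste0(name, ".mean")]] + momentum * mu
    state[[paste0(name, ".var")]] <-
      (1 - momentum) * state[[paste0(name, ".var")]] + momentum * va
  } else {
    mu <- state[[paste0(name, ".mean")]]
    va <- state[[paste0(name, ".var")]]
  }
  inv <- 1 / sqrt(va + eps)
  m <- nrow(Xm)
  Xh <- (Xm - rep(mu, each = m)) * rep(inv, each = m)
  Y <- Xh * rep(gamma, each = m) + rep(beta, each = m)
  dim(Y) <- d
  list(out = Y, state = state, cache = list(Xh = Xh, inv = inv, dims = d))
}

.bn_bwd <- function(dY, gamma, cache) {
  d <- cache$dims; C <- d[4L]
  m <- prod(d[1:3])
  dYm <- dY
  dim(dYm) <- c(m, C)
  dgamma <- colSums(dYm * cache$Xh)
  dbeta <- colSums(dYm)
  dXh <- dYm * rep(gamma, each = m)
  dXm <- (dXh - rep(colMeans(dXh), each = m) -
            cache$Xh * rep(colMeans(dXh * cache$Xh), each = m)) *
    rep(cache$inv, each = m)
  dim(dXm) <- d
  list(dX = dXm, dgamma = dgamma, dbeta = dbeta)
}

.pool_fwd <- function(X) {
  d <- dim(X); H <- d[1L]; W <- d[2L]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  e1 <- seq(1L, W, 2L); e2 <- seq(2L, W, 2L)
  a <- X[o1, e1, , , drop = FALSE]; b <- X[o2, e1, , , drop = FALSE]
  cc <- X[o1, e2, , , drop = FALSE]; dd <- X[o2, e2, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, cache = list(masks = list(a == out, b == out & a != out,
                                            cc == out & a != out & b != out,
                                            dd == out & a != out & b != out & cc != out),
                               dimX = d))
}

.pool_bwd <- function(dY, cache) {
  d <- cache$dimX
  dX <- array(0, d)
  o1 <- seq(1L, d[1L], 2L); o2 <- seq(2L, d[1L], 2L)
  e1 <- seq(1L, d[2L], 2L); e2 <- seq(2L, d[2L], 2L)
  m <- cache$masks
  dX[o1, e1, , ] <- dY * m[[1L]]
  dX[o2, e1, , ] <- dY * m[[2L]]
  dX[o1, e2, , ] <- dY * m[[3L]]
  dX[o2, e2, , ] <- dY * m[[4L]]
  dX
}

.up_fwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

.up_bwd <- function(dY) {
  d <- dim(dY)
  o1 <- seq(1L, d[1L], 2L); o2 <- seq(2L, d[1L], 2L)
  e1 <- seq(1L, d[2L], 2L); e2 <- seq(2L, d[2L], 2L)
  dY[o1, e1, , , drop = FALSE] + dY[o2, e1, , , drop = FALSE] +
    dY[o1, e2, , , drop = FALSE] + dY[o2, e2, , , drop = FALSE]
}

# ---- architecture -----------------------------------------------------------

# Execution plan: ordered ops. Bottleneck = BN -> ReLU -> conv3x3 -> dropout.
# The input stem is a plain convolution: applying a pre-activation bottleneck
# directly to the 1-channel normalized image would clip all sub-mean
# intensities at the very first ReLU before any kernel sees them.
.build_arch <- function(cfg) {
  w <- cfg$base_kernels * 2^(0:(cfg$depth - 1L))
  ops <- list()
  add <- function(kind, name = NULL, ...) {
    ops[[length(ops) + 1L]] <<- c(list(kind = kind, name = name), list(...))
  }
  bneck <- function(name, ci, co) {
    add("bn", name, ch = ci)
    add("relu")
    add("conv", name, ci = ci, co = co, ksize = 3L)
    add("dropout")
  }
  add("conv", "stem", ci = 1L, co = w[1L], ksize = 3L)
  ci <- w[1L]
  for (lvl in seq_len(cfg$depth)) {
    bneck(sprintf("enc%da", lvl), ci, w[lvl])
    bneck(sprintf("enc%db", lvl), w[lvl], w[lvl])
    ci <- w[lvl]
    if (lvl < cfg$depth) {
      add("save", sprintf("skip%d", lvl))
      add("pool")
    }
  }
  for (lvl in (cfg$depth - 1L):1L) {
    add("up")
    add("concat", sprintf("skip%d", lvl))
    bneck(sprintf("dec%da", lvl), ci + w[lvl], w[lvl])
    bneck(sprintf("dec%db", lvl), w[lvl], w[lvl])
    ci <- w[lvl]
  }
  add("conv", "head", ci = ci, co = 2L, ksize = 1L)
  ops
}

#' Build the segmentation network
#'
#' Instantiates the encoder-decoder: at each resolution level two bottlenecks
#' (batch-normalization, ReLU, 3x3 convolution with dropout), 2x2 max-pool
#' down-steps that double the kernel count, nearest-neighbor up-steps that
#' halve it, skip connections by channel concatenation, and a final 1x1
#' convolution producing two class maps turned into probabilities by a
#' softmax. Convolution weights use He initialization under the config seed.
#'
#' @param config A [network_config()].
#' @return Object of class `segnet`: `config`, `arch`, `params` (named list
#'   of weight arrays), `state` (batch-norm running statistics), `meta`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  arch <- .build_arch(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  params <- list(); state <- list()
  for (op in arch) {
    if (op$kind == "conv") {
      fan_in <- op$ksize^2 * op$ci
      params[[paste0(op$name, ".K")]] <-
        matrix(stats::rnorm(fan_in * op$co, 0, sqrt(2 / fan_in)),
               fan_in, op$co)
      params[[paste0(op$name, ".b")]] <- numeric(op$co)
    } else if (op$kind == "bn") {
      params[[paste0(op$name, ".gamma")]] <- rep(1, op$ch)
      params[[paste0(op$name, ".beta")]] <- numeric(op$ch)
      state[[paste0(op$name, ".mean")]] <- numeric(op$ch)
      state[[paste0(op$name, ".var")]] <- rep(1, op$ch)
    }
  }
  structure(list(config = config, arch = arch, params = params,
                 state = state, meta = list(iterations_trained = 0L,
                                            final_loss = NA_real_)),
            class = "segnet")
}

#' Number of trainable parameters of a network configuration
#'
#' @param config A [network_config()] or built `segnet`.
#' @return Integer count of trainable scalars (convolution weights and
#'   biases, batch-norm scales and shifts).
#' @export
count_parameters <- function(config) {
  net <- if (inherits(config, "segnet")) config else {
    cfg <- config
    structure(list(arch = .build_arch(cfg)), class = "segnet_arch_only")
  }
  total <- 0
  for (op in net$arch) {
    if (op$kind == "conv") total <- total + op$ksize^2 * op$ci * op$co + op$co
    if (op$kind == "bn") total <- total + 2L * op$ch
  }
  as.integer(total)
}

# Forward pass; X is [H, W, N, 1]. Returns logits [H, W, N, 2] and caches.
.net_fwd <- function(net, X, training = FALSE) {
  idx_cache <- list()
  saved <- list(); caches <- vector("list", length(net$arch))
  x <- X
  p <- net$params
  for (i in seq_along(net$arch)) {
    op <- net$arch[[i]]
    if (op$kind == "bn") {
      r <- .bn_fwd(x, p[[paste0(op$name, ".gamma")]],
                   p[[paste0(op$name, ".beta")]], net$state, op$name,
                   training)
      net$state <- r$state
      caches[[i]] <- r$cache; x <- r$out
    } else if (op$kind == "relu") {
      caches[[i]] <- x > 0
      x <- x * (x > 0)
    } else if (op$kind == "conv") {
      key <- paste(dim(x)[1:3], collapse = "x")
      if (op$ksize == 3L && is.null(idx_cache[[key]])) {
        idx_cache[[key]] <- .im2col_idx(dim(x)[1L], dim(x)[2L], dim(x)[3L])
      }
      r <- .conv_fwd(x, p[[paste0(op$name, ".K")]],
                     p[[paste0(op$name, ".b")]], idx_cache[[key]])
      caches[[i]] <- c(r$cache, list(idx = idx_cache[[key]]))
      x <- r$out
    } else if (op$kind == "dropout") {
      if (training && net$config$dropout_p > 0) {
        keep <- array(stats::runif(length(x)) >= net$config$dropout_p, dim(x))
        x <- x * keep / (1 - net$config$dropout_p)
        caches[[i]] <- keep
      }
    } else if (op$kind == "pool") {
      r <- .pool_fwd(x); caches[[i]] <- r$cache; x <- r$out
    } else if (op$kind == "up") {
      x <- .up_fwd(x)
    } else if (op$kind == "save") {
      saved[[op$name]] <- x
    } else if (op$kind == "concat") {
      s <- saved[[op$name]]
      caches[[i]] <- dim(x)[4L]
      y <- array(0, c(dim(x)[1L], dim(x)[2L], dim(x)[3L],
                      dim(x)[4L] + dim(s)[4L]))
      y[, , , seq_len(dim(x)[4L])] <- x
      y[, , , dim(x)[4L] + seq_len(dim(s)[4L])] <- s
      x <- y
    }
  }
  list(logits = x, caches = caches, state = net$state)
}

# Backward pass from dlogits; returns named gradient list.
.net_bwd <- function(net, caches, dlogits) {
  grads <- list(); dsaved <- list()
  dx <- dlogits
  p <- net$params
  for (i in rev(seq_along(net$arch))) {
    op <- net$arch[[i]]
    if (op$kind == "bn") {
      r <- .bn_bwd(dx, p[[paste0(op$name, ".gamma")]], caches[[i]])
      grads[[paste0(op$name, ".gamma")]] <- r$dgamma
      grads[[paste0(op$name, ".beta")]] <- r$dbeta
      dx <- r$dX
    } else if (op$kind == "relu") {
      dx <- dx * caches[[i]]
    } else if (op$kind == "conv") {
      r <- .conv_bwd(dx, p[[paste0(op$name, ".K")]], caches[[i]],
                     caches[[i]]$idx)
      grads[[paste0(op$name, ".K")]] <- r$dK
      grads[[paste0(op$name, ".b")]] <- r$db
      dx <- r$dX
    } else if (op$kind == "dropout") {
      if (!is.null(caches[[i]])) {
        dx <- dx * caches[[i]] / (1 - net$config$dropout_p)
      }
    } else if (op$kind == "pool") {
      dx <- .pool_bwd(dx, caches[[i]])
    } else if (op$kind == "up") {
      dx <- .up_bwd(dx)
    } else if (op$kind == "save") {
      if (!is.null(dsaved[[op$name]])) dx <- dx + dsaved[[op$name]]
    } else if (op$kind == "concat") {
      nup <- caches[[i]]
      dsaved[[op$name]] <- dx[, , , (nup + 1L):dim(dx)[4L], drop = FALSE]
      dx <- dx[, , , seq_len(nup), drop = FALSE]
    }
  }
  grads
}

# Softmax over the channel dimension of logits [H, W, N, 2].
.softmax2 <- function(logits) {
  m <- pmax(logits[, , , 1L, drop = FALSE], logits[, , , 2L, drop = FALSE])
  e1 <- exp(logits[, , , 1L, drop = FALSE] - m)
  e2 <- exp(logits[, , , 2L, drop = FALSE] - m)
  z <- e1 + e2
  p <- logits
  p[, , , 1L] <- e1 / z
  p[, , , 2L] <- e2 / z
  p
}

#' Class probability maps for one image
#'
#' Runs the network in inference mode (dropout inactive, batch-norm
#' statistics frozen) and returns the two softmax probability maps.
#'
#' @param image Normalized intensity matrix matching the config input size.
#' @param net A trained (or freshly built) `segnet`.
#' @return Array `H x W x 2`; channel 1 is background, channel 2 myocardium;
#'   the channels sum to 1 at every pixel.
#' @export
predict_probs <- function(image, net) {
  stopifnot(inherits(net, "segnet"))
  if (!all(dim(image) == net$config$input_size)) {
    stop(sprintf("image must be %d x %d for this network",
                 net$config$input_size, net$config$input_size))
  }
  X <- array(image, c(dim(image), 1L, 1L))
  p <- .softmax2(.net_fwd(net, X, training = FALSE)$logits)
  array(p, c(dim(image), 2L))
}

#' Segment a T1-weighted image
#'
#' Per-pixel argmax of the two softmax channels. An exact tie (both
#' probabilities 0.5) resolves to background, so the myocardium label
#' requires strict majority.
#'
#' @param image Normalized intensity matrix.
#' @param net A trained `segnet`.
#' @return Binary matrix: 1 = myocardium, 0 = background.
#' @export
segment <- function(image, net) {
  p <- predict_probs(image, net)
  matrix(as.integer(p[, , 2L] > p[, , 1L]), nrow(image), ncol(image))
}

# ---- augmentation -----------------------------------------------------------

#' Geometric augmentation of a training pair
#'
#' Applies, each with its own probability and with the identical geometric
#' transform to image and label, random translation (0.95), mirroring (0.95)
#' and elastic deformation (0.5). No intensity transform is applied; labels
#' are re-binarized after interpolation.
#'
#' @param image,label Matrices of equal size; `label` binary.
#' @param p_translate,p_mirror,p_elastic Application probabilities.
#' @param max_shift Maximum translation per axis in pixels.
#' @param elastic_sigma,elastic_alpha Smoothness (px) and amplitude (px) of
#'   the elastic displacement field; defaults keep deformed annuli annular.
#' @return List `image`, `label`.
#' @export
augment <- function(image, label, p_translate = 0.95, p_mirror = 0.95,
                    p_elastic = 0.5, max_shift = 5, elastic_sigma = 8,
                    elastic_alpha = 2) {
  stopifnot(all(dim(image) == dim(label)))
  nr <- nrow(image); nc <- ncol(image)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sr <- rows; sc <- cols
  if (stats::runif(1) < p_translate) {
    # whole-pixel shifts: the label warp is then exact, so thin structures
    # are not eroded by re-binarization
    sr <- sr - sample(-max_shift:max_shift, 1L)
    sc <- sc - sample(-max_shift:max_shift, 1L)
  }
  if (stats::runif(1) < p_elastic) {
    dr <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), elastic_sigma)
    dc <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), elastic_sigma)
    dr <- dr / max(abs(dr)) * elastic_alpha
    dc <- dc / max(abs(dc)) * elastic_alpha
    sr <- sr + dr; sc <- sc + dc
  }
  mirror <- stats::runif(1) < p_mirror
  if (mirror) sc <- nc + 1 - sc
  identity_map <- identical(sr, rows) && identical(sc, cols)
  if (identity_map) {
    return(list(image = image, label = label))
  }
  img2 <- warp_bilinear(image, sr, sc)
  lab2 <- matrix(as.integer(warp_bilinear(label, sr, sc) >= 0.5), nr, nc)
  list(image = img2, label = lab2)
}

# ---- training ---------------------------------------------------------------

#' Train the segmenter
#'
#' Minimizes the pixel-wise softmax cross-entropy between predictions and
#' binary labels with Adam (learning rate and weight decay from the config;
#' decay applies to convolution weights). Each iteration draws a random
#' mini-batch, augments it, and takes one optimizer step. All randomness is
#' governed by the config seed, so identical calls give identical weights.
#'
#' @param pairs List of training pairs, each `list(image =, label =)` with
#'   the image already normalized and the label strictly binary.
#' @param config A [network_config()].
#' @param augment_pairs Apply geometric augmentation each draw (default TRUE).
#' @param verbose Print loss every 50 iterations.
#' @return A trained `segnet`; `meta$loss_log` holds the per-iteration loss.
#' @export
train <- function(pairs, config, augment_pairs = TRUE, verbose = FALSE) {
  if (length(pairs) == 0L) stop("empty training set")
  for (p in pairs) {
    stopifnot(all(dim(p$image) == config$input_size),
              all(p$label %in% c(0L, 1L)))
  }
  net <- build_network(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed + 1L)
  m <- v <- lapply(net$params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  H <- config$input_size
  loss_log <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    take <- sample.int(length(pairs), min(config$batch_size, length(pairs)),
                       replace = length(pairs) < config$batch_size)
    X <- array(0, c(H, H, length(take), 1L))
    L <- array(0L, c(H, H, length(take)))
    for (bi in seq_along(take)) {
      pr <- pairs[[take[bi]]]
      if (augment_pairs) pr <- augment(pr$image, pr$label)
      X[, , bi, 1L] <- pr$image
      L[, , bi] <- pr$label
    }
    fw <- .net_fwd(net, X, training = TRUE)
    net$state <- fw$state
    probs <- .softmax2(fw$logits)
    npix <- H * H * length(take)
    p_true <- ifelse(L == 1L, probs[, , , 2L], probs[, , , 1L])
    loss_log[it] <- -mean(log(pmax(p_true, 1e-12)))
    dlogits <- probs
    dlogits[, , , 1L] <- (probs[, , , 1L] - (L == 0L)) / npix
    dlogits[, , , 2L] <- (probs[, , , 2L] - (L == 1L)) / npix
    grads <- .net_bwd(net, fw$caches, dlogits)
    for (nm in names(net$params)) {
      g <- grads[[nm]]
      if (grepl("\\.K$", nm)) g <- g + config$weight_decay * net$params[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
      mhat <- m[[nm]] / (1 - b1^it)
      vhat <- v[[nm]] / (1 - b2^it)
      net$params[[nm]] <- net$params[[nm]] -
        config$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    if (verbose && it %% 50 == 0) {
      message(sprintf("iteration %d: loss %.4f", it, loss_log[it]))
    }
  }
  # batch-norm recalibration: the running statistics accumulated during
  # training reflect dropout and augmentation; refresh them with forward
  # passes over clean batches, dropout off, then freeze for inference
  p_save <- net$config$dropout_p
  net$config$dropout_p <- 0
  for (it in seq_len(25L)) {
    take <- sample.int(length(pairs), min(config$batch_size, length(pairs)),
                       replace = length(pairs) < config$batch_size)
    X <- array(0, c(H, H, length(take), 1L))
    for (bi in seq_along(take)) X[, , bi, 1L] <- pairs[[take[bi]]]$image
    net$state <- .net_fwd(net, X, training = TRUE)$state
  }
  net$config$dropout_p <- p_save
  net$meta$iterations_trained <- config$iterations
  net$meta$final_loss <- loss_log[config$iterations]
  net$meta$loss_log <- loss_log
  net
}

#' Save / load network weights
#'
#' Weights, batch-norm statistics and the producing config are serialized
#' together so a loaded network reproduces identical predictions.
#'
#' @param net A `segnet`.
#' @param path File path.
#' @return `load_weights` returns the `segnet`.
#' @export
save_weights <- function(net, path) {
  stopifnot(inherits(net, "segnet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "segnet"))
  net
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("segnet: depth %d, base %d, input %d px, %s parameters, %d iterations trained\n",
              x$config$depth, x$config$base_kernels, x$config$input_size,
              format(count_parameters(x), big.mark = ","),
              x$meta$iterations_trained))
  invisible(x)
}
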