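test_that("intensity normalization yields zero mean and unit SD", {
  set.seed(2)
  img <- matrix(runif(64 * 64, 10, 500), 64, 64)
  z <- normalize_intensity(img)
  expect_lt(abs(mean(z)), 1e-6)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  # idempotent on already-normalized input, affine-invariant
  expect_equal(normalize_intensity(z), z, tolerance = 1e-9)
  expect_equal(normalize_intensity(2 * z + 5), z, tolerance = 1e-9)
  expect_error(normalize_intensity(matrix(3, 8, 8)), "constant")
})

test_that("network output is a per-pixel softmax of the right shape", {
  cfg <- network_config("tiny", seed = 4)
  net <- build_network(cfg)
  set.seed(6)
  img <- normalize_intensity(matrix(rnorm(64 * 64), 64, 64))
  p <- predict_probs(img, net)
  expect_equal(dim(p), c(64, 64, 2))
  expect_true(all(abs(p[, , 1] + p[, , 2] - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("inference is deterministic and respects the tie rule", {
  cfg <- network_config("tiny", seed = 4)
  net <- build_network(cfg)
  set.seed(6)
  img <- normalize_intensity(matrix(rnorm(64 * 64), 64, 64))
  expect_identical(predict_probs(img, net), predict_probs(img, net))
  expect_identical(segment(img, net), segment(img, net))
  # the tie rule: equal probabilities resolve to background, so an untrained
  # symmetric head cannot label a pixel whose channels are exactly equal
  m <- segment(img, net)
  p <- predict_probs(img, net)
  ties <- p[, , 1] == p[, , 2]
  if (any(ties)) expect_true(all(m[ties] == 0L))
  expect_error(segment(matrix(0, 32, 32), net), "64")
})

test_that("network presets have the expected scale", {
  expect_error(network_config(NULL, input_size = 60, depth = 3,
                              base_kernels = 8, dropout_p = 0.5),
               "divisible")
  n_tiny <- count_parameters(network_config("tiny"))
  expect_lt(n_tiny, 1e5)
  n_full <- count_parameters(network_config("full_scale"))
  expect_lt(abs(n_full - 9e6) / 9e6, 0.2)
})

test_that("augmentation applies paired transforms and keeps labels binary", {
  pr <- make_training_pair(21)
  # all transforms off: identity
  set.seed(1)
  out0 <- augment(pr$image, pr$label, p_translate = 0, p_mirror = 0,
                  p_elastic = 0)
  expect_identical(out0$image, pr$image)
  expect_identical(out0$label, pr$label)
  # mirror only: exact flip of both members
  set.seed(1)
  outm <- augment(pr$image, pr$label, p_translate = 0, p_mirror = 1,
                  p_elastic = 0)
  expect_equal(outm$image, pr$image[, ncol(pr$image):1], tolerance = 1e-9)
  expect_identical(outm$label, pr$label[, ncol(pr$label):1])
  expect_true(all(outm$label %in% c(0L, 1L)))
  # full augmentation keeps labels binary and shapes intact
  set.seed(2)
  for (i in 1:10) {
    out <- augment(pr$image, pr$label)
    expect_equal(dim(out$image), dim(pr$image))
    expect_true(all(out$label %in% c(0L, 1L)))
  }
})

test_that("translation fires at its nominal 0.95 probability", {
  # binomial check: count how often augmentation changes the image over many
  # draws; a fired translation leaves the image unchanged only when both
  # whole-pixel shifts draw 0, probability 1/(2*max_shift + 1)^2
  pr <- list(image = matrix(rnorm(64), 8, 8),
             label = matrix(0L, 8, 8))
  pr$label[3:5, 3:5] <- 1L
  set.seed(99)
  n <- 2000
  fired <- logical(n)
  for (i in 1:n) {
    out <- augment(pr$image, pr$label, p_mirror = 0, p_elastic = 0,
                   max_shift = 3)
    fired[i] <- !identical(out$image, pr$image)
  }
  p_changed <- 0.95 * (1 - 1 / 49)
  expect_lt(abs(sum(fired) - n * p_changed),
            3 * sqrt(n * p_changed * (1 - p_changed)) + 1)
})

test_that("training is seeded-deterministic and decreases the loss", {
  pairs <- lapply(1:10, make_training_pair)
  cfg <- network_config("tiny", iterations = 25, batch_size = 4, seed = 13)
  n1 <- train(pairs, cfg)
  expect_lt(mean(tail(n1$meta$loss_log, 5)), mean(head(n1$meta$loss_log, 5)))
  n2 <- train(pairs, cfg)
  expect_identical(n1$meta$final_loss, n2$meta$final_loss)
  expect_identical(n1$params, n2$params)
  expect_error(train(list(), cfg), "empty")
})

test_that("weights round-trip through serialization with identical output", {
  pairs <- lapply(1:4, make_training_pair)
  cfg <- network_config("tiny", iterations = 5, batch_size = 2, seed = 23)
  net <- train(pairs, cfg)
  f <- tempfile(fileext = ".rds")
  save_weights(net, f)
  net2 <- load_weights(f)
  img <- pairs[[1]]$image
  expect_identical(segment(img, net), segment(img, net2))
  unlink(f)
})

test_that("analytic gradients match central finite differences", {
  cfg <- network_config(NULL, input_size = 16, depth = 2, base_kernels = 3,
                        dropout_p = 0, iterations = 1, batch_size = 2,
                        seed = 3)
  net <- build_network(cfg)
  set.seed(9)
  X <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  L <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  loss_fn <- function(net) {
    fw <- cardiot1:::.net_fwd(net, X, training = TRUE)
    probs <- cardiot1:::.softmax2(fw$logits)
    p_true <- ifelse(L == 1L, probs[, , , 2], probs[, , , 1])
    -mean(log(pmax(p_true, 1e-12)))
  }
  fw <- cardiot1:::.net_fwd(net, X, training = TRUE)
  probs <- cardiot1:::.softmax2(fw$logits)
  npix <- 16 * 16 * 2
  dl <- probs
  dl[, , , 1] <- (probs[, , , 1] - (L == 0)) / npix
  dl[, , , 2] <- (probs[, , , 2] - (L == 1)) / npix
  grads <- cardiot1:::.net_bwd(net, fw$caches, dl)
  eps <- 1e-5
  set.seed(31)
  for (nm in c("stem.K", "enc2b.K", "dec1a.K", "head.K", "enc1a.gamma",
               "dec1b.beta")) {
    i <- sample(length(net$params[[nm]]), 1)
    np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
    nn <- net; nn$params[[nm]][i] <- nn$params[[nm]][i] - eps
    num <- (loss_fn(np) - loss_fn(nn)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("analytic gradient of", nm))
  }
})
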