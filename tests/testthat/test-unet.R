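# Small input sizes keep these structural and smoke tests fast; the
# scaled-up segmentation recovery runs in test-acceptance.R.

tiny_cfg <- function(...) {
  unet_config(input_size = c(32, 32), base_filters = 4, depth = 2,
              bottleneck_filters = 16, seed = 5, ...)
}

test_that("parameter count is independent of the input size", {
  counts <- vapply(c(64, 128, 256), function(s)
    unet_param_count(build_unet(unet_config(input_size = c(s, s)))),
    numeric(1))
  expect_equal(length(unique(counts)), 1)
  expect_error(unet_config(input_size = c(100, 100)), "divisible")
})

test_that("first contracting block has the closed-form parameter count", {
  m <- build_unet(unet_config())
  # (3^2 * 1 + 1) * 16 + (3^2 * 16 + 1) * 16 = 160 + 2320
  n1 <- length(m$params$enc[[1]]$w1) + length(m$params$enc[[1]]$b1) +
    length(m$params$enc[[1]]$w2) + length(m$params$enc[[1]]$b2)
  expect_equal(n1, 2480)
})

test_that("forward pass returns probabilities of the input shape", {
  m <- build_unet(tiny_cfg())
  out <- segment(m, matrix(0, 32, 32))
  expect_equal(dim(out), c(32, 32))
  expect_true(all(out %in% c(0, 1)))
  expect_error(segment(m, matrix(0, 16, 16)), "size")
  # untrained but seeded: deterministic output
  img <- matrix(round(255 * stats::runif(32 * 32)), 32, 32)
  expect_identical(segment(m, img), segment(m, img))
})

test_that("gabor-initialised first block differs from plain init and is 3x3", {
  g <- build_unet(tiny_cfg(gabor_first_block = TRUE))
  p <- build_unet(tiny_cfg(gabor_first_block = FALSE))
  expect_false(identical(g$params$enc[[1]]$w1, p$params$enc[[1]]$w1))
  expect_identical(g$params$enc[[2]], p$params$enc[[2]])
  expect_equal(dim(g$params$enc[[1]]$w1), c(3, 3, 1, 4))
})

test_that("analytic U-Net gradients match numerical differentiation", {
  ns <- asNamespace("wristvein")
  cfg <- unet_config(input_size = c(16, 16), base_filters = 2, depth = 2,
                     bottleneck_filters = 8, dropout_rate = 1e-12, seed = 11)
  m <- build_unet(cfg)
  set.seed(5)
  x <- array(stats::runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array((stats::runif(16 * 16 * 2) > 0.8) * 1, dim = c(16, 16, 1, 2))
  fw <- ns$unet_forward(m$params, cfg, x, training = FALSE, keep = TRUE)
  dl <- ns$dice_loss_batch(fw$prob, y)
  g <- ns$unet_backward(m$params, cfg, fw$cache, dl$grad)
  lossfn <- function(params)
    ns$dice_loss_batch(ns$unet_forward(params, cfg, x)$prob, y)$loss
  # check a handful of coordinates in representative tensors; the forward
  # pass is single precision, so compare with a mixed abs/rel band
  check <- function(get, set, grad) {
    p0 <- get(m$params)
    set.seed(1)
    for (i in sample(length(p0), min(3, length(p0)))) {
      eps <- 1e-3
      pp <- p0; pp[i] <- pp[i] + eps; l1 <- lossfn(set(m$params, pp))
      pp <- p0; pp[i] <- pp[i] - eps; l2 <- lossfn(set(m$params, pp))
      num <- (l1 - l2) / (2 * eps)
      expect_lt(abs(grad[i] - num), 0.05 * max(abs(grad[i]) + abs(num), 0.01))
    }
  }
  check(function(p) p$enc[[1]]$w1,
        function(p, v) { p$enc[[1]]$w1 <- v; p }, g$enc[[1]]$w1)
  check(function(p) p$bott$w2,
        function(p, v) { p$bott$w2 <- v; p }, g$bott$w2)
  check(function(p) p$dec[[2]]$wc,
        function(p, v) { p$dec[[2]]$wc <- v; p }, g$dec[[2]]$wc)
  check(function(p) p$out$w,
        function(p, v) { p$out$w <- v; p }, g$out$w)
})

test_that("a two-image one-epoch training run produces a finite report", {
  cfg <- tiny_cfg(epochs = 1, batch_size = 2)
  set.seed(31)
  imgs <- replicate(2, matrix(round(255 * stats::runif(1024)), 32, 32),
                    simplify = FALSE)
  msks <- replicate(2, matrix(stats::rbinom(1024, 1, 0.2), 32, 32),
                    simplify = FALSE)
  fit <- train_unet(build_unet(cfg), imgs, msks, cfg = cfg)
  expect_equal(nrow(fit$report), 1)
  expect_true(is.finite(fit$report$train_loss))
  expect_error(train_unet(build_unet(cfg), list(), list(), cfg = cfg), "empty")
})

test_that("seeded training is exactly reproducible", {
  cfg <- tiny_cfg(epochs = 2, batch_size = 2)
  set.seed(77)
  imgs <- replicate(4, matrix(round(255 * stats::runif(1024)), 32, 32),
                    simplify = FALSE)
  msks <- replicate(4, matrix(stats::rbinom(1024, 1, 0.2), 32, 32),
                    simplify = FALSE)
  f1 <- train_unet(build_unet(cfg), imgs, msks, cfg = cfg)
  f2 <- train_unet(build_unet(cfg), imgs, msks, cfg = cfg)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training reduces the loss on a learnable toy problem", {
  cfg <- unet_config(input_size = c(64, 64), base_filters = 4, depth = 2,
                     bottleneck_filters = 16, seed = 5, epochs = 8,
                     batch_size = 4, split = 0.75)
  ds <- synthesize_dataset(4, 1, seed = 55, dim = c(64, 64))
  imgs <- ds$images
  msks <- ds$masks
  fit <- train_unet(build_unet(cfg), imgs, msks,
                    subjects = paste(ds$registry$subject_id, ds$registry$wrist),
                    cfg = cfg)
  expect_lt(utils::tail(fit$report$train_loss, 1), fit$report$train_loss[1])
})
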