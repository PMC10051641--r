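small_cnn <- function(...) {
  cnn_matcher_config(input_size = c(32, 32), pathway_filters = c(4, 8),
                     merged_filters = c(8, 8), dense_units = 16, seed = 17, ...)
}

test_that("the default graph reproduces the published architecture counts", {
  aud <- cnn_param_audit(cnn_matcher_config())
  expect_identical(aud$pathway_params, 18816)
  expect_identical(aud$flatten_length, 32768)
  expect_identical(aud$total_params, 18291201)
  # and the built weight arrays agree with the closed-form audit
  m <- build_cnn_matcher(cnn_matcher_config())
  expect_identical(cnn_param_count(m), 18291201)
  pa <- m$params$path_a
  expect_identical(length(pa$w1) + length(pa$b1) + length(pa$w2) + length(pa$b2),
                   18816L)
})

test_that("the audit table sums layerwise (k^2 C_in + 1) C_out counts", {
  aud <- cnn_param_audit(cnn_matcher_config())
  expect_equal(aud$table$params[1], (9 * 1 + 1) * 32)
  expect_equal(aud$table$params[2], (9 * 32 + 1) * 64)
  expect_equal(aud$table$params[3], (9 * 128 + 1) * 256)
  expect_equal(aud$table$params[4], (9 * 256 + 1) * 512)
  expect_equal(aud$table$params[5], (32768 + 1) * 512)
  expect_equal(aud$table$params[6], 513)
  expect_equal(2 * aud$pathway_params + sum(aud$table$params[3:6]),
               aud$total_params)
})

test_that("audit counts track the config, not hard-coded constants", {
  cfg <- small_cnn()
  aud <- cnn_param_audit(cfg)
  expect_identical(cnn_param_count(build_cnn_matcher(cfg)), aud$total_params)
  expect_equal(aud$flatten_length, 2 * 2 * 8)
  expect_error(cnn_matcher_config(input_size = c(40, 40)), "divisible")
})

test_that("match probability is in [0, 1] and deterministic at inference", {
  m <- build_cnn_matcher(small_cnn())
  set.seed(18)
  a <- matrix(stats::rbinom(1024, 1, 0.2), 32, 32)
  b <- matrix(stats::rbinom(1024, 1, 0.2), 32, 32)
  p <- match_probability_cnn(m, a, b)
  expect_true(p >= 0 && p <= 1)
  expect_identical(p, match_probability_cnn(m, a, b))
  expect_error(match_probability_cnn(m, a, b[1:16, ]), "differ")
})

test_that("analytic CNN-matcher gradients match numerical differentiation", {
  ns <- asNamespace("wristvein")
  cfg <- cnn_matcher_config(input_size = c(16, 16), pathway_filters = c(3, 4),
                            merged_filters = c(5, 6), dense_units = 7,
                            dropout = 1e-12, seed = 5)
  m <- build_cnn_matcher(cfg)
  set.seed(9)
  xa <- array((stats::runif(512) > 0.7) * 1, dim = c(16, 16, 1, 2))
  xb <- array((stats::runif(512) > 0.7) * 1, dim = c(16, 16, 1, 2))
  y <- c(1, 0)
  loss <- function(params) {
    p <- pmin(pmax(ns$cnn_forward(params, cfg, xa, xb)$p, 1e-7), 1 - 1e-7)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- ns$cnn_forward(m$params, cfg, xa, xb, training = TRUE, keep = TRUE)
  g <- ns$cnn_backward(m$params, cfg, fw$cache, (fw$p - y) / 2)
  for (layer in list(c("path_a", "w1"), c("path_b", "w2"), c("m1", "w"),
                     c("d1", "w"), c("d2", "w"))) {
    p0 <- m$params[[layer[1]]][[layer[2]]]
    ga <- g[[layer[1]]][[layer[2]]]
    set.seed(2)
    for (i in sample(length(p0), 3)) {
      eps <- 1e-4
      mod <- m$params
      mod[[layer[1]]][[layer[2]]][i] <- p0[i] + eps; l1 <- loss(mod)
      mod[[layer[1]]][[layer[2]]][i] <- p0[i] - eps; l2 <- loss(mod)
      num <- (l1 - l2) / (2 * eps)
      expect_lt(abs(ga[i] - num), 0.05 * max(abs(ga[i]) + abs(num), 1e-3))
    }
  }
})

test_that("a four-pair smoke run trains to finite loss, reproducibly", {
  cfg <- small_cnn(epochs = 2, batch_size = 2)
  ds <- fixture_dataset()
  masks <- lapply(ds$masks, resize_mask, target = c(32, 32))
  pr <- build_pairs(ds$registry, 0.8, seed = 3)
  tp <- pr$train[1:4, ]
  f1 <- train_cnn_matcher(build_cnn_matcher(cfg), masks, tp, pr$test, cfg)
  expect_equal(nrow(f1$report), 2)
  expect_true(all(is.finite(f1$report$train_loss)))
  f2 <- train_cnn_matcher(build_cnn_matcher(cfg), masks, tp, pr$test, cfg)
  expect_identical(f1$report, f2$report)
  expect_error(train_cnn_matcher(build_cnn_matcher(cfg), masks, tp[0, ],
                                 pr$test, cfg), "empty")
})

test_that("training separates genuine from impostor scores on synthetic data", {
  cfg <- small_cnn(epochs = 10, batch_size = 8, lr = 1e-3)
  ds <- fixture_dataset()
  masks <- lapply(ds$masks, resize_mask, target = c(32, 32))
  pr <- build_pairs(ds$registry, 0.7, seed = 19)
  fit <- train_cnn_matcher(build_cnn_matcher(cfg), masks, pr$train, pr$test,
                           cfg)
  ns <- asNamespace("wristvein")
  pv <- ns$cnn_pair_probs(fit$model$params, cfg, masks, pr$train)
  gen <- pr$train$label == "genuine"
  expect_gt(mean(pv[gen]), mean(pv[!gen]))
  expect_lt(utils::tail(fit$report$train_loss, 1), fit$report$train_loss[1])
})
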