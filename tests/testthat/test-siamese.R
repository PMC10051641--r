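small_siam <- function(...) {
  siamese_config(input_size = c(32, 32), conv_filters = 8, dropout = 0.25,
                 seed = 13, ...)
}

test_that("the sub-network always embeds into length 128 by default", {
  for (s in c(64, 128)) {
    m <- build_subnetwork(siamese_config(input_size = c(s, s), conv_filters = 4))
    e <- embed_mask(m, matrix(1, s, s))
    expect_length(e, 128)
    expect_true(all(is.finite(e)))
  }
  expect_error(siamese_config(input_size = c(30, 30)), "divisible")
})

test_that("conv layers carry the closed-form parameter counts", {
  m <- build_subnetwork(siamese_config(input_size = c(64, 64)))
  # first conv 1 -> 64: (9 * 1 + 1) * 64; later convs 64 -> 64: (9 * 64 + 1) * 64
  sz <- function(b) length(b$w) + length(b$b)
  expect_equal(sz(m$params$blocks[[1]]), 640)
  expect_equal(sz(m$params$blocks[[2]]), 36928)
  expect_equal(sz(m$params$blocks[[3]]), 36928)
})

test_that("weight sharing: identical masks embed identically, swaps swap", {
  m <- build_subnetwork(small_siam())
  set.seed(3)
  a <- matrix(stats::rbinom(1024, 1, 0.2), 32, 32)
  b <- matrix(stats::rbinom(1024, 1, 0.2), 32, 32)
  pr <- embed_pair(m, a, b)
  pr_swapped <- embed_pair(m, b, a)
  expect_identical(pr$e_a, pr_swapped$e_b)
  expect_identical(pr$e_b, pr_swapped$e_a)
  expect_identical(embed_mask(m, a), embed_mask(m, a))
  expect_equal(embed_pair(m, a, a)$distance, 0)
})

test_that("embedding distances satisfy metric axioms", {
  m <- build_subnetwork(small_siam())
  set.seed(4)
  masks <- replicate(4, matrix(stats::rbinom(1024, 1, 0.3), 32, 32),
                     simplify = FALSE)
  for (i in 1:3) {
    d_ij <- embed_pair(m, masks[[i]], masks[[i + 1]])$distance
    d_ji <- embed_pair(m, masks[[i + 1]], masks[[i]])$distance
    expect_equal(d_ij, d_ji)
    expect_gte(d_ij, 0)
    expect_equal(embed_pair(m, masks[[i]], masks[[i]])$distance, 0)
  }
})

test_that("contrastive loss matches a termwise scalar oracle", {
  oracle <- function(d, y, M) {
    tot <- 0
    for (i in seq_along(d)) {
      tot <- tot + if (y[i] == 0) d[i]^2 else max(M - d[i], 0)^2
    }
    tot / length(d)
  }
  set.seed(14)
  for (k in 1:1000) {
    n <- sample(1:16, 1)
    d <- stats::runif(n, 0, 2)
    y <- stats::rbinom(n, 1, 0.5)
    M <- stats::runif(1, 0.5, 2)
    expect_equal(contrastive_loss(d, y, M), oracle(d, y, M))
  }
  expect_equal(contrastive_loss(0, 0, 1), 0)   # perfect genuine pair
  expect_equal(contrastive_loss(0, 1, 1), 1)   # colliding impostors
  expect_equal(contrastive_loss(c(1, 1.5), c(1, 1), 1), 0) # separated impostors
  expect_error(contrastive_loss(-0.1, 0, 1), "non-negative")
})

test_that("threshold decisions are inclusive at the boundary and monotone", {
  expect_true(decide(0, 0.5)$verdict)
  expect_true(decide(0.5, 0.5)$verdict)
  expect_false(decide(0.50001, 0.5)$verdict)
  verdicts <- vapply(seq(0, 2, 0.1), function(d) decide(d, 0.7)$verdict,
                     logical(1))
  expect_true(all(diff(verdicts) <= 0))  # never flips reject -> accept
  d <- decide(0.3, 1)
  expect_equal(d$score, 1 / (1 + exp(-0.3)))
})

test_that("a four-pair two-epoch smoke run is finite and reproducible", {
  cfg <- small_siam(epochs = 2, batch_size = 2)
  ds <- fixture_dataset()
  reg <- ds$registry
  masks <- lapply(ds$masks, resize_mask, target = c(32, 32))
  pr <- build_pairs(reg, split_frac = 0.8, seed = 3)
  tp <- pr$train[1:4, ]
  f1 <- train_siamese(build_subnetwork(cfg), masks, tp, pr$test, cfg)
  expect_equal(nrow(f1$report), 2)
  expect_true(all(is.finite(f1$report$train_loss)))
  f2 <- train_siamese(build_subnetwork(cfg), masks, tp, pr$test, cfg)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$model$params, f2$model$params)
  expect_error(train_siamese(build_subnetwork(cfg), masks, tp[0, ], pr$test,
                             cfg), "empty")
})

test_that("training shrinks genuine distances relative to impostors", {
  cfg <- small_siam(epochs = 6, batch_size = 4, lr = 1e-3)
  ds <- fixture_dataset()
  masks <- lapply(ds$masks, resize_mask, target = c(32, 32))
  pr <- build_pairs(ds$registry, split_frac = 0.7, seed = 8)
  ns <- asNamespace("wristvein")
  m0 <- build_subnetwork(cfg)
  sep_ratio <- function(model) {
    d <- ns$siamese_distances(model$params, model$bn_state, cfg, masks,
                              pr$train)
    gen <- pr$train$label == "genuine"
    mean(d[gen]) / mean(d[!gen])
  }
  r0 <- sep_ratio(m0)
  fit <- train_siamese(m0, masks, pr$train, pr$test, cfg)
  # genuine distances shrink relative to impostor distances on the pairs
  # the loss optimises, and the classes end up separated
  expect_lt(sep_ratio(fit$model), r0)
  last <- fit$report[nrow(fit$report), ]
  expect_gt(last$mean_impostor_dist, last$mean_genuine_dist)
  expect_false(is.null(fit$model$cfg$decision_threshold))
})
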