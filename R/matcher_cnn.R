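# Two-input CNN matcher. Each mask follows its own pathway of two blocks
# (conv 3x3 + ReLU + maxpool 2x2 + dropout; 32 then 64 filters, the two
# pathways are identical in shape but not weight-shared). The pathway
# outputs are concatenated along channels (128) and pass two more blocks
# (256, 512 filters), are flattened, reduced by a dense ReLU layer to 512,
# and a final dense sigmoid unit outputs the probability that the pair is
# genuine. Trained with binary cross entropy.
#
# At the default 128 x 128 input the constructed graph reproduces the
# matcher's published architecture arithmetic exactly: 18,816 trainable
# parameters per pathway, a flattened length of 8*8*512 = 32,768, and
# 18,291,201 trainable parameters in total.

#' CNN matcher configuration
#'
#' @param input_size mask size (H, W), divisible by 16 (four poolings).
#'   Masks segmented at 256 x 256 are downsampled to the default 128 x 128.
#' @param pathway_filters filters of the two per-pathway blocks (32, 64).
#' @param merged_filters filters of the two post-merge blocks (256, 512).
#' @param dropout dropout rate after every pooling and the first dense (0.25).
#' @param dense_units width of the penultimate dense layer (512).
#' @param lr Adam learning rate (0.0003).
#' @param batch_size pairs per gradient step (32).
#' @param epochs training epochs (200).
#' @param seed seed for weight init and shuffling.
#' @return A `cnn_matcher_config` list.
#' @export
cnn_matcher_config <- function(input_size = c(128, 128),
                               pathway_filters = c(32, 64),
                               merged_filters = c(256, 512), dropout = 0.25,
                               dense_units = 512, lr = 3e-4, batch_size = 32,
                               epochs = 200, seed = 42) {
  if (any(input_size %% 16 != 0))
    stop("input_size must be divisible by 16 (four 2x2 poolings)")
  structure(list(input_size = as.integer(input_size),
                 pathway_filters = pathway_filters,
                 merged_filters = merged_filters, dropout = dropout,
                 dense_units = dense_units, lr = lr, batch_size = batch_size,
                 epochs = epochs, seed = seed),
            class = "cnn_matcher_config")
}

#' Build the two-pathway CNN matcher
#'
#' @param cfg a [cnn_matcher_config()].
#' @return A `cnn_matcher_model`.
#' @export
build_cnn_matcher <- function(cfg = cnn_matcher_config()) {
  pf <- cfg$pathway_filters; mf <- cfg$merged_filters
  flat <- prod(cfg$input_size / 16) * mf[2]
  with_seed(cfg$seed, {
    path <- function() list(w1 = init_conv(3, 1, pf[1]), b1 = rep(0, pf[1]),
                            w2 = init_conv(3, pf[1], pf[2]), b2 = rep(0, pf[2]))
    params <- list(
      path_a = path(), path_b = path(),
      m1 = list(w = init_conv(3, 2 * pf[2], mf[1]), b = rep(0, mf[1])),
      m2 = list(w = init_conv(3, mf[1], mf[2]), b = rep(0, mf[2])),
      d1 = list(w = init_dense(flat, cfg$dense_units),
                b = rep(0, cfg$dense_units)),
      d2 = list(w = init_dense(cfg$dense_units, 1), b = 0)
    )
    structure(list(cfg = cfg, params = params), class = "cnn_matcher_model")
  })
}

#' Closed-form parameter audit of the CNN matcher
#'
#' Counts every layer as `(k^2 C_in + 1) C_out` (convolutions) or
#' `(n_in + 1) n_out` (dense), independently of the constructed weight
#' arrays, and reports the per-pathway subtotal, flatten length and total.
#'
#' @param cfg a [cnn_matcher_config()].
#' @return list with `table` (per-layer data.frame), `pathway_params`,
#'   `flatten_length`, `total_params`.
#' @export
cnn_param_audit <- function(cfg = cnn_matcher_config()) {
  pf <- cfg$pathway_filters; mf <- cfg$merged_filters
  flat <- prod(cfg$input_size / 16) * mf[2]
  tab <- data.frame(
    layer = c("pathway_conv1", "pathway_conv2", "merged_conv1", "merged_conv2",
              "dense1", "dense2"),
    params = c(conv_param_count(3, 1, pf[1]), conv_param_count(3, pf[1], pf[2]),
               conv_param_count(3, 2 * pf[2], mf[1]),
               conv_param_count(3, mf[1], mf[2]),
               (flat + 1) * cfg$dense_units, cfg$dense_units + 1)
  )
  pathway <- sum(tab$params[1:2])
  list(table = tab, pathway_params = pathway, flatten_length = flat,
       total_params = 2 * pathway + sum(tab$params[3:6]))
}

#' Trainable parameter count of a built CNN matcher
#' @param model a `cnn_matcher_model`.
#' @export
cnn_param_count <- function(model) count_params(model$params)

cnn_block_fw <- function(x, w, b, rate, training, pool = "max") {
  z <- conv_fw(x, w, b)
  a <- relu_fw(z)
  pl <- maxpool2_fw(a)
  dr <- dropout_fw(pl$y, rate, training)
  list(y = dr$y, x = x, a = a, idx = pl$idx, mask = dr$mask)
}

cnn_block_bw <- function(cache, w, rate, gy) {
  g <- dropout_bw(cache$mask, gy, rate)
  ga <- maxpool2_bw(cache$idx, g, dim(cache$a))
  gz <- relu_bw(cache$a, ga)
  conv_bw(cache$x, w, gz)
}

# Forward: xa, xb are H x W x 1 x N arrays of the two mask batches.
cnn_forward <- function(params, cfg, xa, xb, training = FALSE, keep = FALSE) {
  r <- cfg$dropout
  a1 <- cnn_block_fw(xa, params$path_a$w1, params$path_a$b1, r, training)
  a2 <- cnn_block_fw(a1$y, params$path_a$w2, params$path_a$b2, r, training)
  b1 <- cnn_block_fw(xb, params$path_b$w1, params$path_b$b1, r, training)
  b2 <- cnn_block_fw(b1$y, params$path_b$w2, params$path_b$b2, r, training)
  cc <- concat_ch(a2$y, b2$y)
  m1 <- cnn_block_fw(cc, params$m1$w, params$m1$b, r, training)
  m2 <- cnn_block_fw(m1$y, params$m2$w, params$m2$b, r, training)
  d <- dim(m2$y)
  flat <- matrix(m2$y, prod(d[1:3]), d[4])
  h1 <- relu_fw(crossprod(params$d1$w, flat) + params$d1$b)
  dr1 <- dropout_fw(h1, r, training)
  z2 <- as.numeric(crossprod(params$d2$w, dr1$y) + params$d2$b)
  p <- sigmoid(z2)
  cache <- NULL
  if (keep) cache <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, m1 = m1, m2 = m2,
                          flat = flat, flatdim = d, h1 = h1, drmask = dr1$mask,
                          h1d = dr1$y, p = p)
  list(p = p, cache = cache)
}

# Backward from dL/dz2 (the pre-sigmoid gradient, length N).
cnn_backward <- function(params, cfg, cache, gz2) {
  r <- cfg$dropout
  g <- list()
  g$d2 <- list(w = cache$h1d %*% matrix(gz2), b = sum(gz2))
  gh1d <- params$d2$w %*% matrix(gz2, 1)
  gh1 <- dropout_bw(cache$drmask, gh1d, r)
  gh1 <- relu_bw(cache$h1, gh1)
  g$d1 <- list(w = cache$flat %*% t(gh1), b = rowSums(gh1))
  gflat <- params$d1$w %*% gh1
  gm2 <- array(gflat, dim = cache$flatdim)
  bm2 <- cnn_block_bw(cache$m2, params$m2$w, r, gm2)
  g$m2 <- list(w = bm2$gw, b = bm2$gb)
  bm1 <- cnn_block_bw(cache$m1, params$m1$w, r, bm2$gx)
  g$m1 <- list(w = bm1$gw, b = bm1$gb)
  nf <- dim(cache$a2$y)[3]
  sp <- split_ch(bm1$gx, nf)
  ba2 <- cnn_block_bw(cache$a2, params$path_a$w2, r, sp[[1]])
  ba1 <- cnn_block_bw(cache$a1, params$path_a$w1, r, ba2$gx)
  g$path_a <- list(w1 = ba1$gw, b1 = ba1$gb, w2 = ba2$gw, b2 = ba2$gb)
  bb2 <- cnn_block_bw(cache$b2, params$path_b$w2, r, sp[[2]])
  bb1 <- cnn_block_bw(cache$b1, params$path_b$w1, r, bb2$gx)
  g$path_b <- list(w1 = bb1$gw, b1 = bb1$gb, w2 = bb2$gw, b2 = bb2$gb)
  g[c("path_a", "path_b", "m1", "m2", "d1", "d2")]
}

#' Match probability of a mask pair under the CNN matcher
#'
#' The output is the probability that the pair is genuine. The architecture
#' is not weight-shared across the merge, so the output is not guaranteed
#' symmetric in its inputs.
#'
#' @param model a `cnn_matcher_model`.
#' @param mask_a,mask_b `{0, 1}` matrices; resized (nearest neighbour) to the
#'   model input size if needed.
#' @return Probability in `[0, 1]`.
#' @export
match_probability_cnn <- function(model, mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask dimensions differ")
  sz <- model$cfg$input_size
  mask_a <- resize_mask(mask_a, sz); mask_b <- resize_mask(mask_b, sz)
  xa <- array(mask_a, dim = c(sz, 1, 1))
  xb <- array(mask_b, dim = c(sz, 1, 1))
  cnn_forward(model$params, model$cfg, xa, xb)$p
}

#' Train the CNN matcher with binary cross entropy
#'
#' @param model a `cnn_matcher_model`.
#' @param masks list of `{0, 1}` matrices (resized to the model input size
#'   internally).
#' @param train_pairs,val_pairs pair data.frames from [build_pairs()].
#' @param cfg a [cnn_matcher_config()]; defaults to the model's.
#' @param aug_cfg optional [augment_config()], redrawn every epoch.
#' @param verbose print per-epoch metrics.
#' @return list with `model`, `report` (per-epoch loss, val accuracy, F1),
#'   `epochs_run`.
#' @export
train_cnn_matcher <- function(model, masks, train_pairs, val_pairs,
                              cfg = model$cfg, aug_cfg = NULL,
                              verbose = FALSE) {
  if (nrow(train_pairs) == 0) stop("empty pair set")
  sz <- cfg$input_size
  masks <- lapply(masks, resize_mask, target = sz)
  params <- model$params
  opt <- adam_init(params)
  rep <- list()
  for (ep in seq_len(cfg$epochs)) {
    loss_ep <- 0; nb <- 0
    with_seed(derive_seed(cfg$seed, 51, ep), {
      ord <- sample(nrow(train_pairs))
      for (s in seq(1, length(ord), cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        B <- length(idx)
        ma <- lapply(train_pairs$row_a[idx], function(r) masks[[r]])
        mb <- lapply(train_pairs$row_b[idx], function(r) masks[[r]])
        if (!is.null(aug_cfg)) {
          ma <- lapply(ma, augment, cfg = aug_cfg)
          mb <- lapply(mb, augment, cfg = aug_cfg)
        }
        xa <- stack_batch(ma, seq_len(B))
        xb <- stack_batch(mb, seq_len(B))
        y <- as.numeric(train_pairs$label[idx] == "genuine")
        fw <- cnn_forward(params, cfg, xa, xb, training = TRUE, keep = TRUE)
        eps <- 1e-7
        p <- pmin(pmax(fw$p, eps), 1 - eps)
        loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
        gz2 <- (p - y) / B   # BCE gradient through the sigmoid
        grads <- cnn_backward(params, cfg, fw$cache, gz2)
        st <- adam_step(params, grads, opt, cfg$lr)
        params <- st$params; opt <- st$state
        loss_ep <- loss_ep + loss; nb <- nb + 1
      }
    })
    ev <- with_seed(derive_seed(cfg$seed, 52, ep), {
      vmasks <- masks
      if (!is.null(aug_cfg)) {
        vrows <- unique(c(val_pairs$row_a, val_pairs$row_b))
        for (r in vrows) vmasks[[r]] <- augment(masks[[r]], aug_cfg)
      }
      pv <- cnn_pair_probs(params, cfg, vmasks, val_pairs)
      genuine <- val_pairs$label == "genuine"
      list(acc = binary_accuracy(pv >= 0.5, genuine),
           f1 = f1_score(confusion_counts(pv >= 0.5, genuine)))
    })
    rep[[ep]] <- data.frame(epoch = ep, train_loss = loss_ep / nb,
                            val_accuracy = ev$acc, val_f1 = ev$f1)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f  F1 %.3f",
                      ep, loss_ep / nb, ev$acc, ev$f1))
  }
  list(model = structure(list(cfg = cfg, params = params),
                         class = "cnn_matcher_model"),
       report = do.call(rbind, rep), epochs_run = length(rep))
}

cnn_pair_probs <- function(params, cfg, masks, pairs, chunk = 32) {
  n <- nrow(pairs)
  p <- numeric(n)
  for (s in seq(1, n, chunk)) {
    idx <- s:min(s + chunk - 1, n)
    xa <- stack_batch(masks, pairs$row_a[idx])
    xb <- stack_batch(masks, pairs$row_b[idx])
    p[idx] <- cnn_forward(params, cfg, xa, xb)$p
  }
  p
}
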