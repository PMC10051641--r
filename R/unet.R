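# Modified U-Net for vein segmentation. Four contracting blocks of two
# 3 x 3 convolutions (ReLU) + 2 x 2 max pooling, filters doubling 16 -> 128;
# a two-convolution bottleneck; expansive blocks of a 3 x 3 stride-2
# up-convolution, skip concatenation, 10% dropout and a single 3 x 3
# convolution (dropout replaces the second convolution of the classic
# design); a final 1 x 1 convolution and sigmoid. No fully connected layers,
# so the trainable parameter count is independent of the input size. The
# first contracting block may be seeded with Gabor kernels (trainable).
# Training uses Dice loss with Adam, a plateau-triggered learning-rate
# schedule and early stopping.

#' U-Net configuration
#'
#' @param input_size (H, W), each divisible by `2^depth`; default 256 x 256.
#' @param base_filters filters in the first contracting block (16).
#' @param depth number of contracting blocks (4; filters double per block).
#' @param bottleneck_filters filters in the two bottleneck convolutions (256,
#'   continuing the doubling).
#' @param dropout_rate dropout in expansive blocks (0.10).
#' @param gabor_first_block seed the first block's kernels with a Gabor bank.
#' @param gabor Gabor parameters: orientations, wavelength (px), sigma.
#' @param lr0 initial Adam learning rate (0.0015).
#' @param plateau_patience epochs without val-loss improvement before the
#'   learning rate is multiplied by `plateau_factor` (10).
#' @param plateau_factor multiplier applied on plateau. The default is 0.1;
#'   a literal factor of 10 is also accepted but diverges in practice.
#' @param early_stop_patience epochs without val-Dice improvement before
#'   stopping (15).
#' @param epochs maximum training epochs (100).
#' @param batch_size images per gradient step (16).
#' @param split train fraction of the subject-level split (0.8).
#' @param seed seed for weight init, splits and shuffling.
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_size = c(256, 256), base_filters = 16, depth = 4,
                        bottleneck_filters = 256, dropout_rate = 0.10,
                        gabor_first_block = TRUE,
                        gabor = list(orientations = 4, wavelength = 4, sigma = 2),
                        lr0 = 0.0015, plateau_patience = 10, plateau_factor = 0.1,
                        early_stop_patience = 15, epochs = 100, batch_size = 16,
                        split = 0.8, seed = 42) {
  stopifnot(dropout_rate > 0, dropout_rate < 1, depth >= 1, base_filters >= 1)
  if (any(input_size %% 2^depth != 0))
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size), base_filters = base_filters,
                 depth = depth, bottleneck_filters = bottleneck_filters,
                 dropout_rate = dropout_rate, gabor_first_block = gabor_first_block,
                 gabor = gabor, lr0 = lr0, plateau_patience = plateau_patience,
                 plateau_factor = plateau_factor,
                 early_stop_patience = early_stop_patience, epochs = epochs,
                 batch_size = batch_size, split = split, seed = seed),
            class = "unet_config")
}

#' Build a U-Net segmentation model
#'
#' Weights are seeded Glorot-uniform (from `cfg$seed`); the first block is
#' optionally Gabor-initialised. The model maps `(H, W, 1)` inputs to
#' `(H, W, 1)` sigmoid outputs.
#'
#' @param cfg a [unet_config()].
#' @return A `unet_model` (config + parameter list).
#' @export
build_unet <- function(cfg = unet_config()) {
  f <- cfg$base_filters * 2^(seq_len(cfg$depth) - 1)
  with_seed(cfg$seed, {
    enc <- list()
    cin <- 1
    for (i in seq_len(cfg$depth)) {
      enc[[i]] <- list(w1 = init_conv(3, cin, f[i]), b1 = rep(0, f[i]),
                       w2 = init_conv(3, f[i], f[i]), b2 = rep(0, f[i]))
      cin <- f[i]
    }
    if (cfg$gabor_first_block)
      enc[[1]]$w1 <- gabor_bank(f[1], cfg$gabor$orientations,
                                cfg$gabor$wavelength, cfg$gabor$sigma)
    fb <- cfg$bottleneck_filters
    bott <- list(w1 = init_conv(3, cin, fb), b1 = rep(0, fb),
                 w2 = init_conv(3, fb, fb), b2 = rep(0, fb))
    dec <- list()
    cin <- fb
    for (i in rev(seq_len(cfg$depth))) {
      dec[[i]] <- list(wu = init_conv(3, cin, f[i]), bu = rep(0, f[i]),
                       wc = init_conv(3, 2 * f[i], f[i]), bc = rep(0, f[i]))
      cin <- f[i]
    }
    out <- list(w = init_conv(1, f[1], 1), b = 0)
    structure(list(cfg = cfg,
                   params = list(enc = enc, bott = bott, dec = dec, out = out)),
              class = "unet_model")
  })
}

#' Trainable parameter count of a U-Net model
#' @param model a `unet_model`.
#' @export
unet_param_count <- function(model) count_params(model$params)

# Forward pass. x: H x W x 1 x N in [0, 1]. Returns probabilities and, when
# `keep` is TRUE, the cache needed for backprop.
unet_forward <- function(params, cfg, x, training = FALSE, keep = FALSE) {
  cache <- list(x = x, enc = list(), dec = list())
  skips <- list()
  h <- x
  for (i in seq_len(cfg$depth)) {
    p <- params$enc[[i]]
    z1 <- conv_fw(h, p$w1, p$b1); a1 <- relu_fw(z1)
    z2 <- conv_fw(a1, p$w2, p$b2); a2 <- relu_fw(z2)
    pl <- maxpool2_fw(a2)
    if (keep) cache$enc[[i]] <- list(h = h, a1 = a1, a2 = a2, idx = pl$idx)
    skips[[i]] <- a2
    h <- pl$y
  }
  zb1 <- conv_fw(h, params$bott$w1, params$bott$b1); ab1 <- relu_fw(zb1)
  zb2 <- conv_fw(ab1, params$bott$w2, params$bott$b2); ab2 <- relu_fw(zb2)
  if (keep) cache$bott <- list(h = h, a1 = ab1, a2 = ab2)
  h <- ab2
  for (i in rev(seq_len(cfg$depth))) {
    p <- params$dec[[i]]
    up <- upsample2_zero_fw(h)
    zu <- conv_fw(up, p$wu, p$bu)           # linear up-convolution
    cc <- concat_ch(zu, skips[[i]])
    dr <- dropout_fw(cc, cfg$dropout_rate, training)
    zc <- conv_fw(dr$y, p$wc, p$bc); ac <- relu_fw(zc)
    if (keep) cache$dec[[i]] <- list(h = h, up = up, dr = dr$y, mask = dr$mask,
                                     ac = ac)
    h <- ac
  }
  zo <- conv_fw(h, params$out$w, params$out$b)
  prob <- sigmoid(zo)
  if (keep) { cache$hlast <- h; cache$prob <- prob }
  list(prob = prob, cache = cache)
}

# Backward pass given dL/dprob; returns gradient list congruent with params.
unet_backward <- function(params, cfg, cache, gprob) {
  prob <- cache$prob
  gz <- gprob * prob * (1 - prob)
  g <- list(enc = vector("list", cfg$depth), bott = NULL,
            dec = vector("list", cfg$depth), out = NULL)
  bo <- conv_bw(cache$hlast, params$out$w, gz)
  g$out <- list(w = bo$gw, b = bo$gb)
  gh <- bo$gx
  gskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {   # decoder blocks, shallowest first
    p <- params$dec[[i]]
    cc <- cache$dec[[i]]
    gzc <- relu_bw(cc$ac, gh)
    bc <- conv_bw(cc$dr, p$wc, gzc)
    gcc <- dropout_bw(cc$mask, bc$gx, cfg$dropout_rate)
    f_i <- dim(cc$ac)[3]
    sp <- split_ch(gcc, f_i)
    gskips[[i]] <- sp[[2]]
    bu <- conv_bw(cc$up, p$wu, sp[[1]])
    g$dec[[i]] <- list(wu = bu$gw, bu = bu$gb, wc = bc$gw, bc = bc$gb)
    gh <- upsample2_zero_bw(bu$gx)
  }
  cb <- cache$bott
  gzb2 <- relu_bw(cb$a2, gh)
  b2 <- conv_bw(cb$a1, params$bott$w2, gzb2)
  gzb1 <- relu_bw(cb$a1, b2$gx)
  b1 <- conv_bw(cb$h, params$bott$w1, gzb1)
  g$bott <- list(w1 = b1$gw, b1 = b1$gb, w2 = b2$gw, b2 = b2$gb)
  gh <- b1$gx
  for (i in rev(seq_len(cfg$depth))) {  # encoder blocks, deepest first
    p <- params$enc[[i]]
    ce <- cache$enc[[i]]
    ga2 <- maxpool2_bw(ce$idx, gh, dim(ce$a2)) + gskips[[i]]
    gz2 <- relu_bw(ce$a2, ga2)
    b2 <- conv_bw(ce$a1, p$w2, gz2)
    gz1 <- relu_bw(ce$a1, b2$gx)
    b1 <- conv_bw(ce$h, p$w1, gz1)
    g$enc[[i]] <- list(w1 = b1$gw, b1 = b1$gb, w2 = b2$gw, b2 = b2$gb)
    gh <- b1$gx
  }
  g
}

# Soft Dice loss over a batch (mean of per-image losses) and its gradient.
dice_loss_batch <- function(prob, y, eps = 1e-6) {
  N <- dim(prob)[4]
  loss <- 0
  gp <- array(0, dim = dim(prob))
  for (n in seq_len(N)) {
    p <- prob[, , 1, n]; yy <- y[, , 1, n]
    I <- sum(p * yy); S <- sum(p) + sum(yy) + eps
    loss <- loss + (1 - 2 * I / S)
    gp[, , 1, n] <- -(2 * yy * S - 2 * I) / S^2
  }
  list(loss = loss / N, grad = gp / N)
}

stack_batch <- function(lst, idx) {
  d <- dim(lst[[idx[1]]])
  x <- array(0, dim = c(d[1], d[2], 1, length(idx)))
  for (k in seq_along(idx)) x[, , 1, k] <- lst[[idx[k]]]
  x
}

#' Train a U-Net on images and masks
#'
#' Dice loss, Adam at `cfg$lr0`, learning rate multiplied by
#' `cfg$plateau_factor` after `cfg$plateau_patience` epochs without val-loss
#' improvement, early stop after `cfg$early_stop_patience` epochs without
#' val-Dice improvement. The train/validation split is at subject level
#' (sessions of one wrist never straddle the split), seeded from `cfg$seed`.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param images list of intensity matrices in `[0, 255]` at the model input
#'   size.
#' @param masks list of `{0, 1}` matrices (same order).
#' @param subjects character vector grouping images by subject for the split
#'   (defaults to one group per image).
#' @param cfg a [unet_config()]; defaults to the model's.
#' @param verbose print per-epoch metrics.
#' @return list with `model` (trained), `report` (per-epoch data.frame with
#'   train/val loss, val Dice, val pixel accuracy, lr), `epochs_run`.
#' @export
train_unet <- function(model, images, masks, subjects = NULL, cfg = model$cfg,
                       verbose = FALSE) {
  if (length(images) == 0) stop("empty dataset")
  if (length(images) != length(masks)) stop("images/masks length mismatch")
  if (is.null(subjects)) subjects <- as.character(seq_along(images))
  usub <- unique(subjects)
  tr_sub <- with_seed(cfg$seed, sample(usub, max(1, round(cfg$split * length(usub)))))
  tr <- which(subjects %in% tr_sub)
  va <- setdiff(seq_along(images), tr)
  if (length(va) == 0) va <- tr  # degenerate split: validate on train
  xin <- lapply(images, function(m) m / 255)
  params <- model$params
  opt <- adam_init(params)
  lr <- cfg$lr0
  best_loss <- Inf; best_dice <- -Inf; plat <- 0; stale <- 0
  rep <- list()
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 77, ep), sample(tr))
    tl <- 0; nb <- 0
    with_seed(derive_seed(cfg$seed, 88, ep), {
      for (s in seq(1, length(ord), cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        xb <- stack_batch(xin, idx); yb <- stack_batch(masks, idx)
        fw <- unet_forward(params, cfg, xb, training = TRUE, keep = TRUE)
        dl <- dice_loss_batch(fw$prob, yb)
        grads <- unet_backward(params, cfg, fw$cache, dl$grad)
        st <- adam_step(params, grads, opt, lr)
        params <- st$params; opt$m <- st$state$m; opt$v <- st$state$v
        opt$t <- st$state$t
        tl <- tl + dl$loss; nb <- nb + 1
      }
    })
    ev <- evaluate_unet(list(cfg = cfg, params = params), images[va], masks[va])
    rep[[ep]] <- data.frame(epoch = ep, train_loss = tl / nb,
                            val_loss = 1 - ev$dice, val_dice = ev$dice,
                            val_accuracy = ev$accuracy, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val dice %.4f  lr %g",
                      ep, tl / nb, ev$dice, lr))
    vloss <- 1 - ev$dice
    if (vloss < best_loss - 1e-5) { best_loss <- vloss; plat <- 0 }
    else {
      plat <- plat + 1
      if (plat >= cfg$plateau_patience) { lr <- lr * cfg$plateau_factor; plat <- 0 }
    }
    if (ev$dice > best_dice + 1e-5) { best_dice <- ev$dice; stale <- 0 }
    else if ((stale <- stale + 1) >= cfg$early_stop_patience) break
  }
  list(model = structure(list(cfg = cfg, params = params), class = "unet_model"),
       report = do.call(rbind, rep), epochs_run = length(rep))
}

#' Mean validation Dice and pixel accuracy of a U-Net on a dataset
#' @param model a `unet_model`.
#' @param images,masks lists as in [train_unet()].
#' @return list with `dice` (mean over images) and `accuracy` (pixelwise).
#' @export
evaluate_unet <- function(model, images, masks) {
  dsum <- 0; acc <- 0
  for (i in seq_along(images)) {
    pm <- segment(model, images[[i]])
    dsum <- dsum + dice_coefficient(pm, masks[[i]])
    acc <- acc + binary_accuracy(pm, masks[[i]])
  }
  list(dice = dsum / length(images), accuracy = acc / length(images))
}

#' Segment an image into a binary vein mask
#'
#' Forward pass (inference mode) and thresholding of the sigmoid map at 0.5.
#'
#' @param model a trained `unet_model`.
#' @param img intensity matrix in `[0, 255]` at the model's input size.
#' @return `{0, 1}` mask matrix.
#' @export
segment <- function(model, img) {
  if (!all(dim(img) == model$cfg$input_size))
    stop("image dimensions do not match the model input size; resize first")
  x <- array(img / 255, dim = c(dim(img), 1, 1))
  fw <- unet_forward(model$params, model$cfg, x, training = FALSE)
  (fw$prob[, , 1, 1] >= 0.5) * 1
}
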