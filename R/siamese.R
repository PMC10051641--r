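# Siamese verification network. One embedding sub-network (a single weight
# set) maps each binary vein mask to a length-128 feature vector:
#   BN0 -> 3 x [conv 3x3 (64) -> BN -> ReLU -> avgpool 2x2 -> dropout]
#       -> flatten -> BN -> dense 128 (ReLU).
# A pair is compared by the Euclidean distance between its two embeddings
# and trained with contrastive loss (margin M); the match decision is a
# threshold on the distance. A sigmoid of the distance is reported as a
# score for continuity with probability-style matchers, but it is monotone
# increasing in distance and takes no part in training or the decision.

#' Siamese matcher configuration
#'
#' @param input_size mask size (H, W), divisible by 8 (three poolings).
#' @param conv_filters filters per convolutional block (64).
#' @param embed_dim embedding length (128).
#' @param dropout dropout rate per block (0.25).
#' @param margin contrastive-loss margin M (1).
#' @param lr Adam learning rate (0.0003).
#' @param batch_size pairs per gradient step (16).
#' @param epochs training epochs (100).
#' @param decision_threshold distance cutoff tau; NULL until calibrated on
#'   validation pairs.
#' @param seed seed for weight init and shuffling.
#' @return A `siamese_config` list.
#' @export
siamese_config <- function(input_size = c(256, 256), conv_filters = 64,
                           embed_dim = 128, dropout = 0.25, margin = 1,
                           lr = 3e-4, batch_size = 16, epochs = 100,
                           decision_threshold = NULL, seed = 42) {
  if (any(input_size %% 8 != 0))
    stop("input_size must be divisible by 8 (three 2x2 poolings)")
  stopifnot(margin > 0, dropout >= 0, dropout < 1)
  structure(list(input_size = as.integer(input_size), conv_filters = conv_filters,
                 n_blocks = 3L, embed_dim = as.integer(embed_dim),
                 dropout = dropout, margin = margin, lr = lr,
                 batch_size = batch_size, epochs = epochs,
                 decision_threshold = decision_threshold, seed = seed),
            class = "siamese_config")
}

#' Build the shared embedding sub-network
#'
#' Both branches of the Siamese network are this one model: weight sharing is
#' by construction, there is a single parameter store.
#'
#' @param cfg a [siamese_config()].
#' @return A `siamese_model`.
#' @export
build_subnetwork <- function(cfg = siamese_config()) {
  f <- cfg$conv_filters
  flat <- prod(cfg$input_size / 8) * f
  with_seed(cfg$seed, {
    blocks <- list()
    sblocks <- list()
    cin <- 1
    for (i in seq_len(cfg$n_blocks)) {
      blocks[[i]] <- list(w = init_conv(3, cin, f), b = rep(0, f),
                          bn = bn_init(f))
      sblocks[[i]] <- bn_stats_init(f)
      cin <- f
    }
    # margin-matched head init: embedding distances must start below the
    # contrastive margin, otherwise max(M - d, 0) is zero everywhere and the
    # loss has no repulsive term (training then shrinks all distances alike)
    params <- list(bn0 = bn_init(1), blocks = blocks, bnf = bn_init(flat),
                   dw = 0.05 * init_dense(flat, cfg$embed_dim),
                   db = rep(0, cfg$embed_dim))
    bn_state <- list(bn0 = bn_stats_init(1), blocks = sblocks,
                     bnf = bn_stats_init(flat))
    structure(list(cfg = cfg, params = params, bn_state = bn_state),
              class = "siamese_model")
  })
}

#' Trainable parameter count of the embedding sub-network
#'
#' Counts convolution, dense and batch-norm scale/shift parameters (running
#' statistics are not trainable).
#' @param model a `siamese_model`.
#' @export
siamese_param_count <- function(model) {
  p <- model$params
  bn_tr <- function(b) length(b$gamma) + length(b$beta)
  sum(vapply(p$blocks, function(b) length(b$w) + length(b$b) + bn_tr(b$bn),
             numeric(1))) +
    bn_tr(p$bn0) + bn_tr(p$bnf) + length(p$dw) + length(p$db)
}

# Forward through the sub-network. x: H x W x 1 x N. Returns embeddings
# (embed_dim x N); with keep=TRUE also the cache; in training mode batch-norm
# uses batch statistics and the updated running statistics are returned.
siamese_forward <- function(params, bn_state, cfg, x, training = FALSE,
                            keep = FALSE) {
  cache <- list(blocks = list())
  b0 <- bn_conv_fw(x, params$bn0, bn_state$bn0, training)
  bn_state$bn0 <- b0$stats
  h <- b0$y
  if (keep) cache$bn0 <- list(x = x, bn = b0)
  for (i in seq_len(cfg$n_blocks)) {
    bl <- params$blocks[[i]]
    z <- conv_fw(h, bl$w, bl$b)
    bn <- bn_conv_fw(z, bl$bn, bn_state$blocks[[i]], training)
    bn_state$blocks[[i]] <- bn$stats
    a <- relu_fw(bn$y)
    pl <- avgpool2_fw(a)
    dr <- dropout_fw(pl, cfg$dropout, training)
    if (keep) cache$blocks[[i]] <- list(h = h, z = z, bn = bn, a = a,
                                        pldim = dim(a), mask = dr$mask)
    h <- dr$y
  }
  d <- dim(h)
  flat <- matrix(h, prod(d[1:3]), d[4])
  bf <- bn_dense_fw(flat, params$bnf, bn_state$bnf, training)
  bn_state$bnf <- bf$stats
  e <- relu_fw(crossprod(params$dw, bf$y) + params$db)
  if (keep) { cache$flatdim <- d; cache$bnf <- bf; cache$e <- e }
  list(e = e, cache = cache, bn_state = bn_state)
}

siamese_backward <- function(params, cfg, cache, ge) {
  ge <- relu_bw(cache$e, ge)
  g <- list(bn0 = NULL, blocks = vector("list", cfg$n_blocks),
            bnf = NULL, dw = NULL, db = NULL)
  g$dw <- cache$bnf$y %*% t(ge)
  g$db <- rowSums(ge)
  gflat <- params$dw %*% ge
  bb <- bn_dense_bw(cache$bnf, params$bnf$gamma, gflat)
  g$bnf <- list(gamma = bb$ggamma, beta = bb$gbeta)
  gh <- array(bb$gx, dim = cache$flatdim)
  for (i in rev(seq_len(cfg$n_blocks))) {
    cc <- cache$blocks[[i]]
    bl <- params$blocks[[i]]
    gpl <- dropout_bw(cc$mask, gh, cfg$dropout)
    ga <- avgpool2_bw(gpl, cc$pldim)
    gbn <- relu_bw(cc$a, ga)
    bnb <- bn_conv_bw(cc$bn, bl$bn$gamma, gbn)
    cb <- conv_bw(cc$h, bl$w, bnb$gx)
    g$blocks[[i]] <- list(w = cb$gw, b = cb$gb,
                          bn = list(gamma = bnb$ggamma, beta = bnb$gbeta))
    gh <- cb$gx
  }
  b0b <- bn_conv_bw(cache$bn0$bn, params$bn0$gamma, gh)
  g$bn0 <- list(gamma = b0b$ggamma, beta = b0b$gbeta)
  g
}

#' Embed one binary mask into a length-128 feature vector
#' @param model a `siamese_model`.
#' @param mask `{0, 1}` matrix at the model input size.
#' @return Numeric vector of length `cfg$embed_dim`.
#' @export
embed_mask <- function(model, mask) {
  if (!all(dim(mask) == model$cfg$input_size)) stop("mask size mismatch")
  x <- array(mask, dim = c(dim(mask), 1, 1))
  as.numeric(siamese_forward(model$params, model$bn_state, model$cfg, x)$e)
}

#' Embed both masks of a pair through the shared sub-network
#'
#' Order-equivariant: swapping the inputs swaps the outputs.
#' @param model a `siamese_model`.
#' @param mask_a,mask_b `{0, 1}` matrices at the model input size.
#' @return list with `e_a`, `e_b` and the Euclidean `distance`.
#' @export
embed_pair <- function(model, mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask dimensions differ")
  e_a <- embed_mask(model, mask_a)
  e_b <- embed_mask(model, mask_b)
  list(e_a = e_a, e_b = e_b, distance = sqrt(sum((e_a - e_b)^2)))
}

#' Contrastive loss over a batch of pair distances
#'
#' `mean((1 - y) d^2 + y max(M - d, 0)^2)` with y = 0 for genuine/similar
#' pairs and y = 1 for impostor/dissimilar pairs: genuine pairs are pulled
#' together, impostors pushed apart up to the margin.
#'
#' @param d non-negative distances.
#' @param y labels in {0, 1}; 0 = similar.
#' @param margin margin M (> 0).
#' @return Mean loss (scalar).
#' @export
contrastive_loss <- function(d, y, margin = 1) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 (similar) or 1 (dissimilar)")
  mean((1 - y) * d^2 + y * pmax(margin - d, 0)^2)
}

#' Threshold decision on a match distance
#'
#' Accept iff `d <= tau` (boundary inclusive). The sigmoid score
#' `1/(1+exp(-d))` is reported alongside; being monotone increasing in the
#' distance it carries the same information and is not used for the verdict.
#'
#' @param d non-negative distance.
#' @param tau positive distance cutoff.
#' @return A `match_decision`: distance, score, threshold, verdict.
#' @export
decide <- function(d, tau) {
  stopifnot(d >= 0, tau > 0)
  structure(list(distance = d, score = sigmoid(d), threshold = tau,
                 verdict = d <= tau), class = "match_decision")
}

# Distances for a set of pairs under the current parameters (inference mode),
# computed in mini-batches through the shared sub-network.
siamese_distances <- function(params, bn_state, cfg, masks, pairs, chunk = 32) {
  n <- nrow(pairs)
  d <- numeric(n)
  for (s in seq(1, n, chunk)) {
    idx <- s:min(s + chunk - 1, n)
    xa <- stack_batch(masks, pairs$row_a[idx])
    xb <- stack_batch(masks, pairs$row_b[idx])
    ea <- siamese_forward(params, bn_state, cfg, xa)$e
    eb <- siamese_forward(params, bn_state, cfg, xb)$e
    d[idx] <- sqrt(colSums((ea - eb)^2))
  }
  d
}

#' Train the Siamese matcher with contrastive loss
#'
#' Adam at `cfg$lr`. Labels map genuine -> y = 0 (similar), impostor -> y = 1,
#' as the contrastive-loss algebra requires. Both masks of a pair are
#' augmented independently, with fresh draws every epoch, when `aug_cfg` is
#' given. After every epoch the decision threshold tau is calibrated on the
#' validation pairs to maximise F1, and validation accuracy/F1 at that tau
#' are recorded.
#'
#' @param model a `siamese_model`.
#' @param masks list of `{0, 1}` matrices at the model input size.
#' @param train_pairs,val_pairs pair data.frames from [build_pairs()] whose
#'   row_a/row_b index into `masks`.
#' @param cfg a [siamese_config()]; defaults to the model's.
#' @param aug_cfg optional [augment_config()] applied to training and
#'   validation masks.
#' @param verbose print per-epoch metrics.
#' @return list with `model` (trained, `cfg$decision_threshold` set to the
#'   final calibrated tau), `report` (per-epoch loss, val accuracy, F1, tau),
#'   `epochs_run`.
#' @export
train_siamese <- function(model, masks, train_pairs, val_pairs,
                          cfg = model$cfg, aug_cfg = NULL, verbose = FALSE) {
  if (nrow(train_pairs) == 0) stop("empty pair set")
  params <- model$params
  bn_state <- model$bn_state
  opt <- adam_init(params)
  rep <- list()
  for (ep in seq_len(cfg$epochs)) {
    loss_ep <- 0; nb <- 0
    with_seed(derive_seed(cfg$seed, 31, ep), {
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
        x <- stack_batch(c(ma, mb), seq_len(2 * B))
        y <- as.numeric(train_pairs$label[idx] == "impostor")
        fw <- siamese_forward(params, bn_state, cfg, x, training = TRUE,
                              keep = TRUE)
        bn_state <- fw$bn_state
        ea <- fw$e[, seq_len(B), drop = FALSE]
        eb <- fw$e[, B + seq_len(B), drop = FALSE]
        diff <- ea - eb
        d <- sqrt(colSums(diff^2))
        loss <- contrastive_loss(d, y, cfg$margin)
        # dL/dd per pair, then chain to both embeddings
        gd <- (2 * (1 - y) * d - 2 * y * pmax(cfg$margin - d, 0)) / B
        gdiff <- sweep(diff, 2, ifelse(d > 0, gd / d, 0), "*")
        ge <- cbind(gdiff, -gdiff)
        grads <- siamese_backward(params, cfg, fw$cache, ge)
        st <- adam_step(params, grads, opt, cfg$lr)
        params <- st$params
        opt <- st$state
        loss_ep <- loss_ep + loss; nb <- nb + 1
      }
    })
    ev <- with_seed(derive_seed(cfg$seed, 32, ep), {
      vmasks <- masks
      if (!is.null(aug_cfg)) {
        vrows <- unique(c(val_pairs$row_a, val_pairs$row_b))
        for (r in vrows) vmasks[[r]] <- augment(masks[[r]], aug_cfg)
      }
      dv <- siamese_distances(params, bn_state, cfg, vmasks, val_pairs)
      genuine <- val_pairs$label == "genuine"
      tau <- calibrate_threshold(dv, genuine)
      acc <- binary_accuracy(dv <= tau, genuine)
      f1 <- f1_score(confusion_counts(dv <= tau, genuine))
      list(tau = tau, acc = acc, f1 = f1,
           d_gen = mean(dv[genuine]), d_imp = mean(dv[!genuine]))
    })
    rep[[ep]] <- data.frame(epoch = ep, train_loss = loss_ep / nb,
                            val_accuracy = ev$acc, val_f1 = ev$f1,
                            tau = ev$tau, mean_genuine_dist = ev$d_gen,
                            mean_impostor_dist = ev$d_imp)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f  F1 %.3f  dg %.3f di %.3f",
                      ep, loss_ep / nb, ev$acc, ev$f1, ev$d_gen, ev$d_imp))
  }
  cfg$decision_threshold <- rep[[length(rep)]]$tau
  list(model = structure(list(cfg = cfg, params = params, bn_state = bn_state),
                         class = "siamese_model"),
       report = do.call(rbind, rep), epochs_run = length(rep))
}
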