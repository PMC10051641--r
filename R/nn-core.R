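# Minimal neural-network engine: layer primitives with explicit forward /
# backward passes over H x W x C x N arrays, plus Adam. Convolution and
# pooling kernels live in src/kernels.cpp; everything here is plain R.

#' @useDynLib wristvein, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- RNG scoping -----------------------------------------------------------

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child RNG seed from a root seed and integer indices
#'
#' A pure integer map (multiplicative-congruential mixing) used to split one
#' root seed hierarchically across subjects, sessions and training stages;
#' every derived seed stays below 2^31.
#'
#' @param seed root integer seed.
#' @param ... integer indices identifying the branch.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) s <- (s * 48271 + as.double(k) * 16807 + 1) %% 2147483629
  as.integer(s)
}

## ---- initialisers ----------------------------------------------------------

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

init_conv <- function(k, cin, cout) {
  glorot_uniform(c(k, k, cin, cout), fan_in = k * k * cin, fan_out = k * k * cout)
}

init_dense <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -sqrt(6 / (nin + nout)), sqrt(6 / (nin + nout))),
         nin, nout)
}

# Bank of 3 x 3 Gabor kernels cycling through `orientations` evenly spaced
# angles (and alternating phase), used to seed the first contracting block of
# the segmenter. Kernels remain trainable after initialisation.
gabor_bank <- function(n, orientations = 4, wavelength = 4, sigma = 2) {
  ker <- array(0, dim = c(3, 3, 1, n))
  grid <- expand.grid(r = -1:1, c = -1:1)
  for (i in seq_len(n)) {
    th <- pi * ((i - 1) %% orientations) / orientations
    phase <- if (((i - 1) %/% orientations) %% 2 == 0) 0 else pi / 2
    xr <- grid$c * cos(th) + grid$r * sin(th)
    yr <- -grid$c * sin(th) + grid$r * cos(th)
    g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength + phase)
    g <- g - mean(g)
    scale <- 0.5 + 0.1 * ((i - 1) %/% (2 * orientations))
    ker[, , 1, i] <- scale * matrix(g, 3, 3) / max(abs(g))
  }
  ker
}

## ---- elementwise layers ----------------------------------------------------

relu_fw <- function(x) relu_fw_cpp(x)
relu_bw <- function(y, gy) relu_bw_cpp(y, gy)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Inverted dropout. The element mask comes from a counter-based generator in
# C++ seeded by a single draw from the R RNG stream, so training remains a
# pure function of set.seed without millions of R-level draws.
dropout_fw <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL, rate = rate))
  seed <- sample.int(.Machine$integer.max, 1)
  out <- dropout_fw_cpp(x, rate, seed)
  list(y = out$y, mask = out$keep, rate = rate)
}
dropout_bw <- function(mask, gy, rate) {
  if (is.null(mask)) gy else dropout_bw_cpp(gy, mask, rate)
}

## ---- batch normalisation ---------------------------------------------------

# Trainable scale/shift and (separate) running statistics: the latter are
# updated by exponential moving average during training, never by Adam.
bn_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
bn_stats_init <- function(C) list(mean = rep(0, C), var = rep(1, C))

bn_conv_fw <- function(x, p, s, training, momentum = 0.9, eps = 1e-3) {
  if (training) {
    mom <- chan_moments_cpp(x)
    mu <- mom$mean
    va <- mom$meansq - mu^2
    s$mean <- momentum * s$mean + (1 - momentum) * mu
    s$var <- momentum * s$var + (1 - momentum) * va
  } else {
    mu <- s$mean; va <- s$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- chan_affine_cpp(x, istd, -mu * istd)
  y <- chan_affine_cpp(xhat, p$gamma, p$beta)
  list(y = y, xhat = xhat, istd = istd, stats = s)
}

bn_conv_bw <- function(cache, gamma, gy) {
  gxhat <- chan_affine_cpp(gy, gamma, numeric(length(gamma)))
  s1 <- chan_sum_cpp(gxhat)
  s2 <- chan_dot_cpp(gxhat, cache$xhat)
  gx <- bn_bw_combine_cpp(gxhat, cache$xhat, s1, s2, cache$istd)
  list(gx = gx, ggamma = chan_dot_cpp(gy, cache$xhat), gbeta = chan_sum_cpp(gy))
}

bn_dense_fw <- function(x, p, s, training, momentum = 0.9, eps = 1e-3) {
  if (training) {
    mu <- rowMeans(x)
    va <- rowMeans(x^2) - mu^2
    s$mean <- momentum * s$mean + (1 - momentum) * mu
    s$var <- momentum * s$var + (1 - momentum) * va
  } else {
    mu <- s$mean; va <- s$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (x - mu) * istd
  list(y = xhat * p$gamma + p$beta, xhat = xhat, istd = istd, stats = s)
}

bn_dense_bw <- function(cache, gamma, gy) {
  m <- ncol(gy)
  gxhat <- gy * gamma
  gx <- (gxhat * m - rowSums(gxhat) - cache$xhat * rowSums(gxhat * cache$xhat)) *
    cache$istd / m
  list(gx = gx, ggamma = rowSums(gy * cache$xhat), gbeta = rowSums(gy))
}

## ---- spatial helpers -------------------------------------------------------

# Zero-stuffing upsample by 2: input pixels land on the odd grid, the rest is
# zero. Followed by a same-padded 3 x 3 convolution this forms the learnable
# up-convolution used in the expansive path.
upsample2_zero_fw <- function(x) {
  d <- dim(x)
  y <- array(0, dim = c(2 * d[1], 2 * d[2], d[3], d[4]))
  y[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
  y
}
upsample2_zero_bw <- function(gy) {
  d <- dim(gy)
  gy[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}
split_ch <- function(g, c1) {
  list(g[, , seq_len(c1), , drop = FALSE],
       g[, , -seq_len(c1), , drop = FALSE])
}

conv_forward <- function(x, w, b) conv_fw(x, w, b)
conv_backward <- function(x, w, gy) conv_bw(x, w, gy)

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update over an arbitrarily nested list of parameter arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    d <- dim(p)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    # keep the parameter's original shape: gradients may arrive as 1-column
    # matrices or 1-d arrays for vector parameters
    if (is.null(d)) { dim(p) <- NULL; dim(m) <- NULL; dim(v) <- NULL }
    else { dim(p) <- d; dim(m) <- d; dim(v) <- d }
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# Closed-form trainable-parameter audit for a convolution layer:
# (k^2 * C_in + 1) * C_out. Used to cross-check the constructed graphs.
conv_param_count <- function(k, cin, cout) (k * k * cin + 1) * cout

count_params <- function(params) {
  n <- 0
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else n <<- n + length(p)
    invisible(NULL)
  }
  walk(params)
  n
}
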