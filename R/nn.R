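# Self-contained neural-network engine on base R matrix algebra.
#
# Layers store parameters in $par (learnable arrays), normalization running
# statistics in $stats, gradients in $grad and forward caches in $cache.
# Data layouts: flat inputs are [B, F] matrices; 1D signals are [B, T, C]
# arrays; 2D images are [B, H, W, C] arrays (channels last). All forward
# passes are implemented; backpropagation covers the dense/convolutional
# family (dense, relu, conv1d, conv2d, batch norm, max pooling, global
# average pooling, dropout, flatten, residual blocks), which is the family
# the package trains.

init_mat <- function(nr, nc, rng, fan_in) {
  matrix(rng$rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# ---- layer constructors -----------------------------------------------------

layer_dense <- function(d_in, d_out, rng, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  list(type = "dense", d_in = d_in, d_out = d_out, activation = activation,
       par = list(W = init_mat(d_in, d_out, rng, d_in), b = rep(0, d_out)),
       stats = list(), grad = list(), cache = list())
}

layer_relu <- function() {
  list(type = "relu", par = list(), stats = list(), grad = list(), cache = list())
}

layer_flatten <- function() {
  list(type = "flatten", par = list(), stats = list(), grad = list(), cache = list())
}

layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, par = list(), stats = list(),
       grad = list(), cache = list())
}

layer_conv1d <- function(c_in, c_out, k, rng) {
  # same padding, stride 1; W is [k * c_in, c_out], kernel-position major
  list(type = "conv1d", c_in = c_in, c_out = c_out, k = k,
       par = list(W = init_mat(k * c_in, c_out, rng, k * c_in),
                  b = rep(0, c_out)),
       stats = list(), grad = list(), cache = list())
}

layer_conv2d <- function(c_in, c_out, kh, kw, rng) {
  list(type = "conv2d", c_in = c_in, c_out = c_out, kh = kh, kw = kw,
       par = list(W = init_mat(kh * kw * c_in, c_out, rng, kh * kw * c_in),
                  b = rep(0, c_out)),
       stats = list(), grad = list(), cache = list())
}

layer_batchnorm <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", c = c, momentum = momentum, eps = eps,
       par = list(gamma = rep(1, c), beta = rep(0, c)),
       stats = list(running_mean = rep(0, c), running_var = rep(1, c)),
       grad = list(), cache = list())
}

layer_gap1d <- function() {
  list(type = "gap1d", par = list(), stats = list(), grad = list(), cache = list())
}

layer_maxpool1d <- function(p) {
  list(type = "maxpool1d", p = p, par = list(), stats = list(),
       grad = list(), cache = list())
}

layer_maxpool2d <- function(ph, pw) {
  list(type = "maxpool2d", ph = ph, pw = pw, par = list(), stats = list(),
       grad = list(), cache = list())
}

layer_residual1d <- function(branch, shortcut) {
  # y = relu(branch(x) + shortcut(x)); branch/shortcut are layer lists
  list(type = "residual1d", branch = branch, shortcut = shortcut,
       par = list(), stats = list(), grad = list(), cache = list())
}

# forward-only layers ---------------------------------------------------------

layer_prelu <- function(c) {
  list(type = "prelu", c = c, par = list(alpha = rep(0.25, c)),
       stats = list(), grad = list(), cache = list(), forward_only = TRUE)
}

layer_instancenorm <- function(eps = 1e-5) {
  list(type = "instancenorm", eps = eps, par = list(), stats = list(),
       grad = list(), cache = list(), forward_only = TRUE)
}

layer_attention_split <- function() {
  # softmax(first half of channels, over time) * second half, summed over time
  list(type = "attention_split", par = list(), stats = list(), grad = list(),
       cache = list(), forward_only = TRUE)
}

layer_lstm <- function(c_in, units, n_layers, rng) {
  pars <- list()
  for (l in seq_len(n_layers)) {
    d <- if (l == 1L) c_in else units
    pars[[paste0("W", l)]] <- init_mat(d + units, 4L * units, rng, d + units)
    b <- rep(0, 4L * units)
    b[(units + 1L):(2L * units)] <- 1  # forget-gate bias
    pars[[paste0("b", l)]] <- b
  }
  list(type = "lstm", c_in = c_in, units = units, n_layers = n_layers,
       par = pars, stats = list(), grad = list(), cache = list(),
       forward_only = TRUE)
}

layer_transformer_block <- function(d_model, n_heads, d_ff, rng) {
  list(type = "transformer_block", d_model = d_model, n_heads = n_heads,
       d_ff = d_ff,
       par = list(
         ln1_g = rep(1, d_model), ln1_b = rep(0, d_model),
         Wq = init_mat(d_model, d_model, rng, d_model),
         Wk = init_mat(d_model, d_model, rng, d_model),
         Wv = init_mat(d_model, d_model, rng, d_model),
         Wo = init_mat(d_model, d_model, rng, d_model),
         ln2_g = rep(1, d_model), ln2_b = rep(0, d_model),
         W1 = init_mat(d_model, d_ff, rng, d_model), b1 = rep(0, d_ff),
         W2 = init_mat(d_ff, d_model, rng, d_ff), b2 = rep(0, d_model)),
       stats = list(), grad = list(), cache = list(), forward_only = TRUE)
}

layer_positional_encoding <- function(t_len, d_model) {
  pos <- matrix(0, t_len, d_model)
  for (i in seq_len(d_model)) {
    freq <- 1 / 10000^((2 * ((i - 1) %/% 2)) / d_model)
    ang <- (seq_len(t_len) - 1) * freq
    pos[, i] <- if (i %% 2 == 1L) sin(ang) else cos(ang)
  }
  list(type = "posenc", pos = pos, par = list(), stats = list(),
       grad = list(), cache = list(), forward_only = TRUE)
}

# ---- reshaping helpers ------------------------------------------------------

flat_bt <- function(a) {
  # [B, T, C] -> [(B*T), C], row index b + (t-1)*B (column-major safe)
  d <- dim(a); dim(a) <- c(d[1] * d[2], d[3]); a
}

unflat_bt <- function(m, B, T) {
  dim(m) <- c(B, T, ncol(m)); m
}

# ---- conv1d -----------------------------------------------------------------

conv1d_im2col <- function(xp, Tt, k, C) {
  B <- dim(xp)[1]
  X <- matrix(0, B * Tt, k * C)
  for (j in seq_len(k)) {
    X[, ((j - 1L) * C + 1L):(j * C)] <- flat_bt(xp[, j:(j + Tt - 1L), , drop = FALSE])
  }
  X
}

conv1d_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
  k <- layer$k
  pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl
  xp <- array(0, c(B, Tt + k - 1L, C))
  xp[, (pl + 1L):(pl + Tt), ] <- x
  X <- conv1d_im2col(xp, Tt, k, C)
  Y <- X %*% layer$par$W
  Y <- sweep(Y, 2L, layer$par$b, `+`)
  layer$cache <- list(X = X, B = B, Tt = Tt, C = C, pl = pl)
  list(layer = layer, out = unflat_bt(Y, B, Tt))
}

conv1d_backward <- function(layer, dy) {
  ca <- layer$cache
  B <- ca$B; Tt <- ca$Tt; C <- ca$C; k <- layer$k; pl <- ca$pl
  dY <- flat_bt(dy)
  layer$grad$W <- crossprod(ca$X, dY)
  layer$grad$b <- colSums(dY)
  dX <- dY %*% t(layer$par$W)                     # [(B*T), k*C]
  dxp <- array(0, c(B, Tt + k - 1L, C))
  for (j in seq_len(k)) {
    blk <- dX[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    dim(blk) <- c(B, Tt, C)
    dxp[, j:(j + Tt - 1L), ] <- dxp[, j:(j + Tt - 1L), , drop = FALSE] + blk
  }
  dx <- dxp[, (pl + 1L):(pl + Tt), , drop = FALSE]
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

# ---- conv2d (FFT-based linear correlation) ----------------------------------
#
# 'same'-padded stride-1 cross-correlation evaluated in the frequency domain:
# with the input zero-padded to (H+kh-1) x (W+kw-1), circular correlation via
# the 2D FFT equals the linear correlation on the valid region, so forward,
# weight-gradient (input (*) output-grad) and input-gradient (full
# convolution of the output-grad with the kernel) are each a handful of FFTs
# per sample instead of a dense im2col product. Exact to rounding; crucial
# for the 32 x 32 kernels of the spectrum CNN. Weight layout: W[r, f] with
# r = i + (j-1)*kh + (c-1)*kh*kw.

conv2d_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  kh <- layer$kh; kw <- layer$kw; Fo <- layer$c_out
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  Wa <- layer$par$W; dim(Wa) <- c(kh, kw, C, Fo)
  FW <- array(0i, c(Hp, Wp, C, Fo))
  kpad <- matrix(0, Hp, Wp)
  for (cc in seq_len(C)) for (f in seq_len(Fo)) {
    kpad[] <- 0; kpad[1:kh, 1:kw] <- Wa[, , cc, f]
    FW[, , cc, f] <- stats::fft(kpad)
  }
  pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
  out <- array(0, c(B, H, W, Fo))
  FX <- if (training) array(0i, c(Hp, Wp, B, C)) else NULL
  xpad <- matrix(0, Hp, Wp)
  for (b in seq_len(B)) {
    FXb <- array(0i, c(Hp, Wp, C))
    for (cc in seq_len(C)) {
      xpad[] <- 0
      xpad[(pt + 1L):(pt + H), (pl + 1L):(pl + W)] <- x[b, , , cc]
      FXb[, , cc] <- stats::fft(xpad)
    }
    for (f in seq_len(Fo)) {
      acc <- matrix(0i, Hp, Wp)
      for (cc in seq_len(C)) acc <- acc + FXb[, , cc] * Conj(FW[, , cc, f])
      y <- Re(stats::fft(acc, inverse = TRUE)) / (Hp * Wp)
      out[b, , , f] <- y[1:H, 1:W] + layer$par$b[f]
    }
    if (training) FX[, , b, ] <- FXb
  }
  layer$cache <- if (training) list(FX = FX, FW = FW, B = B, H = H, W = W,
                                    C = C) else list()
  list(layer = layer, out = out)
}

conv2d_backward <- function(layer, dy) {
  ca <- layer$cache
  B <- ca$B; H <- ca$H; W <- ca$W; C <- ca$C
  kh <- layer$kh; kw <- layer$kw; Fo <- layer$c_out
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
  FdY <- array(0i, c(Hp, Wp, B, Fo))
  ypad <- matrix(0, Hp, Wp)
  db <- rep(0, Fo)
  for (b in seq_len(B)) for (f in seq_len(Fo)) {
    ypad[] <- 0; ypad[1:H, 1:W] <- dy[b, , , f]
    FdY[, , b, f] <- stats::fft(ypad)
    db[f] <- db[f] + sum(dy[b, , , f])
  }
  # weight gradient: correlation of the padded input with the output grad
  dWa <- array(0, c(kh, kw, C, Fo))
  for (cc in seq_len(C)) for (f in seq_len(Fo)) {
    S <- matrix(0i, Hp, Wp)
    for (b in seq_len(B)) S <- S + ca$FX[, , b, cc] * Conj(FdY[, , b, f])
    g <- Re(stats::fft(S, inverse = TRUE)) / (Hp * Wp)
    dWa[, , cc, f] <- g[1:kh, 1:kw]
  }
  dim(dWa) <- c(kh * kw * C, Fo)
  layer$grad$W <- dWa
  layer$grad$b <- db
  # input gradient: full convolution of the output grad with the kernel
  dx <- array(0, c(B, H, W, C))
  for (b in seq_len(B)) for (cc in seq_len(C)) {
    S <- matrix(0i, Hp, Wp)
    for (f in seq_len(Fo)) S <- S + FdY[, , b, f] * ca$FW[, , cc, f]
    g <- Re(stats::fft(S, inverse = TRUE)) / (Hp * Wp)
    dx[b, , , cc] <- g[(pt + 1L):(pt + H), (pl + 1L):(pl + W)]
  }
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

# ---- batch norm (channels-last, any rank) -----------------------------------

bn_to_mat <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("batchnorm input must be an array")
  C <- d[length(d)]
  dim(x) <- c(prod(d[-length(d)]), C)
  x
}

batchnorm_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- bn_to_mat(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, `-`)
    v <- colMeans(xc * xc)
    layer$stats$running_mean <- layer$momentum * layer$stats$running_mean +
      (1 - layer$momentum) * mu
    layer$stats$running_var <- layer$momentum * layer$stats$running_var +
      (1 - layer$momentum) * v
  } else {
    mu <- layer$stats$running_mean
    v <- layer$stats$running_var
    xc <- sweep(xm, 2L, mu, `-`)
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, layer$par$gamma, `*`), 2L, layer$par$beta, `+`)
  dim(y) <- d
  if (training) layer$cache <- list(xhat = xhat, inv_sd = inv_sd, d = d)
  list(layer = layer, out = y)
}

batchnorm_backward <- function(layer, dy) {
  ca <- layer$cache
  dym <- bn_to_mat(dy)
  M <- nrow(dym)
  layer$grad$gamma <- colSums(dym * ca$xhat)
  layer$grad$beta <- colSums(dym)
  dxhat <- sweep(dym, 2L, layer$par$gamma, `*`)
  # dx = inv_sd/M * (M*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- M * dxhat
  t2 <- matrix(colSums(dxhat), M, ncol(dym), byrow = TRUE)
  t3 <- sweep(ca$xhat, 2L, colSums(dxhat * ca$xhat), `*`)
  dx <- sweep(t1 - t2 - t3, 2L, ca$inv_sd / M, `*`)
  dim(dx) <- ca$d
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

# ---- pooling ----------------------------------------------------------------

maxpool1d_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
  p <- layer$p
  To <- Tt %/% p
  out <- array(-Inf, c(B, To, C))
  arg <- array(1L, c(B, To, C))
  for (i in seq_len(p)) {
    cur <- x[, seq(i, by = p, length.out = To), , drop = FALSE]
    upd <- cur > out
    out[upd] <- cur[upd]
    arg[upd] <- i
  }
  layer$cache <- list(arg = arg, d = d)
  list(layer = layer, out = out)
}

maxpool1d_backward <- function(layer, dy) {
  ca <- layer$cache
  d <- ca$d; B <- d[1]; Tt <- d[2]; C <- d[3]
  p <- layer$p; To <- Tt %/% p
  dx <- array(0, d)
  to_grid <- expand.grid(b = seq_len(B), to = seq_len(To), c = seq_len(C))
  t_in <- (to_grid$to - 1L) * p + as.vector(ca$arg)
  idx <- cbind(to_grid$b, t_in, to_grid$c)
  dx[idx] <- as.vector(dy)
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

maxpool2d_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- layer$ph; pw <- layer$pw
  Ho <- H %/% ph; Wo <- W %/% pw
  if (Ho < 1L || Wo < 1L) stop("pooling window larger than input", call. = FALSE)
  out <- array(-Inf, c(B, Ho, Wo, C))
  argi <- array(1L, c(B, Ho, Wo, C))
  argj <- array(1L, c(B, Ho, Wo, C))
  for (j in seq_len(pw)) {
    for (i in seq_len(ph)) {
      cur <- x[, seq(i, by = ph, length.out = Ho),
               seq(j, by = pw, length.out = Wo), , drop = FALSE]
      upd <- cur > out
      out[upd] <- cur[upd]
      argi[upd] <- i
      argj[upd] <- j
    }
  }
  layer$cache <- list(argi = argi, argj = argj, d = d)
  list(layer = layer, out = out)
}

maxpool2d_backward <- function(layer, dy) {
  ca <- layer$cache
  d <- ca$d; B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ph <- layer$ph; pw <- layer$pw
  Ho <- H %/% ph; Wo <- W %/% pw
  dx <- array(0, d)
  g <- expand.grid(b = seq_len(B), ho = seq_len(Ho), wo = seq_len(Wo),
                   c = seq_len(C))
  h_in <- (g$ho - 1L) * ph + as.vector(ca$argi)
  w_in <- (g$wo - 1L) * pw + as.vector(ca$argj)
  # linear index into dx (column-major over [B, H, W, C])
  lin <- g$b + (h_in - 1L) * B + (w_in - 1L) * (B * H) +
    (g$c - 1L) * (B * H * W)
  dxv <- as.vector(dx)
  dxv[lin] <- as.vector(dy)
  dim(dxv) <- d
  layer$cache <- list()
  list(layer = layer, dx = dxv)
}

# ---- simple layers ----------------------------------------------------------

dense_forward <- function(layer, x, training) {
  d3 <- if (length(dim(x)) == 3L) dim(x) else NULL   # time-distributed case
  if (!is.null(d3)) x <- flat_bt(x)
  z <- sweep(x %*% layer$par$W, 2L, layer$par$b, `+`)
  if (layer$activation == "relu") {
    y <- pmax(z, 0)
    layer$cache <- list(x = x, mask = z > 0)
  } else {
    y <- z
    layer$cache <- list(x = x)
  }
  if (!is.null(d3)) {
    y <- unflat_bt(y, d3[1], d3[2])
    layer$cache$d3 <- d3
  }
  list(layer = layer, out = y)
}

dense_backward <- function(layer, dy) {
  d3 <- layer$cache$d3
  if (!is.null(d3)) dy <- flat_bt(dy)
  if (layer$activation == "relu") dy <- dy * layer$cache$mask
  layer$grad$W <- crossprod(layer$cache$x, dy)
  layer$grad$b <- colSums(dy)
  dx <- dy %*% t(layer$par$W)
  if (!is.null(d3)) dx <- unflat_bt(dx, d3[1], d3[2])
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

relu_forward <- function(layer, x, training) {
  layer$cache <- list(mask = x > 0)
  list(layer = layer, out = pmax(x, 0))
}

relu_backward <- function(layer, dy) {
  dx <- dy * layer$cache$mask
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

flatten_forward <- function(layer, x, training) {
  d <- dim(x)
  layer$cache <- list(d = d)
  # row-major flatten per sample (dims after batch vary fastest last) is not
  # required; any fixed order works as long as it is consistent. Keep
  # column-major with batch first.
  dim(x) <- c(d[1], prod(d[-1]))
  list(layer = layer, out = x)
}

flatten_backward <- function(layer, dy) {
  dim(dy) <- layer$cache$d
  layer$cache <- list()
  list(layer = layer, dx = dy)
}

gap1d_forward <- function(layer, x, training) {
  d <- dim(x)
  layer$cache <- list(d = d)
  out <- apply(x, c(1, 3), mean)
  dim(out) <- c(d[1], d[3])
  list(layer = layer, out = out)
}

gap1d_backward <- function(layer, dy) {
  d <- layer$cache$d
  dx <- array(0, d)
  for (t in seq_len(d[2])) dx[, t, ] <- dy / d[2]
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

dropout_forward <- function(layer, x, training, rng = NULL) {
  if (!training || layer$rate == 0) {
    layer$cache <- list(mask = NULL)
    return(list(layer = layer, out = x))
  }
  keep <- 1 - layer$rate
  mask <- array(as.numeric(rng$runif(length(x)) < keep) / keep,
                dim = dim(x) %||% length(x))
  layer$cache <- list(mask = mask)
  list(layer = layer, out = x * mask)
}

dropout_backward <- function(layer, dy) {
  dx <- if (is.null(layer$cache$mask)) dy else dy * layer$cache$mask
  layer$cache <- list()
  list(layer = layer, dx = dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- forward-only layers ----------------------------------------------------

prelu_forward <- function(layer, x, training) {
  d <- dim(x); C <- d[length(d)]
  xm <- bn_to_mat(x)
  neg <- pmin(xm, 0)
  y <- pmax(xm, 0) + sweep(neg, 2L, layer$par$alpha, `*`)
  dim(y) <- d
  list(layer = layer, out = y)
}

instancenorm_forward <- function(layer, x, training) {
  # normalize each sample's each channel over time: x is [B, T, C]
  d <- dim(x)
  mu <- apply(x, c(1, 3), mean)
  sd <- sqrt(apply(x, c(1, 3), function(v) mean((v - mean(v))^2)) + layer$eps)
  y <- x
  for (t in seq_len(d[2])) y[, t, ] <- (x[, t, ] - mu) / sd
  list(layer = layer, out = y)
}

attention_split_forward <- function(layer, x, training) {
  d <- dim(x); C <- d[3]; half <- C %/% 2L
  a <- x[, , 1:half, drop = FALSE]
  v <- x[, , (half + 1L):C, drop = FALSE]
  # softmax over time per (sample, channel)
  amax <- apply(a, c(1, 3), max)
  for (t in seq_len(d[2])) a[, t, ] <- exp(a[, t, ] - amax)
  asum <- apply(a, c(1, 3), sum)
  for (t in seq_len(d[2])) a[, t, ] <- a[, t, ] / asum
  out <- apply(a * v, c(1, 3), sum)
  dim(out) <- c(d[1], half)
  list(layer = layer, out = out)
}

lstm_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; Tt <- d[2]
  U <- layer$units
  h_in <- x
  for (l in seq_len(layer$n_layers)) {
    W <- layer$par[[paste0("W", l)]]
    b <- layer$par[[paste0("b", l)]]
    h <- matrix(0, B, U); cst <- matrix(0, B, U)
    outs <- array(0, c(B, Tt, U))
    for (t in seq_len(Tt)) {
      xt <- h_in[, t, , drop = TRUE]
      if (is.null(dim(xt))) xt <- matrix(xt, B)
      z <- cbind(xt, h) %*% W
      z <- sweep(z, 2L, b, `+`)
      i_g <- stats::plogis(z[, 1:U, drop = FALSE])
      f_g <- stats::plogis(z[, (U + 1):(2 * U), drop = FALSE])
      g_g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
      o_g <- stats::plogis(z[, (3 * U + 1):(4 * U), drop = FALSE])
      cst <- f_g * cst + i_g * g_g
      h <- o_g * tanh(cst)
      outs[, t, ] <- h
    }
    h_in <- outs
  }
  list(layer = layer, out = h)  # final hidden state of the last layer
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1L, max))
  m / rowSums(m)
}

posenc_forward <- function(layer, x, training) {
  d <- dim(x)
  for (b in seq_len(d[1])) x[b, , ] <- x[b, , ] + layer$pos
  list(layer = layer, out = x)
}

layernorm_rows <- function(m, g, b, eps = 1e-5) {
  mu <- rowMeans(m)
  v <- rowMeans((m - mu)^2)
  sweep(sweep((m - mu) / sqrt(v + eps), 2L, g, `*`), 2L, b, `+`)
}

transformer_block_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; dm <- layer$d_model
  H <- layer$n_heads; dh <- dm %/% H
  out <- x
  for (b in seq_len(B)) {
    xb <- matrix(x[b, , ], Tt, dm)
    h1 <- layernorm_rows(xb, layer$par$ln1_g, layer$par$ln1_b)
    Q <- h1 %*% layer$par$Wq; K <- h1 %*% layer$par$Wk; V <- h1 %*% layer$par$Wv
    att <- matrix(0, Tt, dm)
    for (hh in seq_len(H)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) / sqrt(dh))
      att[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    xb <- xb + att %*% layer$par$Wo
    h2 <- layernorm_rows(xb, layer$par$ln2_g, layer$par$ln2_b)
    ff <- pmax(sweep(h2 %*% layer$par$W1, 2L, layer$par$b1, `+`), 0)
    xb <- xb + sweep(ff %*% layer$par$W2, 2L, layer$par$b2, `+`)
    out[b, , ] <- xb
  }
  list(layer = layer, out = out)
}

# ---- dispatch ---------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE, rng = NULL) {
  switch(layer$type,
    dense = dense_forward(layer, x, training),
    relu = relu_forward(layer, x, training),
    flatten = flatten_forward(layer, x, training),
    dropout = dropout_forward(layer, x, training, rng),
    conv1d = conv1d_forward(layer, x, training),
    conv2d = conv2d_forward(layer, x, training),
    batchnorm = batchnorm_forward(layer, x, training),
    gap1d = gap1d_forward(layer, x, training),
    maxpool1d = maxpool1d_forward(layer, x, training),
    maxpool2d = maxpool2d_forward(layer, x, training),
    residual1d = residual1d_forward(layer, x, training, rng),
    prelu = prelu_forward(layer, x, training),
    instancenorm = instancenorm_forward(layer, x, training),
    attention_split = attention_split_forward(layer, x, training),
    lstm = lstm_forward(layer, x, training),
    posenc = posenc_forward(layer, x, training),
    transformer_block = transformer_block_forward(layer, x, training),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, dy) {
  if (isTRUE(layer$forward_only)) {
    stop("layer type '", layer$type, "' is inference-only", call. = FALSE)
  }
  switch(layer$type,
    dense = dense_backward(layer, dy),
    relu = relu_backward(layer, dy),
    flatten = flatten_backward(layer, dy),
    dropout = dropout_backward(layer, dy),
    conv1d = conv1d_backward(layer, dy),
    conv2d = conv2d_backward(layer, dy),
    batchnorm = batchnorm_backward(layer, dy),
    gap1d = gap1d_backward(layer, dy),
    maxpool1d = maxpool1d_backward(layer, dy),
    maxpool2d = maxpool2d_backward(layer, dy),
    residual1d = residual1d_backward(layer, dy),
    stop("no backward pass for layer type: ", layer$type))
}

residual1d_forward <- function(layer, x, training, rng) {
  h <- x
  for (i in seq_along(layer$branch)) {
    r <- layer_forward(layer$branch[[i]], h, training, rng)
    layer$branch[[i]] <- r$layer
    h <- r$out
  }
  s <- x
  for (i in seq_along(layer$shortcut)) {
    r <- layer_forward(layer$shortcut[[i]], s, training, rng)
    layer$shortcut[[i]] <- r$layer
    s <- r$out
  }
  z <- h + s
  layer$cache <- list(mask = z > 0)
  list(layer = layer, out = pmax(z, 0))
}

residual1d_backward <- function(layer, dy) {
  dz <- dy * layer$cache$mask
  db <- dz
  for (i in rev(seq_along(layer$branch))) {
    r <- layer_backward(layer$branch[[i]], db)
    layer$branch[[i]] <- r$layer
    db <- r$dx
  }
  ds <- dz
  for (i in rev(seq_along(layer$shortcut))) {
    r <- layer_backward(layer$shortcut[[i]], ds)
    layer$shortcut[[i]] <- r$layer
    ds <- r$dx
  }
  layer$cache <- list()
  list(layer = layer, dx = db + ds)
}

# ---- model container --------------------------------------------------------

nn_model <- function(name, input_kind, layers) {
  structure(list(name = name, input_kind = input_kind, layers = layers),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat("<nn_model> ", x$name, " (", x$input_kind, " input), ",
      length(x$layers), " top-level layers, ",
      count_parameters(x), " learnable parameters\n", sep = "")
  invisible(x)
}

model_forward <- function(model, x, training = FALSE, rng = NULL) {
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training, rng)
    model$layers[[i]] <- r$layer
    x <- r$out
  }
  list(model = model, out = x)
}

model_backward <- function(model, dz) {
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], dz)
    model$layers[[i]] <- r$layer
    dz <- r$dx
  }
  list(model = model, dx = dz)
}

#' Predict class-1 probabilities
#'
#' Runs the model in inference mode and applies the sigmoid output unit.
#'
#' @param model An `nn_model` built by [build_signal_model()] or
#'   [build_image_model()].
#' @param x Input batch in the model's layout (`[B, 909]` flat, `[B, 101, 9]`
#'   signal or `[B, H, W, 1]` image).
#' @param chunk Samples per forward pass; batches are processed in chunks of
#'   this size to bound the memory of convolutional intermediates.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_model <- function(model, x, chunk = 128L) {
  B <- if (is.null(dim(x))) length(x) else dim(x)[1]
  nd <- length(dim(x))
  out <- numeric(B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(B, s + chunk - 1L)
    xb <- switch(as.character(nd),
                 "2" = x[s:e, , drop = FALSE],
                 "3" = x[s:e, , , drop = FALSE],
                 "4" = x[s:e, , , , drop = FALSE],
                 stop("unsupported input rank"))
    z <- model_forward(model, xb, training = FALSE)$out
    out[s:e] <- as.vector(z)
  }
  stats::plogis(out)
}

# walk layers (recursing into residual blocks), applying fn(layer) -> layer
walk_layers <- function(layers, fn) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "residual1d") {
      layers[[i]]$branch <- walk_layers(layers[[i]]$branch, fn)
      layers[[i]]$shortcut <- walk_layers(layers[[i]]$shortcut, fn)
    }
    layers[[i]] <- fn(layers[[i]])
  }
  layers
}

collect_counts <- function(layers) {
  learn <- 0; nstat <- 0
  walk_layers(layers, function(l) {
    learn <<- learn + sum(vapply(l$par, length, numeric(1)))
    nstat <<- nstat + sum(vapply(l$stats, length, numeric(1)))
    l
  })
  c(learnable = learn, norm_stats = nstat)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(model, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(opt$t)) opt$t <- 0L
  opt$t <- opt$t + 1L
  t <- opt$t
  idx <- 0L
  model$layers <- walk_layers(model$layers, function(l) {
    for (pn in names(l$par)) {
      idx <<- idx + 1L
      g <- l$grad[[pn]]
      if (is.null(g)) next
      key <- paste0("p", idx)
      if (is.null(opt[[key]])) {
        opt[[key]] <- list(m = g * 0, v = g * 0)
      }
      st <- opt[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      opt[[key]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$par[[pn]] <- l$par[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
    l$grad <- list()
    l
  })
  model
}
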