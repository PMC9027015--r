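# Compact CPU convolutional-network engine.
#
# Activations are stored as (N*H*W) x C matrices (pixel-major, column-major
# within each image) so that 3x3 convolutions become one im2col gather plus
# one BLAS matrix multiply; gradients flow back through the same index maps.
# This representation keeps both training the chroma-regression network and
# optimizing pixels against Gram-matrix losses fast enough for CPU use.

# --- featmap helpers ---------------------------------------------------------

featmap <- function(x, N, H, W) list(x = x, N = N, H = H, W = W)

# H x W x C array (single image) -> featmap
array_to_featmap <- function(a) {
  d <- dim(a)
  featmap(matrix(a, d[1L] * d[2L], d[3L]), 1L, d[1L], d[2L])
}

# stack a list of H x W x C arrays into a batch featmap
stack_featmap <- function(arrs) {
  d <- dim(arrs[[1L]])
  x <- do.call(rbind, lapply(arrs, function(a) matrix(a, d[1L] * d[2L], d[3L])))
  featmap(x, length(arrs), d[1L], d[2L])
}

featmap_to_array <- function(fm, n = 1L) {
  HW <- fm$H * fm$W
  rows <- ((n - 1L) * HW + 1L):(n * HW)
  array(fm$x[rows, , drop = FALSE], c(fm$H, fm$W, ncol(fm$x)))
}

# --- cached index maps -------------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- make()
  .idx_cache[[key]]
}

# 3x3 im2col index map with zero padding 1; pad rows point at N*H*W + 1
conv_index <- function(H, W, N, stride) {
  key <- paste("conv", H, W, N, stride)
  cache_get(key, function() {
    Ho <- as.integer(ceiling(H / stride))
    Wo <- as.integer(ceiling(W / stride))
    yo <- rep(seq_len(Ho), times = Wo)
    xo <- rep(seq_len(Wo), each = Ho)
    yc <- (yo - 1L) * stride + 1L
    xc <- (xo - 1L) * stride + 1L
    offs <- expand.grid(dy = -1:1, dx = -1:1)
    idx1 <- matrix(NA_integer_, Ho * Wo, 9L)
    for (j in 1:9) {
      yi <- yc + offs$dy[j]
      xi <- xc + offs$dx[j]
      v <- yi + (xi - 1L) * H
      v[yi < 1L | yi > H | xi < 1L | xi > W] <- NA_integer_
      idx1[, j] <- v
    }
    HW <- H * W
    pad <- N * HW + 1L
    idx <- matrix(pad, N * Ho * Wo, 9L)
    napos <- is.na(idx1)
    for (n in seq_len(N)) {
      block <- idx1 + (n - 1L) * HW
      block[napos] <- pad
      idx[((n - 1L) * Ho * Wo + 1L):(n * Ho * Wo), ] <- block
    }
    list(idx = idx, Ho = Ho, Wo = Wo)
  })
}

# nearest-neighbour x2 upsample index map (output row -> input row)
upsample_index <- function(H, W, N) {
  key <- paste("up", H, W, N)
  cache_get(key, function() {
    Ho <- 2L * H
    Wo <- 2L * W
    yo <- rep(seq_len(Ho), times = Wo)
    xo <- rep(seq_len(Wo), each = Ho)
    yi <- (yo + 1L) %/% 2L
    xi <- (xo + 1L) %/% 2L
    p1 <- yi + (xi - 1L) * H
    HW <- H * W
    map <- integer(N * Ho * Wo)
    for (n in seq_len(N))
      map[((n - 1L) * Ho * Wo + 1L):(n * Ho * Wo)] <- p1 + (n - 1L) * HW
    list(map = map, Ho = Ho, Wo = Wo)
  })
}

# 2x2 stride-2 max-pool candidate index map (floor semantics, as in VGG)
pool_index <- function(H, W, N) {
  key <- paste("pool", H, W, N)
  cache_get(key, function() {
    Ho <- H %/% 2L
    Wo <- W %/% 2L
    yo <- rep(seq_len(Ho), times = Wo)
    xo <- rep(seq_len(Wo), each = Ho)
    idx4 <- matrix(0L, Ho * Wo, 4L)
    k <- 0L
    for (dx in 0:1) for (dy in 0:1) {
      k <- k + 1L
      idx4[, k] <- (2L * yo - 1L + dy) + (2L * xo - 2L + dx) * H
    }
    HW <- H * W
    idx <- matrix(0L, N * Ho * Wo, 4L)
    for (n in seq_len(N))
      idx[((n - 1L) * Ho * Wo + 1L):(n * Ho * Wo), ] <- idx4 + (n - 1L) * HW
    list(idx = idx, Ho = Ho, Wo = Wo)
  })
}

im2col <- function(fm, stride) {
  ci <- conv_index(fm$H, fm$W, fm$N, stride)
  Cin <- ncol(fm$x)
  Xp <- rbind(fm$x, 0)                  # pad row of zeros
  Xc <- matrix(0, nrow(ci$idx), 9L * Cin)
  for (j in 1:9)
    Xc[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Xp[ci$idx[, j], , drop = FALSE]
  Xc
}

# --- layer constructors ------------------------------------------------------

layer_conv <- function(c_in, c_out, stride = 1L) {
  list(type = "conv", c_in = c_in, c_out = c_out, stride = as.integer(stride),
       W = matrix(0, 9L * c_in, c_out), b = numeric(c_out))
}

layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)

layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", channels = channels, momentum = momentum, eps = eps,
       gamma = rep(1, channels), beta = rep(0, channels),
       run_mean = rep(0, channels), run_var = rep(1, channels))
}

layer_upsample <- function() list(type = "upsample")
layer_maxpool  <- function() list(type = "maxpool")
layer_tanh     <- function() list(type = "tanh")

# He-style initialization of every conv in a layer list, deterministic in seed
init_net_weights <- function(layers, seed) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      if (layers[[i]]$type == "conv") {
        fan_in <- nrow(layers[[i]]$W)
        layers[[i]]$W[] <- stats::rnorm(length(layers[[i]]$W),
                                        sd = sqrt(2 / fan_in))
        layers[[i]]$b[] <- 0
      }
    }
    layers
  })
}

# --- forward / backward ------------------------------------------------------

# Forward pass through `layers` starting from featmap `fm`.
# Returns out featmap plus per-layer caches for backward.
# `upto`: stop after this many layers (features tapped mid-network).
net_forward <- function(layers, fm, train = FALSE, upto = length(layers)) {
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      Xc <- im2col(fm, ly$stride)
      ci <- conv_index(fm$H, fm$W, fm$N, ly$stride)
      Y <- Xc %*% ly$W
      Y <- Y + rep(ly$b, each = nrow(Y))
      caches[[i]] <- list(in_fm = fm)
      fm <- featmap(Y, fm$N, ci$Ho, ci$Wo)
    } else if (ly$type == "lrelu") {
      neg <- fm$x < 0
      y <- fm$x
      y[neg] <- y[neg] * ly$slope
      caches[[i]] <- list(neg = neg)
      fm <- featmap(y, fm$N, fm$H, fm$W)
    } else if (ly$type == "bn") {
      if (train) {
        mu <- colMeans(fm$x)
        xc <- sweep(fm$x, 2L, mu)
        v <- colMeans(xc * xc)
        sd <- sqrt(v + ly$eps)
        xhat <- sweep(xc, 2L, sd, "/")
        caches[[i]] <- list(xhat = xhat, sd = sd, mu = mu, var = v)
      } else {
        sd <- sqrt(ly$run_var + ly$eps)
        xhat <- sweep(sweep(fm$x, 2L, ly$run_mean), 2L, sd, "/")
        caches[[i]] <- list(xhat = xhat, sd = sd)
      }
      y <- sweep(sweep(xhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
      fm <- featmap(y, fm$N, fm$H, fm$W)
    } else if (ly$type == "upsample") {
      ui <- upsample_index(fm$H, fm$W, fm$N)
      caches[[i]] <- list(in_fm = fm)
      fm <- featmap(fm$x[ui$map, , drop = FALSE], fm$N, ui$Ho, ui$Wo)
    } else if (ly$type == "maxpool") {
      pi_ <- pool_index(fm$H, fm$W, fm$N)
      y <- fm$x[pi_$idx[, 1L], , drop = FALSE]
      win <- matrix(1L, nrow(y), ncol(y))
      for (k in 2:4) {
        vk <- fm$x[pi_$idx[, k], , drop = FALSE]
        m <- vk > y
        y[m] <- vk[m]
        win[m] <- k
      }
      caches[[i]] <- list(win = win, in_fm = fm)
      fm <- featmap(y, fm$N, pi_$Ho, pi_$Wo)
    } else if (ly$type == "tanh") {
      y <- tanh(fm$x)
      caches[[i]] <- list(y = y)
      fm <- featmap(y, fm$N, fm$H, fm$W)
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = fm, caches = caches)
}

# Backward pass. `grads_at` is a named list mapping layer index (as character)
# to a gradient matrix added at that layer's OUTPUT; deepest index drives the
# walk. Returns list(d_input, d_params) where d_params[[i]] holds dW/db or
# dgamma/dbeta for parametric layers.
net_backward <- function(layers, fwd, grads_at, train = FALSE) {
  taps <- as.integer(names(grads_at))
  top <- max(taps)
  d_params <- vector("list", top)
  dY <- NULL
  for (i in top:1) {
    key <- as.character(i)
    if (!is.null(grads_at[[key]]))
      dY <- if (is.null(dY)) grads_at[[key]] else dY + grads_at[[key]]
    ly <- layers[[i]]
    cc <- fwd$caches[[i]]
    if (ly$type == "conv") {
      in_fm <- cc$in_fm
      Xc <- im2col(in_fm, ly$stride)
      d_params[[i]] <- list(W = crossprod(Xc, dY), b = colSums(dY))
      dXc <- dY %*% t(ly$W)
      ci <- conv_index(in_fm$H, in_fm$W, in_fm$N, ly$stride)
      Cin <- ncol(in_fm$x)
      dX <- matrix(0, nrow(in_fm$x) + 1L, Cin)
      for (j in 1:9) {
        rows <- ci$idx[, j]
        dX[rows, ] <- dX[rows, ] + dXc[, ((j - 1L) * Cin + 1L):(j * Cin)]
      }
      dY <- dX[-nrow(dX), , drop = FALSE]
    } else if (ly$type == "lrelu") {
      dY[cc$neg] <- dY[cc$neg] * ly$slope
    } else if (ly$type == "bn") {
      d_params[[i]] <- list(gamma = colSums(dY * cc$xhat), beta = colSums(dY))
      dxhat <- sweep(dY, 2L, ly$gamma, "*")
      if (train) {
        m1 <- colMeans(dxhat)
        m2 <- colMeans(dxhat * cc$xhat)
        dY <- sweep(sweep(dxhat, 2L, m1) - sweep(cc$xhat, 2L, m2, "*"),
                    2L, cc$sd, "/")
      } else {
        dY <- sweep(dxhat, 2L, cc$sd, "/")
      }
    } else if (ly$type == "upsample") {
      ui <- upsample_index(cc$in_fm$H, cc$in_fm$W, cc$in_fm$N)
      dY <- rowsum(dY, ui$map, reorder = TRUE)
    } else if (ly$type == "maxpool") {
      N <- cc$in_fm$N
      pi_ <- pool_index(cc$in_fm$H, cc$in_fm$W, N)
      dX <- matrix(0, nrow(cc$in_fm$x), ncol(dY))
      for (k in 1:4) {
        mk <- cc$win == k
        if (!any(mk)) next
        contrib <- dY * mk
        rows <- pi_$idx[, k]
        dX[rows, ] <- dX[rows, ] + contrib
      }
      dY <- dX
    } else if (ly$type == "tanh") {
      dY <- dY * (1 - cc$y * cc$y)
    }
  }
  list(d_input = dY, d_params = d_params)
}

# update batch-norm running statistics after a training-mode forward
bn_update_running <- function(layers, fwd) {
  for (i in seq_along(fwd$caches)) {
    if (layers[[i]]$type == "bn" && !is.null(fwd$caches[[i]]$mu)) {
      mom <- layers[[i]]$momentum
      layers[[i]]$run_mean <- (1 - mom) * layers[[i]]$run_mean +
        mom * fwd$caches[[i]]$mu
      layers[[i]]$run_var <- (1 - mom) * layers[[i]]$run_var +
        mom * fwd$caches[[i]]$var
    }
  }
  layers
}

# --- Adam optimizer ----------------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type == "conv")
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    else if (ly$type == "bn")
      list(mg = ly$gamma * 0, vg = ly$gamma * 0,
           mB = ly$beta * 0, vB = ly$beta * 0)
    else NULL
  })
}

.adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_update <- function(layers, state, d_params, lr, t) {
  for (i in seq_along(d_params)) {
    dp <- d_params[[i]]
    if (is.null(dp)) next
    ly <- layers[[i]]
    if (ly$type == "conv") {
      s <- .adam_step(ly$W, dp$W, state[[i]]$mW, state[[i]]$vW, lr, t)
      layers[[i]]$W <- s$p; state[[i]]$mW <- s$m; state[[i]]$vW <- s$v
      s <- .adam_step(ly$b, dp$b, state[[i]]$mb, state[[i]]$vb, lr, t)
      layers[[i]]$b <- s$p; state[[i]]$mb <- s$m; state[[i]]$vb <- s$v
    } else if (ly$type == "bn") {
      s <- .adam_step(ly$gamma, dp$gamma, state[[i]]$mg, state[[i]]$vg, lr, t)
      layers[[i]]$gamma <- s$p; state[[i]]$mg <- s$m; state[[i]]$vg <- s$v
      s <- .adam_step(ly$beta, dp$beta, state[[i]]$mB, state[[i]]$vB, lr, t)
      layers[[i]]$beta <- s$p; state[[i]]$mB <- s$m; state[[i]]$vB <- s$v
    }
  }
  list(layers = layers, state = state)
}

# run `expr` under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
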