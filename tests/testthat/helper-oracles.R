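# Independent reference implementations used to validate the fast paths.
# These are deliberately written as plain step-by-step computations
# (scalar chains, double loops) that share no code with the package.

# scalar sRGB [0,255] triplet -> Lab via the published sRGB/D65 matrices
oracle_rgb_to_lab <- function(r, g, b) {
  expand <- function(c) {
    c <- c / 255
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  }
  rl <- expand(r); gl <- expand(g); bl <- expand(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  Xn <- 0.4124564 + 0.3575761 + 0.1804375
  Yn <- 0.2126729 + 0.7151522 + 0.0721750
  Zn <- 0.0193339 + 0.1191920 + 0.9503041
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  c(L = 116 * f(Y / Yn) - 16,
    a = 500 * (f(X / Xn) - f(Y / Yn)),
    b = 200 * (f(Y / Yn) - f(Z / Zn)))
}

# scalar sRGB triplet -> Luv via u'v' chromaticities
oracle_rgb_to_luv <- function(r, g, b) {
  expand <- function(c) {
    c <- c / 255
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  }
  rl <- expand(r); gl <- expand(g); bl <- expand(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  Xn <- 0.4124564 + 0.3575761 + 0.1804375
  Yn <- 0.2126729 + 0.7151522 + 0.0721750
  Zn <- 0.0193339 + 0.1191920 + 0.9503041
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  L <- 116 * f(Y / Yn) - 16
  up <- 4 * X / (X + 15 * Y + 3 * Z)
  vp <- 9 * Y / (X + 15 * Y + 3 * Z)
  upn <- 4 * Xn / (Xn + 15 * Yn + 3 * Zn)
  vpn <- 9 * Yn / (Xn + 15 * Yn + 3 * Zn)
  c(L = L, u = 13 * L * (up - upn), v = 13 * L * (vp - vpn))
}

# brute-force Gram matrix: double loop over channel pairs
oracle_gram <- function(feats) {
  C <- dim(feats)[3]
  G <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C))
    G[i, j] <- sum(feats[, , i] * feats[, , j])
  G
}

# brute-force style/content transfer loss for single-layer fixtures
oracle_transfer_loss <- function(ft, fr, fc, w_style, w_content,
                                 style_weight, content_weight) {
  N <- dim(ft)[1] * dim(ft)[2]
  C <- dim(ft)[3]
  Gt <- oracle_gram(ft)
  Gr <- oracle_gram(fr)
  style <- w_style * sum((Gt - Gr)^2) / (2 * N * C)^2
  content <- w_content * mean((ft - fc)^2)
  list(total = style_weight * style + content_weight * content,
       style = style, content = content)
}

# brute-force Gaussian-window SSIM over valid window positions
oracle_ssim <- function(x, y, win = 11, sigma = 1.5, max_value = 255,
                        alpha = 1, beta = 1, gamma = 1) {
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  w2 <- outer(g, g)
  C1 <- (0.01 * max_value)^2
  C2 <- (0.03 * max_value)^2
  C3 <- C2 / 2
  vals <- c()
  for (i in seq_len(nrow(x) - win + 1)) {
    for (j in seq_len(ncol(x) - win + 1)) {
      px <- x[i:(i + win - 1), j:(j + win - 1)]
      py <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(w2 * px); my <- sum(w2 * py)
      vx <- sum(w2 * px^2) - mx^2
      vy <- sum(w2 * py^2) - my^2
      cxy <- sum(w2 * px * py) - mx * my
      l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
      cc <- (2 * sqrt(vx) * sqrt(vy) + C2) / (vx + vy + C2)
      ss <- (cxy + C3) / (sqrt(vx) * sqrt(vy) + C3)
      vals <- c(vals, l^alpha * cc^beta * ss^gamma)
    }
  }
  mean(vals)
}

# flat RGB planar image helpers
flat_rgb <- function(r, g, b, h = 2, w = 2) {
  planar_image(array(rep(c(r, g, b), each = h * w), c(h, w, 3)), "RGB8")
}

flat_gray <- function(v, h = 8, w = 8) {
  planar_image(array(v, c(h, w, 1)), "GRAY")
}

# small seeded extractor used wherever full VGG width is unnecessary
small_extractor_spec <- function() {
  feature_extractor_spec(blocks = list(c(2L, 8L), c(2L, 16L), c(2L, 16L),
                                       c(2L, 32L), c(2L, 32L)))
}
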