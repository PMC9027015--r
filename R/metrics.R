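# Full-reference image quality: MSE, PSNR and SSIM, plus batch reports.
#
# PSNR follows 10*log10(MAX^2 / MSE). SSIM combines local luminance,
# contrast and structure comparisons, each computed over a Gaussian-
# weighted sliding window (valid windows only, no padding), as
# l^alpha * c^beta * s^gamma averaged over window positions.

.as_planes <- function(x) {
  if (is_planar(x)) return(x$pixels)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a planar_image, matrix or H x W x C array")
}

#' Mean squared error between two images
#'
#' @param ref,test images of identical shape (`planar_image`, matrix or
#'   array).
#' @return the per-pixel mean squared difference over all channels.
#' @export
compute_mse <- function(ref, test) {
  a <- .as_planes(ref); b <- .as_planes(test)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(max_value^2 / MSE)` in decibels, with the MSE taken
#' jointly over all channels. Identical images have zero MSE and no finite
#' PSNR; the function then returns `Inf`, which downstream reports
#' serialize as the identical-flag `"inf"`.
#'
#' @param ref,test images of identical shape.
#' @param max_value peak intensity of the value range (255 for 8-bit).
#' @return PSNR in dB, or `Inf` for identical images.
#' @export
compute_psnr <- function(ref, test, max_value = 255) {
  if (max_value <= 0) stop("max_value must be positive")
  mse <- compute_mse(ref, test)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

# valid-mode separable Gaussian window as a band matrix: (n-win+1) x n
.gauss_band <- function(n, win, sigma) {
  if (n < win) stop(sprintf("image extent %d smaller than window %d", n, win))
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  m <- matrix(0, n - win + 1L, n)
  for (i in seq_len(n - win + 1L)) m[i, i:(i + win - 1L)] <- g
  m
}

# luminance plane in [0, max] for SSIM: GRAY as-is, RGB via Lab lightness
.luminance_plane <- function(x, max_value) {
  if (is_planar(x)) {
    if (x$space == "GRAY") return(x$pixels[, , 1L])
    if (x$space == "RGB8") return(rgb_to_lab(x)$pixels[, , 1L] * 2.55)
    stop("SSIM expects GRAY or RGB8 images")
  }
  p <- .as_planes(x)
  if (dim(p)[3L] == 1L) return(p[, , 1L])
  if (dim(p)[3L] == 3L)
    return(rgb_to_lab(planar_image(p, "RGB8"))$pixels[, , 1L] * 2.55)
  stop("SSIM expects 1- or 3-channel input")
}

#' Structural similarity index
#'
#' Local means, variances and covariance are computed under a Gaussian
#' window (default 11 x 11, sigma 1.5) over all fully interior window
#' positions; the three comparison terms are combined per window as
#' `l^alpha * c^beta * s^gamma` and averaged. Color images are reduced to
#' the lightness channel first. With the default stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2` (dynamic range
#' `L = max_value`) and unit exponents this is the standard SSIM; the
#' structure term can make the index negative on anti-correlated inputs,
#' so the attainable range is `[-1, 1]` with 1 reached exactly at
#' identity.
#'
#' @param ref,test images of identical shape.
#' @param alpha,beta,gamma exponents of the luminance, contrast and
#'   structure terms (defaults 1).
#' @param window `c(size, sigma)` of the Gaussian window.
#' @param constants optional `c(C1, C2, C3)` overriding the defaults.
#' @param max_value dynamic range of the data (255 for 8-bit).
#' @return mean SSIM over window positions.
#' @export
compute_ssim <- function(ref, test, alpha = 1, beta = 1, gamma = 1,
                         window = c(11, 1.5), constants = NULL,
                         max_value = 255) {
  x <- .luminance_plane(ref, max_value)
  y <- .luminance_plane(test, max_value)
  if (!identical(dim(x), dim(y)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x")))
  win <- as.integer(window[1L]); sigma <- window[2L]
  if (is.null(constants)) {
    C1 <- (0.01 * max_value)^2
    C2 <- (0.03 * max_value)^2
    C3 <- C2 / 2
  } else {
    C1 <- constants[1L]; C2 <- constants[2L]; C3 <- constants[3L]
  }
  Bh <- .gauss_band(nrow(x), win, sigma)
  Bw <- t(.gauss_band(ncol(x), win, sigma))
  mu_x <- Bh %*% x %*% Bw
  mu_y <- Bh %*% y %*% Bw
  # local second moments; tiny negative variances from roundoff clamp to 0
  var_x <- pmax(Bh %*% (x * x) %*% Bw - mu_x^2, 0)
  var_y <- pmax(Bh %*% (y * y) %*% Bw - mu_y^2, 0)
  cov_xy <- Bh %*% (x * y) %*% Bw - mu_x * mu_y
  sd_x <- sqrt(var_x); sd_y <- sqrt(var_y)
  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cc <- (2 * sd_x * sd_y + C2) / (var_x + var_y + C2)
  ss <- (cov_xy + C3) / (sd_x * sd_y + C3)
  mean(l^alpha * cc^beta * ss^gamma)
}

#' Evaluate a batch of image pairs
#'
#' Computes MSE, PSNR and SSIM for every (reference, test) pair and
#' aggregates the means (PSNR averaged over pairs with finite PSNR).
#' Unreadable or mismatched pairs are reported in the `errors` field, not
#' silently dropped.
#'
#' @param pairs a data.frame with columns `ref` and `test` (file paths),
#'   or a path to a tab-separated file with those columns.
#' @param max_value dynamic range (255 for 8-bit files).
#' @return a `quality_report`: list with `pairs` (per-pair data.frame),
#'   `aggregate` (`mean_psnr`, `mean_ssim`) and `errors` (character).
#' @export
evaluate_batch <- function(pairs, max_value = 255) {
  if (is.character(pairs))
    pairs <- utils::read.delim(pairs, stringsAsFactors = FALSE)
  if (!all(c("ref", "test") %in% names(pairs)))
    stop("pairs must have columns 'ref' and 'test'")
  k <- nrow(pairs)
  out <- data.frame(ref = pairs$ref, test = pairs$test,
                    mse = NA_real_, psnr = NA_real_, ssim = NA_real_)
  errors <- character(0)
  for (i in seq_len(k)) {
    res <- tryCatch({
      r <- read_image(pairs$ref[i])
      t_ <- read_image(pairs$test[i])
      list(mse = compute_mse(r, t_),
           psnr = compute_psnr(r, t_, max_value),
           ssim = compute_ssim(r, t_, max_value = max_value))
    }, error = function(e)
      sprintf("pair %d (%s, %s): %s", i, pairs$ref[i], pairs$test[i],
              conditionMessage(e)))
    if (is.character(res)) {
      errors <- c(errors, res)
    } else {
      out$mse[i] <- res$mse; out$psnr[i] <- res$psnr; out$ssim[i] <- res$ssim
    }
  }
  finite_psnr <- out$psnr[!is.na(out$psnr) & is.finite(out$psnr)]
  structure(list(
    pairs = out,
    aggregate = list(
      mean_psnr = if (length(finite_psnr)) mean(finite_psnr) else NA_real_,
      mean_ssim = mean(out$ssim, na.rm = TRUE)),
    errors = errors), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report %d pair(s)>\n", nrow(x$pairs)))
  print(x$pairs, row.names = FALSE)
  cat(sprintf("aggregate: mean PSNR %.4f dB, mean SSIM %.4f\n",
              x$aggregate$mean_psnr, x$aggregate$mean_ssim))
  if (length(x$errors)) cat("errors:\n ", paste(x$errors, collapse = "\n  "),
                            "\n")
  invisible(x)
}

#' Write a quality report as delimited text
#'
#' Per-pair rows followed by an aggregate row; infinite PSNR (identical
#' images) serializes as `"inf"`.
#'
#' @param report a `quality_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "quality_report")) stop("expected a quality_report")
  df <- report$pairs
  fmt <- function(v) ifelse(is.na(v), "NA",
                            ifelse(is.finite(v), sprintf("%.6f", v), "inf"))
  lines <- c(paste(c("ref", "test", "mse", "psnr", "ssim"), collapse = "\t"),
             vapply(seq_len(nrow(df)), function(i)
               paste(c(df$ref[i], df$test[i], fmt(df$mse[i]),
                       fmt(df$psnr[i]), fmt(df$ssim[i])), collapse = "\t"),
               character(1)),
             paste(c("aggregate", "", "",
                     fmt(report$aggregate$mean_psnr),
                     fmt(report$aggregate$mean_ssim)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
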