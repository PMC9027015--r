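# CIE color space conversions: sRGB (D65, 2-degree observer) <-> Lab / Luv.
#
# The forward path is the textbook chain: piecewise sRGB gamma expansion,
# linear RGB -> XYZ through the sRGB/D65 primaries matrix, then the CIE
# Lab or Luv formulas. The reference white is taken as the XYZ image of
# RGB (1,1,1) under the same matrix, so the neutral axis maps to exactly
# zero chroma rather than inheriting rounding error from an external
# white point.

.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

.xyz_to_srgb_mat <- solve(.srgb_to_xyz_mat)

# reference white: XYZ of sRGB white under the same matrix (self-consistent D65)
.white_xyz <- as.numeric(.srgb_to_xyz_mat %*% c(1, 1, 1))

srgb_expand <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

srgb_compress <- function(lin) {
  lin <- pmax(lin, 0)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

# CIE f() with the (6/29)^3 linear toe
.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_finv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

# N x 3 matrix of [0,255] sRGB -> N x 3 XYZ (Y of white = 1)
rgb255_to_xyz <- function(rgb) {
  lin <- srgb_expand(rgb / 255)
  lin %*% t(.srgb_to_xyz_mat)
}

xyz_to_rgb255 <- function(xyz) {
  lin <- xyz %*% t(.xyz_to_srgb_mat)
  pmin(pmax(srgb_compress(lin) * 255, 0), 255)
}

.chan_mat <- function(img) {
  # H*W x C matrix view of the pixel array (column-major pixel order)
  d <- dim(img$pixels)
  matrix(img$pixels, d[1L] * d[2L], d[3L])
}

.from_chan_mat <- function(m, img, space) {
  planar_image(array(m, c(img$height, img$width, ncol(m))), space)
}

#' Convert an RGB image to CIE Lab
#'
#' sRGB gamma expansion, linear RGB to XYZ under the D65 white point
#' (2-degree observer), then the CIE Lab formulas. `L` lands in
#' `[0, 100]`; `a` and `b` are clamped to `[-128, 127]`.
#'
#' @param img an RGB8 `planar_image`.
#' @return a LAB `planar_image` of the same height and width.
#' @export
rgb_to_lab <- function(img) {
  assert_space(img, "RGB8")
  xyz <- rgb255_to_xyz(.chan_mat(img))
  fx <- .lab_f(xyz[, 1L] / .white_xyz[1L])
  fy <- .lab_f(xyz[, 2L] / .white_xyz[2L])
  fz <- .lab_f(xyz[, 3L] / .white_xyz[3L])
  lab <- cbind(116 * fy - 16,
               pmin(pmax(500 * (fx - fy), -128), 127),
               pmin(pmax(200 * (fy - fz), -128), 127))
  .from_chan_mat(lab, img, "LAB")
}

#' Convert a CIE Lab image back to RGB
#'
#' Inverse of [rgb_to_lab()]. Out-of-gamut results are clipped to
#' `[0, 255]`, never rejected: predicted chroma routinely leaves the sRGB
#' gamut and clipping is the rendering convention here.
#'
#' @param img a LAB `planar_image`.
#' @return an RGB8 `planar_image`.
#' @export
lab_to_rgb <- function(img) {
  assert_space(img, "LAB")
  m <- .chan_mat(img)
  fy <- (m[, 1L] + 16) / 116
  fx <- fy + m[, 2L] / 500
  fz <- fy - m[, 3L] / 200
  xyz <- cbind(.lab_finv(fx) * .white_xyz[1L],
               .lab_finv(fy) * .white_xyz[2L],
               .lab_finv(fz) * .white_xyz[3L])
  .from_chan_mat(xyz_to_rgb255(xyz), img, "RGB8")
}

.luv_uv_prime <- function(xyz) {
  den <- xyz[, 1L] + 15 * xyz[, 2L] + 3 * xyz[, 3L]
  den[den == 0] <- 1          # black: u', v' irrelevant, chroma is zero via L
  cbind(4 * xyz[, 1L] / den, 9 * xyz[, 2L] / den)
}

.white_uv <- .luv_uv_prime(matrix(.white_xyz, 1))

#' Convert an RGB image to CIE Luv
#'
#' Same lightness `L` as Lab; chroma through the `u' v'` chromaticity
#' coordinates, D65 white. `u` is clamped to `[-134, 220]`, `v` to
#' `[-140, 122]`.
#'
#' @param img an RGB8 `planar_image`.
#' @return a LUV `planar_image`.
#' @export
rgb_to_luv <- function(img) {
  assert_space(img, "RGB8")
  xyz <- rgb255_to_xyz(.chan_mat(img))
  L <- 116 * .lab_f(xyz[, 2L] / .white_xyz[2L]) - 16
  uv <- .luv_uv_prime(xyz)
  luv <- cbind(L,
               pmin(pmax(13 * L * (uv[, 1L] - .white_uv[1L]), -134), 220),
               pmin(pmax(13 * L * (uv[, 2L] - .white_uv[2L]), -140), 122))
  .from_chan_mat(luv, img, "LUV")
}

#' Convert a CIE Luv image back to RGB
#'
#' Inverse of [rgb_to_luv()] with gamut clipping to `[0, 255]`.
#'
#' @param img a LUV `planar_image`.
#' @return an RGB8 `planar_image`.
#' @export
luv_to_rgb <- function(img) {
  assert_space(img, "LUV")
  m <- .chan_mat(img)
  L <- m[, 1L]
  nz <- L > 1e-8
  up <- ifelse(nz, m[, 2L] / (13 * pmax(L, 1e-8)) + .white_uv[1L], .white_uv[1L])
  vp <- ifelse(nz, m[, 3L] / (13 * pmax(L, 1e-8)) + .white_uv[2L], .white_uv[2L])
  Y <- .lab_finv((L + 16) / 116) * .white_xyz[2L]
  vp <- pmax(vp, 1e-8)
  X <- Y * 9 * up / (4 * vp)
  Z <- Y * (12 - 3 * up - 20 * vp) / (4 * vp)
  .from_chan_mat(xyz_to_rgb255(cbind(X, Y, Z)), img, "RGB8")
}

# linear-RGB (gamma-expanded, unclipped) image of a Lab / Luv channel matrix
.lab_to_linear <- function(m) {
  fy <- (m[, 1L] + 16) / 116
  fx <- fy + m[, 2L] / 500
  fz <- fy - m[, 3L] / 200
  cbind(.lab_finv(fx) * .white_xyz[1L],
        .lab_finv(fy) * .white_xyz[2L],
        .lab_finv(fz) * .white_xyz[3L]) %*% t(.xyz_to_srgb_mat)
}

.luv_to_linear <- function(m) {
  L <- m[, 1L]
  up <- m[, 2L] / (13 * pmax(L, 1e-8)) + .white_uv[1L]
  vp <- pmax(m[, 3L] / (13 * pmax(L, 1e-8)) + .white_uv[2L], 1e-8)
  Y <- .lab_finv((L + 16) / 116) * .white_xyz[2L]
  cbind(Y * 9 * up / (4 * vp), Y,
        Y * (12 - 3 * up - 20 * vp) / (4 * vp)) %*% t(.xyz_to_srgb_mat)
}

# Render perceptual-space pixels to RGB while preserving lightness exactly:
# out-of-gamut pixels have their chroma scaled toward the neutral axis
# (which is always in gamut for L in [0, 100]) by per-pixel bisection until
# the linear RGB lands inside [0, 1]. Used when re-attaching a predicted
# chroma to an original luminance plane.
render_preserving_lightness <- function(per, space = c("LAB", "LUV")) {
  space <- match.arg(space)
  lin_of <- if (space == "LAB") .lab_to_linear else .luv_to_linear
  d <- dim(per)
  m <- matrix(per, d[1L] * d[2L], 3L)
  tol <- 1e-7
  lin <- lin_of(m)
  bad <- which(lin[, 1L] < -tol | lin[, 1L] > 1 + tol |
               lin[, 2L] < -tol | lin[, 2L] > 1 + tol |
               lin[, 3L] < -tol | lin[, 3L] > 1 + tol)
  if (length(bad)) {
    lo <- rep(0, length(bad))
    hi <- rep(1, length(bad))
    sub <- m[bad, , drop = FALSE]
    for (it in 1:22) {
      s <- (lo + hi) / 2
      cand <- cbind(sub[, 1L], s * sub[, 2L], s * sub[, 3L])
      lc <- lin_of(cand)
      ok <- lc[, 1L] >= -tol & lc[, 1L] <= 1 + tol &
            lc[, 2L] >= -tol & lc[, 2L] <= 1 + tol &
            lc[, 3L] >= -tol & lc[, 3L] <= 1 + tol
      lo[ok] <- s[ok]
      hi[!ok] <- s[!ok]
    }
    m[bad, 2:3] <- lo * sub[, 2:3]
    lin[bad, ] <- lin_of(m[bad, , drop = FALSE])
  }
  rgb <- pmin(pmax(srgb_compress(pmin(pmax(lin, 0), 1)) * 255, 0), 255)
  planar_image(array(rgb, c(d[1L], d[2L], 3L)), "RGB8")
}

# half-spans used to map chroma onto the tanh range of the network head
.chroma_scale <- list(LAB_AB = c(128, 128), LUV_UV = c(177, 131))

#' Chroma channel pair
#'
#' The two chroma planes of a perceptual space, either raw (`a`/`b` or
#' `u`/`v` units) or scaled to the network's `[-1, 1]` range.
#'
#' @param values `H x W x 2` numeric array.
#' @param space `"LAB_AB"` or `"LUV_UV"`.
#' @param normalization `"raw"` or `"network_scaled"`.
#' @return a `chroma_pair` object.
#' @export
chroma_pair <- function(values, space = c("LAB_AB", "LUV_UV"),
                        normalization = c("raw", "network_scaled")) {
  space <- match.arg(space)
  normalization <- match.arg(normalization)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[3L] != 2L)
    stop("'values' must be an H x W x 2 array")
  storage.mode(values) <- "double"
  if (normalization == "network_scaled" &&
      (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9))
    stop("network_scaled chroma must lie in [-1, 1]")
  structure(list(values = values, space = space, normalization = normalization),
            class = "chroma_pair")
}

#' Scale chroma between raw and network ranges
#'
#' `to_network` divides each chroma plane by its half-span (128 for `a`/`b`;
#' 177 and 131 for `u` and `v`) and clamps to `[-1, 1]`, the symmetric
#' target range of the tanh output head. `from_network` multiplies back;
#' it inverts `to_network` exactly for in-range chroma.
#'
#' @param chroma a `chroma_pair`.
#' @param direction `"to_network"` or `"from_network"`.
#' @return a `chroma_pair` with the opposite normalization tag.
#' @export
scale_chroma <- function(chroma, direction = c("to_network", "from_network")) {
  direction <- match.arg(direction)
  if (!inherits(chroma, "chroma_pair")) stop("expected a chroma_pair")
  s <- .chroma_scale[[chroma$space]]
  if (direction == "to_network") {
    if (chroma$normalization != "raw")
      stop("double scaling: chroma is already network_scaled")
    v <- chroma$values
    v[, , 1L] <- pmin(pmax(v[, , 1L] / s[1L], -1), 1)
    v[, , 2L] <- pmin(pmax(v[, , 2L] / s[2L], -1), 1)
    chroma_pair(v, chroma$space, "network_scaled")
  } else {
    if (chroma$normalization != "network_scaled")
      stop("double scaling: chroma is already raw")
    v <- chroma$values
    v[, , 1L] <- v[, , 1L] * s[1L]
    v[, , 2L] <- v[, , 2L] * s[2L]
    chroma_pair(v, chroma$space, "raw")
  }
}
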