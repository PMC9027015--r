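#' Planar image container
#'
#' A `planar_image` is the package's universal image currency: an
#' `H x W x C` numeric array of pixel planes tagged with the color space the
#' values live in. All pixel data is kept in floating point; quantization to
#' 8 bits happens only when a file is written.
#'
#' Recognized spaces and their value ranges:
#' \describe{
#'   \item{RGB8}{3 channels, each in `[0, 255]`.}
#'   \item{GRAY}{1 channel in `[0, 255]`.}
#'   \item{LAB}{`L` in `[0, 100]`, `a` and `b` in `[-128, 127]`.}
#'   \item{LUV}{`L` in `[0, 100]`, `u` in `[-134, 220]`, `v` in `[-140, 122]`.}
#' }
#'
#' @param pixels numeric array of dimension `H x W x C` (a plain `H x W`
#'   matrix is accepted for GRAY and gains a unit channel dimension).
#' @param space one of `"RGB8"`, `"GRAY"`, `"LAB"`, `"LUV"`.
#' @return An object of class `planar_image` with fields `pixels`, `space`,
#'   `height`, `width`, `channels`.
#' @export
planar_image <- function(pixels, space = c("RGB8", "GRAY", "LAB", "LUV")) {
  space <- match.arg(space)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("'pixels' must be an H x W x C array")
  storage.mode(pixels) <- "double"
  want <- c(RGB8 = 3L, GRAY = 1L, LAB = 3L, LUV = 3L)[[space]]
  if (dim(pixels)[3L] != want)
    stop(sprintf("space %s requires %d channel(s), got %d",
                 space, want, dim(pixels)[3L]))
  if (anyNA(pixels) || !all(is.finite(pixels)))
    stop("'pixels' must be finite")
  structure(
    list(pixels = pixels, space = space,
         height = dim(pixels)[1L], width = dim(pixels)[2L],
         channels = dim(pixels)[3L]),
    class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image %dx%dx%d space=%s range=[%.2f, %.2f]>\n",
              x$height, x$width, x$channels, x$space,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.planar_image <- function(x) dim(x$pixels)

is_planar <- function(x) inherits(x, "planar_image")

assert_space <- function(img, space) {
  if (!is_planar(img)) stop("expected a planar_image")
  if (!img$space %in% space)
    stop(sprintf("invalid color space: expected %s, got %s",
                 paste(space, collapse = "/"), img$space))
  invisible(img)
}

#' Promote a grayscale image to a lightness plane
#'
#' Maps GRAY values `[0, 255]` linearly onto the CIE lightness range
#' `[0, 100]`, the convention used when a grayscale target enters either
#' colorization path.
#'
#' @param img a GRAY `planar_image`.
#' @return an `H x W` numeric matrix of `L` values in `[0, 100]`.
#' @export
gray_to_lightness <- function(img) {
  assert_space(img, "GRAY")
  img$pixels[, , 1L] * (100 / 255)
}

#' Read an image file as a planar_image
#'
#' PNG, JPEG and TIFF (8-bit) are supported. Color files load as RGB8,
#' single-channel files as GRAY; an alpha channel, if present, is dropped.
#'
#' @param path file path; format is inferred from the extension.
#' @return a `planar_image` in RGB8 or GRAY.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3L] == 2L) raw <- raw[, , 1L, drop = FALSE]        # gray+alpha
  if (dim(raw)[3L] == 4L) raw <- raw[, , 1:3, drop = FALSE]       # rgb+alpha
  px <- raw * 255
  planar_image(px, if (dim(px)[3L] == 1L) "GRAY" else "RGB8")
}

#' Write a planar_image to an image file
#'
#' RGB8 and GRAY images are quantized to 8 bits (values clipped to
#' `[0, 255]` and rounded) at this point and only at this point.
#'
#' @param img an RGB8 or GRAY `planar_image`.
#' @param path output path ending in .png, .jpg/.jpeg, .tif/.tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_space(img, c("RGB8", "GRAY"))
  px <- round(pmin(pmax(img$pixels, 0), 255)) / 255
  if (dim(px)[3L] == 1L) px <- px[, , 1L]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(px, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(px, path, quality = 0.95),
    tif  = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Bilinear image resize
#'
#' Resizes the pixel planes of an image (or a bare array) to a new height
#' and width with bilinear interpolation. Aspect ratio is not preserved;
#' the caller chooses the target size.
#'
#' @param x a `planar_image` or an `H x W (x C)` numeric array.
#' @param height,width target size in pixels.
#' @return same type as `x`, resized.
#' @export
resize_image <- function(x, height, width) {
  if (is_planar(x)) {
    out <- resize_image(x$pixels, height, width)
    return(planar_image(out, x$space))
  }
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1L] == height && dim(x)[2L] == width) return(x)
  out <- EBImage::resize(x, w = height, h = width, filter = "bilinear")
  array(out, c(height, width, dim(x)[3L]))
}
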