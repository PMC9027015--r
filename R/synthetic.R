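# Procedural stand-ins for the two data families the colorizers consume:
# colored meat-like reference/training textures and grayscale chest-CT-like
# phantoms. Everything is a pure function of its spec (seed included), so
# tests and pipelines need no downloads. Palette centroids are fixed
# constants chosen to mimic each class's hue family; they are synthetic
# stand-ins, not measurements of real meat.

# multi-octave value noise in [0, 1]: seeded random lattices, bilinearly
# interpolated to full resolution and summed with halving amplitudes
value_noise <- function(height, width, scale = 32, octaves = 4L, seed = 0L) {
  with_seed(seed, {
    acc <- matrix(0, height, width)
    amp <- 1
    total <- 0
    sc <- scale
    for (o in seq_len(octaves)) {
      nh <- max(2L, as.integer(ceiling(height / sc)) + 1L)
      nw <- max(2L, as.integer(ceiling(width / sc)) + 1L)
      lattice <- matrix(stats::runif(nh * nw), nh, nw)
      acc <- acc + amp * resize_image(lattice, height, width)[, , 1L]
      total <- total + amp
      amp <- amp / 2
      sc <- max(1, sc / 2)
    }
    acc / total
  })
}

.palettes <- list(
  pork   = list(base = c(232, 158, 168), marble = c(246, 228, 230),
                marbling = 0.15),
  steak  = list(base = c(148, 38, 44),  marble = c(238, 232, 226),
                marbling = 0.12),
  lamb   = list(base = c(172, 58, 60),  marble = c(242, 236, 230),
                marbling = 0.30),
  rotten = list(base = c(112, 72, 52),  marble = c(150, 120, 96),
                marbling = 0.10, second = c(140, 48, 44)))

#' Specification of a meat-like reference texture
#'
#' @param palette_class one of `"pork"`, `"steak"`, `"lamb"`, `"rotten"`.
#'   pork: pink base with pale marbling; steak: deep red with white
#'   marbling; lamb: red with enlarged white fat regions (marbling
#'   fraction at least 0.25); rotten: brown/red mixture.
#' @param size `c(height, width)` in pixels (default 224 x 224, the
#'   training resolution of the automatic colorizer).
#' @param seed integer; the texture is a pure function of the spec.
#' @param blob_scale blob size of the base noise field, in pixels.
#' @param marbling_fraction fraction of pixels covered by marbling
#'   filaments; defaults to the class's own fraction.
#' @return a `texture_spec` object.
#' @export
texture_spec <- function(palette_class = c("pork", "steak", "lamb", "rotten"),
                         size = c(224L, 224L), seed = 0L, blob_scale = 48,
                         marbling_fraction = NULL) {
  palette_class <- match.arg(palette_class)
  if (is.null(marbling_fraction))
    marbling_fraction <- .palettes[[palette_class]]$marbling
  if (palette_class == "lamb" && marbling_fraction < 0.25)
    stop("lamb textures require marbling_fraction >= 0.25")
  if (marbling_fraction < 0 || marbling_fraction > 1)
    stop("marbling_fraction must lie in [0, 1]")
  if (blob_scale <= 0) stop("blob_scale must be positive")
  structure(list(palette_class = palette_class, size = as.integer(size),
                 seed = as.integer(seed), blob_scale = blob_scale,
                 marbling_fraction = marbling_fraction),
            class = "texture_spec")
}

#' Generate a meat-like color texture
#'
#' Smooth multi-octave value-noise blobs tinted by the class palette, with
#' marbling drawn as bright filamentous ridges (level sets of a finer noise
#' field) covering approximately the spec's marbling fraction of pixels.
#' Deterministic for a given spec.
#'
#' @param spec a [texture_spec()].
#' @return an RGB8 `planar_image`.
#' @export
generate_meat_texture <- function(spec) {
  if (!inherits(spec, "texture_spec")) stop("expected a texture_spec")
  h <- spec$size[1L]; w <- spec$size[2L]
  if (h < 16L || w < 16L) stop("texture size must be at least 16 x 16")
  pal <- .palettes[[spec$palette_class]]
  base_n <- value_noise(h, w, spec$blob_scale, 4L, spec$seed + 101L)
  ridge_n <- value_noise(h, w, spec$blob_scale / 3, 3L, spec$seed + 202L)
  ridge <- abs(ridge_n - stats::median(ridge_n))
  thr <- stats::quantile(ridge, spec$marbling_fraction, names = FALSE)
  mask <- ridge <= thr
  px <- array(0, c(h, w, 3L))
  shade <- 0.75 + 0.5 * base_n          # darker/lighter meat blobs
  for (ch in 1:3) px[, , ch] <- pal$base[ch] * shade
  if (!is.null(pal$second)) {           # rotten: brown/red patchwork
    mix_n <- value_noise(h, w, spec$blob_scale * 1.5, 3L, spec$seed + 303L)
    mixw <- pmin(pmax((mix_n - 0.45) / 0.1, 0), 1)
    for (ch in 1:3)
      px[, , ch] <- px[, , ch] * (1 - mixw) + pal$second[ch] * shade * mixw
  }
  for (ch in 1:3) {                     # hard marbling keeps fat near-white
    plane <- px[, , ch]
    plane[mask] <- pal$marble[ch]
    px[, , ch] <- plane
  }
  grain <- with_seed(spec$seed + 404L,
                     matrix(stats::runif(h * w, -6, 6), h, w))
  for (ch in 1:3) px[, , ch] <- pmin(pmax(px[, , ch] + grain, 0), 255)
  planar_image(px, "RGB8")
}

#' Specification of a lung-CT-like grayscale phantom
#'
#' @param condition `"healthy"` or `"infected"`. Healthy phantoms must have
#'   `infiltrate_count = 0`; infected phantoms at least 1.
#' @param size `c(height, width)` in pixels.
#' @param seed integer seed.
#' @param infiltrate_count number of bright infiltrate patches placed
#'   inside the lung fields (infected only).
#' @param infiltrate_intensity patch brightness as a fraction of the
#'   dynamic range, in `(0, 1]`.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(condition = c("healthy", "infected"),
                         size = c(224L, 224L), seed = 0L,
                         infiltrate_count = NULL,
                         infiltrate_intensity = 0.6) {
  condition <- match.arg(condition)
  if (is.null(infiltrate_count))
    infiltrate_count <- if (condition == "healthy") 0L else 3L
  infiltrate_count <- as.integer(infiltrate_count)
  if (condition == "healthy" && infiltrate_count > 0L)
    stop("healthy phantoms must have infiltrate_count = 0")
  if (condition == "infected" && infiltrate_count < 1L)
    stop("infected phantoms require infiltrate_count >= 1")
  if (infiltrate_intensity <= 0 || infiltrate_intensity > 1)
    stop("infiltrate_intensity must lie in (0, 1]")
  structure(list(condition = condition, size = as.integer(size),
                 seed = as.integer(seed),
                 infiltrate_count = infiltrate_count,
                 infiltrate_intensity = infiltrate_intensity),
            class = "phantom_spec")
}

#' Generate a lung-CT-like grayscale phantom
#'
#' A bright body ellipse on a dark background with two dark interior
#' lung-field ellipses carrying faint vessel-like bright filaments.
#' Infected phantoms add blurred bright infiltrate patches inside the lung
#' fields, emulating the more complicated texture of infected-lung CT
#' slices. The returned image carries a `lung_mask` attribute (logical
#' H x W matrix of the lung fields). Deterministic for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return a GRAY `planar_image` with attribute `lung_mask`.
#' @export
generate_lung_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec")
  h <- spec$size[1L]; w <- spec$size[2L]
  if (h < 16L || w < 16L) stop("phantom size must be at least 16 x 16")
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  inside <- function(ecy, ecx, ry, rx)
    ((yy - ecy) / ry)^2 + ((xx - ecx) / rx)^2 <= 1
  body <- inside(cy, cx, 0.42 * h, 0.46 * w)
  lungL <- inside(cy, cx - 0.21 * w, 0.30 * h, 0.15 * w)
  lungR <- inside(cy, cx + 0.21 * w, 0.30 * h, 0.15 * w)
  lungs <- lungL | lungR
  tex <- value_noise(h, w, 24, 3L, spec$seed + 11L)
  img <- 18 + 10 * tex                                # air background
  img[body] <- 175 + 35 * tex[body]                   # soft tissue
  img[lungs] <- 42 + 18 * tex[lungs]                  # aerated lung
  vess_n <- value_noise(h, w, 10, 3L, spec$seed + 22L)
  vridge <- abs(vess_n - stats::median(vess_n))
  vmask <- lungs & vridge <= stats::quantile(vridge, 0.08, names = FALSE)
  img[vmask] <- img[vmask] + 55                       # vessel filaments
  if (spec$infiltrate_count > 0L) {
    lung_px <- which(lungs)
    centers <- with_seed(spec$seed + 33L,
                         sample(lung_px, spec$infiltrate_count))
    radius <- 0.07 * min(h, w)
    for (p in centers) {
      py <- (p - 1) %% h + 1
      px_ <- (p - 1) %/% h + 1
      d2 <- (yy - py)^2 + (xx - px_)^2
      bump <- 150 * spec$infiltrate_intensity * exp(-d2 / (2 * radius^2))
      img[lungs] <- img[lungs] + bump[lungs]          # infiltrates stay inside
    }
  }
  img <- pmin(pmax(img, 0), 255)
  out <- planar_image(array(img, c(h, w, 1L)), "GRAY")
  attr(out, "lung_mask") <- lungs
  out
}

#' Generate a seeded dataset on disk with a manifest
#'
#' Writes `n` PNG images plus a tab-separated manifest describing each.
#' Kinds: `"textures"` cycles through the four palette classes;
#' `"phantoms"` alternates healthy/infected; `"paired"` writes each color
#' texture together with its grayscale rendition (the Lab `L` channel
#' rescaled to `[0, 255]`), the supervised-training format of the
#' automatic colorizer.
#'
#' @param n number of items.
#' @param kind `"textures"`, `"phantoms"` or `"paired"`.
#' @param seed integer; item `i` uses seed `seed + i`.
#' @param out_dir output directory, created if needed.
#' @param size image size `c(height, width)`.
#' @return the manifest as a data.frame (also written to
#'   `manifest.tsv` in `out_dir`), invisibly.
#' @export
generate_dataset <- function(n, kind = c("textures", "phantoms", "paired"),
                             seed = 0L, out_dir, size = c(224L, 224L)) {
  kind <- match.arg(kind)
  if (n < 1L) stop("n must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) stop("out_dir is not writable: ", out_dir)
  classes <- names(.palettes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    item_seed <- seed + i
    if (kind == "phantoms") {
      cond <- if (i %% 2L == 1L) "healthy" else "infected"
      img <- generate_lung_phantom(phantom_spec(cond, size, item_seed))
      fn <- sprintf("phantom_%03d_%s.png", i, cond)
      write_image(img, file.path(out_dir, fn))
      rows[[i]] <- data.frame(file = fn, gray_file = NA_character_,
                              class = cond, seed = item_seed,
                              height = size[1L], width = size[2L])
    } else {
      cls <- classes[(i - 1L) %% 4L + 1L]
      img <- generate_meat_texture(texture_spec(cls, size, item_seed))
      fn <- sprintf("texture_%03d_%s.png", i, cls)
      write_image(img, file.path(out_dir, fn))
      gfn <- NA_character_
      if (kind == "paired") {
        L <- rgb_to_lab(img)$pixels[, , 1L] * 2.55
        gray <- planar_image(array(L, c(size, 1L)), "GRAY")
        gfn <- sprintf("texture_%03d_%s_gray.png", i, cls)
        write_image(gray, file.path(out_dir, gfn))
      }
      rows[[i]] <- data.frame(file = fn, gray_file = gfn, class = cls,
                              seed = item_seed,
                              height = size[1L], width = size[2L])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
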