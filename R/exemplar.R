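# Exemplar colorization by iterative pixel-space optimization: the target
# grayscale image (replicated to three channels) is pushed down the
# gradient of a feature loss whose style term matches Gram matrices of a
# layered convolutional extractor against a colored reference image, and
# whose content term anchors the features of the evolving image to the
# original target. With a strongly colored reference the optimization
# recolors the target wholesale, which is the intended behavior; luminance
# re-imposition is available but off by default.

#' Specification of the exemplar feature extractor
#'
#' The default follows the five-block VGG-19 topology: 3x3 stride-1
#' size-preserving convolutions (so a 400 x 585 input keeps its spatial
#' size through a block), conv counts (2, 2, 4, 4, 4) with filter widths
#' (64, 128, 256, 512, 512), and 2x2 max pooling between blocks. Weights
#' come from a user-supplied file when available, else from a seeded
#' random He-normal initialization; the transfer engine accepts any
#' spec-conforming extractor.
#'
#' @param blocks list of `c(conv_count, filters)` pairs, one per block.
#' @param pooling_between_blocks insert 2x2 max pooling after each block
#'   except the last (default `TRUE`).
#' @param weight_source `"seeded_random"` or a path to a weights file
#'   saved by [save_extractor_weights()].
#' @return a `feature_extractor_spec`.
#' @export
feature_extractor_spec <- function(blocks = list(c(2L, 64L), c(2L, 128L),
                                                 c(4L, 256L), c(4L, 512L),
                                                 c(4L, 512L)),
                                   pooling_between_blocks = TRUE,
                                   weight_source = "seeded_random") {
  if (!length(blocks)) stop("at least one block required")
  structure(list(blocks = blocks,
                 kernel = c(3L, 3L), stride = 1L,
                 pooling_between_blocks = isTRUE(pooling_between_blocks),
                 weight_source = weight_source),
            class = "feature_extractor_spec")
}

#' Build the feature extractor
#'
#' @param spec a [feature_extractor_spec()].
#' @param seed seed for the random initialization (ignored when the spec
#'   names a weights file).
#' @return a `feature_extractor`: engine layers plus a table of named
#'   taps (`blockB_convK`) mapping layer ids to layer indices.
#' @export
build_feature_extractor <- function(spec = feature_extractor_spec(),
                                    seed = 0L) {
  if (!inherits(spec, "feature_extractor_spec"))
    stop("expected a feature_extractor_spec")
  layers <- list()
  taps <- integer(0)
  c_in <- 3L
  for (b in seq_along(spec$blocks)) {
    nconv <- spec$blocks[[b]][1L]
    filters <- spec$blocks[[b]][2L]
    for (k in seq_len(nconv)) {
      layers <- c(layers, list(layer_conv(c_in, filters, 1L),
                               layer_lrelu(0)))   # slope 0 = plain ReLU
      taps[sprintf("block%d_conv%d", b, k)] <- length(layers)
      c_in <- filters
    }
    if (spec$pooling_between_blocks && b < length(spec$blocks))
      layers <- c(layers, list(layer_maxpool()))
  }
  if (is.character(spec$weight_source) &&
      spec$weight_source != "seeded_random") {
    stored <- readRDS(spec$weight_source)
    for (i in seq_along(layers))
      if (layers[[i]]$type == "conv") {
        layers[[i]]$W <- stored[[as.character(i)]]$W
        layers[[i]]$b <- stored[[as.character(i)]]$b
      }
  } else {
    layers <- init_net_weights(layers, seed)
  }
  structure(list(spec = spec, layers = layers, taps = taps),
            class = "feature_extractor")
}

#' @rdname build_feature_extractor
#' @param extractor a built `feature_extractor`.
#' @param path destination file.
#' @export
save_extractor_weights <- function(extractor, path) {
  w <- list()
  for (i in seq_along(extractor$layers))
    if (extractor$layers[[i]]$type == "conv")
      w[[as.character(i)]] <- extractor$layers[[i]][c("W", "b")]
  saveRDS(w, path)
  invisible(path)
}

#' Extract feature activations from the exemplar extractor
#'
#' Runs an image through the extractor once (only as deep as the deepest
#' requested layer) and returns the activation at each requested tap.
#' Layer ids follow the `blockB_convK` naming of
#' [build_feature_extractor()].
#'
#' @param extractor a built `feature_extractor`.
#' @param img an RGB8 `planar_image` or an `H x W x 3` array in `[0, 1]`.
#' @param layer_ids character vector of layer ids.
#' @return named list of `H x W x C` activation arrays.
#' @export
extract_features <- function(extractor, img, layer_ids) {
  if (is_planar(img)) {
    assert_space(img, "RGB8")
    img <- img$pixels / 255
  }
  unknown <- setdiff(layer_ids, names(extractor$taps))
  if (length(unknown))
    stop("unknown extractor layer(s): ", paste(unknown, collapse = ", "))
  tapidx <- extractor$taps[layer_ids]
  fwd <- net_forward(extractor$layers, array_to_featmap(img),
                     train = FALSE, upto = max(tapidx))
  fms <- replay_tap_featmaps(extractor$layers, fwd, tapidx)
  lapply(fms, function(fm) array(fm$x, c(fm$H, fm$W, ncol(fm$x))))
}

#' Gram matrix of a feature activation
#'
#' `G[i, j]` is the sum over all spatial positions of the product of
#' feature channels `i` and `j` — the unnormalized second-order statistic
#' that captures texture while discarding spatial layout. Normalization by
#' `(2 N C)^2` lives in the loss, so Gram entries are exact integers on
#' integer fixtures.
#'
#' @param features an `H x W x C` array (or a featmap from the engine).
#' @return a `C x C` symmetric positive-semidefinite matrix.
#' @export
gram_matrix <- function(features) {
  if (is.list(features) && !is.null(features$x)) {
    F <- features$x
  } else {
    if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
    if (!is.array(features) || length(dim(features)) != 3L)
      stop("expected an H x W x C activation array")
    if (length(features) == 0L) stop("empty activation")
    d <- dim(features)
    F <- matrix(features, d[1L] * d[2L], d[3L])
  }
  if (nrow(F) == 0L || ncol(F) == 0L) stop("empty activation")
  crossprod(F)
}

#' Configuration for exemplar color transfer
#'
#' @param style_layers named numeric vector: extractor layer ids
#'   (`"blockB_convK"`) to per-layer style weights. Default: the first
#'   convolution of each of the five blocks, equally weighted.
#' @param content_layers named numeric vector of content layer weights.
#'   Default: the second convolution of block 4.
#' @param style_weight,content_weight global weights of the two loss
#'   terms; at least one must be positive.
#' @param iterations gradient-descent steps (default 200).
#' @param step_size initial pixel-space step, in units of the `[0, 1]`
#'   intensity range per iteration. The descent direction is the gradient
#'   scaled to unit root-mean-square, so `step_size` is an intensity
#'   budget per step; it is halved whenever the recorded loss rises, which
#'   damps the overshoot a fixed step would otherwise sustain.
#' @param seed integer seed (drives extractor initialization when the
#'   engine builds the extractor itself).
#' @param snapshot_every record an intermediate image every this many
#'   iterations.
#' @param working_size `c(height, width)` both images are resized to
#'   before optimization (default 400 x 585).
#' @param preserve_luminance re-impose the target's luminance on the
#'   result (default `FALSE`: bright regions may be recolored wholesale).
#' @return a `style_transfer_config`.
#' @export
style_transfer_config <- function(style_layers = NULL, content_layers = NULL,
                                  style_weight = 1, content_weight = 1e-4,
                                  iterations = 200L, step_size = 0.02,
                                  seed = 0L, snapshot_every = 20L,
                                  working_size = c(400L, 585L),
                                  preserve_luminance = FALSE) {
  if (is.null(style_layers)) {
    style_layers <- rep(1 / 5, 5)
    names(style_layers) <- sprintf("block%d_conv1", 1:5)
  }
  if (is.null(content_layers))
    content_layers <- c(block4_conv2 = 1)
  if (style_weight < 0 || content_weight < 0)
    stop("loss weights must be non-negative")
  if (style_weight == 0 && content_weight == 0)
    stop("at least one of style_weight, content_weight must be positive")
  if (iterations < 0L) stop("iterations must be non-negative")
  if (step_size <= 0) stop("step_size must be positive")
  if (snapshot_every < 1L) stop("snapshot_every must be positive")
  structure(list(style_layers = style_layers,
                 content_layers = content_layers,
                 style_weight = style_weight,
                 content_weight = content_weight,
                 iterations = as.integer(iterations), step_size = step_size,
                 seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every),
                 working_size = as.integer(working_size),
                 preserve_luminance = isTRUE(preserve_luminance)),
            class = "style_transfer_config")
}

# features: named lists of featmaps keyed by layer id
.style_layer_loss <- function(Ft, Gr, N, C) {
  Gt <- crossprod(Ft)
  sum((Gt - Gr)^2) / (2 * N * C)^2
}

#' Style/content transfer loss
#'
#' The style part sums, over the configured style layers, the
#' `(2 N C)^-2`-normalized squared Frobenius difference of the Gram
#' matrices of target and reference features (`N` spatial positions, `C`
#' channels). The content part sums the per-layer mean squared feature
#' difference between target and content anchor. The total is
#' `style_weight * style + content_weight * content`.
#'
#' @param target_feats,reference_feats,content_feats named lists of
#'   `H x W x C` activation arrays keyed by layer id. `reference_feats`
#'   must cover the style layers, `content_feats` the content layers,
#'   `target_feats` both.
#' @param config a [style_transfer_config()].
#' @return list with `total`, `style_part`, `content_part`.
#' @export
transfer_loss <- function(target_feats, reference_feats, content_feats,
                          config) {
  as_fm <- function(a) {
    if (is.list(a) && !is.null(a$x)) return(a)
    d <- dim(a)
    featmap(matrix(a, d[1L] * d[2L], d[3L]), 1L, d[1L], d[2L])
  }
  need <- function(feats, id, who) {
    if (is.null(feats[[id]]))
      stop(sprintf("layer %s missing from %s features", id, who))
    as_fm(feats[[id]])
  }
  style_part <- 0
  for (id in names(config$style_layers)) {
    Ft <- need(target_feats, id, "target")
    Fr <- need(reference_feats, id, "reference")
    N <- nrow(Ft$x); C <- ncol(Ft$x)
    style_part <- style_part + config$style_layers[[id]] *
      .style_layer_loss(Ft$x, crossprod(Fr$x), N, C)
  }
  content_part <- 0
  for (id in names(config$content_layers)) {
    Ft <- need(target_feats, id, "target")
    Fc <- need(content_feats, id, "content")
    content_part <- content_part + config$content_layers[[id]] *
      mean((Ft$x - Fc$x)^2)
  }
  list(total = config$style_weight * style_part +
         config$content_weight * content_part,
       style_part = style_part, content_part = content_part)
}

#' Transfer colors from a reference image onto a grayscale target
#'
#' The target is promoted to three channels by replication, both images
#' are resized to the working size, and the output pixels are optimized
#' by gradient descent on [transfer_loss()]: style anchored to the
#' reference, content anchored to the replicated-gray target,
#' initialization at the replicated-gray target. Pixels are clamped to
#' the valid range after every step. Fully seeded and deterministic.
#'
#' @param target a GRAY `planar_image` (an RGB8 image is converted to
#'   luminance first).
#' @param reference an RGB8 `planar_image`.
#' @param extractor a built `feature_extractor`, or a
#'   [feature_extractor_spec()] (built with `config$seed`).
#' @param config a [style_transfer_config()].
#' @return list with `result` (RGB8 `planar_image`), `snapshots` (list of
#'   RGB8 images, one per `snapshot_every` iterations), `loss_trace` and
#'   `best_loss_trace` (numeric, one entry per iteration).
#' @export
transfer_colors <- function(target, reference,
                            extractor = feature_extractor_spec(),
                            config = style_transfer_config()) {
  if (!inherits(config, "style_transfer_config"))
    stop("expected a style_transfer_config")
  if (inherits(extractor, "feature_extractor_spec"))
    extractor <- build_feature_extractor(extractor, seed = config$seed)
  if (!inherits(extractor, "feature_extractor"))
    stop("expected a feature_extractor or feature_extractor_spec")
  if (is_planar(target) && target$space == "RGB8")
    target <- planar_image(
      array(rgb_to_lab(target)$pixels[, , 1L] * 2.55,
            c(target$height, target$width, 1L)), "GRAY")
  assert_space(target, "GRAY")
  assert_space(reference, "RGB8")
  hw <- config$working_size
  gray01 <- resize_image(target$pixels, hw[1L], hw[2L])[, , 1L] / 255
  x0 <- array(rep(gray01, 3L), c(hw[1L], hw[2L], 3L))
  ref01 <- resize_image(reference$pixels, hw[1L], hw[2L]) / 255

  all_ids <- union(names(config$style_layers), names(config$content_layers))
  unknown <- setdiff(all_ids, names(extractor$taps))
  if (length(unknown))
    stop("unknown extractor layer(s): ", paste(unknown, collapse = ", "))
  tapidx <- extractor$taps[all_ids]
  upto <- max(tapidx)

  # fixed anchors: reference Grams at style layers, target features at
  # content layers
  tap_featmaps <- function(img) {
    fwd <- net_forward(extractor$layers, array_to_featmap(img),
                       train = FALSE, upto = upto)
    fms <- replay_tap_featmaps(extractor$layers, fwd, tapidx)
    list(fwd = fwd, fms = fms)
  }
  ref_fms <- tap_featmaps(ref01)$fms
  ref_grams <- lapply(names(config$style_layers), function(id)
    crossprod(ref_fms[[id]]$x))
  names(ref_grams) <- names(config$style_layers)
  con_fms <- tap_featmaps(x0)$fms[names(config$content_layers)]

  x <- x0
  step <- config$step_size
  loss_trace <- numeric(config$iterations)
  snapshots <- list()
  to_img <- function(a) planar_image(pmin(pmax(a, 0), 1) * 255, "RGB8")
  if (config$iterations == 0L) {
    res <- to_img(x)
    return(list(result = res, snapshots = list(),
                loss_trace = numeric(0), best_loss_trace = numeric(0)))
  }
  for (it in seq_len(config$iterations)) {
    tf <- tap_featmaps(x)
    # loss and per-tap gradients
    grads_at <- list()
    style_part <- 0
    for (id in names(config$style_layers)) {
      fmt <- tf$fms[[id]]
      N <- nrow(fmt$x); C <- ncol(fmt$x)
      Gt <- crossprod(fmt$x)
      dG <- Gt - ref_grams[[id]]
      style_part <- style_part +
        config$style_layers[[id]] * sum(dG * dG) / (2 * N * C)^2
      gF <- (4 * config$style_weight * config$style_layers[[id]] /
               (2 * N * C)^2) * (fmt$x %*% dG)
      key <- as.character(tapidx[[id]])
      grads_at[[key]] <- if (is.null(grads_at[[key]])) gF
                         else grads_at[[key]] + gF
    }
    content_part <- 0
    for (id in names(config$content_layers)) {
      fmt <- tf$fms[[id]]
      diff <- fmt$x - con_fms[[id]]$x
      content_part <- content_part +
        config$content_layers[[id]] * mean(diff * diff)
      gF <- (2 * config$content_weight * config$content_layers[[id]] /
               length(diff)) * diff
      key <- as.character(tapidx[[id]])
      grads_at[[key]] <- if (is.null(grads_at[[key]])) gF
                         else grads_at[[key]] + gF
    }
    loss_trace[it] <- config$style_weight * style_part +
      config$content_weight * content_part
    # overshooting shows up as a loss increase; halve the step when it does
    if (it > 1L && loss_trace[it] > loss_trace[it - 1L])
      step <- step / 2
    bwd <- net_backward(extractor$layers, tf$fwd, grads_at, train = FALSE)
    g <- array(bwd$d_input, dim(x))
    rms <- sqrt(mean(g * g))
    if (rms > 0) x <- x - step * g / rms
    x <- pmin(pmax(x, 0), 1)
    if (it %% config$snapshot_every == 0L)
      snapshots[[length(snapshots) + 1L]] <- to_img(x)
  }
  result <- to_img(x)
  if (config$preserve_luminance) {
    lab <- rgb_to_lab(result)$pixels
    lab[, , 1L] <- gray01 * 100
    result <- lab_to_rgb(planar_image(lab, "LAB"))
  }
  list(result = result, snapshots = snapshots, loss_trace = loss_trace,
       best_loss_trace = cummin(loss_trace))
}

# reconstruct featmaps at tapped layer indices from a cached forward pass:
# caches store layer inputs for conv, so the tap output equals the input of
# the following layer; for the deepest tap it is fwd$out when upto == idx.
replay_tap_featmaps <- function(layers, fwd, tapidx) {
  out <- list()
  upto <- length(fwd$caches)
  for (id in names(tapidx)) {
    i <- tapidx[[id]]
    if (i == upto) {
      out[[id]] <- fwd$out
    } else {
      # taps sit on rectifier outputs whose following layer (conv, pool,
      # upsample) caches its input featmap — that input IS the tap output
      nxt <- fwd$caches[[i + 1L]]
      if (is.null(nxt$in_fm))
        stop("internal: cannot replay features at layer ", i)
      out[[id]] <- nxt$in_fm
    }
  }
  out
}
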