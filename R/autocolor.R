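# Automatic colorization: an eight-block linear convolutional stack that
# maps a luminance plane to the two chroma planes of a perceptual color
# space. The encoder halves resolution three times with stride-2
# convolutions while widening to 128 feature maps at the bottleneck; the
# decoder restores the input resolution with nearest-neighbour upsampling
# followed by convolution (no transposed convolutions, no pooling anywhere).
# A 2-channel tanh head emits chroma in [-1, 1]; the input lightness is
# re-attached afterwards, so the method can only ever change color, never
# luminance.

#' Declarative description of the automatic colorization network
#'
#' The default architecture has eight blocks. Each block holds two or three
#' 3x3 convolutions, each followed by a leaky rectifier (negative slope
#' 0.2), and terminates in one batch-normalization stage. Blocks 2-4 open
#' with a stride-2 convolution (downsampling is by strided convolution
#' only); blocks 5-7 open with a nearest-neighbour x2 upsampling stage, so
#' the output returns to the input resolution. Block 4 is the bottleneck
#' with 128 feature maps. After block 8 a 2-channel tanh head maps to
#' chroma in `[-1, 1]`.
#'
#' @param input_size `c(height, width)`, each divisible by 8
#'   (default 224 x 224).
#' @param chroma_space `"LAB_AB"` or `"LUV_UV"`.
#' @param blocks optional list of custom block descriptors, each a list
#'   with fields `convs` (integer vector of 2 or 3 output-channel counts),
#'   `stride_first` (1 or 2) and `upsample_before` (logical). The default
#'   progression is used when `NULL`.
#' @return a `colorizer_spec` object (validated).
#' @export
colorizer_spec <- function(input_size = c(224L, 224L),
                           chroma_space = c("LAB_AB", "LUV_UV"),
                           blocks = NULL) {
  chroma_space <- match.arg(chroma_space)
  if (is.null(blocks)) {
    blocks <- list(
      list(convs = c(16L, 16L),   stride_first = 1L, upsample_before = FALSE),
      list(convs = c(32L, 32L),   stride_first = 2L, upsample_before = FALSE),
      list(convs = c(64L, 64L),   stride_first = 2L, upsample_before = FALSE),
      list(convs = c(128L, 128L), stride_first = 2L, upsample_before = FALSE),
      list(convs = c(64L, 64L),   stride_first = 1L, upsample_before = TRUE),
      list(convs = c(32L, 32L),   stride_first = 1L, upsample_before = TRUE),
      list(convs = c(16L, 16L),   stride_first = 1L, upsample_before = TRUE),
      list(convs = c(16L, 16L),   stride_first = 1L, upsample_before = FALSE))
  }
  spec <- structure(
    list(blocks = blocks, input_size = as.integer(input_size),
         chroma_space = chroma_space,
         feature_maps_at_bottleneck = max(vapply(blocks, function(b)
           max(b$convs), integer(1L)))),
    class = "colorizer_spec")
  validate_colorizer_spec(spec)
  spec
}

#' Validate a colorization network spec against its structural contract
#'
#' Checks, and reports by clause: exactly 8 blocks; 2 or 3 convolutions
#' per block; strides limited to 1 or 2 (downsampling by strided
#' convolution only); spatial size restored to `input_size` at the output;
#' a 128-feature-map stage present.
#'
#' @param spec a `colorizer_spec`.
#' @return `spec` invisibly; stops with the violated clause(s) otherwise.
#' @export
validate_colorizer_spec <- function(spec) {
  bad <- character(0)
  if (length(spec$blocks) != 8L)
    bad <- c(bad, sprintf("block count must be 8 (got %d)",
                          length(spec$blocks)))
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (!length(b$convs) %in% c(2L, 3L))
      bad <- c(bad, sprintf("block %d must have 2 or 3 convolutions", i))
    if (!b$stride_first %in% c(1L, 2L))
      bad <- c(bad, sprintf("block %d stride must be 1 or 2", i))
    if (any(b$convs < 1L))
      bad <- c(bad, sprintf("block %d channel counts must be positive", i))
  }
  h <- spec$input_size[1L]; w <- spec$input_size[2L]
  for (b in spec$blocks) {
    if (isTRUE(b$upsample_before)) { h <- 2L * h; w <- 2L * w }
    if (b$stride_first == 2L) { h <- ceiling(h / 2); w <- ceiling(w / 2) }
  }
  if (h != spec$input_size[1L] || w != spec$input_size[2L])
    bad <- c(bad, sprintf(
      "spatial size not restored at output (%dx%d after blocks, input %dx%d)",
      h, w, spec$input_size[1L], spec$input_size[2L]))
  if (spec$input_size[1L] %% 8L != 0L || spec$input_size[2L] %% 8L != 0L)
    bad <- c(bad, "input_size must be divisible by 8")
  if (length(bad)) stop("invalid colorizer spec:\n  - ",
                        paste(bad, collapse = "\n  - "))
  invisible(spec)
}

# index of the layer ending the bottleneck block (deepest stride-2 block)
.bottleneck_block <- function(spec) {
  s2 <- which(vapply(spec$blocks, function(b) b$stride_first == 2L, logical(1)))
  if (length(s2)) max(s2) else 4L
}

# flatten block descriptors into engine layers; records block boundaries
.colorizer_layers <- function(spec) {
  layers <- list()
  block_end <- integer(length(spec$blocks))
  c_in <- 1L
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (isTRUE(b$upsample_before)) layers <- c(layers, list(layer_upsample()))
    for (k in seq_along(b$convs)) {
      stride <- if (k == 1L) b$stride_first else 1L
      layers <- c(layers, list(layer_conv(c_in, b$convs[k], stride),
                               layer_lrelu(0.2)))
      c_in <- b$convs[k]
    }
    layers <- c(layers, list(layer_bn(c_in)))
    block_end[i] <- length(layers)
  }
  # output head: 2-channel conv + tanh, outside the blocks
  layers <- c(layers, list(layer_conv(c_in, 2L, 1L), layer_tanh()))
  list(layers = layers, block_end = block_end)
}

#' Build an (untrained) automatic colorizer
#'
#' Instantiates the layer graph described by the spec with seeded
#' He-normal weight initialization. An untrained model is fully usable:
#' it emits arbitrary (but valid, `[-1, 1]`) chroma, so colorization
#' before training still produces a well-formed color image.
#'
#' @param spec a [colorizer_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `colorizer` object with fields `spec`, `layers` (the weight
#'   container), `history` (per-epoch training loss, empty until trained).
#' @export
build_colorizer <- function(spec = colorizer_spec(), seed = 0L) {
  validate_colorizer_spec(spec)
  lg <- .colorizer_layers(spec)
  structure(list(spec = spec,
                 layers = init_net_weights(lg$layers, seed),
                 block_end = lg$block_end,
                 history = numeric(0)),
            class = "colorizer")
}

#' @export
print.colorizer <- function(x, ...) {
  np <- sum(vapply(x$layers, function(ly)
    if (ly$type == "conv") length(ly$W) + length(ly$b)
    else if (ly$type == "bn") 2L * ly$channels else 0L, numeric(1)))
  cat(sprintf(
    "<colorizer %d blocks, %s, input %dx%d, %d parameters, %s>\n",
    length(x$spec$blocks), x$spec$chroma_space,
    x$spec$input_size[1L], x$spec$input_size[2L], np,
    if (length(x$history)) sprintf("trained %d epochs", length(x$history))
    else "untrained"))
  invisible(x)
}

# forward a batch of lightness planes (list of H x W matrices, values [0,100])
# returns list(chroma = fm in [-1,1], bottleneck_channels)
.colorizer_forward <- function(model, L_list, train = FALSE) {
  fm <- stack_featmap(lapply(L_list, function(L)
    array(L / 100, c(dim(L), 1L))))
  fwd <- net_forward(model$layers, fm, train = train)
  fwd
}

#' Channel width of the bottleneck activation
#'
#' Runs one luminance image through the network and reports how many
#' feature maps the deepest (bottleneck) block emits.
#'
#' @param model a `colorizer`.
#' @param gray a GRAY `planar_image` (resized internally to the spec's
#'   input size); a seeded flat image is used when omitted.
#' @return integer channel count of the bottleneck activation.
#' @export
bottleneck_channels <- function(model, gray = NULL) {
  sz <- model$spec$input_size
  if (is.null(gray))
    gray <- planar_image(array(128, c(sz[1L], sz[2L], 1L)), "GRAY")
  assert_space(gray, "GRAY")
  L <- resize_image(gray$pixels, sz[1L], sz[2L])[, , 1L] * (100 / 255)
  upto <- model$block_end[.bottleneck_block(model$spec)]
  fwd <- net_forward(model$layers,
                     stack_featmap(list(array(L / 100, c(dim(L), 1L)))),
                     train = FALSE, upto = upto)
  ncol(fwd$out$x)
}

#' Training configuration for the automatic colorizer
#'
#' `steps_per_epoch` is derived as `ceiling(n_images / batch_size)` when a
#' dataset is attached at training time; supplying it explicitly is only a
#' consistency check. Default batch size 50 makes a 2,100-image dataset
#' resolve to 42 steps per epoch; the 30-image regime with batch size 10
#' resolves to 3.
#'
#' @param epochs positive integer.
#' @param batch_size positive integer (default 50).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed driving shuffling.
#' @param chroma_space `"LAB_AB"` or `"LUV_UV"`; must match the model.
#' @param steps_per_epoch optional; checked against the dataset.
#' @return a `training_config` object.
#' @export
training_config <- function(epochs, batch_size = 50L, learning_rate = 1e-3,
                            seed = 0L, chroma_space = c("LAB_AB", "LUV_UV"),
                            steps_per_epoch = NULL) {
  chroma_space <- match.arg(chroma_space)
  if (epochs < 1L) stop("epochs must be positive")
  if (batch_size < 1L) stop("batch_size must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 chroma_space = chroma_space,
                 steps_per_epoch = steps_per_epoch),
            class = "training_config")
}

# load a paired manifest into lightness planes and scaled-chroma targets
# at the model's input size; manifest: data.frame or path to manifest.tsv
.load_paired <- function(manifest, dir = NULL, spec) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  if (nrow(manifest) == 0L) stop("empty dataset")
  sz <- spec$input_size
  L_list <- vector("list", nrow(manifest))
  T_list <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fp <- if (is.null(dir)) manifest$file[i] else
      file.path(dir, manifest$file[i])
    img <- read_image(fp)
    img <- planar_image(resize_image(img$pixels, sz[1L], sz[2L]), img$space)
    per <- if (spec$chroma_space == "LAB_AB") rgb_to_lab(img)
           else rgb_to_luv(img)
    L_list[[i]] <- per$pixels[, , 1L]
    raw <- chroma_pair(per$pixels[, , 2:3],
                       space = spec$chroma_space, normalization = "raw")
    T_list[[i]] <- scale_chroma(raw, "to_network")$values
  }
  list(L = L_list, target = T_list)
}

#' Train the automatic colorizer by chroma regression
#'
#' Minimizes the mean-squared error between predicted and true
#' network-scaled chroma with Adam. Shuffling, initialization and every
#' other source of randomness are seeded, so identical seed/config/data
#' give identical loss histories.
#'
#' @param model a `colorizer` from [build_colorizer()].
#' @param dataset a paired manifest: the data.frame returned by
#'   [generate_dataset()] (`kind = "paired"`) or a path to its
#'   `manifest.tsv`.
#' @param config a [training_config()]; its `chroma_space` must match the
#'   model's.
#' @param dataset_dir directory holding the manifest's image files
#'   (required when `dataset` is a data.frame of bare filenames).
#' @param verbose print per-epoch loss lines.
#' @return the trained `colorizer`, with `history` holding one mean
#'   training loss per epoch.
#' @export
train_colorizer <- function(model, dataset, config, dataset_dir = NULL,
                            verbose = FALSE) {
  if (!inherits(model, "colorizer")) stop("expected a colorizer")
  if (!inherits(config, "training_config")) stop("expected a training_config")
  if (config$chroma_space != model$spec$chroma_space)
    stop(sprintf("chroma_space mismatch: config %s vs model %s",
                 config$chroma_space, model$spec$chroma_space))
  data <- .load_paired(dataset, dataset_dir, model$spec)
  n <- length(data$L)
  steps <- as.integer(ceiling(n / config$batch_size))
  if (!is.null(config$steps_per_epoch) && config$steps_per_epoch != steps)
    stop(sprintf("steps_per_epoch=%d inconsistent with ceiling(%d/%d)=%d",
                 config$steps_per_epoch, n, config$batch_size, steps))
  layers <- model$layers
  state <- adam_state(layers)
  t_step <- 0L
  history <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq_len(steps)) {
        ids <- ord[((s - 1L) * config$batch_size + 1L):
                     min(s * config$batch_size, n)]
        fm <- stack_featmap(lapply(data$L[ids], function(L)
          array(L / 100, c(dim(L), 1L))))
        tg <- do.call(rbind, lapply(data$target[ids], function(a)
          matrix(a, length(a) / 2L, 2L)))
        fwd <- net_forward(layers, fm, train = TRUE)
        diff <- fwd$out$x - tg
        loss <- mean(diff * diff)
        dY <- 2 * diff / length(diff)
        bwd <- net_backward(layers, fwd,
                            stats::setNames(list(dY),
                                            as.character(length(layers))),
                            train = TRUE)
        layers <- bn_update_running(layers, fwd)
        t_step <- t_step + 1L
        upd <- adam_update(layers, state, bwd$d_params,
                           config$learning_rate, t_step)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + loss
      }
      history[ep] <- ep_loss / steps
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.6f", ep, config$epochs,
                        history[ep]))
    }
  })
  model$layers <- layers
  model$history <- c(model$history, history)
  model
}

#' Colorize a grayscale image with a trained model
#'
#' The input is resized to the network's input size for prediction; the
#' predicted chroma is mapped back to raw units, bilinearly upsampled to
#' the original resolution, merged with the ORIGINAL lightness channel,
#' and converted to RGB. Output size equals input size, and luminance is
#' preserved by construction.
#'
#' @param model a `colorizer` (an untrained one yields a neutral-gray
#'   rendition).
#' @param gray a GRAY `planar_image` of any size.
#' @return an RGB8 `planar_image` with the input's height and width.
#' @export
colorize_image <- function(model, gray) {
  if (!inherits(model, "colorizer")) stop("expected a colorizer")
  assert_space(gray, "GRAY")
  sz <- model$spec$input_size
  L_orig <- gray_to_lightness(gray)
  L_net <- resize_image(gray$pixels, sz[1L], sz[2L])[, , 1L] * (100 / 255)
  fwd <- .colorizer_forward(model, list(L_net), train = FALSE)
  chroma_net <- array(fwd$out$x, c(sz[1L], sz[2L], 2L))
  scaled <- chroma_pair(chroma_net, space = model$spec$chroma_space,
                        normalization = "network_scaled")
  raw <- scale_chroma(scaled, "from_network")$values
  raw_up <- resize_image(raw, gray$height, gray$width)
  per <- array(c(L_orig, raw_up), c(gray$height, gray$width, 3L))
  # chroma is gamut-mapped at fixed lightness, so the input luminance
  # survives the RGB rendering exactly (up to 8-bit quantization)
  render_preserving_lightness(
    per, if (model$spec$chroma_space == "LAB_AB") "LAB" else "LUV")
}

#' Save / load a colorizer checkpoint
#'
#' The checkpoint is a single-file container holding the spec, all layer
#' weights and statistics, and the training-loss history.
#'
#' @param model a `colorizer`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `colorizer` (load).
#' @export
save_colorizer <- function(model, path) {
  if (!inherits(model, "colorizer")) stop("expected a colorizer")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_colorizer
#' @export
load_colorizer <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "colorizer")) stop("not a colorizer checkpoint: ", path)
  model
}
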