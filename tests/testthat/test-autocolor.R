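test_that("the default network conforms to its architectural contract", {
  spec <- colorizer_spec()
  expect_length(spec$blocks, 8)
  expect_true(all(vapply(spec$blocks, function(b)
    length(b$convs) %in% c(2L, 3L), logical(1))))
  expect_equal(spec$feature_maps_at_bottleneck, 128)
  expect_equal(spec$input_size, c(224L, 224L))
  # no pooling layers anywhere in the realized graph
  model <- build_colorizer(colorizer_spec(c(64, 64)), seed = 1)
  types <- vapply(model$layers, `[[`, character(1), "type")
  expect_false("maxpool" %in% types)
  expect_equal(sum(types == "bn"), 8)        # one batch norm per block
  expect_equal(types[length(types)], "tanh") # bounded 2-channel head
  expect_equal(model$layers[[length(model$layers) - 1L]]$c_out, 2L)
})

test_that("structural validation names the violated clause", {
  spec <- colorizer_spec()
  bad <- spec
  bad$blocks <- bad$blocks[1:5]
  expect_error(validate_colorizer_spec(bad), "block count must be 8")
  bad2 <- spec
  bad2$blocks[[3]]$convs <- c(8L, 8L, 8L, 8L)
  expect_error(validate_colorizer_spec(bad2),
               "block 3 must have 2 or 3 convolutions")
  bad3 <- spec
  bad3$blocks[[7]]$upsample_before <- FALSE
  expect_error(validate_colorizer_spec(bad3), "not restored")
})

test_that("the bottleneck activation carries 128 feature maps", {
  model <- build_colorizer(colorizer_spec(), seed = 2)
  expect_equal(bottleneck_channels(model), 128)
})

test_that("forward output is H x W x 2 in [-1, 1] and untrained output is valid", {
  model <- build_colorizer(colorizer_spec(c(64, 64)), seed = 3)
  gray <- generate_lung_phantom(phantom_spec("healthy", c(64, 64), 4))
  fwd <- ctcolor:::.colorizer_forward(
    model, list(gray_to_lightness(gray)))
  expect_equal(nrow(fwd$out$x), 64 * 64)
  expect_equal(ncol(fwd$out$x), 2)
  expect_true(all(abs(fwd$out$x) <= 1))
  out <- colorize_image(model, gray)
  expect_equal(out$space, "RGB8")
  expect_equal(c(out$height, out$width), c(64L, 64L))
})

test_that("output size follows the input even when it differs from 224", {
  model <- build_colorizer(colorizer_spec(c(64, 64)), seed = 3)
  gray <- flat_gray(120, 41, 57)
  out <- colorize_image(model, gray)
  expect_equal(c(out$height, out$width), c(41L, 57L))
  expect_error(colorize_image(model, flat_rgb(1, 2, 3)),
               "invalid color space")
})

test_that("a zeroed output head renders the neutral-gray rendition", {
  model <- build_colorizer(colorizer_spec(c(64, 64)), seed = 5)
  nl <- length(model$layers)
  model$layers[[nl - 1L]]$W[] <- 0
  model$layers[[nl - 1L]]$b[] <- 0
  gray <- generate_lung_phantom(phantom_spec("healthy", c(64, 64), 6))
  out <- colorize_image(model, gray)
  ab <- rgb_to_lab(out)$pixels[, , 2:3]
  expect_lt(max(abs(ab)), 1e-6)
})

test_that("luminance is preserved for arbitrary (even untrained) models", {
  for (space in c("LAB_AB", "LUV_UV")) {
    model <- build_colorizer(colorizer_spec(c(64, 64), space), seed = 8)
    gray <- flat_gray(0, 64, 64)
    gray$pixels[, , 1] <- matrix(seq(0, 255, length.out = 64 * 64), 64)
    out <- colorize_image(model, gray)
    L_back <- rgb_to_lab(out)$pixels[, , 1] * 2.55
    expect_lt(max(abs(L_back - gray$pixels[, , 1])), 1)
  }
})

test_that("training reduces chroma regression loss and is reproducible", {
  td <- file.path(tempdir(), "train8")
  man <- generate_dataset(8, "paired", seed = 5, out_dir = td,
                          size = c(64, 64))
  spec <- colorizer_spec(c(64, 64))
  cfg <- training_config(epochs = 12, batch_size = 8, seed = 11)
  m1 <- train_colorizer(build_colorizer(spec, seed = 3), man, cfg,
                        dataset_dir = td)
  expect_length(m1$history, 12)
  expect_lt(m1$history[12], m1$history[1])
  m2 <- train_colorizer(build_colorizer(spec, seed = 3), man, cfg,
                        dataset_dir = td)
  expect_identical(m1$history, m2$history)
})

test_that("training rejects inconsistent configs and empty datasets", {
  td <- file.path(tempdir(), "train2")
  man <- generate_dataset(2, "paired", seed = 1, out_dir = td,
                          size = c(24, 24))
  spec <- colorizer_spec(c(64, 64))
  model <- build_colorizer(spec, seed = 1)
  bad_steps <- training_config(epochs = 1, batch_size = 50,
                               steps_per_epoch = 42)
  expect_error(train_colorizer(model, man, bad_steps, dataset_dir = td),
               "steps_per_epoch")
  luv_cfg <- training_config(epochs = 1, chroma_space = "LUV_UV")
  expect_error(train_colorizer(model, man, luv_cfg, dataset_dir = td),
               "chroma_space mismatch")
  expect_error(train_colorizer(model, man[0, ],
                               training_config(epochs = 1),
                               dataset_dir = td),
               "empty dataset")
  expect_error(training_config(epochs = 0), "epochs")
})

test_that("checkpoints round-trip spec, weights and history", {
  model <- build_colorizer(colorizer_spec(c(64, 64)), seed = 4)
  model$history <- c(0.5, 0.4)
  p <- tempfile(fileext = ".rds")
  save_colorizer(model, p)
  back <- load_colorizer(p)
  expect_identical(back$history, model$history)
  expect_identical(back$layers, model$layers)
})
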