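test_that("gram_matrix matches the double-loop oracle and simple cases", {
  expect_equal(gram_matrix(array(0, c(4, 4, 3))), matrix(0, 3, 3))
  expect_equal(gram_matrix(array(1, c(2, 2, 1))), matrix(4, 1, 1))
  # two channels over two positions: channel1 = (1,0), channel2 = (0,1)
  f <- array(c(1, 0, 0, 1), c(2, 1, 2))
  expect_equal(gram_matrix(f), diag(2))
  set.seed(21)
  for (rep in 1:5) {
    feats <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
    G <- gram_matrix(feats)
    G0 <- oracle_gram(feats)
    expect_lt(max(abs(G - G0)) / max(abs(G0)), 1e-10)
    expect_equal(G, t(G))
    expect_true(all(eigen(G, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
  expect_error(gram_matrix(array(numeric(0), c(0, 0, 3))), "empty")
})

test_that("transfer_loss reproduces a brute-force fixture and isolates terms", {
  set.seed(33)
  ft <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  fr <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  fc <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  cfg <- style_transfer_config(style_layers = c(block1_conv1 = 0.7),
                               content_layers = c(block1_conv1 = 1.3),
                               style_weight = 2, content_weight = 0.5,
                               iterations = 1)
  got <- transfer_loss(list(block1_conv1 = ft), list(block1_conv1 = fr),
                       list(block1_conv1 = fc), cfg)
  want <- oracle_transfer_loss(ft, fr, fc, 0.7, 1.3, 2, 0.5)
  expect_equal(got$total, want$total, tolerance = 1e-12)
  expect_equal(got$style_part, want$style, tolerance = 1e-12)
  expect_equal(got$content_part, want$content, tolerance = 1e-12)
  # self-loss is zero
  self <- transfer_loss(list(block1_conv1 = ft), list(block1_conv1 = ft),
                        list(block1_conv1 = ft), cfg)
  expect_equal(self$total, 0)
  # style_weight = 0 leaves exactly the weighted content term
  cfg0 <- style_transfer_config(style_layers = c(block1_conv1 = 0.7),
                                content_layers = c(block1_conv1 = 1.3),
                                style_weight = 0, content_weight = 0.5,
                                iterations = 1)
  got0 <- transfer_loss(list(block1_conv1 = ft), list(block1_conv1 = fr),
                        list(block1_conv1 = fc), cfg0)
  expect_equal(got0$total, 0.5 * got0$content_part)
  expect_error(
    transfer_loss(list(block1_conv1 = ft), list(), list(), cfg),
    "block1_conv1")
})

test_that("the default extractor spec matches the five-block contract", {
  spec <- feature_extractor_spec()
  expect_length(spec$blocks, 5)
  expect_equal(spec$blocks[[1]], c(2L, 64L))
  expect_equal(spec$kernel, c(3L, 3L))
  expect_equal(spec$stride, 1L)
})

test_that("extractor convolutions preserve spatial size at stride 1", {
  extr <- build_feature_extractor(small_extractor_spec(), seed = 2)
  img <- generate_meat_texture(texture_spec("pork", c(40, 58), 3))
  feats <- extract_features(extr, img, c("block1_conv2", "block2_conv1"))
  expect_equal(dim(feats$block1_conv2), c(40, 58, 8))
  # after one 2x2 pool the second block halves the grid
  expect_equal(dim(feats$block2_conv1), c(20, 29, 16))
  expect_error(extract_features(extr, img, "block9_conv1"), "block9_conv1")
})

test_that("transfer with zero iterations returns the initialization", {
  target <- generate_lung_phantom(phantom_spec("healthy", c(32, 32), 5))
  ref <- generate_meat_texture(texture_spec("steak", c(32, 32), 6))
  cfg <- style_transfer_config(iterations = 0, working_size = c(32L, 32L))
  tr <- transfer_colors(target, ref, small_extractor_spec(), cfg)
  expect_length(tr$snapshots, 0)
  expect_length(tr$loss_trace, 0)
  init <- resize_image(target$pixels, 32, 32)[, , 1]
  expect_equal(tr$result$pixels[, , 1], init, tolerance = 1e-9)
  expect_equal(tr$result$pixels[, , 2], init, tolerance = 1e-9)
})

test_that("content-only transfer initialized at the content anchor stays put", {
  target <- generate_lung_phantom(phantom_spec("healthy", c(32, 32), 5))
  ref <- generate_meat_texture(texture_spec("steak", c(32, 32), 6))
  cfg <- style_transfer_config(style_weight = 0, content_weight = 1,
                               iterations = 4, working_size = c(32L, 32L))
  tr <- transfer_colors(target, ref, small_extractor_spec(), cfg)
  init <- resize_image(target$pixels, 32, 32)[, , 1]
  expect_equal(tr$loss_trace, rep(0, 4))
  expect_lt(max(abs(tr$result$pixels[, , 1] - init)), 1e-9)
})

test_that("best-so-far loss is non-increasing and snapshots are bookkept", {
  extr <- build_feature_extractor(small_extractor_spec(), seed = 6)
  target <- generate_lung_phantom(phantom_spec("healthy", c(64, 64), 21))
  ref <- generate_meat_texture(texture_spec("steak", c(64, 64), 22))
  cfg <- style_transfer_config(iterations = 30, snapshot_every = 10,
                               working_size = c(64L, 64L), seed = 6)
  tr <- transfer_colors(target, ref, extr, cfg)
  expect_length(tr$loss_trace, 30)
  expect_true(all(diff(tr$best_loss_trace) <= 0))
  expect_lt(tr$loss_trace[30], tr$loss_trace[1])
  expect_length(tr$snapshots, 3)  # floor(30 / 10)
  tr2 <- transfer_colors(target, ref, extr, cfg)
  expect_identical(tr$result$pixels, tr2$result$pixels)
})

test_that("a red reference pushes the result's mean a-channel upward", {
  extr <- build_feature_extractor(small_extractor_spec(), seed = 6)
  target <- generate_lung_phantom(phantom_spec("healthy", c(64, 64), 21))
  ref <- generate_meat_texture(texture_spec("steak", c(64, 64), 22))
  cfg <- style_transfer_config(iterations = 30, working_size = c(64L, 64L),
                               seed = 6)
  tr <- transfer_colors(target, ref, extr, cfg)
  gray01 <- resize_image(target$pixels, 64, 64)[, , 1]
  init <- planar_image(array(rep(gray01, 3), c(64, 64, 3)), "RGB8")
  a_init <- mean(rgb_to_lab(init)$pixels[, , 2])
  a_res <- mean(rgb_to_lab(tr$result)$pixels[, , 2])
  expect_gt(a_res, a_init)
})

test_that("configs reject degenerate weight and iteration choices", {
  expect_error(style_transfer_config(style_weight = 0, content_weight = 0),
               "at least one")
  expect_error(style_transfer_config(step_size = 0), "step_size")
  expect_error(style_transfer_config(snapshot_every = 0), "snapshot_every")
})
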