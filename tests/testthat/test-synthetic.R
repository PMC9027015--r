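test_that("texture generation is a pure function of its spec", {
  spec <- texture_spec("steak", c(32, 32), seed = 42)
  a <- generate_meat_texture(spec)
  b <- generate_meat_texture(spec)
  expect_identical(a$pixels, b$pixels)
  c_ <- generate_meat_texture(texture_spec("steak", c(32, 32), seed = 43))
  expect_false(identical(a$pixels, c_$pixels))
})

test_that("palette construction gives steak a red cast and lamb more fat", {
  steak <- generate_meat_texture(texture_spec("steak", c(64, 64), seed = 7))
  expect_gt(mean(steak$pixels[, , 1]), mean(steak$pixels[, , 3]))
  lamb <- generate_meat_texture(texture_spec("lamb", c(64, 64), seed = 7))
  near_white <- function(img)
    mean(img$pixels[, , 1] > 200 & img$pixels[, , 2] > 200 &
           img$pixels[, , 3] > 200)
  expect_gte(near_white(lamb), near_white(steak))
})

test_that("pork and steak are separable by a nearest-centroid rule", {
  mean_rgb <- function(cls, seed)
    apply(generate_meat_texture(
      texture_spec(cls, c(32, 32), seed))$pixels, 3, mean)
  pork <- t(sapply(1:10, function(s) mean_rgb("pork", s)))
  steak <- t(sapply(1:10, function(s) mean_rgb("steak", s + 100)))
  cen_p <- colMeans(pork); cen_s <- colMeans(steak)
  classify <- function(x)
    if (sum((x - cen_p)^2) < sum((x - cen_s)^2)) "pork" else "steak"
  preds <- c(apply(pork, 1, classify), apply(steak, 1, classify))
  truth <- rep(c("pork", "steak"), each = 10)
  expect_gte(mean(preds == truth), 0.9)
})

test_that("texture spec validation rejects bad inputs", {
  expect_error(generate_meat_texture(texture_spec("pork", c(8, 8))),
               "at least 16")
  expect_error(texture_spec("lamb", marbling_fraction = 0.1), "lamb")
  expect_error(texture_spec("pork", marbling_fraction = 1.5), "\\[0, 1\\]")
})

test_that("phantoms have dark lung fields in a bright body", {
  ph <- generate_lung_phantom(phantom_spec("healthy", c(64, 64), seed = 3))
  mask <- attr(ph, "lung_mask")
  expect_true(is.matrix(mask) && any(mask))
  img <- ph$pixels[, , 1]
  expect_lt(mean(img[mask]), mean(img[!mask]))
})

test_that("infiltrates brighten the lung fields of infected phantoms", {
  healthy <- generate_lung_phantom(phantom_spec("healthy", c(64, 64), 9))
  infected <- generate_lung_phantom(
    phantom_spec("infected", c(64, 64), 9, infiltrate_count = 3))
  mask <- attr(healthy, "lung_mask")
  expect_gt(mean(infected$pixels[, , 1][mask]),
            mean(healthy$pixels[, , 1][mask]))
  expect_identical(healthy$pixels,
                   generate_lung_phantom(
                     phantom_spec("healthy", c(64, 64), 9))$pixels)
})

test_that("phantom condition and infiltrate count are mutually constrained", {
  expect_error(phantom_spec("healthy", infiltrate_count = 2),
               "infiltrate_count = 0")
  expect_error(phantom_spec("infected", infiltrate_count = 0),
               ">= 1")
})

test_that("datasets conserve counts and manifests are reproducible", {
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  m1 <- generate_dataset(6, "textures", seed = 5, out_dir = d1,
                         size = c(24, 24))
  expect_equal(nrow(m1), 6)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  m2 <- generate_dataset(6, "textures", seed = 5, out_dir = d2,
                         size = c(24, 24))
  expect_identical(m1, m2)
})

test_that("paired datasets store the lightness rendition of each color member", {
  d <- file.path(tempdir(), "synth_paired")
  m <- generate_dataset(3, "paired", seed = 8, out_dir = d, size = c(24, 24))
  for (i in seq_len(nrow(m))) {
    col <- read_image(file.path(d, m$file[i]))
    gray <- read_image(file.path(d, m$gray_file[i]))
    L255 <- rgb_to_lab(col)$pixels[, , 1] * 2.55
    expect_lt(max(abs(gray$pixels[, , 1] - L255)), 1 + 0.51)
  }
})
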