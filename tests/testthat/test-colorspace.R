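test_that("Lab conversion matches the CIE reference chain", {
  # reference white and black
  lab_w <- rgb_to_lab(flat_rgb(255, 255, 255))$pixels[1, 1, ]
  expect_equal(lab_w, c(100, 0, 0), tolerance = 1e-3,
               ignore_attr = TRUE)
  lab_k <- rgb_to_lab(flat_rgb(0, 0, 0))$pixels[1, 1, ]
  expect_equal(lab_k, c(0, 0, 0), tolerance = 1e-3, ignore_attr = TRUE)
  # saturated red against an independent scalar computation
  expected <- oracle_rgb_to_lab(255, 0, 0)
  got <- rgb_to_lab(flat_rgb(255, 0, 0))$pixels[1, 1, ]
  expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(expected), c(53.2408, 80.0925, 67.2032),
               tolerance = 1e-4)
})

test_that("Luv conversion matches the CIE reference chain", {
  luv_w <- rgb_to_luv(flat_rgb(255, 255, 255))$pixels[1, 1, ]
  expect_equal(luv_w, c(100, 0, 0), tolerance = 1e-3, ignore_attr = TRUE)
  luv_k <- rgb_to_luv(flat_rgb(0, 0, 0))$pixels[1, 1, ]
  expect_equal(luv_k, c(0, 0, 0), tolerance = 1e-3, ignore_attr = TRUE)
  expected <- oracle_rgb_to_luv(255, 0, 0)
  got <- rgb_to_luv(flat_rgb(255, 0, 0))$pixels[1, 1, ]
  expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(expected), c(53.2408, 175.0150, 37.7564),
               tolerance = 1e-4)
})

test_that("conversions agree with an established converter on the red primary", {
  skip_if_not_installed("farver")
  mine <- rgb_to_lab(flat_rgb(255, 0, 0))$pixels[1, 1, ]
  ref <- farver::convert_colour(matrix(c(255, 0, 0), 1), "rgb", "lab")
  expect_equal(unname(mine), as.numeric(ref), tolerance = 0.01)
})

test_that("inverse conversions recover the forward examples", {
  red_lab <- planar_image(
    array(rep(c(53.24, 80.09, 67.20), each = 4), c(2, 2, 3)), "LAB")
  expect_equal(lab_to_rgb(red_lab)$pixels[1, 1, ], c(255, 0, 0),
               tolerance = 1, ignore_attr = TRUE)
  white_lab <- planar_image(array(rep(c(100, 0, 0), each = 4),
                                  c(2, 2, 3)), "LAB")
  expect_equal(lab_to_rgb(white_lab)$pixels[1, 1, ], c(255, 255, 255),
               tolerance = 1e-3, ignore_attr = TRUE)
  red_luv <- planar_image(
    array(rep(c(53.24, 175.05, 37.75), each = 4), c(2, 2, 3)), "LUV")
  expect_equal(luv_to_rgb(red_luv)$pixels[1, 1, ], c(255, 0, 0),
               tolerance = 1, ignore_attr = TRUE)
  black_luv <- planar_image(array(0, c(2, 2, 3)), "LUV")
  expect_equal(luv_to_rgb(black_luv)$pixels[1, 1, ], c(0, 0, 0),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("round trips are within one intensity level on a 512-triplet grid", {
  set.seed(512)
  grid <- matrix(sample(0:255, 512 * 3, replace = TRUE), ncol = 3)
  img <- planar_image(array(c(grid[, 1], grid[, 2], grid[, 3]),
                            c(512, 1, 3)), "RGB8")
  rt_lab <- lab_to_rgb(rgb_to_lab(img))
  expect_lt(max(abs(rt_lab$pixels - img$pixels)), 1)
  rt_luv <- luv_to_rgb(rgb_to_luv(img))
  expect_lt(max(abs(rt_luv$pixels - img$pixels)), 1)
})

test_that("neutral axis maps to zero chroma and L is monotone in gray level", {
  v <- 0:255
  img <- planar_image(array(rep(v, 3), c(256, 1, 3)), "RGB8")
  lab <- rgb_to_lab(img)$pixels
  luv <- rgb_to_luv(img)$pixels
  expect_lt(max(abs(lab[, , 2:3])), 1e-3)
  expect_lt(max(abs(luv[, , 2:3])), 1e-3)
  expect_true(all(diff(lab[, 1, 1]) > 0))
})

test_that("invalid spaces are rejected", {
  g <- flat_gray(128)
  expect_error(rgb_to_lab(g), "invalid color space")
  expect_error(lab_to_rgb(flat_rgb(1, 2, 3)), "invalid color space")
  expect_error(rgb_to_luv(g), "invalid color space")
})

test_that("chroma scaling maps boundaries, fixes zero, and inverts exactly", {
  ab <- chroma_pair(array(rep(c(128, -128), each = 4), c(2, 2, 2)), "LAB_AB")
  sc <- scale_chroma(ab, "to_network")
  expect_equal(unique(as.vector(sc$values[, , 1])), 1)
  expect_equal(unique(as.vector(sc$values[, , 2])), -1)
  zero <- scale_chroma(chroma_pair(array(0, c(2, 2, 2)), "LAB_AB"),
                       "to_network")
  expect_true(all(zero$values == 0))
  set.seed(7)
  vals <- array(runif(2 * 3 * 2, -100, 100), c(2, 3, 2))
  c0 <- chroma_pair(vals, "LUV_UV")
  back <- scale_chroma(scale_chroma(c0, "to_network"), "from_network")
  expect_equal(back$values, vals)
  expect_error(scale_chroma(scale_chroma(c0, "to_network"), "to_network"),
               "double scaling")
  expect_error(scale_chroma(c0, "from_network"), "double scaling")
})

test_that("image files round-trip through write and read", {
  img <- generate_meat_texture(texture_spec("pork", c(24, 24), seed = 1))
  for (ext in c("png", "tiff")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_equal(back$space, "RGB8")
    expect_lt(max(abs(back$pixels - round(img$pixels))), 0.51)
  }
  gray <- flat_gray(77, 10, 12)
  p <- tempfile(fileext = ".png")
  write_image(gray, p)
  expect_equal(read_image(p)$space, "GRAY")
})
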