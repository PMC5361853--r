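test_that("load_image rescales 8-bit and 16-bit rasters to [0,1]", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(204, 128, 26) / 255
  p <- tempfile(fileext = ".png")
  png::writePNG(px, p)
  img <- load_image(p, plot_id = "p1", date = "2014-11-07")
  expect_equal(img$pixels[1, 1, ], c(0.8, 128 / 255, 26 / 255), tolerance = 1e-6)
  expect_identical(img$plot_id, "p1")
  expect_identical(img$date, as.Date("2014-11-07"))

  p16 <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(array(runif(2 * 3 * 3), c(2, 3, 3)), p16, bits.per.sample = 16L)
  img16 <- load_image(p16)
  expect_lte(max(img16$pixels), 1.0)
  expect_gte(min(img16$pixels), 0.0)
})

test_that("load_image enforces the channel and I/O contracts", {
  expect_error(load_image(tempfile(fileext = ".png")), class = "ccpipe_io_error")

  p <- tempfile(fileext = ".png")
  set.seed(99)
  png::writePNG(array(runif(20 * 20 * 3), c(20, 20, 3)), p)
  raw <- readBin(p, "raw", file.size(p))
  writeBin(raw[1:100], p)   # truncated mid-stream
  expect_error(load_image(p), class = "ccpipe_io_error")

  gray <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), gray)
  expect_error(load_image(gray), class = "ccpipe_channel_error")

  rgba <- tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(4, 4, 4)), rgba)
  expect_error(load_image(rgba), class = "ccpipe_channel_error")
  expect_identical(dim(load_image(rgba, drop_alpha = TRUE)$pixels), c(4L, 4L, 3L))
})

test_that("colour planes follow the HSV and Lab conventions", {
  gray <- flat_image(c(0.5, 0.5, 0.5))
  cp <- to_color_planes(gray)
  expect_equal(max(abs(cp$S)), 0, tolerance = 1e-3)
  expect_equal(max(abs(cp$a)), 0, tolerance = 1e-3)
  expect_equal(max(abs(cp$b)), 0, tolerance = 1e-3)

  red <- flat_image(c(1, 0, 0))
  cpr <- to_color_planes(red)
  expect_equal(cpr$H[1, 1], 0)
  expect_equal(cpr$S[1, 1], 1)
  expect_equal(cpr$V[1, 1], 1)

  img <- random_image(seed = 7)
  cpx <- to_color_planes(img)
  expect_equal(cpx$V, pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3]))
  expect_true(all(cpx$S >= 0 & cpx$S <= 1))
  expect_true(all(cpx$L >= 0 & cpx$L <= 100))
})

test_that("vegetation-index formulas match hand evaluation", {
  img <- flat_image(c(0.5, 0.7, 0.2))
  expect_equal(compute_vi(img, "ExR")$values[1, 1], 1.4 * 0.5 - 0.7)
  expect_equal(compute_vi(img, "ExB")$values[1, 1], 1.4 * 0.2 - 0.7)

  gray <- flat_image(c(0.3, 0.3, 0.3))
  expect_equal(compute_vi(gray, "NDI3")$values[1, 1], 0)

  img2 <- flat_image(c(0.8, 0.5, 0.1))
  expect_equal(compute_vi(img2, "NDI2")$values[1, 1], (0.8 - 0.1) / (0.8 + 0.1))
  expect_equal(compute_vi(img2, "NDI3")$values[1, 1], 1.1 / 1.5)

  black <- flat_image(c(0, 0, 0))
  expect_equal(compute_vi(black, "NDI2")$values[1, 1], 0)
  expect_equal(compute_vi(black, "NDI3")$values[1, 1], 0)

  expect_error(compute_vi(img, "NDVI"), class = "ccpipe_config_error")
})

test_that("NDI2 and NDI3 stay within [-1, 1] over an exhaustive channel grid", {
  g <- seq(0, 1, by = 0.05)
  grid <- expand.grid(R = g, G = g, B = g)
  px <- array(0, c(nrow(grid), 1, 3))
  px[, 1, ] <- as.matrix(grid)
  img <- rgb_image(px)
  for (vi in c("NDI2", "NDI3")) {
    v <- compute_vi(img, vi)$values
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("compute_vi commutes with spatial permutation of pixels", {
  img <- random_image(10, 10, seed = 3)
  set.seed(4)
  perm <- sample(100)
  pixperm <- img$pixels
  for (ch in 1:3) pixperm[, , ch] <- matrix(as.vector(img$pixels[, , ch])[perm], 10, 10)
  imgp <- rgb_image(pixperm)
  v <- as.vector(compute_vi(img, "NDI3")$values)
  vp <- as.vector(compute_vi(imgp, "NDI3")$values)
  expect_equal(vp, v[perm])
})

test_that("product indices are element-wise products with the documented rescale", {
  img <- random_image(9, 11, seed = 5)
  cp <- to_color_planes(img)
  ndi3 <- compute_vi(img, "NDI3")$values
  ndi2 <- compute_vi(img, "NDI2")$values

  expect_equal(compute_product_vi(img, "NDI3V")$values, ndi3 * cp$V)
  a01 <- (cp$a - min(cp$a)) / diff(range(cp$a))
  expect_equal(compute_product_vi(img, "NDI3a")$values, ndi3 * a01)
  expect_equal(compute_product_vi(img, "NDI2a")$values, ndi2 * a01)

  # NDI3V equals NDI3 wherever V = 1, and is 0 wherever NDI3 = 0
  sat <- which(cp$V == 1)
  ndi3v <- compute_product_vi(img, "NDI3V")$values
  expect_equal(ndi3v[sat], ndi3[sat])

  gray <- flat_image(c(0.4, 0.4, 0.4))
  expect_warning(pv <- compute_product_vi(gray, "NDI3a"),
                 class = "ccpipe_degenerate_warning")
  expect_equal(pv$values, compute_vi(gray, "NDI3")$values * 0.5)
})

test_that("pixel feature tables have the canonical 10 columns and exact lookups", {
  img <- random_image(2, 2, seed = 9)
  tab <- extract_pixel_features(img)
  expect_identical(names(tab), PIXEL_FEATURES)
  expect_identical(ncol(tab), 10L)
  expect_identical(nrow(tab), 4L)

  big <- random_image(20, 20, seed = 10)
  set.seed(11)
  idx <- sample(400, 100)
  sub <- extract_pixel_features(big, pixels = idx)
  expect_identical(nrow(sub), 100L)
  expect_equal(sub$R, as.vector(big$pixels[, , 1])[idx])
  expect_equal(sub$G, as.vector(big$pixels[, , 2])[idx])
  expect_equal(sub$B, as.vector(big$pixels[, , 3])[idx])
  expect_error(extract_pixel_features(big, pixels = c(1, 401)),
               class = "ccpipe_value_error")
})

test_that("index planes survive a float-TIFF inspection round trip", {
  img <- random_image(6, 8, seed = 12)
  vi <- compute_vi(img, "NDI3")
  f <- tempfile(fileext = ".tif")
  write_vi_tiff(vi, f)
  back <- tiff::readTIFF(f)
  rng <- range(vi$values)
  expect_equal(back * diff(rng) + rng[1], vi$values, tolerance = 1e-6)
})
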