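vi_from_matrix <- function(m, name = "test") {
  px <- array(0, c(nrow(m), ncol(m), 3))
  structure(list(values = m, vi_name = name), class = "vi_image")
}

test_that("Otsu matches the brute-force between-class-variance maximiser", {
  for (seed in 1:10) {
    set.seed(seed)
    v <- c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05))
    vi <- vi_from_matrix(matrix(v, 100, 100))
    expect_equal(otsu_threshold(vi)$threshold, otsu_bruteforce(v),
                 info = paste("seed", seed))
  }
})

test_that("Otsu separates a perfect bimodal sample and rejects constants", {
  vi <- vi_from_matrix(matrix(c(0, 0, 0, 1, 1), 1, 5))
  t <- otsu_threshold(vi)$threshold
  expect_gt(t, 0)
  expect_lt(t, 1)
  m <- apply_threshold(vi, t)
  expect_identical(sum(m), 2L)

  expect_error(otsu_threshold(vi_from_matrix(matrix(0.4, 4, 4))),
               class = "ccpipe_degenerate")
})

test_that("Otsu is antisymmetric under negation up to one bin width", {
  set.seed(21)
  v <- runif(4000)
  vi <- vi_from_matrix(matrix(v, 40, 100))
  vin <- vi_from_matrix(matrix(-v, 40, 100))
  bw <- diff(range(v)) / 256
  expect_lt(abs(otsu_threshold(vin)$threshold + otsu_threshold(vi)$threshold), bw + 1e-12)
})

test_that("muRow finds one peak per crop row and a separating threshold", {
  s <- small_scene(rows = 6, cc = 0.3, seed = 3, size = c(100, 150))
  vi <- compute_index(s$image, "NDI3V")
  res <- murow_threshold(vi)
  expect_identical(length(res$peaks), 6L)
  expect_identical(res$axis, "vertical_rows")
  plant_mu <- mean(vi$values[s$truth == 1])
  soil_mu <- mean(vi$values[s$truth == 0])
  expect_gt(res$threshold, soil_mu)
  expect_lt(res$threshold, plant_mu)
  # threshold is the arithmetic mean of the smoothed profile at the peaks
  expect_equal(res$threshold, mean(res$smoothed_profile[res$peaks]))
})

test_that("muRow threshold is the mean of the detected peak values", {
  # three wide bumps with distinct heights on a flat background; each image
  # column is constant so the column-means profile is exact
  n <- 150
  prof <- rep(0.1, n)
  bump <- function(center, height) height * exp(-((seq_len(n) - center) / 8)^2)
  prof <- prof + bump(30, 0.50) + bump(75, 0.54) + bump(120, 0.52)
  vi <- vi_from_matrix(matrix(rep(prof, each = 40), 40, n))
  res <- murow_threshold(vi, row_axis = "vertical_rows")
  expect_identical(length(res$peaks), 3L)
  expect_equal(res$threshold, mean(res$smoothed_profile[res$peaks]))
  expect_equal(res$threshold, mean(c(0.60, 0.64, 0.62)), tolerance = 0.02)
})

test_that("muRow raises a no-rows error on structureless images", {
  expect_error(murow_threshold(vi_from_matrix(matrix(0.2, 60, 90))),
               class = "ccpipe_no_rows")
  # profile-flat but pixel-wise bimodal: a checkerboard has identical column
  # and row means everywhere, so no row structure is detectable either way
  chk <- outer(1:60, 1:90, function(i, j) 0.1 + 0.6 * ((i + j) %% 2))
  expect_error(murow_threshold(vi_from_matrix(chk)), class = "ccpipe_no_rows")
})

test_that("muRow is equivariant under affine index rescaling", {
  s <- small_scene(rows = 8, cc = 0.3, seed = 5, size = c(100, 160))
  vi <- compute_index(s$image, "NDI3V")
  t1 <- murow_threshold(vi)$threshold
  vi2 <- vi
  vi2$values <- 2.5 * vi$values + 0.3
  expect_equal(murow_threshold(vi2)$threshold, 2.5 * t1 + 0.3, tolerance = 1e-8)
})

test_that("auto axis orientation follows the crop rows", {
  s <- small_scene(rows = 7, cc = 0.3, seed = 8, size = c(100, 150))
  vi <- compute_index(s$image, "NDI3V")
  res_v <- murow_threshold(vi, "auto")
  expect_identical(res_v$axis, "vertical_rows")
  vit <- vi
  vit$values <- t(vi$values)
  res_h <- murow_threshold(vit, "auto")
  expect_identical(res_h$axis, "horizontal_rows")
  expect_equal(res_h$threshold, res_v$threshold)
})

test_that("apply_threshold uses the strict > convention and is monotone", {
  vi <- vi_from_matrix(matrix(c(0.1, 0.5, 0.9), 1, 3))
  expect_identical(as.vector(apply_threshold(vi, 0.5)), c(0L, 0L, 1L))
  expect_identical(sum(apply_threshold(vi, 0.05)), 3L)
  expect_identical(sum(apply_threshold(vi, 0.9)), 0L)
  set.seed(6)
  viu <- vi_from_matrix(matrix(runif(500), 20, 25))
  counts <- sapply(seq(0, 1, by = 0.1), function(t) sum(apply_threshold(viu, t)))
  expect_true(all(diff(counts) <= 0))
})
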