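train_table_from_scenes <- function(scenes, n_per_class = 800L) {
  do.call(rbind, lapply(seq_along(scenes), function(i)
    pixel_training_table(scenes[[i]]$image, scenes[[i]]$truth,
                         n_per_class = n_per_class, seed = i)))
}

test_that("DT and SVM nearly perfectly fit a separable pixel table", {
  scenes <- lapply(1:3, function(s) small_scene("LLC", seed = s))
  tab <- train_table_from_scenes(scenes, 1700L)  # ~10k rows
  expect_gte(nrow(tab), 10000L)

  # one-feature oracle: a plain NDI3V cut must already separate the classes,
  # establishing that >= 0.99 accuracy is attainable before any model runs
  cut <- mean(tapply(tab$NDI3V, tab$label, mean))
  expect_gte(mean((tab$NDI3V > cut) == tab$label), 0.99)

  for (alg in c("DT", "SVM")) {
    m <- train_pixel_model(tab, alg, "LLC", seed = 1)
    expect_gte(m$summary$training_accuracy, 0.99)
  }
})

test_that("training enforces schema, class presence, and the pixel budget", {
  s <- small_scene(seed = 4)
  tab <- pixel_training_table(s$image, s$truth, n_per_class = 500, seed = 1)
  expect_error(train_pixel_model(tab[tab$label == 1, ], "DT"),
               class = "ccpipe_train_error")
  expect_error(train_pixel_model(tab[, -1], "DT"), class = "ccpipe_schema_error")

  m <- train_pixel_model(tab, "DT", seed = 1, max_pixels = 200L)
  expect_lte(sum(m$summary$n_per_class), 220L)  # stratified subsample
  expect_gt(min(m$summary$n_per_class), 0L)
})

test_that("identical seeds give identical trained predictions", {
  s <- small_scene(seed = 5)
  tab <- pixel_training_table(s$image, s$truth, n_per_class = 600, seed = 1)
  probe <- small_scene(seed = 6)
  for (alg in c("DT", "SVM")) {
    m1 <- train_pixel_model(tab, alg, seed = 9, max_pixels = 800L)
    m2 <- train_pixel_model(tab, alg, seed = 9, max_pixels = 800L)
    expect_identical(as.vector(segment_supervised(m1, probe$image)),
                     as.vector(segment_supervised(m2, probe$image)))
  }
})

test_that("segmentation memorizes pure-class images and matches feature-wise prediction", {
  s <- small_scene(seed = 7)
  tab <- pixel_training_table(s$image, s$truth, n_per_class = 800, seed = 1)
  m <- train_pixel_model(tab, "DT", "LLC", seed = 1)

  plant_img <- flat_image(c(0.75, 0.55, 0.15), 6, 6)  # plant colour model mean
  soil_img <- flat_image(c(0.45, 0.40, 0.35), 6, 6)
  expect_true(all(segment_supervised(m, plant_img) == 1L))
  expect_true(all(segment_supervised(m, soil_img) == 0L))

  # pipeline consistency: full-image segmentation == row-wise prediction on
  # the extracted feature table
  probe <- small_scene(seed = 8, size = c(40, 60))
  mask <- segment_supervised(m, probe$image)
  feats <- extract_pixel_features(probe$image)
  pred <- ccpipe:::predict_pixels(m, feats)
  expect_identical(as.vector(mask), pred)
})

test_that("an LLC-trained model segments LLC scenes accurately", {
  scenes <- lapply(11:13, function(s) small_scene("LLC", seed = s))
  tab <- train_table_from_scenes(scenes)
  m <- train_pixel_model(tab, "DT", "LLC", seed = 1)
  test_scene <- small_scene("LLC", seed = 7)
  q <- evaluate_segmentation(segment_supervised(m, test_scene$image), test_scene$truth)
  expect_gte(q$qseg, 0.9)
})

test_that("scenario routing picks the matching model with ALC fallback", {
  s <- small_scene(seed = 20, size = c(40, 60))
  tab <- pixel_training_table(s$image, s$truth, n_per_class = 300, seed = 1)
  m_llc <- train_pixel_model(tab, "DT", "LLC", seed = 1)
  m_hlc <- train_pixel_model(tab, "DT", "HLC", seed = 1)
  m_alc <- train_pixel_model(tab, "DT", "ALC", seed = 1)

  bank <- model_bank(ALC = m_alc, HLC = m_hlc, LLC = m_llc)
  expect_identical(route_scenario(bank, 1L)$scenario, "LLC")
  expect_identical(route_scenario(bank, 2L)$scenario, "HLC")

  partial <- model_bank(ALC = m_alc)
  expect_warning(got <- route_scenario(partial, 2L), class = "ccpipe_fallback_warning")
  expect_identical(got$scenario, "ALC")

  expect_error(route_scenario(model_bank(), 1L), class = "ccpipe_config_error")
  expect_error(model_bank(LLC = m_hlc), class = "ccpipe_config_error")
})

test_that("k-means recovers three separable colour populations", {
  # plant / dry soil / wet soil, well separated in (a, b); plant has the
  # highest NDI3 by construction
  set.seed(30)
  h <- 60L; w <- 90L
  kind <- matrix(sample(1:3, h * w, replace = TRUE, prob = c(0.3, 0.4, 0.3)), h, w)
  cols <- rbind(c(0.75, 0.55, 0.10),   # plant (high NDI3)
                c(0.55, 0.42, 0.30),   # dry soil
                c(0.25, 0.20, 0.18))   # wet soil
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- cols[kind, ch] + rnorm(h * w, sd = 0.01)
  img <- rgb_image(pmin(pmax(px, 0), 1))

  mask <- segment_kmeans(img, seed = 1)
  recall <- sum(mask == 1L & kind == 1L) / sum(kind == 1L)
  expect_gte(recall, 0.99)
  # precision too: the other two populations stay background
  expect_lte(sum(mask == 1L & kind != 1L) / sum(kind != 1L), 0.01)

  expect_identical(as.vector(segment_kmeans(img, seed = 1)), as.vector(mask))

  two <- flat_image(c(0.2, 0.2, 0.2), 4, 4)
  two$pixels[1, 1, ] <- c(0.9, 0.1, 0.1)
  expect_error(segment_kmeans(rgb_image(two$pixels)), class = "ccpipe_degenerate")
})

test_that("externally labeled pixel tables round-trip through CSV", {
  s <- small_scene(seed = 40, size = c(30, 45))
  tab <- pixel_training_table(s$image, s$truth, n_per_class = 100, seed = 1)
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read_pixel_table(f)
  expect_equal(back$NDI3V, tab$NDI3V, tolerance = 1e-12)
  bad <- tab[, c("R", "G", "label")]
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_pixel_table(f), class = "ccpipe_schema_error")
})
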