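test_that("band_threshold uses inclusive bounds", {
  img <- raster_image(matrix(c(0, 175, 176, 255), 2, 2))
  m <- band_threshold(img, 0, 175)
  expect_true(m[1, 1]); expect_true(m[2, 1])   # 175 is wall
  expect_false(m[1, 2]); expect_false(m[2, 2]) # 176 is background
  expect_true(all(band_threshold(img, 0, 255)))
  expect_error(band_threshold(img, 200, 100), "invalid band")

  toy <- raster_image(matrix(c(10, 180, 50, 200, 175, 255, 0, 190,
                               30, 250, 240, 230, 220, 210, 205, 195), 4, 4))
  expect_equal(sum(band_threshold(toy, 0, 175)), 5)
})

test_that("clean_mask removes small specks and fills enclosed holes", {
  m <- matrix(FALSE, 9, 9)
  m[2, 2] <- TRUE                       # single-pixel speck
  m[5:9, 1:9] <- TRUE                   # large block (area 45)
  m[7, 5] <- FALSE                      # 1-px hole inside the block
  out <- clean_mask(m, min_speck_area = 5, max_hole_area = 5)
  expect_false(out[2, 2])
  expect_true(out[7, 5])
  expect_equal(sum(out), 45)

  big <- matrix(TRUE, 5, 5); big[1, ] <- FALSE
  expect_equal(clean_mask(big, 5, 5), big)  # one large component untouched

  # component-labeling oracle: areas {1, 3, 40}
  m2 <- matrix(FALSE, 10, 12)
  m2[1, 1] <- TRUE
  m2[3, 5:7] <- TRUE
  m2[6:9, 1:10] <- TRUE
  out3 <- clean_mask(m2, min_speck_area = 3, max_hole_area = 0)
  expect_equal(sum(out3), 43)           # {3, 40} survive at threshold 3
  out4 <- clean_mask(m2, min_speck_area = 4, max_hole_area = 0)
  expect_equal(sum(out4), 40)           # only {40} survives at threshold 4
})

test_that("edm matches the brute-force oracle and treats borders as wall-safe", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(edm(m)[3, 3], 1)

  strip <- matrix(FALSE, 7, 9); strip[3:5, ] <- TRUE
  d <- edm(strip)
  # border is not background: center row is 2 from the strip edges
  expect_true(all(d[4, ] == 2))
  expect_true(all(d[3, ] == 1))

  expect_true(all(edm(matrix(FALSE, 4, 6)) == 0))
  expect_error(edm(matrix(TRUE, 3, 3)), "no background")

  for (seed in 1:25) {
    m <- random_mask(seed)
    expect_equal(edm(m), oracle_edm(m))
  }
})

test_that("thin_walls thresholds the distance map monotonically", {
  strip <- matrix(FALSE, 9, 12); strip[3:7, ] <- TRUE  # 5-px-wide strip
  d <- edm(strip)
  expect_equal(thin_walls(strip, d, 0), strip)
  expect_true(all(!thin_walls(strip, d, max(d) + 1)))
  t2 <- thin_walls(strip, d, 2)
  expect_equal(unname(rowSums(t2)), c(0, 0, 0, 12, 12, 12, 0, 0, 0))

  prev <- strip
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    cur <- thin_walls(strip, d, k)
    expect_true(all(!cur | prev))  # larger threshold never adds pixels
    prev <- cur
  }
})

test_that("pixel classifier separates a two-intensity image perfectly", {
  set.seed(3)
  p <- matrix(200, 20, 20)
  p[, 9:11] <- 40
  img <- raster_image(p)
  scrib <- matrix(0L, 20, 20)
  wall_at <- which(p == 40); int_at <- which(p == 200)
  scrib[sample(wall_at, 10)] <- 1L
  scrib[sample(int_at, 10)] <- 2L
  clf <- train_classifier(img, scrib, seed = 99)
  expect_equal(clf$train_accuracy, 1.0)
  m1 <- classify(img, clf)
  expect_equal(m1, band_threshold(img, 0, 120))  # separating band
  expect_identical(m1, classify(img, clf))       # deterministic

  const <- raster_image(matrix(200, 20, 20))
  expect_true(all(!classify(const, clf)))

  scrib_one <- scrib; scrib_one[scrib_one == 2L] <- 0L
  expect_error(train_classifier(img, scrib_one), "insufficient training data")
})

test_that("classifier reaches 0.90 pixel accuracy on a noisy honeycomb", {
  g <- honeycomb_graph(3, 3, edge_len = 20, wall_thickness = 2)
  r <- render_image(g, px_per_um = 2, wall_px = 3, noise_sigma = 10, seed = 5)
  truth_wall <- unclass(r$truth) == 0
  set.seed(21)
  scrib <- matrix(0L, nrow(truth_wall), ncol(truth_wall))
  scrib[sample(which(truth_wall), 200)] <- 1L
  scrib[sample(which(!truth_wall), 200)] <- 2L
  clf <- train_classifier(r$image, scrib, seed = 42)
  pred <- classify(r$image, clf)
  acc <- mean(pred == truth_wall)
  expect_gte(acc, 0.90)
})
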