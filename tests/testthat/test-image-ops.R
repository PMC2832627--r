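test_that("black top-hat matches a brute-force closing oracle", {
  # single dark pixel: becomes a bright peak of its full depth
  m <- matrix(200, 5, 5)
  m[3, 3] <- 100
  bt <- black_top_hat(m, 3)
  expect_equal(bt[3, 3], 100)
  expect_true(all(bt[-13] == 0))
  expect_equal(bt, brute_force_closing(m, 3) - m)

  # dark square larger than the element: interior response is zero
  big <- matrix(200, 15, 15)
  big[4:12, 4:12] <- 50
  bt2 <- black_top_hat(big, 5)
  expect_true(all(bt2[6:10, 6:10] == 0))

  # random rasters agree with the oracle away from the border (two
  # element radii of slack so border policies cannot interfere)
  set.seed(1)
  for (side in c(3, 5)) {
    img <- matrix(sample(0:255, 225, replace = TRUE), 15, 15)
    got <- black_top_hat(img, side)
    want <- brute_force_closing(img, side) - img
    expect_true(all(want >= 0))  # closing is extensive
    inner <- (1 + side):(15 - side)
    expect_equal(got[inner, inner], want[inner, inner])
  }
})

test_that("black top-hat is non-negative, zero on flat images, strict on bad elements", {
  expect_true(all(black_top_hat(matrix(37, 8, 8), 3) == 0))
  set.seed(2)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_true(all(black_top_hat(img, 5) >= 0))
  expect_error(black_top_hat(img, 4), "odd")
  expect_error(black_top_hat(img, 1), "odd")
})

test_that("crop_edges does the arithmetic and rejects oversized margins", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  expect_equal(dim(crop_edges(img, 10)), c(80, 80))
  expect_identical(crop_edges(img, 0), img)
  expect_equal(crop_edges(img, c(1, 2, 3, 4)), img[2:98, 4:96])
  expect_error(crop_edges(img, 60), "margins")
})

test_that("scan rotation is recovered within 0.2 degrees", {
  for (angle in c(0, 1)) {
    cfg <- rot_config(rotation_deg = angle)
    sim <- simulate_profiles(cfg)
    img <- render_image(sim$profiles[1, ], sim$truth$layout, cfg)
    expect_lt(abs(estimate_rotation(img) - angle), 0.2)
  }
})

test_that("correct_rotation undoes a synthetic rotation", {
  cfg <- rot_config(rotation_deg = 1.5)
  sim <- simulate_profiles(cfg)
  lay <- sim$truth$layout
  img <- render_image(sim$profiles[1, ], lay, cfg)
  fixed <- correct_rotation(img)
  expect_lt(abs(attr(fixed, "rotation_corrected") - 1.5), 0.2)
  # after correction the straight render is closely reproduced
  straight <- render_image(sim$profiles[1, ], lay, rot_config())
  inner <- crop_edges(fixed, lay$margin)
  straight_inner <- crop_edges(straight, lay$margin)
  expect_gt(cor(as.numeric(inner), as.numeric(straight_inner)), 0.9)
})

test_that("a constant image yields a warning and no correction", {
  img <- matrix(128L, 60, 60)
  expect_warning(out <- correct_rotation(img), "no grid signal")
  expect_equal(attr(out, "rotation_corrected"), 0)
  expect_true(all(out == 128L))
})

test_that("array images survive PNG and TIFF round-trips", {
  set.seed(3)
  img <- matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40)
  storage.mode(img) <- "integer"
  for (ext in c(".png", ".tiff")) {
    path <- withr::local_tempfile(fileext = ext)
    write_array_image(img, path)
    expect_identical(read_array_image(path), img)
  }
})
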