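test_that("segment_grid counts areas and enforces image bounds", {
  cfg <- small_config(n_antigens = 50, n_subgrid_rows = 2, n_subgrid_cols = 2,
                      spots_per_subgrid = 25)
  lay <- generate_layout(cfg)
  sim <- simulate_profiles(cfg)
  img <- crop_edges(render_image(sim$profiles[1, ], lay, cfg), lay$margin)
  areas <- segment_grid(img, lay)
  expect_equal(nrow(areas), 100L)
  # every true spot center falls inside its assigned target area
  sp <- lay$spots
  expect_true(all(sp$center_row >= sp$row0 & sp$center_row < sp$row1 &
                    sp$center_col >= sp$col0 & sp$center_col < sp$col1))
  expect_error(segment_grid(img[1:40, ], lay), "subgrid")
})

test_that("spot clustering equals the brute-force optimal 1-D 2-partition", {
  got <- cluster_spot_pixels(c(10, 10, 10, 200, 200))
  expect_equal(got$foreground, c(TRUE, TRUE, TRUE, FALSE, FALSE))

  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    v <- if (i %% 2) sample(0:255, n, replace = TRUE)
         else round(rnorm(n, 120, 40))
    if (max(v) == min(v)) next
    expect_identical(cluster_spot_pixels(v)$foreground,
                     brute_force_2partition(v))
  }
})

test_that("degenerate constant areas are flagged with empty foreground", {
  got <- cluster_spot_pixels(rep(42, 9))
  expect_true(got$flag_empty)
  expect_false(any(got$foreground))
  expect_error(cluster_spot_pixels(c(1, 2, 3)), ">= 4 pixels")
})

test_that("clustering a rendered disc recovers exactly the disc pixels", {
  cfg <- small_config(n_antigens = 4, n_subgrid_rows = 1, n_subgrid_cols = 1,
                      spots_per_subgrid = 8)
  lay <- generate_layout(cfg)
  img <- crop_edges(render_image(c(100, 0, 0, 0), lay, cfg), lay$margin)
  a <- lay$spots[1, ]
  patch <- img[(a$row0 + 1):a$row1, (a$col0 + 1):a$col1]
  fg <- matrix(cluster_spot_pixels(as.vector(patch))$foreground,
               nrow(patch), ncol(patch))
  expect_identical(fg, patch == cfg$background_level - 100)
})

test_that("spot areas grow only when the spot spills over", {
  bg <- 200
  img <- matrix(bg, 40, 40)
  # disc of radius 4 centred in a 12x12 target area: fully interior
  ctr <- c(14, 14)
  for (r in 1:40) for (c in 1:40) {
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 16) img[r, c] <- 90
  }
  rect <- c(8L, 8L, 20L, 20L)
  res <- adjust_spot_area(img, rect)
  expect_false(res$adjusted)
  expect_equal(res$rect, rect)

  # same disc but offset so it straddles the target border
  res2 <- adjust_spot_area(img, c(8L, 14L, 20L, 26L))
  expect_true(res2$adjusted)
  true_disc <- sum(img == 90)
  captured <- sum(img[res2$foreground] == 90)
  expect_gte(captured / true_disc, 0.99)
})

test_that("growth stops and flags when it would swallow a neighboring spot", {
  bg <- 200
  img <- matrix(bg, 30, 60)
  # two abutting discs either side of the rect border at col 24
  for (r in 1:30) for (c in 1:60) {
    if ((r - 15)^2 + (c - 23)^2 <= 25) img[r, c] <- 80
    if ((r - 15)^2 + (c - 31)^2 <= 25) img[r, c] <- 80
  }
  neighbor <- which((row(img) - 15)^2 + (col(img) - 31)^2 <= 25,
                    arr.ind = TRUE)
  res <- adjust_spot_area(img, c(9L, 12L, 21L, 24L), neighbor_fg = neighbor)
  expect_true(res$flag_overlap)
  # the returned area stayed clear of the neighbor disc
  expect_lte(res$rect[4], 25L)
})

test_that("spot intensity is the foreground mean with a flagged empty case", {
  proc <- matrix(c(10, 20, 30, 99), 2, 2)
  fg <- cbind(row = c(1, 2, 1), col = c(1, 1, 2))
  got <- spot_intensity(proc, fg)
  expect_equal(got$intensity, 20)
  expect_false(got$flag_empty)

  empty <- spot_intensity(proc, fg[0, , drop = FALSE])
  expect_equal(empty$intensity, 0)
  expect_true(empty$flag_empty)
})

test_that("duplicate averaging rounds half-up and handles missing replicates", {
  lay <- generate_layout(sim_config(n_antigens = 3, n_subgrid_rows = 1,
                                    n_subgrid_cols = 1,
                                    spots_per_subgrid = 6))
  m <- data.frame(
    antigen_id = c(1, 1, 2, 2, 3, 3),
    processed_mean = c(100, 110, 100, 101, 50, 999),
    flag_empty = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  got <- build_profile(m, lay)
  expect_identical(unname(got$profile), c(105L, 101L, 50L))
  expect_equal(got$flags$n_missing, c(0L, 0L, 1L))

  m$flag_empty[5:6] <- TRUE
  expect_identical(unname(build_profile(m, lay)$profile[3]), 0L)
})
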