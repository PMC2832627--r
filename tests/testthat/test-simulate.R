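test_that("simulation is reproducible and respects its contracts", {
  cfg <- panel_config()
  a <- simulate_profiles(cfg)
  b <- simulate_profiles(cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth$informative_antigens, b$truth$informative_antigens)

  expect_true(is.integer(a$profiles))
  expect_true(all(a$profiles >= 0L & a$profiles <= 255L))
  expect_equal(length(a$truth$informative_antigens),
               round(cfg$frac_informative * cfg$n_antigens))
  expect_true(all(a$truth$informative_antigens <= cfg$n_antigens))
  expect_equal(as.character(unique(a$groups)), c("group1", "group2"))
})

test_that("no effect means antigens are indistinguishable on average", {
  sim <- simulate_profiles(panel_config(effect_size = 0, seed = 3L))
  tab <- auc_table(quantile_normalize(sim$profiles), sim$groups)
  expect_lt(abs(mean(tab$auc) - 0.5), 0.02)
})

test_that("a large effect drives planted antigens to extreme AUCs", {
  sim <- simulate_profiles(panel_config(effect_size = 100, noise_sd = 5,
                                        seed = 4L))
  tab <- auc_table(quantile_normalize(sim$profiles), sim$groups)
  planted <- tab$auc[sim$truth$informative_antigens]
  # group 1 carries the shift, so planted AUCs approach 0 under the
  # group-2-higher orientation
  expect_true(all(planted < 0.1))
})

test_that("rendering honours depths, background and rotation", {
  cfg <- small_config(n_antigens = 4, n_subgrid_cols = 1,
                      n_subgrid_rows = 1, spots_per_subgrid = 8)
  lay <- generate_layout(cfg)

  flat <- render_image(rep(0, 4), lay, cfg)
  expect_true(all(flat == cfg$background_level))

  one <- render_image(c(80, 0, 0, 0), lay, cfg)
  sp <- lay$spots[lay$spots$antigen_id == 1, ]
  for (i in 1:2) {
    cr <- sp$center_row[i] + lay$margin
    cc <- sp$center_col[i] + lay$margin
    # pixels well inside the disc
    expect_equal(one[round(cr) + 1, round(cc) + 1],
                 cfg$background_level - 80)
  }
  # disc pixel count matches both duplicates of a discretized disc
  expect_equal(sum(one < cfg$background_level), 2 * sum(one[
    (round(sp$center_row[1] + lay$margin) + 1 - 4):(round(sp$center_row[1] + lay$margin) + 1 + 4),
    (round(sp$center_col[1] + lay$margin) + 1 - 4):(round(sp$center_col[1] + lay$margin) + 1 + 4)] <
      cfg$background_level))

  rot_cfg <- small_config(n_antigens = 4, n_subgrid_cols = 1,
                          n_subgrid_rows = 1, spots_per_subgrid = 8,
                          rotation_deg = 1)
  rot <- render_image(c(80, 0, 0, 0), lay, rot_cfg)
  expect_equal(attr(rot, "applied_rotation"), 1)
  expect_false(all(rot == one))
})

test_that("depths above background are clipped with a warning", {
  cfg <- small_config(n_antigens = 4, n_subgrid_cols = 1,
                      n_subgrid_rows = 1, spots_per_subgrid = 8,
                      background_level = 100)
  lay <- generate_layout(cfg)
  expect_warning(img <- render_image(c(150, 0, 0, 0), lay, cfg), "clipped")
  expect_gte(min(img), 0)
})

test_that("rendered images are byte-identical under a fixed seed", {
  cfg <- small_config(noise_sd = 8)
  sim <- simulate_profiles(cfg)
  lay <- sim$truth$layout
  a <- render_image(sim$profiles[1, ], lay, cfg, seed = 5)
  b <- render_image(sim$profiles[1, ], lay, cfg, seed = 5)
  expect_identical(a, b)
})
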