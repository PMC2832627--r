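# Small array geometries used across the suite: quick to render and
# quantify, but with >= 2 subgrids in each direction so gridding,
# rotation and adjustment are exercised for real.

small_config <- function(...) {
  defaults <- list(n_antigens = 60, n_subgrid_rows = 2, n_subgrid_cols = 3,
                   spots_per_subgrid = 20, spot_pitch = 12, spot_radius = 3,
                   margin = 16, noise_sd = 0, rotation_deg = 0,
                   n_group1 = 4, n_group2 = 4, background_gradient = 0,
                   scale_sd = 0, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Geometry for rotation-recovery tests: enough subgrids that a 1-degree
# rotation shears the grid by several pixels across the image.
rot_config <- function(...) {
  small_config(n_antigens = 120, n_subgrid_rows = 3, n_subgrid_cols = 4, ...)
}

# A profile-only panel (no image geometry constraints): 500 antigens on a
# 5x5 grid of 42-spot subgrids.
panel_config <- function(...) {
  defaults <- list(n_antigens = 500, n_subgrid_rows = 5, n_subgrid_cols = 5,
                   spots_per_subgrid = 42, n_group1 = 20, n_group2 = 20,
                   frac_informative = 0.1, effect_size = 50, noise_sd = 10,
                   seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Brute-force oracles -------------------------------------------------

# Optimal 1-D two-cluster partition: try every split of the sorted values
# (between distinct neighbors) and minimize within-cluster sum of squares
# computed naively.
brute_force_2partition <- function(v) {
  s <- sort(v)
  n <- length(s)
  best <- Inf
  best_thr <- NA_real_
  for (k in seq_len(n - 1)) {
    if (s[k] == s[k + 1]) next
    left <- s[1:k]
    right <- s[(k + 1):n]
    wss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (wss < best) {
      best <- wss
      best_thr <- s[k]
    }
  }
  v <= best_thr
}

# Midrank Mann-Whitney AUC: P(random group-2 value > random group-1
# value), ties counted one half.
ranksum_auc <- function(g1, g2) {
  r <- rank(c(g1, g2))
  n1 <- length(g1)
  n2 <- length(g2)
  (sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

# Grayscale morphological closing with a flat square element, computed
# naively with replicated borders: dilation (max filter) then erosion
# (min filter).
brute_force_closing <- function(img, side) {
  h <- (side - 1) %/% 2
  filt <- function(m, fun) {
    out <- m
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        rows <- max(1, i - h):min(nrow(m), i + h)
        cols <- max(1, j - h):min(ncol(m), j + h)
        out[i, j] <- fun(m[rows, cols])
      }
    }
    out
  }
  filt(filt(img, max), min)
}
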