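#' Simulate serum autoantibody profiles with known ground truth
#'
#' Draws a sera-by-antigens matrix of spot depths (intensity below the
#' membrane background, 0--255) with the statistical structure the
#' downstream analysis assumes: sparse baseline reactivity (exponential
#' per-antigen mean depths: most antigens weak, a few strong), a subset of
#' informative antigens shifted upward by `effect_size` in group-1 sera,
#' additive Gaussian measurement noise, and a log-normal per-serum
#' multiplicative array effect that makes quantile normalization
#' non-trivial. Values are clipped to [0, 255] and rounded to integers.
#'
#' @param config A [sim_config()]; `n_group1` and `n_group2` must be >= 2.
#' @return An object of class `serum_simulation`: list with
#'   \describe{
#'     \item{profiles}{integer matrix, sera x antigens, row/col named.}
#'     \item{groups}{factor of length `n_group1 + n_group2` with levels
#'       `group1`, `group2`.}
#'     \item{truth}{ground truth: `true_spot_depths` (the rendered depths,
#'       identical to `profiles`), `mean_depths` (noise-free expected
#'       depths), `informative_antigens` (antigen indices with a planted
#'       effect), `serum_scale` (array effects), `applied_rotation`
#'       (degrees) and the `layout`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_profiles(sim_config(n_antigens = 50, n_subgrid_rows = 2,
#'   n_subgrid_cols = 2, spots_per_subgrid = 25, n_group1 = 5, n_group2 = 5))
#' dim(sim$profiles)
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_group1 < 2L || config$n_group2 < 2L) {
    stop("need at least 2 sera per group", call. = FALSE)
  }
  layout <- generate_layout(config)
  n_ant <- config$n_antigens
  n_sera <- config$n_group1 + config$n_group2
  groups <- factor(rep(c("group1", "group2"),
                       c(config$n_group1, config$n_group2)),
                   levels = c("group1", "group2"))

  set.seed(config$seed)
  n_inf <- round(config$frac_informative * n_ant)
  informative <- sort(sample.int(n_ant, n_inf))

  baseline <- pmin(stats::rexp(n_ant, rate = 1 / max(config$baseline_mean_depth,
                                                     .Machine$double.eps)),
                   0.95 * config$background_level)
  if (config$baseline_mean_depth == 0) baseline <- numeric(n_ant)

  mu <- matrix(baseline, n_sera, n_ant, byrow = TRUE)
  if (n_inf > 0 && config$effect_size != 0) {
    mu[groups == "group1", informative] <-
      mu[groups == "group1", informative] + config$effect_size
  }
  serum_scale <- exp(stats::rnorm(n_sera, 0, config$scale_sd))
  noise <- matrix(stats::rnorm(n_sera * n_ant, 0, config$noise_sd),
                  n_sera, n_ant)
  depths <- serum_scale * (mu + noise)
  depths <- round(pmin(pmax(depths, 0), 255))
  storage.mode(depths) <- "integer"
  dimnames(depths) <- list(sprintf("S%03d", seq_len(n_sera)),
                           layout$antigen_ids)

  truth <- list(
    true_spot_depths = depths,
    mean_depths = mu,
    informative_antigens = informative,
    serum_scale = serum_scale,
    applied_rotation = config$rotation_deg,
    layout = layout
  )
  structure(list(profiles = depths, groups = groups, truth = truth,
                 config = config),
            class = "serum_simulation")
}

#' @export
print.serum_simulation <- function(x, ...) {
  cat(sprintf("Simulated serum panel: %d sera (%d vs %d) x %d antigens, %d informative\n",
              nrow(x$profiles), x$config$n_group1, x$config$n_group2,
              ncol(x$profiles), length(x$truth$informative_antigens)))
  invisible(x)
}

#' Render one serum profile as a synthetic macroarray scan
#'
#' Inverse of the quantification stage: draws each antigen's spot depth as
#' two dark discs (duplicate spots) on a brighter membrane background with
#' optional linear gradient, adds Gaussian pixel noise, applies a small
#' global rotation about the image center (bilinear resampling), and
#' re-quantizes to 8-bit integers. Depths exceeding the local background
#' are clipped to black with a warning.
#'
#' @param depths Named or plain numeric vector of per-antigen spot depths
#'   (length = number of antigens in `layout`), e.g. one row of
#'   `simulate_profiles()$profiles`.
#' @param layout A `grid_layout` from [generate_layout()].
#' @param config The [sim_config()] providing background, noise and
#'   rotation parameters.
#' @param seed Optional seed for the pixel noise; defaults to
#'   `config$seed` so a full render is reproducible.
#' @return Integer matrix (`full_height` x `full_width`) of 0--255 pixel
#'   values with attribute `applied_rotation` (degrees).
#' @examples
#' cfg <- sim_config(n_antigens = 4, n_subgrid_rows = 1, n_subgrid_cols = 1,
#'                   spots_per_subgrid = 8, noise_sd = 0)
#' img <- render_image(rep(100, 4), generate_layout(cfg), cfg)
#' range(img)
#' @export
render_image <- function(depths, layout, config, seed = config$seed) {
  stopifnot(inherits(layout, "grid_layout"))
  if (length(depths) != layout$n_antigens) {
    stop("profile length (", length(depths), ") does not match layout (",
         layout$n_antigens, " antigens)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  H <- layout$full_height
  W <- layout$full_width
  bg_row <- config$background_level +
    config$background_gradient * (seq_len(W) - 1)
  img <- matrix(bg_row, H, W, byrow = TRUE)

  clipped <- FALSE
  sp <- layout$spots
  r <- layout$spot_radius
  for (i in seq_len(nrow(sp))) {
    d <- depths[sp$antigen_id[i]]
    if (d <= 0) next
    # uncropped 0-based center -> 1-based pixel indices
    cr <- sp$center_row[i] + layout$margin
    cc <- sp$center_col[i] + layout$margin
    rows <- max(1, floor(cr - r) + 1):min(H, ceiling(cr + r) + 1)
    cols <- max(1, floor(cc - r) + 1):min(W, ceiling(cc + r) + 1)
    dr <- (rows - 1) - cr
    dc <- (cols - 1) - cc
    mask <- outer(dr^2, dc^2, `+`) <= r^2
    patch <- img[rows, cols]
    val <- patch - d
    if (any(val[mask] < 0)) clipped <- TRUE
    patch[mask] <- pmax(val[mask], 0)
    img[rows, cols] <- patch
  }
  if (clipped) {
    warning("some spot depths exceed the local background; pixels clipped to 0",
            call. = FALSE)
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
  }
  if (config$rotation_deg != 0) {
    img <- rotate_raster(img, config$rotation_deg,
                         bg = config$background_level)
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  attr(img, "applied_rotation") <- config$rotation_deg
  img
}

# Rotate a 0-255 raster about its center, keeping dimensions, bilinear
# resampling, background fill for exposed corners.
rotate_raster <- function(img, degrees, bg) {
  out <- EBImage::rotate(img / 255, degrees, filter = "bilinear",
                         output.dim = dim(img), bg.col = bg / 255)
  out <- EBImage::imageData(out) * 255
  matrix(out, nrow(img), ncol(img))
}
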