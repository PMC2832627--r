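#' Quantify a macroarray scan into an autoantibody profile
#'
#' Runs the full image-analysis pipeline on one scanned array:
#' \enumerate{
#'   \item correct the global scan rotation ([correct_rotation()]);
#'   \item crop the image edges by the layout margin ([crop_edges()]);
#'   \item segment into spot target areas ([segment_grid()]);
#'   \item per spot, split pixels into foreground/background on the *raw*
#'     image by exact 2-means clustering ([cluster_spot_pixels()]),
#'     growing the area when the spot spills over its border
#'     ([adjust_spot_area()]);
#'   \item black top-hat filter the whole raw image ([black_top_hat()]);
#'   \item measure each spot as the mean of the *processed* image over its
#'     foreground pixels ([spot_intensity()]);
#'   \item average duplicates into an integer 0--255 profile
#'     ([build_profile()]).
#' }
#'
#' @param img Pixel matrix as rendered by [render_image()] or read by
#'   [read_array_image()].
#' @param layout The `grid_layout` describing the array geometry.
#' @param se_side Structuring-element side for the top-hat; default
#'   [default_se_side()] of the layout.
#' @param adjust Grow spot areas whose foreground touches the target
#'   border (default `TRUE`).
#' @param rotate Estimate and correct the scan rotation (default `TRUE`).
#' @param crop Crop the layout margin (default `TRUE`; set `FALSE` when
#'   passing an already-cropped image).
#' @param max_grow Maximum growth steps per spot (1 pixel per side each).
#' @return Object of class `quantified_array`: list with
#'   \describe{
#'     \item{profile}{named integer vector, one 0--255 value per antigen.}
#'     \item{measurements}{per-spot table: `antigen_id`, `spot_id`,
#'       `row0`, `col0`, `row1`, `col1`, `n_fg_pixels`, `adjusted`,
#'       `flag_overlap`, `flag_empty`, `raw_mean`, `processed_mean`.}
#'     \item{rotation_corrected}{estimated scan rotation (degrees).}
#'     \item{flags}{per-antigen missing-replicate table.}
#'   }
#' @examples
#' cfg <- sim_config(n_antigens = 6, n_subgrid_rows = 1, n_subgrid_cols = 3,
#'                   spots_per_subgrid = 4, noise_sd = 0)
#' lay <- generate_layout(cfg)
#' img <- render_image(c(0, 20, 40, 60, 80, 100), lay, cfg)
#' quantify_image(img, lay)$profile
#' @export
quantify_image <- function(img, layout, se_side = NULL, adjust = TRUE,
                           rotate = TRUE, crop = TRUE, max_grow = 5L) {
  stopifnot(inherits(layout, "grid_layout"))
  if (is.null(se_side)) se_side <- default_se_side(layout)

  theta <- 0
  if (rotate) {
    img <- correct_rotation(img)
    theta <- attr(img, "rotation_corrected")
  }
  if (crop) img <- crop_edges(img, layout$margin)

  areas <- segment_grid(img, layout)
  n_spots <- nrow(areas)

  # initial clustering of every spot on the raw image
  init <- vector("list", n_spots)
  for (i in seq_len(n_spots)) {
    patch <- img[(areas$row0[i] + 1):areas$row1[i],
                 (areas$col0[i] + 1):areas$col1[i], drop = FALSE]
    cl <- cluster_spot_pixels(as.vector(patch))
    fg <- matrix(cl$foreground, nrow(patch), ncol(patch))
    idx <- which(fg, arr.ind = TRUE)
    init[[i]] <- list(
      coords = cbind(row = areas$row0[i] + idx[, 1],
                     col = areas$col0[i] + idx[, 2]),
      flag_empty = cl$flag_empty,
      # growth is only worth attempting for a coherent minority-dark
      # foreground whose border contact is a contiguous chord (>= 3
      # consecutive pixels); isolated dark noise pixels on the border
      # are not a spilling spot
      on_border = !cl$flag_empty && mean(fg) <= 0.45 &&
        spans_border(fg)
    )
  }

  # neighbor lookup by target-area cell coordinates
  pitch <- layout$spot_pitch
  cell_r <- areas$row0 %/% pitch
  cell_c <- areas$col0 %/% pitch

  res <- data.frame(
    antigen_id = areas$antigen_id, spot_id = areas$spot_id,
    row0 = areas$row0, col0 = areas$col0,
    row1 = areas$row1, col1 = areas$col1,
    n_fg_pixels = 0L, adjusted = FALSE, flag_overlap = FALSE,
    flag_empty = FALSE, raw_mean = NA_real_, processed_mean = NA_real_
  )

  coords_list <- vector("list", n_spots)
  for (i in seq_len(n_spots)) {
    if (adjust && init[[i]]$on_border) {
      nb <- which(abs(cell_r - cell_r[i]) <= 1L &
                    abs(cell_c - cell_c[i]) <= 1L)
      nb <- setdiff(nb, i)
      neighbor_fg <- do.call(rbind, lapply(init[nb], `[[`, "coords"))
      adj <- adjust_spot_area(
        img, c(areas$row0[i], areas$col0[i], areas$row1[i], areas$col1[i]),
        neighbor_fg = neighbor_fg, max_grow = max_grow
      )
      coords_list[[i]] <- adj$foreground
      res$row0[i] <- adj$rect[1]; res$col0[i] <- adj$rect[2]
      res$row1[i] <- adj$rect[3]; res$col1[i] <- adj$rect[4]
      res$adjusted[i] <- adj$adjusted
      res$flag_overlap[i] <- adj$flag_overlap
      res$flag_empty[i] <- adj$flag_empty
    } else {
      coords_list[[i]] <- init[[i]]$coords
      res$flag_empty[i] <- init[[i]]$flag_empty
    }
    res$n_fg_pixels[i] <- nrow(coords_list[[i]])
    if (res$n_fg_pixels[i] > 0) {
      res$raw_mean[i] <- mean(img[coords_list[[i]]])
    }
  }

  processed <- black_top_hat(img, se_side)
  for (i in seq_len(n_spots)) {
    m <- spot_intensity(processed, coords_list[[i]])
    res$processed_mean[i] <- m$intensity
    res$flag_empty[i] <- res$flag_empty[i] || m$flag_empty
  }

  prof <- build_profile(res, layout)
  structure(list(profile = prof$profile, measurements = res,
                 rotation_corrected = theta, flags = prof$flags,
                 se_side = se_side),
            class = "quantified_array")
}

# TRUE when the foreground touches the patch border with a contiguous
# run of at least `min_run` pixels on one side (a spilling spot's chord).
spans_border <- function(fg, min_run = 3L) {
  sides <- list(fg[1, ], fg[nrow(fg), ], fg[, 1], fg[, ncol(fg)])
  for (s in sides) {
    r <- rle(s)
    if (any(r$values & r$lengths >= min_run)) return(TRUE)
  }
  FALSE
}

#' @export
print.quantified_array <- function(x, ...) {
  cat(sprintf("Quantified macroarray: %d antigens (%d spots), rotation corrected %.2f deg\n",
              length(x$profile), nrow(x$measurements), x$rotation_corrected))
  cat(sprintf("  empty spots: %d; adjusted areas: %d; overlap flags: %d\n",
              sum(x$measurements$flag_empty), sum(x$measurements$adjusted),
              sum(x$measurements$flag_overlap)))
  invisible(x)
}

#' Quantify every serum of a simulated panel
#'
#' Convenience wrapper: renders each serum of a [simulate_profiles()]
#' result with [render_image()] and quantifies it back with
#' [quantify_image()], returning the recovered profile matrix. Useful for
#' end-to-end validation of the image pipeline against known truth.
#'
#' @param sim A `serum_simulation`.
#' @param ... Passed to [quantify_image()].
#' @return Integer matrix sera x antigens of recovered profiles.
#' @export
quantify_simulation <- function(sim, ...) {
  stopifnot(inherits(sim, "serum_simulation"))
  lay <- sim$truth$layout
  n <- nrow(sim$profiles)
  out <- matrix(0L, n, lay$n_antigens,
                dimnames = dimnames(sim$profiles))
  for (i in seq_len(n)) {
    img <- render_image(sim$profiles[i, ], lay, sim$config,
                        seed = sim$config$seed + i)
    out[i, ] <- quantify_image(img, lay, ...)$profile
  }
  out
}
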