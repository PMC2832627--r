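#' Segment a cropped array image into spot target areas
#'
#' Validates that the layout's subgrids and spot target areas fall inside
#' the image and returns the per-spot rectangles (0-based, half-open).
#'
#' @param img Cropped pixel matrix.
#' @param layout A `grid_layout`.
#' @return Data frame of spot target areas (`spot_id`, `antigen_id`,
#'   `subgrid`, `row0`, `col0`, `row1`, `col1`).
#' @export
segment_grid <- function(img, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  sp <- layout$spots
  bad <- sp$row1 > nrow(img) | sp$col1 > ncol(img) | sp$row0 < 0 | sp$col0 < 0
  if (any(bad)) {
    stop("layout exceeds image bounds (", nrow(img), " x ", ncol(img),
         ") in subgrid(s) ",
         paste(sort(unique(sp$subgrid[bad])), collapse = ", "),
         call. = FALSE)
  }
  sp[, c("spot_id", "antigen_id", "subgrid", "row0", "col0", "row1", "col1")]
}

#' Split spot-area pixels into foreground and background
#'
#' 2-means clustering of the pixel intensities of one spot target area.
#' In one dimension the optimal 2-means partition is a threshold split of
#' the sorted values, so the global optimum is found exactly and
#' deterministically by scanning all splits and minimizing the
#' within-cluster sum of squares (no random initialization). The darker
#' cluster is the foreground, because protein spots are dark on a bright
#' membrane. A zero-variance area has no spot: the whole area is assigned
#' to background and flagged.
#'
#' @param values Numeric vector of pixel intensities (>= 4 pixels).
#' @return List with `foreground` (logical vector parallel to `values`),
#'   `threshold` (foreground iff value <= threshold; `NA` when flagged),
#'   `centers` (foreground/background means), and `flag_empty`.
#' @examples
#' cluster_spot_pixels(c(10, 10, 10, 200, 200))$foreground
#' @export
cluster_spot_pixels <- function(values) {
  n <- length(values)
  if (n < 4L) stop("spot target area must contain >= 4 pixels", call. = FALSE)
  if (max(values) == min(values)) {
    return(list(foreground = rep(FALSE, n), threshold = NA_real_,
                centers = c(NA_real_, NA_real_), flag_empty = TRUE))
  }
  s <- sort(values)
  k <- seq_len(n - 1L)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  wss_left <- cs2[k] - cs[k]^2 / k
  wss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  total <- wss_left + wss_right
  # only splits between distinct values yield a valid threshold partition
  valid <- s[k] < s[k + 1L]
  total[!valid] <- Inf
  kbest <- which.min(total)
  thr <- s[kbest]
  fg <- values <= thr
  list(foreground = fg,
       threshold = thr,
       centers = c(mean(values[fg]), mean(values[!fg])),
       flag_empty = FALSE)
}

#' Grow a spot target area when the spot spills over its border
#'
#' If foreground pixels of the initial clustering touch the border of the
#' target rectangle, the rectangle is enlarged by one pixel per side and
#' re-clustered, up to `max_grow` iterations, so spots slightly larger
#' than their nominal target area are measured whole. Growth stops (and
#' the overlap flag is set) when the next expansion would swallow
#' foreground pixels of a neighboring spot.
#'
#' @param img Cropped pixel matrix.
#' @param rect Integer vector `c(row0, col0, row1, col1)`, 0-based
#'   half-open target rectangle.
#' @param neighbor_fg Optional 2-column matrix of 1-based (row, col) pixel
#'   coordinates belonging to neighboring spots' foreground.
#' @param max_grow Maximum number of 1-pixel-per-side growth steps.
#' @return List with the final `rect`, `foreground` (2-column matrix of
#'   1-based pixel coordinates), `threshold`, `adjusted`, `flag_overlap`
#'   and `flag_empty`.
#' @export
adjust_spot_area <- function(img, rect, neighbor_fg = NULL, max_grow = 5L) {
  adjusted <- FALSE
  overlap <- FALSE
  for (i in seq_len(max_grow + 1L)) {
    rows <- (rect[1] + 1):rect[3]
    cols <- (rect[2] + 1):rect[4]
    patch <- img[rows, cols, drop = FALSE]
    cl <- cluster_spot_pixels(as.vector(patch))
    fg <- matrix(cl$foreground, nrow(patch), ncol(patch))
    if (cl$flag_empty || i > max_grow) break
    on_border <- any(fg[1, ]) || any(fg[nrow(fg), ]) ||
      any(fg[, 1]) || any(fg[, ncol(fg)])
    if (!on_border) break
    grown <- c(max(rect[1] - 1L, 0L), max(rect[2] - 1L, 0L),
               min(rect[3] + 1L, nrow(img)), min(rect[4] + 1L, ncol(img)))
    if (all(grown == rect)) break
    if (!is.null(neighbor_fg) && nrow(neighbor_fg) > 0) {
      hit <- neighbor_fg[, 1] > grown[1] & neighbor_fg[, 1] <= grown[3] &
        neighbor_fg[, 2] > grown[2] & neighbor_fg[, 2] <= grown[4]
      if (any(hit)) {
        overlap <- TRUE
        break
      }
    }
    rect <- grown
    adjusted <- TRUE
  }
  idx <- which(fg, arr.ind = TRUE)
  coords <- cbind(row = rect[1] + idx[, 1], col = rect[2] + idx[, 2])
  list(rect = rect, foreground = coords, threshold = cl$threshold,
       adjusted = adjusted, flag_overlap = overlap,
       flag_empty = cl$flag_empty)
}

#' Mean processed intensity of one spot
#'
#' The spot intensity is the mean of the black-top-hat-processed pixel
#' values over the spot's foreground pixels. An empty foreground (no spot
#' detected) yields intensity 0 with a flag.
#'
#' @param processed Processed (top-hat) pixel matrix.
#' @param foreground 2-column matrix of 1-based (row, col) coordinates.
#' @return List with `intensity` and `flag_empty`.
#' @export
spot_intensity <- function(processed, foreground) {
  if (is.null(foreground) || nrow(foreground) == 0L) {
    return(list(intensity = 0, flag_empty = TRUE))
  }
  vals <- processed[foreground]
  list(intensity = mean(vals), flag_empty = FALSE)
}

#' Average duplicate spots into an autoantibody profile
#'
#' Every antigen is spotted twice; its profile value is the mean of the
#' two replicate spot intensities, rounded half-up to an integer and
#' clamped to [0, 255]. A missing (empty-foreground) replicate is dropped
#' and the antigen flagged; if both replicates are missing the value is 0.
#'
#' @param measurements Data frame with columns `antigen_id`,
#'   `processed_mean` and `flag_empty` (one row per spot), e.g. from
#'   [quantify_image()].
#' @param layout A `grid_layout` giving antigen order and names.
#' @return List with `profile` (named integer vector, one value per
#'   antigen) and `flags` (data frame `antigen_id`, `n_missing`).
#' @examples
#' m <- data.frame(antigen_id = c(1, 1), processed_mean = c(100, 101),
#'                 flag_empty = FALSE)
#' lay <- generate_layout(sim_config(n_antigens = 1, n_subgrid_rows = 1,
#'   n_subgrid_cols = 1, spots_per_subgrid = 2))
#' build_profile(m, lay)$profile  # 101: round half-up of 100.5
#' @export
build_profile <- function(measurements, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  n <- layout$n_antigens
  prof <- numeric(n)
  n_missing <- integer(n)
  for (a in seq_len(n)) {
    rows <- measurements$antigen_id == a
    vals <- measurements$processed_mean[rows]
    ok <- !measurements$flag_empty[rows]
    n_missing[a] <- sum(!ok)
    prof[a] <- if (any(ok)) mean(vals[ok]) else 0
  }
  prof <- pmin(pmax(floor(prof + 0.5), 0), 255)  # round half-up
  storage.mode(prof) <- "integer"
  names(prof) <- layout$antigen_ids
  list(profile = prof,
       flags = data.frame(antigen_id = seq_len(n), n_missing = n_missing))
}
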