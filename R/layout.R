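#' Generate the geometric grid layout of a macroarray
#'
#' Builds the geometric model of the array: subgrids tiled on the membrane,
#' each divided into square spot target areas containing exactly one protein
#' spot, and the duplicate map assigning every antigen to two distinct spot
#' positions. All rectangles are 0-based, half-open pixel coordinates
#' relative to the *cropped* image (the rendered image adds `margin` blank
#' pixels on every side).
#'
#' Spot positions are enumerated row-major: subgrids left-to-right,
#' top-to-bottom, and cells within a subgrid likewise. Antigen `i` occupies
#' positions `2i - 1` and `2i`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `grid_layout`: a list with elements
#'   `spots` (data frame: `spot_id`, `antigen_id`, `subgrid`, `row0`,
#'   `col0`, `row1`, `col1`, `center_row`, `center_col`),
#'   `subgrids` (data frame of subgrid rectangles), `n_antigens`,
#'   `spot_pitch`, `spot_radius`, `margin`, and the cropped/full image
#'   dimensions `height`, `width`, `full_height`, `full_width`.
#' @examples
#' lay <- generate_layout(sim_config(n_antigens = 10, n_subgrid_rows = 2,
#'                                   n_subgrid_cols = 2, spots_per_subgrid = 5))
#' nrow(lay$spots)  # 20 positions, 10 antigens in duplicate
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$spots_per_subgrid
  inner_cols <- ceiling(sqrt(s))
  inner_rows <- ceiling(s / inner_cols)
  pitch <- config$spot_pitch

  sub_h <- inner_rows * pitch
  sub_w <- inner_cols * pitch
  height <- config$n_subgrid_rows * sub_h
  width <- config$n_subgrid_cols * sub_w

  n_pos <- 2L * config$n_antigens
  # enumerate subgrids row-major, cells row-major, keep first n_pos
  sub_idx <- expand.grid(sc = seq_len(config$n_subgrid_cols),
                         sr = seq_len(config$n_subgrid_rows))[, c("sr", "sc")]
  cells <- expand.grid(cc = seq_len(inner_cols) - 1L,
                       cr = seq_len(inner_rows) - 1L)[, c("cr", "cc")]
  cells <- cells[seq_len(s), , drop = FALSE]  # drop unused ragged cells

  sub_rep <- sub_idx[rep(seq_len(nrow(sub_idx)), each = s), ]
  cell_rep <- cells[rep(seq_len(s), times = nrow(sub_idx)), ]
  r0 <- (sub_rep$sr - 1L) * sub_h + cell_rep$cr * pitch
  c0 <- (sub_rep$sc - 1L) * sub_w + cell_rep$cc * pitch

  keep <- seq_len(n_pos)
  spots <- data.frame(
    spot_id = keep,
    antigen_id = rep(seq_len(config$n_antigens), each = 2L),
    subgrid = (sub_rep$sr[keep] - 1L) * config$n_subgrid_cols + sub_rep$sc[keep],
    row0 = r0[keep], col0 = c0[keep],
    row1 = r0[keep] + pitch, col1 = c0[keep] + pitch,
    center_row = r0[keep] + (pitch - 1) / 2,
    center_col = c0[keep] + (pitch - 1) / 2
  )

  subgrids <- data.frame(
    subgrid = seq_len(nrow(sub_idx)),
    row0 = (sub_idx$sr - 1L) * sub_h, col0 = (sub_idx$sc - 1L) * sub_w,
    row1 = sub_idx$sr * sub_h, col1 = sub_idx$sc * sub_w
  )

  structure(list(
    spots = spots,
    subgrids = subgrids,
    n_antigens = config$n_antigens,
    antigen_ids = antigen_names(config$n_antigens),
    inner_rows = inner_rows,
    inner_cols = inner_cols,
    spot_pitch = pitch,
    spot_radius = config$spot_radius,
    margin = config$margin,
    height = height,
    width = width,
    full_height = height + 2L * config$margin,
    full_width = width + 2L * config$margin
  ), class = "grid_layout")
}

antigen_names <- function(n) sprintf("A%04d", seq_len(n))

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("Macroarray layout: %d antigens in duplicate (%d spots)\n",
              x$n_antigens, nrow(x$spots)))
  cat(sprintf("  %d subgrids, pitch %d px, cropped image %d x %d px (margin %d)\n",
              nrow(x$subgrids), x$spot_pitch, x$height, x$width, x$margin))
  invisible(x)
}

#' Write / read a grid layout as JSON
#'
#' Serializes the full geometric model, including the duplicate map, so a
#' layout produced by the simulator (or described by hand for a real scan)
#' can be fed to [quantify_image()].
#'
#' @param layout A `grid_layout`.
#' @param path File path for the JSON document.
#' @return `write_layout_json` returns `path` invisibly; `read_layout_json`
#'   returns a `grid_layout`.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "grid_layout"))
  x <- unclass(layout)
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spots <- as.data.frame(x$spots)
  x$subgrids <- as.data.frame(x$subgrids)
  needed <- c("spots", "subgrids", "n_antigens", "spot_pitch", "margin",
              "height", "width")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("layout JSON is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(x, class = "grid_layout")
}
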