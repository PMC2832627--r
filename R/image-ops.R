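#' Read / write an 8-bit grayscale array image
#'
#' Thin wrappers around the png and tiff readers that convert to the
#' package's working representation: an integer matrix of 0--255 pixel
#' values (rows = image rows). Multi-channel inputs are averaged to
#' grayscale.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param img Integer or numeric matrix with values in [0, 255].
#' @return `read_array_image` returns an integer matrix;
#'   `write_array_image` returns `path` invisibly.
#' @export
read_array_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "'", call. = FALSE)
  )
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  img <- round(x * 255)
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_array_image
#' @export
write_array_image <- function(img, path) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 255)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Estimate and correct the global rotation of a scanned array
#'
#' Scanned membranes are often slightly rotated. `estimate_rotation`
#' works on the dark (spot) pixels only: their coordinates, weighted by
#' darkness below the median background, are rotated by each candidate
#' correction angle and projected onto the row and column axes into
#' 1-pixel histogram bins (triangular splitting between adjacent bins, so
#' the criterion is continuous in the angle). The summed variance of the
#' two projection histograms peaks when the spot grid is axis-aligned.
#' Rotating point coordinates instead of resampling the image avoids the
#' interpolation blur that would otherwise bias small angles toward zero.
#' A coarse pass (0.25 degree steps over `max_deg`) is refined locally at
#' `step` resolution. `correct_rotation` applies the counter-rotation
#' (bilinear resampling) and records it.
#'
#' Angles whose shear across the image is below one pixel are physically
#' indistinguishable from zero and estimate as zero.
#'
#' @param img Integer/numeric matrix of 0--255 pixel values.
#' @param max_deg Half-width of the scanned angle range in degrees.
#' @param step Resolution of the fine scan, degrees.
#' @return `estimate_rotation`: the estimated applied rotation in degrees
#'   (so the correction rotates by its negative). `correct_rotation`: the
#'   corrected image with attribute `rotation_corrected` set to the
#'   estimate. On a degenerate image with no grid signal (no dark pixels
#'   or a flat criterion) the input is returned unchanged with a warning
#'   and an estimate of 0.
#' @examples
#' cfg <- sim_config(n_antigens = 8, n_subgrid_rows = 2, n_subgrid_cols = 2,
#'                   spots_per_subgrid = 4, noise_sd = 0, rotation_deg = 1)
#' img <- render_image(rep(120, 8), generate_layout(cfg), cfg)
#' estimate_rotation(img)
#' @export
estimate_rotation <- function(img, max_deg = 5, step = 0.05) {
  med <- stats::median(img)
  thr <- med - 0.25 * (med - min(img))
  keep <- img < thr
  if (sum(keep) < 16L) {
    warning("no grid signal detected; rotation left uncorrected",
            call. = FALSE)
    return(structure(0, flat = TRUE))
  }
  idx <- which(keep, arr.ind = TRUE)
  wt <- (med - img)[keep]
  y <- idx[, 1] - round(nrow(img) / 2)
  x <- idx[, 2] - round(ncol(img) / 2)

  proj_var <- function(p) {
    lo <- floor(p)
    f <- p - lo
    b <- lo - min(lo) + 1L
    h <- numeric(max(b) + 1L)
    vv <- rowsum(c(wt * (1 - f), wt * f), c(b, b + 1L))
    h[as.integer(rownames(vv))] <- vv
    stats::var(h)
  }
  crit <- function(a) {
    th <- a * pi / 180
    proj_var(y * cos(th) - x * sin(th)) +
      proj_var(y * sin(th) + x * cos(th))
  }

  coarse_step <- 0.25
  coarse <- seq(-max_deg, max_deg, by = coarse_step)
  cc <- vapply(coarse, crit, 0)
  if (max(cc) - min(cc) <= 1e-9 * max(abs(cc), 1)) {
    warning("no grid signal detected; rotation left uncorrected",
            call. = FALSE)
    return(structure(0, flat = TRUE))
  }
  best <- coarse[which.max(cc)]
  fine <- seq(max(best - coarse_step, -max_deg),
              min(best + coarse_step, max_deg), by = step)
  cf <- vapply(fine, crit, 0)
  # correction angle maximizing alignment; estimate of the applied
  # rotation is its negative
  -fine[which.max(cf)]
}

#' @rdname estimate_rotation
#' @export
correct_rotation <- function(img, max_deg = 5, step = 0.05) {
  theta <- estimate_rotation(img, max_deg = max_deg, step = step)
  if (isTRUE(attr(theta, "flat"))) {
    attr(img, "rotation_corrected") <- 0
    return(img)
  }
  out <- if (theta != 0) {
    m <- round(pmin(pmax(rotate_raster(img, -theta, bg = stats::median(img)),
                         0), 255))
    storage.mode(m) <- "integer"
    m
  } else {
    img
  }
  attr(out, "rotation_corrected") <- as.numeric(theta)
  out
}

#' Crop the image edges
#'
#' Virtually cuts away a margin on every side, removing membrane borders
#' and rotation fill before gridding.
#'
#' @param img Pixel matrix.
#' @param margins Either a single margin applied to all four sides or a
#'   length-4 vector `c(top, bottom, left, right)`, in pixels.
#' @return The cropped sub-matrix.
#' @export
crop_edges <- function(img, margins) {
  if (length(margins) == 1L) margins <- rep(margins, 4L)
  stopifnot(length(margins) == 4L, all(margins >= 0))
  m <- as.integer(margins)
  if (m[1] + m[2] >= nrow(img) || m[3] + m[4] >= ncol(img)) {
    stop("crop margins (", paste(m, collapse = ", "),
         ") leave no pixels of a ", nrow(img), " x ", ncol(img), " image",
         call. = FALSE)
  }
  img[(m[1] + 1):(nrow(img) - m[2]), (m[3] + 1):(ncol(img) - m[4]),
      drop = FALSE]
}

#' Black top-hat filtering of the array image
#'
#' Morphological closing of the image with a flat square structuring
#' element, minus the image. Dark features narrower than the element
#' (the protein spots) become bright peaks on a zero background; the
#' response is non-negative everywhere and zero on constant images.
#'
#' @param img Pixel matrix, values in [0, 255].
#' @param se_side Side length of the square structuring element in pixels;
#'   odd, >= 3. A practical choice is the next odd integer at least 1.5x
#'   the expected spot diameter (see [default_se_side()]).
#' @return Numeric matrix of top-hat responses (>= 0, on the 0--255 scale).
#' @examples
#' m <- matrix(200L, 7, 7); m[4, 4] <- 100L
#' black_top_hat(m, 3)[4, 4]  # 100: the dark pixel becomes a bright peak
#' @export
black_top_hat <- function(img, se_side) {
  se_side <- as.integer(se_side)
  if (se_side < 3L || se_side %% 2L == 0L) {
    stop("'se_side' must be an odd integer >= 3, got ", se_side,
         call. = FALSE)
  }
  kern <- EBImage::makeBrush(se_side, shape = "box")
  out <- EBImage::blackTopHat(img / 255, kern) * 255
  pmax(matrix(EBImage::imageData(out), nrow(img), ncol(img)), 0)
}

#' Default structuring-element side for a layout
#'
#' The next odd integer at least 1.5 times the expected spot diameter
#' (`2 * spot_radius`), so that the closing removes whole spots and the
#' top-hat response inside a spot equals its depth below background.
#'
#' @param layout A `grid_layout`.
#' @return Odd integer >= 3.
#' @export
default_se_side <- function(layout) {
  side <- ceiling(1.5 * 2 * layout$spot_radius)
  side <- max(side, 3L)
  if (side %% 2L == 0L) side <- side + 1L
  as.integer(side)
}
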